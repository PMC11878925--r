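test_that("width-1 smoothing reduces to clipped, centered residuals", {
  set.seed(4)
  v <- matrix(rpois(40 * 6, 20), 40, 6,
              dimnames = list(sprintf("g%03d", 1:40), sprintf("c%d", 1:6)))
  ann <- data.frame(gene_id = rownames(v), chromosome = rep("1", 40),
                    start = seq_len(40) * 100, end = seq_len(40) * 100 + 50)
  cm <- count_matrix(v)
  prof <- infer_cnv(cm, c("c1", "c2"), ann, window = 1, expr_cutoff = 0,
                    max_centered = 1, denoise = FALSE)
  # recompute independently from the definition
  depth <- colSums(v)
  nrm <- t(t(v) * stats::median(depth) / depth)
  lg <- log2(nrm + 1)
  resid <- lg - rowMeans(lg[, c("c1", "c2")])
  resid <- pmin(pmax(resid, -1), 1)
  resid <- sweep(resid, 2, apply(resid, 2, stats::median))
  expect_equal(prof$ratios, t(2^resid), tolerance = 1e-12)
})

test_that("reference spots stay near diploid on the null fixture", {
  prof <- default_profile()
  ref <- prof$reference_obs
  rr <- prof$ratios[match(ref, prof$obs_ids), ]
  expect_gt(mean(rr >= 0.9 & rr <= 1.1), 0.9)
  expect_equal(mean(rr), 1, tolerance = 0.02)
  # reference honesty: burden of the reference itself stays below 1.05
  b <- cnv_burden(prof)
  expect_lte(max(b$raw[b$obs_id %in% ref]), 1.05)
  # per-gene mean reference ratio is centered at 1
  ref_gene_means <- colMeans(rr)
  expect_true(all(ref_gene_means >= 0.98 & ref_gene_means <= 1.02))
})

test_that("a planted chr7 gain separates clone spots from the rest", {
  prof <- default_profile()
  tr <- default_st()$truth
  idx <- which(prof$chromosome == "7")
  clone <- tr$obs_id[tr$clone == "clone_1"]
  rest <- tr$obs_id[tr$clone != "clone_1"]
  d <- mean(prof$ratios[match(clone, prof$obs_ids), idx]) -
    mean(prof$ratios[match(rest, prof$obs_ids), idx])
  expect_gte(d, 0.15)
})

test_that("clone burden rises monotonically with the planted fold", {
  burdens <- vapply(c(1.2, 1.5, 2.0), function(fold) {
    cfg <- cohort_config(n_sections = 1, spots_per_section = 150,
                         n_cells = 10, programs = NULL,
                         clones = list(clone_spec("c1", events = list(
                           list(chromosome = "7", fraction = 1,
                                direction = "gain", fold = fold)),
                           prevalence = 0.5)), seed = 55)
    co <- generate_cohort(cfg)
    tr <- co$truth$spots
    ref <- tr$obs_id[tr$type != "tumor"]
    prof <- infer_cnv(co$sections$S1$counts, ref, co$annotation)
    b <- cnv_burden(prof)
    mean(b$raw[b$obs_id %in% tr$obs_id[tr$clone == "c1"]])
  }, numeric(1))
  expect_true(all(diff(burdens) > 0))
})

test_that("burden arithmetic follows the magnitude-mean definition", {
  mk <- function(rats) toy_profile(
    matrix(rats, nrow = 1, dimnames = list("s1", sprintf("g%d", seq_along(rats)))),
    chromosome = rep("1", length(rats)))
  expect_equal(cnv_burden(mk(rep(1, 10)))$raw, 1)
  expect_equal(cnv_burden(mk(c(rep(1.5, 5), rep(1, 5))))$raw, 1.25)
  expect_equal(cnv_burden(mk(rep(0.5, 8)))$raw, 1.5)
})

test_that("the nCNV normalization maps raw scores onto [0, 1]", {
  sc <- data.frame(obs_id = c("a", "b", "c"), raw = c(1, 1.5, 2))
  out <- normalize_cnv(sc)
  expect_equal(out$normalized, c(0, 0.5, 1))
  flat <- normalize_cnv(data.frame(obs_id = c("a", "b"), raw = c(1, 1)))
  expect_equal(flat$normalized, c(0, 0))
  one <- normalize_cnv(data.frame(obs_id = "a", raw = 1.7))
  expect_equal(one$normalized, 1)
  # invariance under pure scaling of the excess burden
  withr::with_seed(8, {
    raw <- 1 + runif(50)
    base <- normalize_cnv(data.frame(obs_id = as.character(1:50), raw = raw))
    scaled <- normalize_cnv(data.frame(obs_id = as.character(1:50),
                                       raw = 1 + 3 * (raw - 1)))
    expect_equal(base$normalized, scaled$normalized, tolerance = 1e-12)
  })
})

test_that("only eligible cells above the threshold flip to tumor", {
  labels <- data.frame(obs_id = c("m1", "m2", "f1", "e1"),
                       label = c("mesothelial", "mesothelial", "fibroblast",
                                 "endothelial"))
  scores <- data.frame(obs_id = c("m1", "m2", "f1", "e1"),
                       normalized = c(0.31, 0.30, 0.9, 0.300001))
  out <- reclassify_tumor_cells(labels, scores, threshold = 0.3)
  expect_equal(out$label, c("tumor", "mesothelial", "fibroblast", "tumor"))
  expect_error(reclassify_tumor_cells(
    data.frame(obs_id = "zz", label = "mesothelial"), scores), "zz")
})

test_that("clone detection recovers two planted clones across seeds", {
  for (s in 1:5) {
    cfg <- cohort_config(n_sections = 1, spots_per_section = 250,
                         n_cells = 10, programs = NULL, seed = 100 + s)
    co <- generate_cohort(cfg)
    tr <- co$truth$spots
    ref <- tr$obs_id[tr$type != "tumor"]
    prof <- infer_cnv(co$sections$S1$counts, ref, co$annotation)
    keep <- prof$obs_ids %in% c(tr$obs_id[tr$type == "tumor"], ref)
    prof$ratios <- prof$ratios[keep, , drop = FALSE]
    prof$obs_ids <- prof$obs_ids[keep]
    cl <- detect_clones(prof)
    expect_equal(cl$label[match(ref, cl$obs_id)],
                 rep("normal", length(ref)))
    sub <- cl[cl$label != "normal", ]
    truth <- stats::setNames(tr$clone, tr$obs_id)[sub$obs_id]
    expect_gte(ari(sub$label, truth), 0.9)
  }
})

test_that("degenerate clone structures behave as documented", {
  rat <- matrix(1, 6, 30, dimnames = list(sprintf("s%d", 1:6),
                                          sprintf("g%03d", 1:30)))
  prof <- toy_profile(rat, rep("1", 30))
  auto <- detect_clones(prof, "auto")
  expect_equal(length(unique(auto$label)), 1)
  withr::with_seed(2, {
    rat2 <- rat + matrix(runif(180, 0, 0.3), 6, 30)
  })
  prof2 <- toy_profile(rat2, rep("1", 30))
  singles <- detect_clones(prof2, n_clones = 6)
  expect_equal(length(unique(singles$label)), 6)
  expect_error(detect_clones(prof2, n_clones = 7), "exceeds")
})

test_that("segmentation calls planted whole-chromosome events", {
  prof <- default_profile()
  tr <- default_st()$truth
  clones <- data.frame(obs_id = tr$obs_id,
                       label = ifelse(tr$type == "tumor", tr$clone, "normal"))
  ev <- segment_events(prof, clones)$events
  # clone_1: one gain spanning >= 80% of chr7
  chr7_n <- sum(prof$chromosome == "7")
  e1 <- ev[ev$clone == "clone_1" & ev$chromosome == "7" & ev$state == "gain", ]
  expect_equal(nrow(e1), 1)
  expect_gte(e1$n_genes / chr7_n, 0.8)
  # clone_2: chr2 gain and chr17 loss; no chr7 event
  expect_true(any(ev$clone == "clone_2" & ev$chromosome == "2" &
                    ev$state == "gain"))
  expect_true(any(ev$clone == "clone_2" & ev$chromosome == "17" &
                    ev$state == "loss"))
  expect_false(any(ev$clone == "clone_2" & ev$chromosome == "7"))
  # gains sit above 1, losses below
  expect_true(all(ev$mean_ratio[ev$state == "gain"] > 1))
  expect_true(all(ev$mean_ratio[ev$state == "loss"] < 1))
})

test_that("flat and alternating profiles yield no events", {
  flat <- toy_profile(matrix(1, 4, 60, dimnames = list(sprintf("s%d", 1:4),
                                                       sprintf("g%03d", 1:60))),
                      rep("1", 60))
  cl <- data.frame(obs_id = sprintf("s%d", 1:4), label = "clone_1")
  expect_equal(nrow(segment_events(flat, cl)$events), 0)
  alt <- flat
  alt$ratios[] <- rep(c(1.2, 0.8), 30)
  expect_equal(nrow(segment_events(alt, cl, min_genes = 10)$events), 0)
})

test_that("event regions join onto gene sets correctly", {
  ev <- toy_events(data.frame(clone = "clone_1", chromosome = "1",
                              start_index = 5L, end_index = 8L,
                              state = "loss", mean_ratio = 0.7,
                              stringsAsFactors = FALSE), 20)
  ann <- data.frame(gene_id = ev$gene_ids, chromosome = "1",
                    start = seq_len(20), end = seq_len(20))
  sets <- list(ESTROGEN = c("g0005", "g0006"), OTHER = "g0099")
  tab <- link_events_to_gene_sets(ev, ann, sets)
  expect_equal(nrow(tab), 4)
  expect_equal(tab$set_name[tab$gene_id == "g0005"], "ESTROGEN")
  expect_equal(tab$set_name[tab$gene_id == "g0007"], "none")
  empty <- toy_events(data.frame(clone = character(), chromosome = character(),
                                 start_index = integer(), end_index = integer(),
                                 state = character(), mean_ratio = numeric(),
                                 stringsAsFactors = FALSE))
  expect_equal(nrow(link_events_to_gene_sets(empty, ann, sets)), 0)
})
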