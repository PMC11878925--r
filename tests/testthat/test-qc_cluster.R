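test_that("gene-count and mitochondrial filters apply their boundaries", {
  # s1: 399 detected genes; s2: 400; s3: 500 with mito exactly 13%
  g <- c(sprintf("g%03d", 1:500), "MT-ND1")
  v <- matrix(0L, length(g), 3, dimnames = list(g, c("s1", "s2", "s3")))
  v[1:399, 1] <- 1L
  v[1:400, 2] <- 1L
  v[1:500, 3] <- 1L
  cm <- count_matrix(v, g, c("s1", "s2", "s3"))
  expect_equal(filter_observations(cm, qc_thresholds(min_genes = 400)),
               c("s2", "s3"))
  # mito boundary: 13 mito counts over 100 total is exactly 0.13
  g2 <- c(sprintf("g%02d", 1:87), "MT-ND1")
  v2 <- matrix(0L, length(g2), 2, dimnames = list(g2, c("a", "b")))
  v2[1:87, 1] <- 1L; v2["MT-ND1", 1] <- 13L           # fraction 0.13
  v2[1:87, 2] <- 1L; v2["MT-ND1", 2] <- 12L           # fraction 0.1212
  cm2 <- count_matrix(v2, g2, c("a", "b"))
  kept <- filter_observations(cm2, qc_thresholds(max_mito_fraction = 0.13))
  expect_equal(kept, "b")
  # vacuous thresholds keep everything, in order
  expect_equal(filter_observations(cm2, qc_thresholds(0, NULL, NULL)),
               c("a", "b"))
})

test_that("filtering is idempotent and presets encode the two regimes", {
  co <- generate_cohort(cohort_config(n_sections = 1, spots_per_section = 200,
                                      n_cells = 10, n_genes = 800,
                                      baseline_mean = 0.3, seed = 2))
  cm <- co$sections$S1$counts
  kept <- filter_observations(cm, "geo")
  again <- filter_observations(subset_obs(cm, kept), "geo")
  expect_identical(kept, again)
  geo <- qc_preset("geo")
  expect_equal(geo$min_genes, 400)
  expect_null(geo$max_genes)
  prop <- qc_preset("proprietary")
  expect_equal(c(prop$min_genes, prop$max_genes, prop$max_mito_fraction),
               c(200, 4000, 0.13))
})

test_that("normalization is depth-invariant and rejects empty observations", {
  v <- cbind(a = c(2, 4, 0), b = c(4, 8, 0), d = c(1, 1, 1))
  rownames(v) <- c("g1", "g2", "g3")
  cm <- count_matrix(v)
  nm <- normalize_log(cm)
  expect_equal(as.numeric(nm$values[, "a"]), as.numeric(nm$values[, "b"]))
  v2 <- cbind(a = c(1, 2), z = c(0, 0))
  expect_error(normalize_log(count_matrix(v2, c("g1", "g2"), c("a", "z"))),
               "z")
  # single observation: log1p of median-scaled values (scale factor 1)
  one <- count_matrix(cbind(s = c(3, 1)), c("g1", "g2"), "s")
  expect_equal(as.numeric(normalize_log(one)$values[, 1]), log1p(c(3, 1)))
})

test_that("HVG selection recovers planted high-variance genes", {
  # 50 planted bimodal genes spread across the expression range of 2000
  # Poisson background genes
  set.seed(21)
  n_cells <- 120
  lambda <- exp(runif(2000, log(1), log(30)))
  v <- matrix(rpois(2000 * n_cells, lambda), 2000, n_cells,
              dimnames = list(sprintf("g%04d", 1:2000), sprintf("c%03d", 1:n_cells)))
  planted <- sample(rownames(v), 50)
  on <- sample(n_cells, n_cells / 2)
  v[planted, on] <- rpois(50 * length(on), 5 * lambda[match(planted, rownames(v))])
  nm <- normalize_log(count_matrix(v))
  top <- select_hvg(nm, 200)
  expect_gte(length(intersect(top, planted)), 45)
  # n equal to the gene count returns every gene; larger n errors
  expect_setequal(select_hvg(nm, 2000), rownames(v))
  expect_error(select_hvg(nm, 2001), "exceeds")
})

test_that("HVG ties at the cutoff break lexicographically", {
  base <- matrix(rep(c(1, 2, 1, 2), 10), nrow = 4, byrow = FALSE)
  v <- rbind(B = base[1, ], A = base[2, ], C = c(rep(1, 9), 11),
             D = rep(1.5, 10))
  nm <- structure(list(values = spathet:::to_dgc(v), gene_ids = rownames(v),
                       obs_ids = sprintf("c%d", 1:10)),
                  class = "NormalizedMatrix")
  # A and B are identical rows (tied dispersion); C is the clear top
  top2 <- select_hvg(nm, 2, n_bins = 1)
  expect_equal(sort(top2), c("A", "C"))
})

test_that("clustering separates planted populations across seeds", {
  co <- cached("twopop", function() generate_cohort(cohort_config(
    n_sections = 1, spots_per_section = 300, n_cells = 10, n_genes = 800,
    clones = list(), programs = NULL,
    cell_types = list(cell_type_spec("tumor", 50, 5),
                      cell_type_spec("fibroblast", 50, 5)),
    seed = 19)))
  nm <- normalize_log(co$sections$S1$counts)
  hv <- select_hvg(nm, 300)
  truth <- co$truth$spots$type
  for (s in 1:5) {
    cl <- embed_and_cluster(nm, hv, n_pcs = 20, resolution = 0.8, seed = s)
    expect_gte(ari(cl$label, truth), 0.9)
  }
  # determinism for a fixed seed
  c1 <- embed_and_cluster(nm, hv, seed = 3)
  c2 <- embed_and_cluster(nm, hv, seed = 3)
  expect_identical(c1, c2)
  # vanishing resolution merges everything (on a connected neighbour
  # graph; strongly separated populations can disconnect it)
  withr::with_seed(9, {
    vr <- matrix(rpois(400 * 80, 5), 400, 80,
                 dimnames = list(sprintf("g%03d", 1:400),
                                 sprintf("c%02d", 1:80)))
  })
  nmr <- normalize_log(count_matrix(vr))
  c0 <- embed_and_cluster(nmr, rownames(vr)[1:200], resolution = 1e-3,
                          seed = 1)
  expect_equal(length(unique(c0$label)), 1)
})

test_that("marker detection finds planted markers and nothing under the null", {
  co <- .fixtures$twopop %||% generate_cohort(cohort_config(
    n_sections = 1, spots_per_section = 300, n_cells = 10, n_genes = 800,
    clones = list(), programs = NULL,
    cell_types = list(cell_type_spec("tumor", 50, 5),
                      cell_type_spec("fibroblast", 50, 5)),
    seed = 19))
  nm <- normalize_log(co$sections$S1$counts)
  labels <- data.frame(obs_id = co$truth$spots$obs_id,
                       label = co$truth$spots$type)
  mk <- find_markers(nm, labels)
  tum_mk <- mk$gene_id[mk$cluster == "tumor"]
  planted <- co$truth$markers$tumor
  expect_gte(length(intersect(tum_mk, planted)) / length(planted), 0.9)
  # permutation null: label-shuffled data yields almost no marker calls
  fracs <- vapply(1:20, function(i) {
    perm <- labels
    perm$label <- withr::with_seed(1000 + i, sample(perm$label))
    pm <- find_markers(nm, perm)
    nrow(pm) / (2 * length(nm$gene_ids))
  }, numeric(1))
  expect_lte(mean(fracs), 0.05)
})

test_that("identical clusters produce no markers and tiny clusters warn", {
  v <- matrix(rpois(100 * 20, 4), 100, 20,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("c%02d", 1:20)))
  v[, 11:20] <- v[, 1:10]  # cluster B duplicates cluster A
  nm <- normalize_log(count_matrix(v))
  labels <- data.frame(obs_id = colnames(v), label = rep(c("A", "B"), each = 10))
  expect_equal(nrow(find_markers(nm, labels)), 0)
  labels$label[1:2] <- "tiny"
  labels$label[3:10] <- "A"
  expect_warning(find_markers(nm, labels), "tiny")
})

test_that("wilcoxon p-values match exact enumeration for small groups", {
  exact_wilcox_p <- function(a, b) {
    # two-sided exact p by full enumeration of group assignments
    pooled <- c(a, b)
    n1 <- length(a)
    rk <- rank(pooled)
    combs <- utils::combn(length(pooled), n1)
    stats_all <- apply(combs, 2, function(idx) sum(rk[idx]))
    w_obs <- sum(rk[seq_len(n1)])
    p_le <- mean(stats_all <= w_obs)
    p_ge <- mean(stats_all >= w_obs)
    min(1, 2 * min(p_le, p_ge))
  }
  withr::with_seed(77, {
    for (rep in 1:10) {
      n1 <- sample(3:8, 1)
      n2 <- sample(3:8, 1)
      a <- rnorm(n1)
      b <- rnorm(n2, 0.8)
      mat <- matrix(c(a, b), nrow = 1,
                    dimnames = list("g1", sprintf("c%02d", seq_len(n1 + n2))))
      res <- spathet:::marker_test_cluster(mat, seq_len(n1),
                                           n1 + seq_len(n2))
      expect_equal(res$p_value, exact_wilcox_p(a, b), tolerance = 1e-12)
    }
  })
})

test_that("cluster classification follows overlap and tie rules", {
  mk <- data.frame(cluster = c(rep("c1", 10), rep("c2", 6), rep("c3", 2)),
                   gene_id = c(sprintf("t%d", 1:10), sprintf("s%d", 1:3),
                               sprintf("t%d", 1:3), c("t1", "s1")),
                   stringsAsFactors = FALSE)
  tumor_sig <- sprintf("t%d", 1:10)
  stromal_sig <- sprintf("s%d", 1:10)
  cls <- classify_clusters(mk, tumor_sig, stromal_sig, min_overlap = 3)
  got <- stats::setNames(cls$class, cls$cluster)
  expect_equal(unname(got["c1"]), "tumor")
  expect_equal(unname(got["c2"]), "unknown")  # equal 3/3 overlap -> tie
  expect_equal(unname(got["c3"]), "unknown")  # below min_overlap
  # unlabeled cluster with no marker rows is unknown
  cls2 <- classify_clusters(mk, tumor_sig, stromal_sig, min_overlap = 3,
                            clusters = c("c1", "empty"))
  expect_equal(cls2$class[cls2$cluster == "empty"], "unknown")
})
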