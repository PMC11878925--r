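# End-to-end orchestration: a flat key=value config, staged execution
# with structured logging, and a JSON run manifest with output hashes.

pipeline_defaults <- function() {
  list(
    simulate = TRUE, data_dir = NA_character_,
    n_sections = 3, spots_per_section = 400, n_cells = 1500,
    n_cell_samples = 5, n_genes = 2000,
    qc_preset = "geo", n_hvg = 2000, n_pcs = 20, resolution = 1,
    min_overlap = 5,
    window = 101, expr_cutoff = 0.1, gain_thr = 1.05, loss_thr = 0.95,
    min_genes_event = 20,
    alpha = 0.05, min_sections = 0,
    rank_min = 2, rank_max = 6, top_n = 50, cut = 0.8,
    share_fraction = 1 / 3,
    seed = 1)
}

pipeline_ranges <- list(
  resolution = c(0, 100), expr_cutoff = c(0, Inf),
  alpha = c(1e-12, 1), cut = c(0, 2), share_fraction = c(1e-9, 1),
  gain_thr = c(1, Inf), loss_thr = c(0, 1))

#' Parse and validate a pipeline configuration file
#'
#' The file is flat text, one `key = value` pair per line, `#` comments
#' allowed. Unknown keys are rejected; missing keys take documented
#' defaults (window 101, top_n 50, alpha 0.05, ...); out-of-range values
#' error with the allowed range. When `simulate = false`, `data_dir`
#' must point at a directory in the layout written by [write_cohort()].
#'
#' @param path Path to the config file, or NULL for all defaults.
#' @return A list of class `PipelineConfig`.
#' @export
validate_config <- function(path = NULL) {
  cfg <- pipeline_defaults()
  if (!is.null(path)) {
    assert_that(file.exists(path), paste("config file not found:", path))
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
      assert_that(length(kv) == 2, paste("malformed config line:", ln))
      key <- trimws(kv[1])
      val <- trimws(kv[2])
      assert_that(key %in% names(cfg), paste("unknown config key:", key))
      cfg[[key]] <- parse_config_value(key, val, cfg[[key]])
    }
  }
  assert_that(cfg$window %% 2 == 1, "window must be odd")
  assert_that(cfg$rank_min >= 2 && cfg$rank_min < cfg$rank_max,
              "need 2 <= rank_min < rank_max")
  assert_that(cfg$loss_thr < 1 && cfg$gain_thr > 1,
              "need loss_thr < 1 < gain_thr")
  for (key in names(pipeline_ranges)) {
    rng <- pipeline_ranges[[key]]
    assert_that(cfg[[key]] >= rng[1] && cfg[[key]] <= rng[2],
                sprintf("%s = %s outside allowed range [%s, %s]",
                        key, cfg[[key]], rng[1], rng[2]))
  }
  if (!isTRUE(cfg$simulate))
    assert_that(!is.na(cfg$data_dir) && dir.exists(cfg$data_dir),
                "data_dir must exist when simulate = false")
  structure(cfg, class = "PipelineConfig")
}

parse_config_value <- function(key, val, default) {
  if (is.logical(default)) {
    assert_that(tolower(val) %in% c("true", "false"),
                paste(key, "must be true or false"))
    return(tolower(val) == "true")
  }
  if (is.numeric(default)) {
    num <- suppressWarnings(as.numeric(val))
    assert_that(!is.na(num), paste(key, "must be numeric"))
    return(num)
  }
  val
}

#' Run the full analysis pipeline
#'
#' Executes simulate (or load) -> qc -> cluster -> markers -> classify ->
#' cnv -> clones -> tree -> mia -> tumorscore -> coloc -> programs,
#' writing every stage's outputs under `out_dir` before the next stage
#' starts, a timestamped `run.log`, and a `run_manifest.json` recording
#' parameters and md5 hashes of all outputs. All randomness derives from
#' the single config seed via stage-salted seeds, so individual stages
#' re-run reproducibly.
#'
#' @param config A `PipelineConfig` from [validate_config()], or a path
#'   to a config file.
#' @param out_dir Output directory (created if missing).
#' @param verbose Echo log lines to stderr (default TRUE).
#' @return The manifest, invisibly.
#' @export
run_all <- function(config, out_dir, verbose = TRUE) {
  if (is.character(config)) config <- validate_config(config)
  stopifnot(inherits(config, "PipelineConfig"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  log_line <- function(stage, msg) {
    line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S"),
                    stage, msg)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
    if (verbose) message(line)
  }
  manifest <- list()
  state <- new.env(parent = emptyenv())
  run_stage <- function(stage, params, fn) {
    log_line(stage, "started")
    t0 <- Sys.time()
    outputs <- tryCatch(fn(), error = function(e) {
      log_line(stage, paste("FAILED:", conditionMessage(e)))
      stop(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
           call. = FALSE)
    })
    hashes <- as.list(tools::md5sum(outputs))
    names(hashes) <- basename(outputs)
    manifest[[stage]] <<- list(params = params,
                               outputs = basename(outputs),
                               md5 = hashes, status = "ok",
                               seconds = as.numeric(difftime(Sys.time(), t0,
                                                             units = "secs")))
    log_line(stage, sprintf("done (%d output file(s))", length(outputs)))
  }
  seed_of <- function(stage) stage_seed(config$seed, stage)

  run_stage("simulate", config[c("n_sections", "spots_per_section",
                                 "n_cells", "n_genes", "seed")], function() {
    if (isTRUE(config$simulate)) {
      cc <- cohort_config(
        n_sections = config$n_sections,
        spots_per_section = config$spots_per_section,
        n_cells = config$n_cells, n_cell_samples = config$n_cell_samples,
        n_genes = config$n_genes, seed = seed_of("simulate"))
      state$cohort <- generate_cohort(cc)
    } else {
      state$cohort <- read_cohort(config$data_dir)
    }
    data_dir <- file.path(out_dir, "data")
    write_cohort(state$cohort, data_dir)
    list.files(data_dir, full.names = TRUE)
  })

  run_stage("qc", list(preset = config$qc_preset), function() {
    merged <- merge_sections(state$cohort)
    kept <- filter_observations(merged$counts, config$qc_preset)
    state$st <- subset_obs(merged$counts, kept)
    state$spots <- merged$spots[merged$spots$obs_id %in% kept, ]
    f <- file.path(out_dir, "qc_retained.tsv")
    write_tsv(data.frame(obs_id = kept), f)
    f
  })

  run_stage("cluster", config[c("n_hvg", "n_pcs", "resolution")], function() {
    state$norm <- normalize_log(state$st)
    hvgs <- select_hvg(state$norm, min(config$n_hvg, length(state$norm$gene_ids)))
    state$clusters <- embed_and_cluster(
      state$norm, hvgs, n_pcs = min(config$n_pcs, length(state$norm$obs_ids)),
      resolution = config$resolution, seed = seed_of("cluster"))
    f <- file.path(out_dir, "clusters.tsv")
    write_tsv(state$clusters, f)
    f
  })

  run_stage("markers", list(), function() {
    state$markers <- find_markers(state$norm, state$clusters)
    f <- file.path(out_dir, "markers.tsv")
    write_tsv(state$markers, f)
    f
  })

  run_stage("classify", list(min_overlap = config$min_overlap), function() {
    sigs <- state$cohort$truth$markers
    state$tumor_sig <- sigs$tumor
    state$stromal_sig <- unique(unlist(sigs[setdiff(names(sigs), "tumor")],
                                       use.names = FALSE))
    state$classes <- classify_clusters(
      state$markers, state$tumor_sig, state$stromal_sig,
      min_overlap = config$min_overlap,
      clusters = sort(unique(state$clusters$label)))
    f <- file.path(out_dir, "cluster_classes.tsv")
    write_tsv(state$classes, f)
    f
  })

  run_stage("cnv", config[c("window", "expr_cutoff")], function() {
    stromal_clusters <- state$classes$cluster[state$classes$class == "stromal"]
    ref <- state$clusters$obs_id[state$clusters$label %in% stromal_clusters]
    assert_that(length(ref) > 0, "no stromal reference spots identified")
    state$profile <- infer_cnv(state$st, ref, state$cohort$annotation,
                               window = config$window,
                               expr_cutoff = config$expr_cutoff)
    state$burden <- normalize_cnv(cnv_burden(state$profile))
    f <- file.path(out_dir, "cnv_burden.tsv")
    write_tsv(state$burden, f)
    f
  })

  run_stage("clones", list(), function() {
    tumor_clusters <- state$classes$cluster[state$classes$class == "tumor"]
    tum_obs <- state$clusters$obs_id[state$clusters$label %in% tumor_clusters]
    prof <- state$profile
    state$tumor_profile <- subset_profile(
      prof, prof$obs_ids[prof$obs_ids %in% c(tum_obs, prof$reference_obs)])
    state$clones <- detect_clones(prof)
    f <- file.path(out_dir, "clones.tsv")
    write_tsv(state$clones, f)
    f
  })

  run_stage("tree", config[c("gain_thr", "loss_thr", "min_genes_event")],
            function() {
    state$events <- segment_events(
      state$tumor_profile, state$clones, gain_thr = config$gain_thr,
      loss_thr = config$loss_thr, min_genes = config$min_genes_event)
    tree <- build_clone_tree(state$events)
    f1 <- file.path(out_dir, "clone_events.tsv")
    write_tsv(state$events$events, f1)
    f2 <- file.path(out_dir, "clone_tree.nwk")
    write_newick(tree, f2)
    f3 <- file.path(out_dir, "clone_tree_edges.tsv")
    write_tsv(clone_tree_edges(tree), f3)
    c(f1, f2, f3)
  })

  run_stage("mia", list(), function() {
    cells_norm <- normalize_log(state$cohort$cells$counts)
    type_markers <- find_markers(cells_norm, state$cohort$cells$types)
    background <- intersect(state$norm$gene_ids, cells_norm$gene_ids)
    cl_sets <- split(state$markers$gene_id, state$markers$cluster)
    ty_sets <- split(type_markers$gene_id, type_markers$cluster)
    cl_sets <- lapply(cl_sets, intersect, background)
    ty_sets <- lapply(ty_sets, intersect, background)
    state$mia <- mia_table(cl_sets, ty_sets, background)
    state$type_markers <- ty_sets
    f <- file.path(out_dir, "mia.tsv")
    write_tsv(state$mia, f)
    f
  })

  run_stage("tumorscore", list(), function() {
    state$sig <- signature_score(state$norm, state$tumor_sig, state$spots)
    state$tscore <- tumor_score(state$burden, state$sig)
    f <- file.path(out_dir, "tumor_score.tsv")
    out <- merge(state$tscore, state$spots, by = "obs_id")
    write_tsv(out[, c("obs_id", "section_id", "x", "y", "tumor_score")], f)
    f
  })

  run_stage("coloc", config[c("alpha", "min_sections")], function() {
    min_sections <- if (config$min_sections > 0) config$min_sections else NULL
    rows <- list()
    for (ty in names(state$type_markers)) {
      if (ty == "tumor" || length(state$type_markers[[ty]]) == 0) next
      ct <- signature_score(state$norm, state$type_markers[[ty]], state$spots)
      res <- colocalize(state$tscore, ct, state$spots,
                        alpha = config$alpha, min_sections = min_sections)
      rows[[ty]] <- data.frame(cell_type = ty,
                               n_significant = res$n_significant,
                               colocalized = res$colocalized,
                               stringsAsFactors = FALSE)
    }
    f <- file.path(out_dir, "colocalization.tsv")
    write_tsv(do.call(rbind, c(rows, list(make.row.names = FALSE))), f)
    f
  })

  run_stage("programs", config[c("rank_min", "rank_max", "top_n", "cut",
                                 "share_fraction")], function() {
    cells <- state$cohort$cells
    tumor_cells <- cells$types$obs_id[cells$types$label == "tumor"]
    cn <- normalize_log(subset_obs(cells$counts, tumor_cells))
    samp <- cells$samples[cells$samples$obs_id %in% tumor_cells, ]
    progs <- sample_programs(cn, samp, rank_min = config$rank_min,
                             rank_max = config$rank_max,
                             top_n = config$top_n, seed = seed_of("programs"))
    f1 <- file.path(out_dir, "programs.gmt")
    sets <- stats::setNames(
      lapply(progs, `[[`, "genes"),
      vapply(progs, function(p) paste0(p$sample_id, ".", p$factor_index),
             character(1)))
    write_gmt(sets, f1)
    mps <- if (length(progs) >= 2)
      cluster_programs(progs, cut = config$cut,
                       share_fraction = config$share_fraction)
    else list()
    f2 <- file.path(out_dir, "metaprograms.gmt")
    mp_sets <- stats::setNames(
      lapply(mps, `[[`, "signature"),
      paste0("metaprogram_", seq_along(mps)))
    write_gmt(mp_sets, f2)
    c(f1, f2)
  })

  manifest_path <- file.path(out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE)
  log_line("pipeline", "complete")
  invisible(manifest)
}

#' Read a cohort directory written by [write_cohort()]
#'
#' @param dir Directory path.
#' @return A `Cohort`-shaped list (without the generative ground truth
#'   fields that only the generator knows).
#' @export
read_cohort <- function(dir) {
  sections <- sub("_matrix\\.mtx$", "",
                  basename(Sys.glob(file.path(dir, "S*_matrix.mtx"))))
  assert_that(length(sections) > 0, "no section matrices found in data_dir")
  sec <- lapply(sections, function(s) {
    list(counts = read_counts(file.path(dir, paste0(s, "_matrix.mtx")),
                              file.path(dir, paste0(s, "_genes.tsv")),
                              file.path(dir, paste0(s, "_barcodes.tsv"))),
         spots = read_spot_table(file.path(dir, paste0(s, "_spots.tsv"))))
  })
  names(sec) <- sections
  cells <- list(
    counts = read_counts(file.path(dir, "cells_matrix.mtx"),
                         file.path(dir, "cells_genes.tsv"),
                         file.path(dir, "cells_barcodes.tsv")),
    types = read_label_table(file.path(dir, "cells_types.tsv")),
    samples = read_label_table(file.path(dir, "cells_samples.tsv")))
  truth <- list(markers = read_gmt(file.path(dir, "marker_signatures.gmt")))
  structure(list(sections = sec, cells = cells,
                 annotation = read_gene_annotation(
                   file.path(dir, "gene_annotation.tsv")),
                 truth = truth), class = "Cohort")
}
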