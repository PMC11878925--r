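# Expression-based copy number inference and clone analysis.
#
# Copy ratios are inferred from smoothed deviations of log2 expression
# relative to a reference (typically stromal) population, in the spirit of
# reference-based CNV callers for single-cell expression data: lowly
# expressed genes are removed, residuals are clipped, averaged along the
# chromosome, re-centered per observation, denoised against the reference
# noise band, and exponentiated so the diploid state sits at ratio 1.

#' Infer expression-based copy ratio profiles
#'
#' @param x A `CountMatrix` holding both query and reference observations.
#' @param reference_obs Observation ids forming the diploid reference
#'   (e.g. stromal spots); must be non-empty and present in `x`.
#' @param annotation Gene annotation from [read_gene_annotation()]; only
#'   annotated genes participate, in karyotype order.
#' @param window Odd moving-average width, in genes, for the along-
#'   chromosome smoothing (default 101).
#' @param expr_cutoff Genes whose mean depth-normalized expression across
#'   all observations falls below this are dropped (default 0.1).
#' @param max_centered Reference-centered log2 residuals are clipped to
#'   +/- this value before smoothing (default 1).
#' @param denoise When TRUE (default), smoothed residuals within
#'   `sd_amplifier` reference standard deviations of zero are set to zero,
#'   suppressing the reference noise band.
#' @param sd_amplifier Width of the denoising band (default 1.5).
#' @return A list of class `CnvProfile`: `ratios` (observations x ordered
#'   genes, centered at 1), `obs_ids`, `gene_ids`, `chromosome`, `window`,
#'   `reference_obs`.
#' @export
infer_cnv <- function(x, reference_obs, annotation, window = 101,
                      expr_cutoff = 0.1, max_centered = 1, denoise = TRUE,
                      sd_amplifier = 1.5) {
  assert_that(length(reference_obs) > 0, "reference_obs must be non-empty")
  assert_that(all(reference_obs %in% x$obs_ids),
              "reference observations missing from the matrix")
  assert_that(window %% 2 == 1 && window >= 1, "window must be odd")

  depth <- Matrix::colSums(x$values)
  assert_that(all(depth > 0), "all-zero observations in the matrix")
  norm <- as.matrix(x$values %*% Matrix::Diagonal(x = stats::median(depth) / depth))
  dimnames(norm) <- list(x$gene_ids, x$obs_ids)

  keep <- rowMeans(norm) >= expr_cutoff
  ann <- annotation[annotation$gene_id %in% x$gene_ids[keep], , drop = FALSE]
  assert_that(nrow(ann) > 0, "no annotated genes pass the expression cutoff")
  chrom_sizes <- table(ann$chromosome)
  if (all(chrom_sizes < window))
    stop("every chromosome has fewer genes than the smoothing window",
         call. = FALSE)

  lg <- log2(norm[ann$gene_id, , drop = FALSE] + 1)
  ref_mean <- rowMeans(lg[, reference_obs, drop = FALSE])
  resid <- lg - ref_mean
  resid[resid > max_centered] <- max_centered
  resid[resid < -max_centered] <- -max_centered

  sm <- matrix(0, nrow(resid), ncol(resid), dimnames = dimnames(resid))
  for (ch in unique(ann$chromosome)) {
    idx <- which(ann$chromosome == ch)
    sm[idx, ] <- runmean_columns(resid[idx, , drop = FALSE], window)
  }
  sm <- sweep(sm, 2, apply(sm, 2, stats::median))
  if (denoise) {
    ref_sd <- stats::sd(sm[, reference_obs])
    sm[abs(sm) < sd_amplifier * ref_sd] <- 0
  }
  structure(list(ratios = t(2^sm), obs_ids = x$obs_ids,
                 gene_ids = ann$gene_id, chromosome = ann$chromosome,
                 window = window, reference_obs = reference_obs),
            class = "CnvProfile")
}

# Centered moving average down the rows of a matrix, window truncated at
# the edges; width 1 is the identity.
runmean_columns <- function(m, window) {
  g <- nrow(m)
  if (window == 1 || g == 1) return(m)
  h <- (window - 1) / 2
  cs <- rbind(0, apply(m, 2, cumsum))
  i <- seq_len(g)
  lo <- pmax(i - h, 1)
  hi <- pmin(i + h, g)
  (cs[hi + 1, , drop = FALSE] - cs[lo, , drop = FALSE]) / (hi - lo + 1)
}

#' @export
print.CnvProfile <- function(x, ...) {
  cat(sprintf("<CnvProfile> %d observations x %d genes, window %d, %d reference obs\n",
              nrow(x$ratios), length(x$gene_ids), x$window,
              length(x$reference_obs)))
  invisible(x)
}

#' Restrict a CNV profile to a set of observations
#'
#' Reference observations absent from `obs_ids` are dropped from the
#' reference list as well.
#'
#' @param profile A `CnvProfile`.
#' @param obs_ids Observations to keep.
#' @return The restricted `CnvProfile`.
#' @export
subset_profile <- function(profile, obs_ids) {
  missing <- setdiff(obs_ids, profile$obs_ids)
  assert_that(length(missing) == 0,
              paste("unknown observations:", paste(missing, collapse = ", ")))
  profile$ratios <- profile$ratios[match(obs_ids, profile$obs_ids), ,
                                   drop = FALSE]
  profile$obs_ids <- obs_ids
  profile$reference_obs <- intersect(profile$reference_obs, obs_ids)
  profile
}

#' Per-observation CNV burden
#'
#' The burden of observation i is `1 + mean_g |ratio_ig - 1|`: one plus
#' the mean absolute deviation of its copy ratios from the diploid state.
#' Losses and gains both contribute magnitude; a flat diploid profile
#' scores exactly 1, so the downstream `(score - 1) / (max - 1)`
#' normalization maps it to 0.
#'
#' @param profile A `CnvProfile`.
#' @return data.frame with columns `obs_id`, `raw`.
#' @export
cnv_burden <- function(profile) {
  raw <- 1 + rowMeans(abs(profile$ratios - 1))
  data.frame(obs_id = profile$obs_ids, raw = unname(raw),
             stringsAsFactors = FALSE)
}

#' Normalize CNV burden scores to \[0, 1\]
#'
#' Applies `nCNV_i = (CNV_i - 1) / (maxCNV - 1)`. When every raw score
#' equals 1 (no CNV signal anywhere) all normalized scores are 0;
#' otherwise the arg-max observation scores exactly 1.
#'
#' @param scores data.frame from [cnv_burden()] (columns `obs_id`, `raw`).
#' @return The input with a `normalized` column and attribute `max_raw`.
#' @export
normalize_cnv <- function(scores) {
  assert_that(all(scores$raw >= 1), "raw CNV scores must be >= 1")
  max_raw <- max(scores$raw)
  scores$normalized <- if (max_raw > 1) (scores$raw - 1) / (max_raw - 1)
                       else rep(0, nrow(scores))
  attr(scores, "max_raw") <- max_raw
  scores
}

#' Reclassify high-burden cells as tumor
#'
#' Cells whose label is one of the eligible source types and whose
#' normalized CNV score strictly exceeds the threshold are relabeled
#' "tumor"; every other label is left untouched.
#'
#' @param labels data.frame with `obs_id`, `label`.
#' @param scores Normalized scores from [normalize_cnv()].
#' @param threshold Strict lower bound on the normalized score
#'   (default 0.3).
#' @param eligible Source labels allowed to flip (default mesothelial and
#'   endothelial).
#' @return The label table with reclassified cells.
#' @export
reclassify_tumor_cells <- function(labels, scores, threshold = 0.3,
                                   eligible = c("mesothelial", "endothelial")) {
  missing <- setdiff(labels$obs_id, scores$obs_id)
  if (length(missing))
    stop("no CNV score for: ", paste(missing, collapse = ", "), call. = FALSE)
  sc <- stats::setNames(scores$normalized, scores$obs_id)[labels$obs_id]
  flip <- labels$label %in% eligible & sc > threshold
  labels$label[flip] <- "tumor"
  labels
}

#' Group observations into CNV clones
#'
#' Average-linkage hierarchical clustering of the non-reference
#' observations on the Euclidean distance between their copy ratio
#' vectors. With `n_clones = "auto"` the tree is cut at the largest
#' relative gap in merge heights among cuts 2..12 (a flat profile set
#' yields a single clone). Reference observations are labeled "normal".
#' Clone labels are numbered by decreasing size.
#'
#' @param profile A `CnvProfile`.
#' @param n_clones Integer number of clones, or `"auto"`.
#' @return data.frame with columns `obs_id`, `label`.
#' @export
detect_clones <- function(profile, n_clones = "auto") {
  query <- setdiff(profile$obs_ids, profile$reference_obs)
  assert_that(length(query) >= 2, "need at least 2 non-reference observations")
  rat <- profile$ratios[match(query, profile$obs_ids), , drop = FALSE]
  hc <- stats::hclust(stats::dist(rat), method = "average")
  if (identical(n_clones, "auto")) {
    n_clones <- pick_cut_by_gap(hc$height, max_k = 12)
  } else {
    assert_that(n_clones <= length(query),
                "n_clones exceeds the number of observations")
  }
  memb <- if (n_clones == 1) rep(1L, length(query))
          else stats::cutree(hc, k = n_clones)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(paste0("clone_", seq_along(sizes)), names(sizes))
  out <- data.frame(obs_id = profile$obs_ids, label = "normal",
                    stringsAsFactors = FALSE)
  out$label[match(query, out$obs_id)] <- relabel[as.character(memb)]
  out
}

# Number of clusters maximizing the relative gap between consecutive merge
# heights; degenerate (near-zero) trees collapse to one cluster.
pick_cut_by_gap <- function(heights, max_k = 12) {
  n <- length(heights) + 1
  if (max(heights) < 1e-8) return(1L)
  ks <- 2:min(max_k, n)
  gaps <- vapply(ks, function(k) {
    top <- heights[n - k + 1]
    below <- if (n - k >= 1) heights[n - k] else 0
    (top - below) / top
  }, numeric(1))
  ks[which.max(gaps)]
}

#' Call gain/loss events per clone by run-length segmentation
#'
#' For each clone the mean copy ratio per gene is thresholded into
#' loss / neutral / gain states; maximal runs of at least `min_genes`
#' consecutive same-state genes within one chromosome become events,
#' reported with their mean ratio. The clone labeled "normal" is skipped.
#'
#' @param profile A `CnvProfile`.
#' @param clones Clone labels from [detect_clones()] (or ground truth).
#' @param gain_thr,loss_thr State thresholds around 1 (defaults 1.05 and
#'   0.95).
#' @param min_genes Minimum run length, in genes (default 20).
#' @return A list of class `CnvEventSet`: `events` (data.frame with
#'   `clone`, `chromosome`, `start_index`, `end_index`, `n_genes`,
#'   `state`, `mean_ratio`; indices refer to the profile's gene order),
#'   `gene_ids`, `chromosome`.
#' @export
segment_events <- function(profile, clones, gain_thr = 1.05,
                           loss_thr = 0.95, min_genes = 20) {
  assert_that(loss_thr < 1 && 1 < gain_thr,
              "need loss_thr < 1 < gain_thr")
  rows <- list()
  for (cl in setdiff(sort(unique(clones$label)), "normal")) {
    obs <- clones$obs_id[clones$label == cl]
    obs <- intersect(obs, profile$obs_ids)
    if (length(obs) == 0) next
    mean_ratio <- colMeans(profile$ratios[match(obs, profile$obs_ids), ,
                                          drop = FALSE])
    state <- ifelse(mean_ratio > gain_thr, "gain",
                    ifelse(mean_ratio < loss_thr, "loss", "neutral"))
    for (ch in unique(profile$chromosome)) {
      idx <- which(profile$chromosome == ch)
      r <- rle(state[idx])
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1
      for (j in seq_along(r$values)) {
        if (r$values[j] == "neutral" || r$lengths[j] < min_genes) next
        gi <- idx[starts[j]:ends[j]]
        rows[[length(rows) + 1]] <- data.frame(
          clone = cl, chromosome = ch, start_index = gi[1],
          end_index = gi[length(gi)], n_genes = length(gi),
          state = r$values[j], mean_ratio = mean(mean_ratio[gi]),
          stringsAsFactors = FALSE)
      }
    }
  }
  events <- if (length(rows)) do.call(rbind, c(rows, list(make.row.names = FALSE)))
            else data.frame(clone = character(), chromosome = character(),
                            start_index = integer(), end_index = integer(),
                            n_genes = integer(), state = character(),
                            mean_ratio = numeric(), stringsAsFactors = FALSE)
  structure(list(events = events, gene_ids = profile$gene_ids,
                 chromosome = profile$chromosome),
            class = "CnvEventSet")
}

#' Join event regions to gene sets
#'
#' Every annotated gene whose profile index falls inside an event region
#' is reported once per gene set containing it; genes belonging to no set
#' appear with `set_name = "none"`.
#'
#' @param events A `CnvEventSet` from [segment_events()].
#' @param annotation Gene annotation (used to restrict to annotated genes).
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @return data.frame with columns `clone`, `chromosome`, `state`,
#'   `gene_id`, `set_name`.
#' @export
link_events_to_gene_sets <- function(events, annotation, sets) {
  ev <- events$events
  out <- list()
  for (i in seq_len(nrow(ev))) {
    genes <- events$gene_ids[ev$start_index[i]:ev$end_index[i]]
    genes <- genes[genes %in% annotation$gene_id]
    for (g in genes) {
      hits <- names(sets)[vapply(sets, function(s) g %in% s, logical(1))]
      if (length(hits) == 0) hits <- "none"
      out[[length(out) + 1]] <- data.frame(
        clone = ev$clone[i], chromosome = ev$chromosome[i],
        state = ev$state[i], gene_id = g, set_name = hits,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(clone = character(), chromosome = character(),
                      state = character(), gene_id = character(),
                      set_name = character(), stringsAsFactors = FALSE))
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}
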