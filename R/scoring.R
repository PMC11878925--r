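# Cell-type enrichment (MIA), per-spot signature scoring, the
# geometric-mean tumor score and the chi-square co-localization rule.

#' Multimodal intersection analysis of two gene sets
#'
#' Tests whether a query gene set (typically an ST cluster's markers)
#' overlaps a cell type's marker genes more than expected by chance,
#' under a hypergeometric model with the full gene universe as
#' background. Enrichment is `-log10 P[X >= k]`; depletion is
#' `-log10(1 - p)`, large when the overlap is improbably small. p is
#' clamped to \[1e-300, 1 - 1e-16\] before taking logs so neither score is
#' infinite.
#'
#' @param query_genes Character vector (subset of `background`).
#' @param type_markers Character vector (subset of `background`).
#' @param background Character vector, the gene universe.
#' @return data.frame row with `overlap`, `p`, `enrichment`, `depletion`.
#' @export
mia <- function(query_genes, type_markers, background) {
  assert_that(length(background) > 0, "background must be non-empty")
  query_genes <- unique(query_genes)
  type_markers <- unique(type_markers)
  background <- unique(background)
  assert_that(all(query_genes %in% background),
              "query genes missing from the background")
  assert_that(all(type_markers %in% background),
              "type markers missing from the background")
  n_bg <- length(background)
  k_set <- length(type_markers)
  n_query <- length(query_genes)
  k <- length(intersect(query_genes, type_markers))
  # upper tail P[X >= k]; k = 0 gives exactly 1
  p <- stats::phyper(k - 1, k_set, n_bg - k_set, n_query, lower.tail = FALSE)
  p <- min(max(p, 1e-300), 1 - 1e-16)
  data.frame(overlap = k, p = p, enrichment = -log10(p),
             depletion = -log10(1 - p))
}

#' MIA across all cluster / cell-type pairs
#'
#' @param cluster_markers Named list: cluster -> marker gene vector.
#' @param type_markers Named list: cell type -> marker gene vector.
#' @param background Gene universe containing all of the above.
#' @return data.frame with one row per (cluster, cell_type) pair.
#' @export
mia_table <- function(cluster_markers, type_markers, background) {
  rows <- list()
  for (cl in names(cluster_markers)) for (ty in names(type_markers)) {
    r <- mia(cluster_markers[[cl]], type_markers[[ty]], background)
    rows[[length(rows) + 1]] <- cbind(
      data.frame(cluster = cl, cell_type = ty, stringsAsFactors = FALSE), r)
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Per-spot signature score with per-section min-max normalization
#'
#' The raw score of a spot is the mean normalized expression of the
#' signature genes present in the matrix; the normalized score rescales
#' raw scores to \[0, 1\] within each section (a section with constant raw
#' scores maps to all zeros).
#'
#' @param x A `NormalizedMatrix`.
#' @param genes Signature gene ids (at least one must be in the matrix).
#' @param spots Spot table with `obs_id`, `section_id` covering the
#'   matrix's observations.
#' @return data.frame with `obs_id`, `section_id`, `raw`, `normalized`.
#' @export
signature_score <- function(x, genes, spots) {
  present <- intersect(genes, x$gene_ids)
  assert_that(length(present) > 0, "no signature gene present in the matrix")
  raw <- Matrix::colMeans(x$values[present, , drop = FALSE])
  sec <- stats::setNames(spots$section_id, spots$obs_id)[x$obs_ids]
  assert_that(!anyNA(sec), "spot table does not cover all observations")
  out <- data.frame(obs_id = x$obs_ids, section_id = unname(sec),
                    raw = unname(raw), stringsAsFactors = FALSE)
  out$normalized <- stats::ave(out$raw, out$section_id, FUN = function(v) {
    rng <- range(v)
    if (rng[2] > rng[1]) (v - rng[1]) / (rng[2] - rng[1]) else rep(0, length(v))
  })
  out
}

#' Geometric-mean tumor score
#'
#' Combines a spot's normalized CNV burden with its normalized tumor
#' signature score as `sqrt(nCNV * nSig)`, so a spot scores high only
#' when both genomic and transcriptional evidence agree; either factor at
#' zero annihilates the score.
#'
#' @param cnv_scores Normalized scores from [normalize_cnv()].
#' @param sig_scores Scores from [signature_score()].
#' @return data.frame with `obs_id`, `tumor_score`.
#' @export
tumor_score <- function(cnv_scores, sig_scores) {
  missing <- union(setdiff(cnv_scores$obs_id, sig_scores$obs_id),
                   setdiff(sig_scores$obs_id, cnv_scores$obs_id))
  if (length(missing))
    stop("observations not covered by both maps: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sig <- stats::setNames(sig_scores$normalized, sig_scores$obs_id)
  data.frame(obs_id = cnv_scores$obs_id,
             tumor_score = sqrt(cnv_scores$normalized *
                                  sig[cnv_scores$obs_id]),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Chi-square co-localization of a cell type with tumor
#'
#' Per section, both the tumor score and the cell-type signature score
#' are dichotomized at that section's arithmetic mean (strictly greater
#' is "high") and tested for association with an uncorrected Pearson
#' chi-square on the 2x2 table. Sections where either variable is
#' constant (a degenerate margin) are flagged and skipped. The cell type
#' is called co-localized when at least `min_sections` sections reach
#' `p < alpha`; `min_sections` defaults to the number of sections, the
#' strictest form of the rule.
#'
#' @param tumor Tumor scores from [tumor_score()].
#' @param celltype_scores Cell-type signature scores from
#'   [signature_score()].
#' @param spots Spot table with `obs_id`, `section_id`.
#' @param alpha Per-section significance level (default 0.05).
#' @param min_sections Sections required significant, or NULL for all.
#' @return A list of class `ColocResult`: `per_section` (data.frame with
#'   `section_id`, `chi2`, `p_value`, `skipped` and the 2x2 counts),
#'   `n_significant`, `colocalized`.
#' @export
colocalize <- function(tumor, celltype_scores, spots, alpha = 0.05,
                       min_sections = NULL) {
  sections <- unique(spots$section_id)
  assert_that(length(sections) >= 1, "need at least one section")
  min_sections <- min_sections %||% length(sections)
  ts <- stats::setNames(tumor$tumor_score, tumor$obs_id)
  cs <- stats::setNames(celltype_scores$normalized, celltype_scores$obs_id)
  assert_that(all(spots$obs_id %in% names(ts)) &&
                all(spots$obs_id %in% names(cs)),
              "every spot must be scored by both maps")
  rows <- list()
  for (s in sections) {
    ids <- spots$obs_id[spots$section_id == s]
    t_high <- ts[ids] > mean(ts[ids])
    c_high <- cs[ids] > mean(cs[ids])
    a <- sum(t_high & c_high); b <- sum(t_high & !c_high)
    cc <- sum(!t_high & c_high); d <- sum(!t_high & !c_high)
    degenerate <- (a + b == 0) || (cc + d == 0) || (a + cc == 0) || (b + d == 0)
    if (degenerate) {
      rows[[s]] <- data.frame(section_id = s, chi2 = NA_real_,
                              p_value = NA_real_, skipped = TRUE,
                              hh = a, hl = b, lh = cc, ll = d,
                              stringsAsFactors = FALSE)
      next
    }
    tab <- matrix(c(a, cc, b, d), nrow = 2)
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    rows[[s]] <- data.frame(section_id = s, chi2 = unname(ct$statistic),
                            p_value = ct$p.value, skipped = FALSE,
                            hh = a, hl = b, lh = cc, ll = d,
                            stringsAsFactors = FALSE)
  }
  per_section <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  n_sig <- sum(!per_section$skipped & per_section$p_value < alpha)
  structure(list(per_section = per_section, n_significant = n_sig,
                 colocalized = n_sig >= min_sections,
                 alpha = alpha, min_sections = min_sections),
            class = "ColocResult")
}

#' @export
print.ColocResult <- function(x, ...) {
  cat(sprintf("<ColocResult> %d/%d sections significant (alpha %.3g); colocalized: %s\n",
              x$n_significant, nrow(x$per_section), x$alpha, x$colocalized))
  invisible(x)
}
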