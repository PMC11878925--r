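#' Quality-control thresholds for spots or cells
#'
#' @param min_genes Minimum number of detected genes; observations with
#'   fewer are dropped (an observation with exactly `min_genes` is kept).
#' @param max_genes Upper bound on detected genes (inclusive), or NULL.
#' @param max_mito_fraction Strict upper bound on the fraction of counts
#'   from mitochondrial (`MT-`) genes, or NULL. An observation at exactly
#'   this fraction is dropped ("less than" rule).
#' @return A list of class `QcThresholds`.
#' @export
qc_thresholds <- function(min_genes = 0, max_genes = NULL,
                          max_mito_fraction = NULL) {
  assert_that(min_genes >= 0, "min_genes must be >= 0")
  if (!is.null(max_genes))
    assert_that(max_genes > min_genes, "max_genes must exceed min_genes")
  if (!is.null(max_mito_fraction))
    assert_that(max_mito_fraction >= 0 && max_mito_fraction <= 1,
                "max_mito_fraction must be in [0, 1]")
  structure(list(min_genes = min_genes, max_genes = max_genes,
                 max_mito_fraction = max_mito_fraction),
            class = "QcThresholds")
}

#' Named QC presets
#'
#' Two regimes: `"geo"` keeps spots with at least 400 detected genes and
#' applies no other filter (public repository sections); `"proprietary"`
#' requires between 200 and 4,000 detected genes and strictly less than
#' 13% mitochondrial content.
#'
#' @param name `"geo"` or `"proprietary"`.
#' @return A [qc_thresholds()].
#' @export
qc_preset <- function(name = c("geo", "proprietary")) {
  name <- match.arg(name)
  switch(name,
         geo = qc_thresholds(min_genes = 400),
         proprietary = qc_thresholds(min_genes = 200, max_genes = 4000,
                                     max_mito_fraction = 0.13))
}

#' Filter observations by detected genes and mitochondrial content
#'
#' An observation is retained iff its detected-gene count is `>=
#' min_genes`, `<= max_genes` (when set), and its mitochondrial count
#' fraction is strictly `< max_mito_fraction` (when set). Order is
#' preserved; filtering is idempotent.
#'
#' @param x A `CountMatrix`.
#' @param thresholds A [qc_thresholds()] or preset name.
#' @return Character vector of retained observation ids.
#' @export
filter_observations <- function(x, thresholds) {
  if (is.character(thresholds)) thresholds <- qc_preset(thresholds)
  stopifnot(inherits(thresholds, "QcThresholds"))
  detected <- Matrix::colSums(x$values > 0)
  keep <- detected >= thresholds$min_genes
  if (!is.null(thresholds$max_genes))
    keep <- keep & detected <= thresholds$max_genes
  if (!is.null(thresholds$max_mito_fraction)) {
    mt <- grepl("^MT-", x$gene_ids)
    total <- Matrix::colSums(x$values)
    mito <- Matrix::colSums(x$values[mt, , drop = FALSE])
    frac <- ifelse(total > 0, mito / total, 0)
    keep <- keep & frac < thresholds$max_mito_fraction
  }
  x$obs_ids[keep]
}

#' Depth-normalize and log-transform a count matrix
#'
#' Scales every observation to the median total count of the matrix, then
#' applies `log(1 + x)`. Two observations with proportional count vectors
#' become identical. Centering and scaling are deferred to the embedding
#' step so the normalized values stay non-negative.
#'
#' @param x A `CountMatrix`.
#' @return A list of class `NormalizedMatrix` with the same layout.
#' @export
normalize_log <- function(x) {
  depth <- Matrix::colSums(x$values)
  if (any(depth == 0))
    stop("observation(s) with all-zero counts: ",
         paste(x$obs_ids[depth == 0], collapse = ", "), call. = FALSE)
  med <- stats::median(depth)
  v <- x$values %*% Matrix::Diagonal(x = med / depth)
  v@x <- log1p(v@x)
  dimnames(v) <- list(x$gene_ids, x$obs_ids)
  structure(list(values = v, gene_ids = x$gene_ids, obs_ids = x$obs_ids),
            class = "NormalizedMatrix")
}

#' Select highly variable genes by binned dispersion
#'
#' Genes are ranked by standardized dispersion: the variance/mean ratio of
#' the normalized expression, z-scored within 20 equal-frequency bins of
#' the gene means. Ties at the cutoff break lexicographically by gene id.
#'
#' @param x A `NormalizedMatrix`.
#' @param n Number of genes to return (must not exceed the gene count).
#' @param n_bins Number of mean bins for the dispersion standardization.
#' @return Character vector of `n` gene ids, highest dispersion first.
#' @export
select_hvg <- function(x, n, n_bins = 20) {
  assert_that(n <= length(x$gene_ids),
              "n exceeds the number of genes in the matrix")
  m <- Matrix::rowMeans(x$values)
  sq <- Matrix::rowMeans(x$values^2)
  v <- (sq - m^2) * ncol(x$values) / max(ncol(x$values) - 1, 1)
  disp <- ifelse(m > 0, v / m, NA_real_)
  # equal-frequency mean bins; z-score dispersion within each bin
  ranks <- rank(m, ties.method = "first")
  bin <- ceiling(ranks / length(m) * n_bins)
  z <- rep(NA_real_, length(m))
  for (b in unique(bin)) {
    idx <- which(bin == b & !is.na(disp))
    if (length(idx) == 0) next
    mu_b <- mean(disp[idx])
    sd_b <- stats::sd(disp[idx])
    z[idx] <- if (is.na(sd_b) || sd_b == 0) 0 else (disp[idx] - mu_b) / sd_b
  }
  z[is.na(z)] <- -Inf
  ord <- order(-z, x$gene_ids)
  x$gene_ids[ord][seq_len(n)]
}
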