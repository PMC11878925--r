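# Intratumor expression programs by per-sample NMF and their clustering
# into cross-sample meta-programs.

#' Non-negative matrix factorization by multiplicative updates
#'
#' Minimizes the Frobenius reconstruction error of `V ~ W %*% H` with
#' Lee-Seung multiplicative updates from a seeded uniform random
#' initialization. Iteration stops when the relative improvement of the
#' error drops below `tol` or after `max_iter` iterations; given a seed
#' the factorization is deterministic.
#'
#' @param v Non-negative numeric matrix (genes x cells).
#' @param rank Factorization rank (`< min(dim(v))`).
#' @param seed Integer seed for the initialization.
#' @param tol Relative tolerance on the error improvement (default 1e-4).
#' @param max_iter Iteration cap (default 500).
#' @return List with `w` (genes x rank), `h` (rank x cells),
#'   `rel_error` (final relative Frobenius error), `iterations`.
#' @export
fit_nmf <- function(v, rank, seed = 1, tol = 1e-4, max_iter = 500) {
  v <- as.matrix(v)
  if (any(v < 0)) stop("NMF input must be non-negative", call. = FALSE)
  assert_that(rank >= 1 && rank < min(dim(v)), "rank must be < min(dim(v))")
  eps <- .Machine$double.eps
  nv <- norm(v, "F")
  assert_that(nv > 0, "NMF input is all zero")
  scale0 <- sqrt(mean(v) / rank)
  init <- withr::with_seed(seed, list(
    w = matrix(stats::runif(nrow(v) * rank, 0, 2 * scale0), nrow(v), rank),
    h = matrix(stats::runif(rank * ncol(v), 0, 2 * scale0), rank, ncol(v))))
  w <- init$w
  h <- init$h
  err_prev <- Inf
  it <- 0
  repeat {
    it <- it + 1
    h <- h * (crossprod(w, v) / (crossprod(w) %*% h + eps))
    w <- w * (v %*% t(h)) / (w %*% tcrossprod(h) + eps)
    err <- norm(v - w %*% h, "F") / nv
    if (it >= max_iter || (is.finite(err_prev) &&
                           (err_prev - err) / max(err_prev, eps) < tol)) break
    err_prev <- err
  }
  rownames(w) <- rownames(v)
  colnames(h) <- colnames(v)
  list(w = w, h = h, rel_error = err, iterations = it)
}

#' Choose an NMF rank by the error elbow
#'
#' Fits every rank in `rank_min:rank_max` and returns the smallest rank
#' whose relative Frobenius error improves by less than `drop` (default
#' 5%) when one more factor is added -- the point just before the
#' improvement curve flattens. If no rank qualifies, `rank_max` is
#' returned.
#'
#' @param v Non-negative matrix.
#' @param rank_min,rank_max Sweep bounds (defaults 2 and 6).
#' @param seed Seed passed to every fit.
#' @param drop Relative-improvement threshold.
#' @return Selected integer rank.
#' @export
select_rank <- function(v, rank_min = 2, rank_max = 6, seed = 1,
                        drop = 0.05) {
  assert_that(rank_min >= 2 && rank_min < rank_max,
              "need 2 <= rank_min < rank_max")
  ranks <- rank_min:rank_max
  errs <- vapply(ranks, function(r) fit_nmf(v, r, seed = seed)$rel_error,
                 numeric(1))
  for (i in seq_len(length(ranks) - 1)) {
    if ((errs[i] - errs[i + 1]) / errs[i] < drop) return(ranks[i])
  }
  ranks[length(ranks)]
}

#' Extract top-weight gene programs from an NMF basis
#'
#' One program per factor, defined by the `top_n` genes with the highest
#' basis weight (ties break lexicographically by gene id). Membership is
#' invariant to positive rescaling of a factor.
#'
#' @param w Basis matrix (genes x rank) with gene-id rownames or
#'   `gene_ids` supplied.
#' @param gene_ids Gene ids for the rows of `w`.
#' @param sample_id Sample the factorization came from.
#' @param top_n Program size (default 50, the standard program size).
#' @return List of `Program` objects (`sample_id`, `factor_index`,
#'   `genes` in descending weight order).
#' @export
extract_programs <- function(w, gene_ids = rownames(w), sample_id,
                             top_n = 50) {
  assert_that(!is.null(gene_ids), "gene ids are required")
  assert_that(top_n <= nrow(w), "top_n exceeds the gene count")
  lapply(seq_len(ncol(w)), function(j) {
    ord <- order(-w[, j], gene_ids)
    structure(list(sample_id = sample_id, factor_index = j,
                   genes = gene_ids[ord][seq_len(top_n)]),
              class = "Program")
  })
}

#' Jaccard index of two gene sets
#'
#' `|A intersect B| / |A union B|`; errors if both sets are empty.
#'
#' @param a,b Character vectors.
#' @return Numeric in \[0, 1\].
#' @export
jaccard <- function(a, b) {
  a <- unique(a)
  b <- unique(b)
  u <- length(union(a, b))
  assert_that(u > 0, "both sets are empty")
  length(intersect(a, b)) / u
}

#' Pairwise Jaccard matrix of programs
#'
#' @param programs List of `Program` objects.
#' @return Symmetric matrix with unit diagonal.
#' @export
jaccard_matrix <- function(programs) {
  n <- length(programs)
  jm <- diag(1, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (j <= i) next
    jm[i, j] <- jm[j, i] <- jaccard(programs[[i]]$genes, programs[[j]]$genes)
  }
  labs <- vapply(programs, function(p)
    paste0(p$sample_id, ".", p$factor_index), character(1))
  dimnames(jm) <- list(labs, labs)
  jm
}

#' Cluster programs across samples into meta-programs
#'
#' Average-linkage hierarchical clustering on distance `1 - Jaccard`,
#' cut at height `cut`. Clusters spanning at least two samples become
#' meta-programs; a meta-program's signature comprises the genes that
#' occur in programs from at least `ceiling(share_fraction *
#' n_contributing_samples)` distinct samples.
#'
#' @param programs List of at least two `Program` objects.
#' @param cut Dendrogram cut height (default 0.8, i.e. programs with
#'   Jaccard >= 0.2 tend to co-cluster).
#' @param share_fraction Sharing floor for signature genes (default 1/3).
#' @return List of `MetaProgram` objects (`members`,
#'   `contributing_samples`, `signature`).
#' @export
cluster_programs <- function(programs, cut = 0.8, share_fraction = 1 / 3) {
  assert_that(length(programs) >= 2, "need at least two programs")
  jm <- jaccard_matrix(programs)
  hc <- stats::hclust(stats::as.dist(1 - jm), method = "average")
  memb <- stats::cutree(hc, h = cut)
  out <- list()
  for (g in sort(unique(memb))) {
    idx <- which(memb == g)
    members <- programs[idx]
    samples <- unique(vapply(members, `[[`, character(1), "sample_id"))
    if (length(samples) < 2) next
    floor_n <- ceiling(share_fraction * length(samples))
    gene_sample <- unique(do.call(rbind, lapply(members, function(p)
      data.frame(gene = p$genes, sample = p$sample_id,
                 stringsAsFactors = FALSE))))
    tab <- table(gene_sample$gene)
    signature <- sort(names(tab)[tab >= floor_n])
    out[[length(out) + 1]] <- structure(
      list(members = members, contributing_samples = sort(samples),
           signature = signature), class = "MetaProgram")
  }
  out
}

#' Score a meta-program per cell
#'
#' Mean of the centered, unit-variance expression of the signature genes
#' present in the matrix; invariant genes contribute zero, so a constant
#' matrix scores zero everywhere.
#'
#' @param x A `NormalizedMatrix`.
#' @param mp A `MetaProgram` (or plain character vector of genes).
#' @return data.frame with `obs_id`, `score`.
#' @export
score_metaprogram <- function(x, mp) {
  genes <- if (inherits(mp, "MetaProgram")) mp$signature else mp
  present <- intersect(genes, x$gene_ids)
  assert_that(length(present) > 0, "no signature gene present in the matrix")
  sub <- as.matrix(x$values[present, , drop = FALSE])
  mu <- rowMeans(sub)
  sds <- apply(sub, 1, stats::sd)
  sds[sds == 0] <- 1
  z <- (sub - mu) / sds
  data.frame(obs_id = x$obs_ids, score = unname(colMeans(z)),
             stringsAsFactors = FALSE)
}

#' Per-sample NMF programs for a set of tumor cells
#'
#' Convenience driver: for each sample, restricts the normalized
#' expression of that sample's tumor cells to its own highly variable
#' genes, selects the NMF rank on the error elbow and extracts top-`top_n`
#' programs.
#'
#' @param x A `NormalizedMatrix` of tumor cells.
#' @param samples data.frame `obs_id`, `label` giving each cell's sample.
#' @param n_hvg Highly variable genes per sample (default 500).
#' @param rank_min,rank_max NMF rank sweep (defaults 2 and 6).
#' @param top_n Program size (default 50).
#' @param seed Integer seed.
#' @param min_cells Samples with fewer tumor cells are skipped.
#' @return List of `Program` objects across samples.
#' @export
sample_programs <- function(x, samples, n_hvg = 500, rank_min = 2,
                            rank_max = 6, top_n = 50, seed = 1,
                            min_cells = 20) {
  out <- list()
  for (s in sort(unique(samples$label))) {
    ids <- intersect(samples$obs_id[samples$label == s], x$obs_ids)
    if (length(ids) < min_cells) next
    sub <- subset_obs(x, ids)
    hvgs <- select_hvg(sub, min(n_hvg, length(sub$gene_ids)))
    v <- nmf_input(sub, hvgs)
    rk <- select_rank(v, rank_min, rank_max, seed = stage_seed(seed, s))
    fit <- fit_nmf(v, rk, seed = stage_seed(seed, s))
    out <- c(out, extract_programs(fit$w, sample_id = s, top_n = top_n))
  }
  out
}

#' Assemble the NMF input for a set of genes
#'
#' Expression relative to the gene's mean across the cells, with negative
#' residuals truncated to zero. Working on non-negative residuals rather
#' than absolute expression prevents the shared baseline profile from
#' absorbing the leading factors, so the factors capture the cell-subset
#' programs.
#'
#' @param x A `NormalizedMatrix`.
#' @param genes Genes to include (rows of the result).
#' @return Dense non-negative matrix (genes x cells).
#' @export
nmf_input <- function(x, genes) {
  sub <- as.matrix(x$values[genes, , drop = FALSE])
  sub <- sub - rowMeans(sub)
  sub[sub < 0] <- 0
  sub
}
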