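#' Embed observations with PCA and cluster the neighbour graph
#'
#' Centers and scales the highly-variable-gene submatrix, projects the
#' observations onto the leading principal components, builds a
#' k-nearest-neighbour graph in PC space and partitions it by Louvain
#' community detection at the given resolution. Labels are deterministic
#' for a fixed seed and are numbered by decreasing cluster size.
#'
#' @param x A `NormalizedMatrix`.
#' @param hvgs Gene ids to embed on (typically from [select_hvg()]).
#' @param n_pcs Number of principal components (default 20).
#' @param resolution Louvain resolution; smaller values merge clusters and
#'   values near zero yield a single cluster.
#' @param k Neighbours per observation in the graph.
#' @param seed Integer seed.
#' @return data.frame with columns `obs_id`, `label`.
#' @export
embed_and_cluster <- function(x, hvgs, n_pcs = 20, resolution = 1, k = 15,
                              seed = 1) {
  assert_that(all(hvgs %in% x$gene_ids), "hvgs must be genes of the matrix")
  n_obs <- length(x$obs_ids)
  assert_that(n_obs >= n_pcs, "fewer observations than requested PCs")
  emb <- pca_embed(x, hvgs, n_pcs)
  k <- min(k, n_obs - 1)
  d <- as.matrix(stats::dist(emb))
  edges <- matrix(0L, nrow = n_obs * k, ncol = 2)
  for (i in seq_len(n_obs)) {
    nb <- order(d[i, ])[2:(k + 1)]
    edges[((i - 1) * k + 1):(i * k), ] <- cbind(i, nb)
  }
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::simplify(g)
  comm <- withr::with_seed(seed,
    igraph::cluster_louvain(g, resolution = resolution))
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  data.frame(obs_id = x$obs_ids,
             label = as.character(relabel[as.character(memb)]),
             stringsAsFactors = FALSE)
}

# Centered/scaled PCA embedding of the HVG submatrix (observations x PCs).
pca_embed <- function(x, hvgs, n_pcs) {
  sub <- t(as.matrix(x$values[hvgs, , drop = FALSE]))
  sds <- apply(sub, 2, stats::sd)
  sds[sds == 0] <- 1
  sub <- scale(sub, center = TRUE, scale = sds)
  pc <- stats::prcomp(sub, center = FALSE, scale. = FALSE, rank. = n_pcs)
  pc$x[, seq_len(n_pcs), drop = FALSE]
}

#' One-vs-rest Wilcoxon marker detection per cluster
#'
#' For every cluster, each gene is tested with a two-sided Wilcoxon
#' rank-sum test of that cluster's observations against all others;
#' p-values are Benjamini-Hochberg adjusted within the cluster. Reported
#' markers satisfy `adjusted_p < max_adj_p` and `log2_fold_change >
#' min_lfc`; rows are sorted by adjusted p then decreasing fold change.
#' Clusters smaller than `min_cluster_size` are skipped with a warning.
#'
#' @param x A `NormalizedMatrix`.
#' @param labels data.frame with `obs_id`, `label` covering the matrix.
#' @param min_cluster_size Smallest cluster that is tested.
#' @param max_adj_p Adjusted p-value cutoff.
#' @param min_lfc log2 fold-change cutoff (on depth-normalized means).
#' @return data.frame with columns `cluster`, `gene_id`,
#'   `log2_fold_change`, `p_value`, `adjusted_p`.
#' @export
find_markers <- function(x, labels, min_cluster_size = 3, max_adj_p = 0.05,
                         min_lfc = 0.25) {
  assert_that(all(labels$obs_id %in% x$obs_ids),
              "labels refer to unknown observations")
  labs <- stats::setNames(labels$label, labels$obs_id)[x$obs_ids]
  keep_obs <- !is.na(labs)
  labs <- labs[keep_obs]
  clusters <- sort(unique(labs))
  assert_that(length(clusters) >= 2, "need at least 2 clusters")
  mat <- as.matrix(x$values[, keep_obs, drop = FALSE])
  out <- list()
  for (cl in clusters) {
    in_cl <- which(labs == cl)
    if (length(in_cl) < min_cluster_size) {
      warning(sprintf("cluster '%s' has fewer than %d observations; skipped",
                      cl, min_cluster_size), call. = FALSE)
      next
    }
    rest <- which(labs != cl)
    res <- marker_test_cluster(mat, in_cl, rest)
    res$adjusted_p <- stats::p.adjust(res$p_value, method = "BH")
    keep <- res$adjusted_p < max_adj_p & res$log2_fold_change > min_lfc
    res <- res[keep, , drop = FALSE]
    if (nrow(res)) {
      res <- res[order(res$adjusted_p, -res$log2_fold_change, res$gene_id), ]
      res <- cbind(cluster = cl, res)
      out[[cl]] <- res
    }
  }
  if (length(out) == 0)
    return(data.frame(cluster = character(), gene_id = character(),
                      log2_fold_change = numeric(), p_value = numeric(),
                      adjusted_p = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, c(out, list(make.row.names = FALSE)))
  res
}

# Vectorized two-sided Wilcoxon rank-sum of columns `in_cl` against
# `rest`, one test per row. Uses the exact null distribution for small
# tie-free groups and the tie- and continuity-corrected normal
# approximation otherwise, matching stats::wilcox.test.
marker_test_cluster <- function(mat, in_cl, rest) {
  n1 <- length(in_cl)
  n2 <- length(rest)
  nn <- n1 + n2
  genes <- rownames(mat)
  rk <- t(apply(mat, 1, rank))
  ties <- apply(mat, 1, function(r) {
    tt <- tabulate(match(r, r))
    sum(tt^3 - tt)
  })
  W <- rowSums(rk[, in_cl, drop = FALSE]) - n1 * (n1 + 1) / 2
  mu_w <- n1 * n2 / 2
  sigma <- sqrt(n1 * n2 / 12 * ((nn + 1) - ties / (nn * (nn - 1))))
  z <- W - mu_w
  p <- ifelse(sigma > 0,
              pmin(1, 2 * stats::pnorm((abs(z) - 0.5) / sigma,
                                       lower.tail = FALSE)),
              1)
  if (n1 < 50 && n2 < 50) {
    exact <- which(ties == 0)
    if (length(exact)) {
      pe <- vapply(exact, function(g) {
        w <- W[g]
        if (w > mu_w) min(1, 2 * stats::pwilcox(w - 1, n1, n2, lower.tail = FALSE))
        else min(1, 2 * stats::pwilcox(w, n1, n2))
      }, numeric(1))
      p[exact] <- pe
    }
  }
  lfc <- log2((rowMeans(expm1(mat[, in_cl, drop = FALSE])) + 1) /
                (rowMeans(expm1(mat[, rest, drop = FALSE])) + 1))
  data.frame(gene_id = genes, log2_fold_change = unname(lfc),
             p_value = unname(p), stringsAsFactors = FALSE)
}

#' Classify clusters as tumor, stromal or unknown
#'
#' A cluster is called tumor when its markers overlap the tumor signature
#' in at least `min_overlap` genes and more than they overlap the stromal
#' signature; symmetrically for stromal. Ties and weak overlaps give
#' "unknown".
#'
#' @param markers Marker table from [find_markers()].
#' @param tumor_sig,stromal_sig Character vectors of signature genes.
#' @param min_overlap Minimum marker/signature overlap for a call.
#' @param clusters Optional cluster ids to classify (defaults to those in
#'   the marker table).
#' @return data.frame with columns `cluster`, `class`.
#' @export
classify_clusters <- function(markers, tumor_sig, stromal_sig,
                              min_overlap = 5, clusters = NULL) {
  assert_that(length(tumor_sig) > 0 && length(stromal_sig) > 0,
              "signatures must be non-empty")
  clusters <- clusters %||% sort(unique(markers$cluster))
  cls <- vapply(clusters, function(cl) {
    mk <- markers$gene_id[markers$cluster == cl]
    ot <- length(intersect(mk, tumor_sig))
    os <- length(intersect(mk, stromal_sig))
    if (ot >= min_overlap && ot > os) "tumor"
    else if (os >= min_overlap && os > ot) "stromal"
    else "unknown"
  }, character(1))
  data.frame(cluster = clusters, class = unname(cls), stringsAsFactors = FALSE)
}
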