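#' Construct a gene-by-observation count matrix
#'
#' The central container of the pipeline: a sparse non-negative integer
#' matrix of transcript counts with unique gene and observation
#' identifiers. Observations are spatial spots or dissociated cells.
#'
#' @param values Matrix-like (dense or `Matrix` sparse) of non-negative
#'   counts, genes in rows, observations in columns.
#' @param gene_ids Character vector of unique gene identifiers, one per row.
#' @param obs_ids Character vector of unique observation identifiers, one
#'   per column.
#' @return An object of class `CountMatrix`: a list with elements `values`
#'   (a `dgCMatrix`), `gene_ids` and `obs_ids`.
#' @export
count_matrix <- function(values, gene_ids = rownames(values),
                         obs_ids = colnames(values)) {
  values <- to_dgc(values)
  assert_that(!is.null(gene_ids) && !is.null(obs_ids),
              "gene_ids and obs_ids are required")
  gene_ids <- as.character(gene_ids)
  obs_ids <- as.character(obs_ids)
  assert_that(length(gene_ids) == nrow(values),
              "gene_ids length does not match the number of rows")
  assert_that(length(obs_ids) == ncol(values),
              "obs_ids length does not match the number of columns")
  assert_that(!anyDuplicated(gene_ids), "gene_ids must be unique")
  assert_that(!anyDuplicated(obs_ids), "obs_ids must be unique")
  if (length(values@x) && min(values@x) < 0)
    stop("count matrix contains negative entries", call. = FALSE)
  dimnames(values) <- list(gene_ids, obs_ids)
  structure(list(values = values, gene_ids = gene_ids, obs_ids = obs_ids),
            class = "CountMatrix")
}

#' @export
dim.CountMatrix <- function(x) dim(x$values)

#' @export
print.CountMatrix <- function(x, ...) {
  cat(sprintf("<CountMatrix> %d genes x %d observations (%d nonzero)\n",
              nrow(x$values), ncol(x$values), length(x$values@x)))
  invisible(x)
}

#' Subset a count matrix to a set of observations
#'
#' @param x A `CountMatrix` (or normalized matrix of the same shape).
#' @param obs_ids Observation identifiers to keep, in the order given.
#' @return An object of the same class restricted to `obs_ids`.
#' @export
subset_obs <- function(x, obs_ids) {
  missing <- setdiff(obs_ids, x$obs_ids)
  assert_that(length(missing) == 0,
              paste("unknown observations:", paste(missing, collapse = ", ")))
  out <- x
  out$values <- x$values[, obs_ids, drop = FALSE]
  out$obs_ids <- obs_ids
  out
}

#' Read a count matrix from Matrix Market or dense TSV
#'
#' Reads the 10x-style triple layout: a matrix file plus one-id-per-line
#' gene and observation (barcode) files. The matrix file may be Matrix
#' Market coordinate format (`.mtx`) or a headerless dense TSV with genes
#' in rows. Duplicated gene identifiers are collapsed by summing their
#' rows, which is lossless for count data.
#'
#' @param matrix_path Path to the `.mtx` or dense TSV matrix.
#' @param genes_path Path to the gene id file (first column used).
#' @param obs_path Path to the observation id file (first column used).
#' @return A [count_matrix()].
#' @export
read_counts <- function(matrix_path, genes_path, obs_path) {
  for (p in c(matrix_path, genes_path, obs_path))
    assert_that(file.exists(p), paste("file not found:", p))
  gene_ids <- read_id_column(genes_path)
  obs_ids <- read_id_column(obs_path)
  first <- readLines(matrix_path, n = 1L)
  if (grepl("MatrixMarket", first, fixed = TRUE)) {
    m <- tryCatch(Matrix::readMM(matrix_path),
                  error = function(e) stop("malformed Matrix Market file: ",
                                           conditionMessage(e), call. = FALSE))
  } else {
    tab <- utils::read.delim(matrix_path, header = FALSE)
    m <- as.matrix(tab)
  }
  if (nrow(m) != length(gene_ids))
    stop(sprintf("matrix has %d rows but gene file lists %d ids",
                 nrow(m), length(gene_ids)), call. = FALSE)
  if (ncol(m) != length(obs_ids))
    stop(sprintf("matrix has %d columns but observation file lists %d ids",
                 ncol(m), length(obs_ids)), call. = FALSE)
  m <- to_dgc(m)
  if (length(m@x) && min(m@x) < 0)
    stop("count matrix contains negative entries", call. = FALSE)
  if (anyDuplicated(gene_ids)) {
    fac <- factor(gene_ids, levels = unique(gene_ids))
    m <- Matrix::fac2sparse(fac) %*% m
    gene_ids <- unique(gene_ids)
  }
  count_matrix(m, gene_ids, obs_ids)
}

read_id_column <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  vapply(strsplit(lines, "\t", fixed = TRUE), `[[`, character(1), 1L)
}

#' Write a count matrix as a Matrix Market triple
#'
#' Inverse of [read_counts()]; round-trips all nonzero entries exactly.
#'
#' @param x A `CountMatrix`.
#' @param matrix_path,genes_path,obs_path Output paths.
#' @export
write_counts <- function(x, matrix_path, genes_path, obs_path) {
  Matrix::writeMM(x$values, matrix_path)
  writeLines(x$gene_ids, genes_path)
  writeLines(x$obs_ids, obs_path)
  invisible(matrix_path)
}

#' Read gene genomic positions
#'
#' Expects a tab-delimited table with columns `gene_id`, `chromosome`,
#' `start`, `end` (header optional). Coordinates are 1-based inclusive,
#' following the GTF convention; only the start position matters
#' downstream, where genes are ordered along the genome for CNV
#' inference. Genes on chromosomes outside 1-22 and X are dropped with a
#' warning; rows are returned sorted by (karyotype order, start, gene_id).
#'
#' @param path Path to the annotation TSV.
#' @return A data.frame with columns `gene_id`, `chromosome`, `start`,
#'   `end`, sorted in karyotype order.
#' @export
read_gene_annotation <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_annotation())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4)
  assert_that(length(bad) == 0,
              paste("annotation line", bad[1], "has fewer than 4 columns"))
  first <- fields[[1]]
  has_header <- is.na(suppressWarnings(as.numeric(first[3])))
  if (has_header) fields <- fields[-1]
  if (length(fields) == 0) return(empty_annotation())
  ann <- data.frame(
    gene_id = vapply(fields, `[[`, character(1), 1L),
    chromosome = normalize_chrom(vapply(fields, `[[`, character(1), 2L)),
    start = as.numeric(vapply(fields, `[[`, character(1), 3L)),
    end = as.numeric(vapply(fields, `[[`, character(1), 4L)),
    stringsAsFactors = FALSE
  )
  assert_that(!anyDuplicated(ann$gene_id),
              "duplicated gene_id in annotation")
  if (any(ann$start > ann$end))
    stop("annotation has start > end for gene ",
         ann$gene_id[which(ann$start > ann$end)[1]], call. = FALSE)
  off <- !(ann$chromosome %in% KARYOTYPE)
  if (any(off)) {
    warning(sprintf("dropped %d gene(s) on chromosomes outside 1-22,X",
                    sum(off)), call. = FALSE)
    ann <- ann[!off, , drop = FALSE]
  }
  sort_annotation(ann)
}

empty_annotation <- function() {
  data.frame(gene_id = character(), chromosome = character(),
             start = numeric(), end = numeric(), stringsAsFactors = FALSE)
}

sort_annotation <- function(ann) {
  ord <- order(match(ann$chromosome, KARYOTYPE), ann$start, ann$gene_id)
  out <- ann[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read gene sets in GMT format
#'
#' One set per line: name, description, then tab-separated member genes.
#' Duplicate genes within a set are removed (first occurrence kept); set
#' order follows the file.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path) {
  assert_that(file.exists(path), paste("file not found:", path))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(stats::setNames(list(), character()))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3)
  assert_that(length(bad) == 0,
              paste0("GMT line ", bad[1], " has fewer than 3 fields"))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  assert_that(!anyDuplicated(names(sets)), "duplicated set names in GMT")
  sets
}

#' Write gene sets in GMT format
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], "na", sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a spot coordinate table
#'
#' Tab-delimited with header columns `obs_id`, `section_id`, `x`, `y`.
#'
#' @param path Path to the TSV.
#' @return data.frame with those columns.
#' @export
read_spot_table <- function(path) {
  df <- read_tsv(path)
  need <- c("obs_id", "section_id", "x", "y")
  assert_that(all(need %in% names(df)),
              paste("spot table must have columns:", paste(need, collapse = ", ")))
  assert_that(!anyDuplicated(df$obs_id), "duplicated obs_id in spot table")
  df[, need]
}

#' Read an observation label table
#'
#' Tab-delimited with header columns `obs_id`, `label` (cluster id, cell
#' type or clone id). Each observation may be labeled at most once.
#'
#' @param path Path to the TSV.
#' @return data.frame with columns `obs_id`, `label`.
#' @export
read_label_table <- function(path) {
  df <- read_tsv(path)
  need <- c("obs_id", "label")
  assert_that(all(need %in% names(df)),
              paste("label table must have columns:", paste(need, collapse = ", ")))
  assert_that(!anyDuplicated(df$obs_id), "duplicated obs_id in label table")
  df[, need]
}
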