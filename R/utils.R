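# Internal helpers shared across modules.

# Chromosomes retained in karyotype order; everything else (Y, MT, scaffolds)
# is dropped before position-based analyses.
KARYOTYPE <- c(as.character(1:22), "X")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @keywords internal
assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}

# Strip an optional "chr" prefix so "chr7" and "7" are the same chromosome.
normalize_chrom <- function(x) sub("^chr", "", as.character(x))

# Deterministic per-stage seed derived from a single run seed; stays within
# 32-bit integer range.
stage_seed <- function(seed, stage) {
  as.integer((as.numeric(seed) + sum(utf8ToInt(stage)) * 131) %% .Machine$integer.max)
}

# Coerce dense or sparse input to a general numeric CsparseMatrix.
to_dgc <- function(values) {
  if (!inherits(values, "Matrix"))
    values <- Matrix::Matrix(as.matrix(values), sparse = TRUE)
  methods::as(methods::as(methods::as(values, "dMatrix"), "generalMatrix"),
              "CsparseMatrix")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.delim(path, stringsAsFactors = FALSE, ...)
}
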