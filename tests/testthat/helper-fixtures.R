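# Shared fixtures, memoized so expensive cohorts are generated once per
# test run.

.fixtures <- new.env(parent = emptyenv())

cached <- function(key, fn) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- fn()
  .fixtures[[key]]
}

# The reference cohort: package defaults (3 x 400 spots, 1500 cells,
# 2000 genes, two clones, three programs).
default_cohort <- function() {
  cached("default", function() generate_cohort(cohort_config(seed = 42)))
}

# Merged + normalized views of the reference cohort's spatial sections.
default_st <- function() {
  cached("default_st", function() {
    co <- default_cohort()
    m <- merge_sections(co)
    list(cohort = co, counts = m$counts, spots = m$spots,
         norm = normalize_log(m$counts), truth = co$truth$spots)
  })
}

# CNV profile of the reference cohort against the true stromal spots.
default_profile <- function() {
  cached("default_profile", function() {
    st <- default_st()
    ref <- st$truth$obs_id[st$truth$type != "tumor"]
    infer_cnv(st$counts, ref, st$cohort$annotation)
  })
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# Tiny deterministic count matrix.
toy_counts <- function(values, genes = NULL, obs = NULL) {
  genes <- genes %||% sprintf("g%d", seq_len(nrow(values)))
  obs <- obs %||% sprintf("c%d", seq_len(ncol(values)))
  count_matrix(values, genes, obs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Hand-built CnvProfile for unit tests of burden/segmentation.
toy_profile <- function(ratios, chromosome, reference_obs = character()) {
  structure(list(
    ratios = ratios,
    obs_ids = rownames(ratios),
    gene_ids = colnames(ratios),
    chromosome = chromosome,
    window = 1,
    reference_obs = reference_obs), class = "CnvProfile")
}

# Hand-built CnvEventSet rows for tree tests.
toy_events <- function(df, n_genes_total = 200) {
  df$n_genes <- df$end_index - df$start_index + 1
  structure(list(events = df,
                 gene_ids = sprintf("g%04d", seq_len(n_genes_total)),
                 chromosome = rep("1", n_genes_total)),
            class = "CnvEventSet")
}
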