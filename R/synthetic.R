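# Synthetic multi-section cohort generator.
#
# Emulates the structure of a multi-patient ovarian-tumor study: several
# spatial sections of barcoded spots plus a matched dissociated cell set,
# with planted chromosome-scale CNV clones on top of a diploid baseline,
# planted cell-type marker signatures, and planted co-expressed programs
# shared across a subset of samples. Every planted feature is recorded in
# a ground-truth object so downstream stages can be validated exactly.

MT_GENES <- c("MT-ND1", "MT-ND2", "MT-CO1", "MT-CO2", "MT-ATP8", "MT-ATP6",
              "MT-CO3", "MT-ND3", "MT-ND4L", "MT-ND4", "MT-ND5", "MT-ND6",
              "MT-CYB")

# Approximate relative protein-coding gene counts per chromosome, used to
# spread synthetic genes over the karyotype in realistic proportions.
CHROM_WEIGHTS <- c(
  "1" = 2000, "2" = 1250, "3" = 1080, "4" = 760, "5" = 880, "6" = 1050,
  "7" = 950, "8" = 700, "9" = 790, "10" = 750, "11" = 1300, "12" = 1050,
  "13" = 330, "14" = 650, "15" = 640, "16" = 870, "17" = 1200, "18" = 300,
  "19" = 1450, "20" = 550, "21" = 250, "22" = 450, "X" = 850)

#' Describe a synthetic cell type
#'
#' @param name Cell-type name; `"tumor"` marks the malignant compartment.
#' @param n_marker_genes Number of genes up-regulated in this type.
#' @param marker_fold Fold change applied to marker genes (> 1).
#' @export
cell_type_spec <- function(name, n_marker_genes = 40, marker_fold = 4) {
  assert_that(n_marker_genes > 0, "n_marker_genes must be positive")
  assert_that(marker_fold > 1, "marker_fold must exceed 1")
  list(name = name, n_marker_genes = n_marker_genes, marker_fold = marker_fold)
}

#' Describe a planted CNV clone
#'
#' A clone is a set of chromosome-scale copy number events plus a
#' prevalence among tumor spots. A child clone (non-NULL `parent_id`)
#' carries every parental event in addition to its own, mirroring clonal
#' evolution where early events are inherited by all descendants.
#'
#' @param clone_id Clone name.
#' @param parent_id Parent clone name, or NULL for a founding clone.
#' @param events List of events, each a list with `chromosome`, `fraction`
#'   (fraction of the chromosome's genes affected, anchored at the start of
#'   the chromosome), `direction` ("gain" or "loss") and `fold` (> 1; a
#'   loss multiplies expression by 1/fold).
#' @param prevalence Fraction of tumor spots carrying this clone.
#' @param sections Section ids where the clone occurs (NULL = all).
#' @export
clone_spec <- function(clone_id, parent_id = NULL, events = list(),
                       prevalence = 0.5, sections = NULL) {
  for (e in events) {
    assert_that(all(c("chromosome", "fraction", "direction", "fold") %in% names(e)),
                "each event needs chromosome, fraction, direction, fold")
    assert_that(e$direction %in% c("gain", "loss"),
                "event direction must be 'gain' or 'loss'")
    assert_that(e$fold > 1, "event fold must exceed 1")
    assert_that(e$fraction > 0 && e$fraction <= 1,
                "event fraction must be in (0, 1]")
  }
  assert_that(prevalence > 0 && prevalence <= 1, "prevalence must be in (0, 1]")
  list(clone_id = clone_id, parent_id = parent_id, events = events,
       prevalence = prevalence, sections = sections)
}

#' Describe a planted co-expression program
#'
#' @param program_id Program name.
#' @param gene_ids Explicit member genes (>= 50), or NULL to let the
#'   generator pick `n_genes` moderately-to-highly expressed genes.
#' @param n_genes Number of genes when `gene_ids` is NULL.
#' @param active_samples Cell-sample ids in which the program is active.
#' @param activity_fold Fold change applied to program genes in
#'   program-active cells.
#' @export
program_spec <- function(program_id, gene_ids = NULL, n_genes = 50,
                         active_samples, activity_fold = 3) {
  assert_that(activity_fold > 1, "activity_fold must exceed 1")
  if (!is.null(gene_ids)) assert_that(length(gene_ids) >= 50,
                                      "programs need at least 50 genes")
  list(program_id = program_id, gene_ids = gene_ids, n_genes = n_genes,
       active_samples = active_samples, activity_fold = activity_fold)
}

default_cell_types <- function() {
  list(cell_type_spec("tumor", 60, 4),
       cell_type_spec("fibroblast", 40, 4),
       cell_type_spec("macrophage", 40, 4),
       cell_type_spec("endothelial", 30, 4),
       cell_type_spec("mesothelial", 30, 4))
}

default_clones <- function() {
  # Two founding clones with disjoint events: tumors arising from multiple
  # CNV origins rather than a single source.
  list(
    clone_spec("clone_1", events = list(
      list(chromosome = "7", fraction = 1, direction = "gain", fold = 1.5)),
      prevalence = 0.5),
    clone_spec("clone_2", events = list(
      list(chromosome = "2", fraction = 1, direction = "gain", fold = 1.5),
      list(chromosome = "17", fraction = 1, direction = "loss", fold = 1.5)),
      prevalence = 0.5))
}

default_programs <- function(n_cell_samples = 5) {
  active <- paste0("P", seq_len(max(n_cell_samples - 1, 1)))
  list(program_spec("prog_1", active_samples = active),
       program_spec("prog_2", active_samples = active),
       program_spec("prog_3", active_samples = active))
}

#' Configuration of a synthetic cohort
#'
#' Defaults describe the reference fixture: 3 sections of 400 spots,
#' 1,500 cells from 5 samples, 2,000 genes (13 of them mitochondrial),
#' negative binomial counts with shared dispersion 0.3, baseline mean 3
#' counts per gene per observation (the depth scale of a well-covered
#' spot), two founding CNV clones and three shared expression programs.
#'
#' @param n_sections,spots_per_section,n_cells,n_cell_samples,n_genes
#'   Cohort dimensions.
#' @param baseline_mean Mean counts per gene per observation before any
#'   multiplier; per-gene means are lognormal around this value.
#' @param mu_sdlog Log-sd of the per-gene baseline means.
#' @param dispersion Negative binomial dispersion shared by all genes
#'   (`size = 1/dispersion`).
#' @param depth_sdlog Log-sd of per-observation sequencing-depth factors.
#' @param tumor_fraction Fraction of spots (and cells) that are tumor.
#' @param mito_fraction_range Range of the per-observation mitochondrial
#'   count fraction (uniform draw).
#' @param cell_types List of [cell_type_spec()]; must contain "tumor".
#' @param clones List of [clone_spec()].
#' @param programs List of [program_spec()], or NULL for none.
#' @param seed Integer seed; identical config + seed gives identical output.
#' @return A list of class `CohortConfig`.
#' @export
cohort_config <- function(n_sections = 3, spots_per_section = 400,
                          n_cells = 1500, n_cell_samples = 5, n_genes = 2000,
                          baseline_mean = 3, mu_sdlog = 1, dispersion = 0.3,
                          depth_sdlog = 0.35, tumor_fraction = 0.5,
                          mito_fraction_range = c(0.01, 0.20),
                          cell_types = default_cell_types(),
                          clones = default_clones(),
                          programs = default_programs(n_cell_samples),
                          seed = 1) {
  assert_that(all(c(n_sections, spots_per_section, n_cells, n_genes) > 0),
              "all cohort dimensions must be positive")
  assert_that(n_genes > length(MT_GENES), "n_genes must exceed 13")
  assert_that(baseline_mean > 0 && dispersion > 0, "rates must be positive")
  assert_that(tumor_fraction > 0 && tumor_fraction < 1,
              "tumor_fraction must be in (0, 1)")
  assert_that(length(mito_fraction_range) == 2 &&
                all(mito_fraction_range >= 0 & mito_fraction_range < 1) &&
                mito_fraction_range[1] <= mito_fraction_range[2],
              "mito_fraction_range must be an increasing pair in [0, 1)")
  assert_that("tumor" %in% vapply(cell_types, `[[`, character(1), "name"),
              "cell_types must include a 'tumor' type")
  sections <- paste0("S", seq_len(n_sections))
  for (s in sections) {
    tot <- 0
    for (cl in clones)
      if (is.null(cl$sections) || s %in% cl$sections) tot <- tot + cl$prevalence
    assert_that(tot <= 1 + 1e-9,
                paste("clone prevalences exceed 1 in section", s))
  }
  structure(list(
    n_sections = n_sections, spots_per_section = spots_per_section,
    n_cells = n_cells, n_cell_samples = n_cell_samples, n_genes = n_genes,
    baseline_mean = baseline_mean, mu_sdlog = mu_sdlog,
    dispersion = dispersion, depth_sdlog = depth_sdlog,
    tumor_fraction = tumor_fraction,
    mito_fraction_range = mito_fraction_range, cell_types = cell_types,
    clones = clones, programs = programs, seed = seed),
    class = "CohortConfig")
}

# Assign contiguous patches: repeatedly seed a random unassigned position
# and claim its `size` nearest unassigned neighbours.
grow_patches <- function(xy, sizes) {
  lab <- rep(NA_character_, nrow(xy))
  for (i in seq_along(sizes)) {
    free <- which(is.na(lab))
    if (length(free) == 0) break
    size <- min(sizes[i], length(free))
    center <- free[sample.int(length(free), 1)]
    d <- (xy$x[free] - xy$x[center])^2 + (xy$y[free] - xy$y[center])^2
    take <- free[order(d)[seq_len(size)]]
    lab[take] <- names(sizes)[i]
  }
  lab
}

# Resolve each clone's effective events (own plus inherited) as gene sets.
resolve_clone_events <- function(clones, ann) {
  by_id <- stats::setNames(clones, vapply(clones, `[[`, character(1), "clone_id"))
  out <- list()
  for (id in names(by_id)) {
    chain <- list()
    cur <- by_id[[id]]
    repeat {
      chain <- c(cur$events, chain)
      if (is.null(cur$parent_id)) break
      assert_that(cur$parent_id %in% names(by_id),
                  paste("unknown parent clone:", cur$parent_id))
      cur <- by_id[[cur$parent_id]]
    }
    events <- lapply(chain, function(e) {
      chrom <- normalize_chrom(e$chromosome)
      genes <- ann$gene_id[ann$chromosome == chrom]
      n_take <- ceiling(e$fraction * length(genes))
      e$gene_ids <- genes[seq_len(n_take)]
      e$multiplier <- if (e$direction == "gain") e$fold else 1 / e$fold
      e
    })
    out[[id]] <- events
  }
  out
}

#' Generate a synthetic cohort with planted ground truth
#'
#' Counts for gene g in observation i are negative binomial with mean
#' `mu_g * depth_i * f_type * f_clone * f_program` and shared dispersion;
#' mitochondrial genes are rescaled per observation to occupy a drawn
#' fraction of total counts. Clone spots form contiguous patches per
#' section; stromal types likewise occupy coherent regions.
#'
#' @param config A [cohort_config()].
#' @return A list of class `Cohort` with elements `sections` (list of
#'   `list(counts, spots)`), `cells` (`list(counts, types, samples)`),
#'   `annotation` (gene positions, karyotype-sorted) and `truth` (planted
#'   assignments, marker/program gene sets, per-gene means, clone events).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "CohortConfig"))
  withr::with_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(config) {
  G <- config$n_genes
  n_reg <- G - length(MT_GENES)
  gene_ids <- c(sprintf("G%05d", seq_len(n_reg)), MT_GENES)

  # genome layout for the non-mitochondrial genes
  w <- CHROM_WEIGHTS / sum(CHROM_WEIGHTS)
  n_per_chrom <- floor(w * n_reg)
  rem <- n_reg - sum(n_per_chrom)
  if (rem > 0) {
    top <- order(w * n_reg - n_per_chrom, decreasing = TRUE)[seq_len(rem)]
    n_per_chrom[top] <- n_per_chrom[top] + 1
  }
  chroms <- rep(names(CHROM_WEIGHTS), n_per_chrom)
  starts <- unlist(lapply(n_per_chrom, function(n)
    sort(sample.int(1e8, n))), use.names = FALSE)
  ann <- data.frame(gene_id = gene_ids[seq_len(n_reg)], chromosome = chroms,
                    start = starts, end = starts + 999,
                    stringsAsFactors = FALSE)
  ann <- sort_annotation(ann)

  mu <- stats::setNames(stats::rlnorm(
    G, meanlog = log(config$baseline_mean) - config$mu_sdlog^2 / 2,
    sdlog = config$mu_sdlog), gene_ids)

  # marker genes: disjoint random blocks of non-mitochondrial genes
  type_names <- vapply(config$cell_types, `[[`, character(1), "name")
  pool <- sample(gene_ids[seq_len(n_reg)])
  markers <- list()
  offset <- 0
  for (ct in config$cell_types) {
    assert_that(offset + ct$n_marker_genes <= n_reg,
                "not enough genes for the requested marker blocks")
    markers[[ct$name]] <- pool[(offset + 1):(offset + ct$n_marker_genes)]
    offset <- offset + ct$n_marker_genes
  }

  # program genes: drawn from expressed (mu >= median), non-marker genes
  programs <- config$programs %||% list()
  prog_genes <- list()
  if (length(programs)) {
    used <- unlist(markers, use.names = FALSE)
    avail <- setdiff(gene_ids[seq_len(n_reg)], used)
    avail <- avail[mu[avail] >= stats::median(mu)]
    avail <- sample(avail)
    off2 <- 0
    for (p in programs) {
      if (is.null(p$gene_ids)) {
        assert_that(off2 + p$n_genes <= length(avail),
                    "not enough expressed genes for the requested programs")
        prog_genes[[p$program_id]] <- avail[(off2 + 1):(off2 + p$n_genes)]
        off2 <- off2 + p$n_genes
      } else {
        prog_genes[[p$program_id]] <- p$gene_ids
      }
    }
  }

  clone_events <- resolve_clone_events(config$clones, ann)
  clone_ids <- names(clone_events)

  # per-type / per-clone / per-program expression multipliers
  type_mult <- lapply(config$cell_types, function(ct) {
    m <- rep(1, G)
    m[match(markers[[ct$name]], gene_ids)] <- ct$marker_fold
    m
  })
  names(type_mult) <- type_names
  clone_mult <- lapply(clone_events, function(evts) {
    m <- rep(1, G)
    for (e in evts) m[match(e$gene_ids, gene_ids)] <- m[match(e$gene_ids, gene_ids)] * e$multiplier
    m
  })
  prog_mult <- lapply(names(prog_genes), function(pid) {
    p <- programs[[which(vapply(programs, `[[`, character(1), "program_id") == pid)]]
    m <- rep(1, G)
    m[match(prog_genes[[pid]], gene_ids)] <- p$activity_fold
    m
  })
  names(prog_mult) <- names(prog_genes)

  stromal_types <- setdiff(type_names, "tumor")
  sections <- paste0("S", seq_len(config$n_sections))
  is_mt <- gene_ids %in% MT_GENES
  size_nb <- 1 / config$dispersion

  draw_counts <- function(mean_mat) {
    cnt <- matrix(0, nrow = G, ncol = ncol(mean_mat))
    for (j in seq_len(ncol(mean_mat)))
      cnt[, j] <- stats::rnbinom(G, size = size_nb, mu = mean_mat[, j])
    cnt
  }

  obs_mean <- function(type, clone, program, depth) {
    m <- mu * depth
    if (!is.na(type) && type %in% names(type_mult)) m <- m * type_mult[[type]]
    if (!is.na(clone) && clone %in% names(clone_mult)) m <- m * clone_mult[[clone]]
    if (!is.na(program) && program %in% names(prog_mult)) m <- m * prog_mult[[program]]
    # rescale mitochondrial genes to a drawn fraction of total counts
    f <- stats::runif(1, config$mito_fraction_range[1], config$mito_fraction_range[2])
    s_other <- sum(m[!is_mt])
    s_mt <- sum(m[is_mt])
    if (s_mt > 0 && f > 0) m[is_mt] <- m[is_mt] * (f / (1 - f)) * s_other / s_mt
    m
  }

  # --- spatial sections -------------------------------------------------
  section_out <- list()
  spot_truth <- list()
  for (s in sections) {
    n <- config$spots_per_section
    nx <- ceiling(sqrt(n))
    xy <- data.frame(x = (seq_len(n) - 1) %% nx, y = (seq_len(n) - 1) %/% nx)
    n_tumor <- round(config$tumor_fraction * n)
    region <- grow_patches(xy, c(tumor = n_tumor))
    region[is.na(region)] <- "stroma"
    tumor_idx <- which(region == "tumor")
    stroma_idx <- which(region == "stroma")

    # clones occupy contiguous patches inside the tumor region
    active <- Filter(function(cl) is.null(cl$sections) || s %in% cl$sections,
                     config$clones)
    clone_lab <- rep(NA_character_, n)
    if (length(active)) {
      sizes <- stats::setNames(
        vapply(active, function(cl) floor(cl$prevalence * length(tumor_idx)), numeric(1)),
        vapply(active, `[[`, character(1), "clone_id"))
      clone_lab[tumor_idx] <- grow_patches(xy[tumor_idx, , drop = FALSE], sizes)
    }

    type_lab <- rep(NA_character_, n)
    type_lab[tumor_idx] <- "tumor"
    if (length(stroma_idx)) {
      base <- length(stroma_idx) %/% length(stromal_types)
      sz <- rep(base, length(stromal_types))
      sz[seq_len(length(stroma_idx) - base * length(stromal_types))] <-
        sz[seq_len(length(stroma_idx) - base * length(stromal_types))] + 1
      names(sz) <- stromal_types
      type_lab[stroma_idx] <- grow_patches(xy[stroma_idx, , drop = FALSE], sz)
    }

    obs_ids <- sprintf("%s_spot%04d", s, seq_len(n))
    depth <- stats::rlnorm(n, 0, config$depth_sdlog)
    means <- vapply(seq_len(n), function(i)
      obs_mean(type_lab[i], clone_lab[i], NA_character_, depth[i]),
      numeric(G))
    cnt <- draw_counts(means)
    dimnames(cnt) <- list(gene_ids, obs_ids)
    section_out[[s]] <- list(
      counts = count_matrix(cnt),
      spots = data.frame(obs_id = obs_ids, section_id = s, x = xy$x, y = xy$y,
                         stringsAsFactors = FALSE))
    spot_truth[[s]] <- data.frame(
      obs_id = obs_ids, section_id = s, x = xy$x, y = xy$y, type = type_lab,
      clone = ifelse(is.na(clone_lab), "none", clone_lab),
      stringsAsFactors = FALSE)
  }

  # --- dissociated cells ------------------------------------------------
  n_cells <- config$n_cells
  samples <- paste0("P", seq_len(config$n_cell_samples))
  cell_sample <- sample(samples, n_cells, replace = TRUE)
  cell_type <- ifelse(stats::runif(n_cells) < config$tumor_fraction, "tumor",
                      sample(stromal_types, n_cells, replace = TRUE))
  cell_clone <- rep(NA_character_, n_cells)
  tum <- which(cell_type == "tumor")
  if (length(clone_ids) && length(tum)) {
    prev <- vapply(config$clones, `[[`, numeric(1), "prevalence")
    probs <- c(prev, max(0, 1 - sum(prev)))
    cell_clone[tum] <- sample(c(clone_ids, "none"), length(tum),
                              replace = TRUE, prob = probs)
    cell_clone[cell_clone == "none"] <- NA_character_
  }
  cell_prog <- rep(NA_character_, n_cells)
  if (length(programs)) {
    for (i in tum) {
      act <- vapply(programs, function(p)
        cell_sample[i] %in% p$active_samples, logical(1))
      opts <- c(names(prog_genes)[act], "none")
      pick <- sample(opts, 1)
      if (pick != "none") cell_prog[i] <- pick
    }
  }
  cell_ids <- sprintf("cell%05d", seq_len(n_cells))
  depth_c <- stats::rlnorm(n_cells, 0, config$depth_sdlog)
  means_c <- vapply(seq_len(n_cells), function(i)
    obs_mean(cell_type[i], cell_clone[i], cell_prog[i], depth_c[i]),
    numeric(G))
  cnt_c <- draw_counts(means_c)
  dimnames(cnt_c) <- list(gene_ids, cell_ids)

  truth <- list(
    spots = do.call(rbind, c(spot_truth, list(make.row.names = FALSE))),
    cells = data.frame(obs_id = cell_ids, sample_id = cell_sample,
                       type = cell_type,
                       clone = ifelse(is.na(cell_clone), "none", cell_clone),
                       program = ifelse(is.na(cell_prog), "none", cell_prog),
                       stringsAsFactors = FALSE),
    gene_mu = mu,
    markers = markers,
    programs = prog_genes,
    clone_events = clone_events,
    mito_genes = MT_GENES,
    config = config)

  structure(list(
    sections = section_out,
    cells = list(
      counts = count_matrix(cnt_c),
      types = data.frame(obs_id = cell_ids, label = cell_type,
                         stringsAsFactors = FALSE),
      samples = data.frame(obs_id = cell_ids, label = cell_sample,
                           stringsAsFactors = FALSE)),
    annotation = ann,
    truth = truth), class = "Cohort")
}

#' Concatenate the spatial sections of a cohort
#'
#' @param cohort A `Cohort`.
#' @return `list(counts, spots)` with all sections' spots side by side.
#' @export
merge_sections <- function(cohort) {
  mats <- lapply(cohort$sections, function(s) s$counts$values)
  spots <- do.call(rbind, c(lapply(cohort$sections, `[[`, "spots"),
                            list(make.row.names = FALSE)))
  list(counts = count_matrix(do.call(cbind, mats)), spots = spots)
}

#' Write a cohort to disk in the pipeline's exchange formats
#'
#' Emits, per section and for the cell set, a Matrix Market triple, plus
#' spot/label/sample tables, the gene annotation, and GMT files of the
#' planted marker signatures and programs.
#'
#' @param cohort A `Cohort`.
#' @param dir Output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (s in names(cohort$sections)) {
    sec <- cohort$sections[[s]]
    write_counts(sec$counts,
                 file.path(dir, paste0(s, "_matrix.mtx")),
                 file.path(dir, paste0(s, "_genes.tsv")),
                 file.path(dir, paste0(s, "_barcodes.tsv")))
    write_tsv(sec$spots, file.path(dir, paste0(s, "_spots.tsv")))
  }
  write_counts(cohort$cells$counts, file.path(dir, "cells_matrix.mtx"),
               file.path(dir, "cells_genes.tsv"),
               file.path(dir, "cells_barcodes.tsv"))
  write_tsv(cohort$cells$types, file.path(dir, "cells_types.tsv"))
  write_tsv(cohort$cells$samples, file.path(dir, "cells_samples.tsv"))
  write_tsv(cohort$annotation, file.path(dir, "gene_annotation.tsv"))
  write_gmt(cohort$truth$markers, file.path(dir, "marker_signatures.gmt"))
  if (length(cohort$truth$programs))
    write_gmt(cohort$truth$programs, file.path(dir, "planted_programs.gmt"))
  write_tsv(cohort$truth$spots, file.path(dir, "truth_spots.tsv"))
  write_tsv(cohort$truth$cells, file.path(dir, "truth_cells.tsv"))
  invisible(dir)
}
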