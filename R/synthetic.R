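#' Simulation configuration
#'
#' Collects every knob of the synthetic-data generator in one validated
#' object. Defaults describe the experimental design the analysis targets:
#' a three-group single-cell comparison (lean-vehicle, obese-vehicle,
#' obese-drug), a 2x2 fraction-by-treatment polysome RNA-seq design with
#' three replicates per cell, negative-binomial counts with log-normal
#' gene baselines and log-normal library-size heterogeneity, and 5'UTRs of
#' realistic length (50-300 nt) with a G-rich hexamer planted in the
#' foreground set.
#'
#' @param seed master seed; every stage derives its own stream from it via
#'   [child_seed()].
#' @param n_genes number of genes.
#' @param n_cells_per_group cells per single-cell group.
#' @param groups ordered group labels (reference, disease, disease+drug).
#' @param n_reps bulk replicates per (fraction, treatment) cell; must be
#'   at least 2 so the interaction model has residual degrees of freedom.
#' @param dispersion NB inverse-size parameter (> 0), shared across genes.
#' @param depth_mean expected single-cell library size (UMIs).
#' @param bulk_depth_mean expected bulk library size (counts).
#' @param effect_log2fc planted effect size, log2 units.
#' @param frac_reversed,frac_buffered,frac_dtet planted class proportions
#'   (each split evenly between up and down where signed); must sum to
#'   at most 1.
#' @param utr_len_range 5'UTR length range in nt, within `[20, 5000]`.
#' @param motif planted hexamer over `{A,C,G,T}`.
#' @param motif_rate expected planted copies per foreground 5'UTR
#'   (Poisson).
#' @param base_probs background base probabilities (named A/C/G/T).
#' @param n_cell_types number of cell types in the single-cell design.
#' @param frac_marker proportion of genes planted as cell-type markers
#'   (drawn from the null class).
#' @param qc_violation_frac fraction of cells engineered to violate each
#'   QC criterion (high mito; low depth; high depth).
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_genes = 1000L,
                       n_cells_per_group = 200L,
                       groups = c("lean-vehicle", "obese-vehicle",
                                  "obese-drug"),
                       n_reps = 3L,
                       dispersion = 0.1,
                       depth_mean = 5000,
                       bulk_depth_mean = 1e6,
                       effect_log2fc = 2,
                       frac_reversed = 0.10,
                       frac_buffered = 0.05,
                       frac_dtet = 0.10,
                       utr_len_range = c(50L, 300L),
                       motif = "GGCGGG",
                       motif_rate = 2,
                       base_probs = c(A = 0.25, C = 0.25, G = 0.25,
                                      T = 0.25),
                       n_cell_types = 2L,
                       frac_marker = 0.02,
                       qc_violation_frac = 0.02) {
  cfg <- list(seed = as.integer(seed), n_genes = as.integer(n_genes),
              n_cells_per_group = as.integer(n_cells_per_group),
              groups = groups, n_reps = as.integer(n_reps),
              dispersion = dispersion, depth_mean = depth_mean,
              bulk_depth_mean = bulk_depth_mean,
              effect_log2fc = effect_log2fc,
              frac_reversed = frac_reversed,
              frac_buffered = frac_buffered, frac_dtet = frac_dtet,
              utr_len_range = as.integer(utr_len_range), motif = motif,
              motif_rate = motif_rate, base_probs = base_probs,
              n_cell_types = as.integer(n_cell_types),
              frac_marker = frac_marker,
              qc_violation_frac = qc_violation_frac)
  validate_sim_config(cfg)
}

#' @rdname sim_config
#' @param cfg a `sim_config` list to re-validate.
#' @export
validate_sim_config <- function(cfg) {
  check_scalar(cfg$dispersion, "dispersion", lower = 0, closed_lower = FALSE)
  check_scalar(cfg$depth_mean, "depth_mean", lower = 0, closed_lower = FALSE)
  check_scalar(cfg$bulk_depth_mean, "bulk_depth_mean", lower = 0,
               closed_lower = FALSE)
  check_scalar(cfg$n_genes, "n_genes", lower = 1)
  check_scalar(cfg$n_cells_per_group, "n_cells_per_group", lower = 1)
  check_scalar(cfg$n_reps, "n_reps", lower = 1)
  check_scalar(cfg$motif_rate, "motif_rate", lower = 0)
  for (f in c("frac_reversed", "frac_buffered", "frac_dtet",
              "frac_marker", "qc_violation_frac"))
    check_scalar(cfg[[f]], f, lower = 0, upper = 1)
  if (cfg$frac_reversed + cfg$frac_buffered + cfg$frac_dtet > 1)
    abort("planted class proportions sum to more than 1")
  if (length(cfg$groups) != 3L)
    abort("exactly three group labels are required")
  if (nchar(cfg$motif) != 6L)
    abort("motif must be a hexamer (6 nt), got '", cfg$motif, "'")
  if (grepl("[^ACGT]", cfg$motif))
    abort("motif contains characters outside {A,C,G,T}: '", cfg$motif, "'")
  if (length(cfg$utr_len_range) != 2L || cfg$utr_len_range[1] < 20L ||
      cfg$utr_len_range[2] > 5000L ||
      cfg$utr_len_range[1] > cfg$utr_len_range[2])
    abort("utr_len_range must be an increasing pair within [20, 5000]")
  if (abs(sum(cfg$base_probs) - 1) > 1e-8 || any(cfg$base_probs < 0) ||
      !identical(sort(names(cfg$base_probs)), c("A", "C", "G", "T")))
    abort("base_probs must be named A/C/G/T probabilities summing to 1")
  structure(cfg, class = "sim_config")
}

# internal: deterministic per-gene planted class assignment
plant_classes <- function(cfg) {
  n <- cfg$n_genes
  n_rev <- as.integer(round(cfg$frac_reversed * n))
  n_buf <- as.integer(round(cfg$frac_buffered * n))
  n_dte <- as.integer(round(cfg$frac_dtet * n))
  cls <- rep("null", n)
  i <- 0L
  take <- function(k) {
    idx <- seq_len(k) + i
    i <<- i + k
    idx
  }
  cls[take(ceiling(n_rev / 2))] <- "reversed_up"
  cls[take(floor(n_rev / 2))] <- "reversed_down"
  cls[take(n_buf)] <- "buffered"
  cls[take(ceiling(n_dte / 2))] <- "dtet_up"
  cls[take(floor(n_dte / 2))] <- "dtet_down"
  genes <- sprintf("gene%04d", seq_len(n))
  data.frame(gene = genes, class = cls, stringsAsFactors = FALSE)
}

# internal: log-normal relative expression, normalised to sum 1
baseline_rel <- function(n_genes, sdlog = 1) {
  r <- stats::rlnorm(n_genes, meanlog = 0, sdlog = sdlog)
  r / sum(r)
}

#' Simulate a three-group single-cell experiment
#'
#' Generates NB cell x gene counts for the lean-vehicle / obese-vehicle /
#' obese-drug design. Genes planted as `reversed_up` have their mean
#' multiplied by `2^effect_log2fc` in the disease group and restored to
#' baseline under drug; `reversed_down` is symmetric. A `frac_marker`
#' share of null genes is upregulated in one cell type to exercise marker
#' detection, and `qc_violation_frac` of cells per criterion are
#' engineered to fail QC (high mitochondrial fraction; very low or very
#' high library size).
#'
#' @param cfg a [sim_config()].
#' @return list with elements `matrix` (a [cell_matrix()]) and `truth`
#'   (data.frame: gene, class, marker_for).
#' @export
simulate_sc_experiment <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, "sc"))
  truth <- plant_classes(cfg)
  n_cells <- 3L * cfg$n_cells_per_group
  group <- rep(cfg$groups, each = cfg$n_cells_per_group)
  cell_type <- paste0("type", sample.int(cfg$n_cell_types, n_cells,
                                         replace = TRUE))

  # marker genes: null genes upregulated in one cell type
  n_marker <- as.integer(round(cfg$frac_marker * cfg$n_genes))
  null_idx <- which(truth$class == "null")
  marker_idx <- utils::head(null_idx, n_marker)
  truth$marker_for <- NA_character_
  if (n_marker > 0)
    truth$marker_for[marker_idx] <-
      paste0("type", rep_len(seq_len(cfg$n_cell_types), n_marker))

  rel <- baseline_rel(cfg$n_genes)
  fc <- 2^cfg$effect_log2fc
  # group multipliers: disease effect present in group 2 only (restored by drug)
  mult <- matrix(1, nrow = cfg$n_genes, ncol = 3)
  mult[truth$class == "reversed_up", 2] <- fc
  mult[truth$class == "reversed_down", 2] <- 1 / fc

  sf <- stats::rlnorm(n_cells, 0, 0.2)
  n_viol <- as.integer(round(cfg$qc_violation_frac * n_cells))
  ord <- sample.int(n_cells)                  # violators spread across groups
  low_depth <- ord[seq_len(n_viol)]
  high_depth <- ord[seq_len(n_viol) + n_viol]
  high_mito <- ord[seq_len(n_viol) + 2L * n_viol]
  sf[low_depth] <- sf[low_depth] * 0.02
  sf[high_depth] <- sf[high_depth] * 8

  mito <- stats::rbeta(n_cells, 2, 20)        # typical healthy-cell range
  mito[high_mito] <- stats::runif(length(high_mito), 0.26, 0.6)

  group_idx <- rep(1:3, each = cfg$n_cells_per_group)
  counts <- matrix(0L, nrow = n_cells, ncol = cfg$n_genes)
  for (g in 1:3) {
    rows <- which(group_idx == g)
    mu <- outer(sf[rows] * cfg$depth_mean, rel * mult[, g])
    counts[rows, ] <- stats::rnbinom(length(mu), mu = mu,
                                     size = 1 / cfg$dispersion)
  }
  colnames(counts) <- truth$gene

  # upregulate markers in their own cell type by re-drawing those cells
  if (n_marker > 0) {
    for (j in seq_along(marker_idx)) {
      gi <- marker_idx[j]
      rows <- which(cell_type == truth$marker_for[gi])
      mu <- sf[rows] * cfg$depth_mean * rel[gi] * fc
      counts[rows, gi] <- stats::rnbinom(length(rows), mu = mu,
                                         size = 1 / cfg$dispersion)
    }
  }

  cells <- data.frame(cell = sprintf("cell%05d", seq_len(n_cells)),
                      group = group, cell_type = cell_type,
                      mito_frac = mito, stringsAsFactors = FALSE)
  list(matrix = cell_matrix(counts, cells, truth$gene), truth = truth)
}

#' Simulate a 2x2 polysome RNA-seq experiment
#'
#' Generates NB gene x sample counts over the fraction (total, polysome)
#' by treatment (vehicle, drug) design with `n_reps` replicates per cell.
#' `buffered` genes carry `effect_log2fc` in the total-RNA treatment
#' contrast but none in the polysome contrast (their interaction term is
#' therefore `-effect_log2fc`); `dtet_up`/`dtet_down` genes carry the
#' effect only in the polysome fraction, i.e. a pure interaction of
#' `+/- effect_log2fc`.
#'
#' @param cfg a [sim_config()] with `n_reps >= 2`.
#' @return list with elements `counts` (a [bulk_counts()]) and `truth`.
#' @export
simulate_polysome_experiment <- function(cfg) {
  cfg <- validate_sim_config(cfg)
  if (cfg$n_reps < 2L)
    abort("n_reps = ", cfg$n_reps,
          " leaves no residual degrees of freedom; need at least 2")
  set.seed(child_seed(cfg$seed, "bulk"))
  truth <- plant_classes(cfg)
  rel <- baseline_rel(cfg$n_genes)
  fc <- 2^cfg$effect_log2fc

  design <- expand.grid(replicate = seq_len(cfg$n_reps),
                        treatment = c("vehicle", "drug"),
                        fraction = c("total", "polysome"),
                        stringsAsFactors = FALSE)
  design$sample <- sprintf("%s_%s_r%d", design$fraction, design$treatment,
                           design$replicate)
  n_s <- nrow(design)

  # per-gene drug multiplier in each fraction
  drug_total <- rep(1, cfg$n_genes)
  drug_poly <- rep(1, cfg$n_genes)
  drug_total[truth$class == "buffered"] <- fc
  drug_poly[truth$class == "dtet_up"] <- fc
  drug_poly[truth$class == "dtet_down"] <- 1 / fc

  sf <- stats::rlnorm(n_s, 0, 0.2)
  counts <- matrix(0L, nrow = cfg$n_genes, ncol = n_s)
  for (s in seq_len(n_s)) {
    m <- rel * cfg$bulk_depth_mean * sf[s]
    if (design$treatment[s] == "drug")
      m <- m * (if (design$fraction[s] == "total") drug_total else drug_poly)
    counts[, s] <- stats::rnbinom(cfg$n_genes, mu = m,
                                  size = 1 / cfg$dispersion)
  }
  rownames(counts) <- truth$gene
  list(counts = bulk_counts(counts,
                            design[, c("sample", "fraction", "treatment",
                                       "replicate")]),
       truth = truth)
}

# internal: one random sequence from base_probs
random_seq <- function(len, base_probs) {
  paste(sample(names(base_probs), len, replace = TRUE, prob = base_probs),
        collapse = "")
}

#' Simulate transcript-region sequences with a planted 5'UTR motif
#'
#' Foreground 5'UTRs receive `Poisson(motif_rate)` non-overlapping copies
#' of the configured hexamer at uniform positions; background 5'UTRs, and
#' all CDS/3'UTR regions, contain none beyond chance. Base composition is
#' i.i.d. from `cfg$base_probs`.
#'
#' @param cfg a [sim_config()].
#' @param n_fg,n_bg foreground and background transcript counts.
#' @return list with `regions` (data.frame: tx, region, seq) and `truth`
#'   (list: `foreground` tx ids, `sites` data.frame of planted 0-based
#'   motif start positions).
#' @export
simulate_transcripts <- function(cfg, n_fg = 200L, n_bg = 200L) {
  cfg <- validate_sim_config(cfg)
  set.seed(child_seed(cfg$seed, "utr"))
  n <- n_fg + n_bg
  tx <- c(sprintf("txFG%04d", seq_len(n_fg)),
          sprintf("txBG%04d", seq_len(n_bg)))
  is_fg <- c(rep(TRUE, n_fg), rep(FALSE, n_bg))
  utr_len <- sample(seq(cfg$utr_len_range[1], cfg$utr_len_range[2]), n,
                    replace = TRUE)
  sites <- list()
  utr5 <- character(n)
  for (i in seq_len(n)) {
    s <- random_seq(utr_len[i], cfg$base_probs)
    if (is_fg[i] && cfg$motif_rate > 0) {
      k <- stats::rpois(1, cfg$motif_rate)
      placed <- integer(0)
      for (j in seq_len(k)) {
        pos <- sample.int(utr_len[i] - 5L, 1L) - 1L   # 0-based start
        if (any(abs(placed - pos) < 6L)) next          # keep plants disjoint
        substr(s, pos + 1L, pos + 6L) <- cfg$motif
        placed <- c(placed, pos)
      }
      if (length(placed))
        sites[[tx[i]]] <- sort(placed)
    }
    utr5[i] <- s
  }
  cds_len <- 3L * sample(100:400, n, replace = TRUE)
  utr3_len <- sample(seq(cfg$utr_len_range[1], cfg$utr_len_range[2]), n,
                     replace = TRUE)
  cds <- vapply(cds_len, random_seq, character(1),
                base_probs = cfg$base_probs)
  utr3 <- vapply(utr3_len, random_seq, character(1),
                 base_probs = cfg$base_probs)
  regions <- data.frame(
    tx = rep(tx, 3L),
    region = rep(c("5UTR", "CDS", "3UTR"), each = n),
    seq = c(utr5, cds, utr3), stringsAsFactors = FALSE)
  site_df <- if (length(sites))
    data.frame(tx = rep(names(sites), lengths(sites)),
               start = unlist(sites, use.names = FALSE),
               stringsAsFactors = FALSE)
  else data.frame(tx = character(0), start = integer(0))
  list(regions = regions,
       truth = list(foreground = tx[is_fg], sites = site_df))
}
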