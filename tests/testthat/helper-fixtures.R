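# Small configurations and hand-built containers shared across tests.

small_sim <- function(seed = 1, ...) {
  args <- utils::modifyList(
    list(seed = seed, n_genes = 200L, n_cells_per_group = 60L,
         n_reps = 3L), list(...))
  do.call(sim_config, args)
}

# cell_matrix with fully controlled metadata, counts chosen so that
# umi/n_genes recomputed from the matrix hit the requested values
toy_cells <- function(umi, genes, mito, group = NULL) {
  n <- length(umi)
  stopifnot(length(genes) == n, length(mito) == n)
  n_gene_cols <- max(genes) + 1L
  counts <- matrix(0, nrow = n, ncol = n_gene_cols)
  for (i in seq_len(n)) {
    g <- seq_len(genes[i])
    counts[i, g] <- 1
    counts[i, 1] <- counts[i, 1] + umi[i] - genes[i]
  }
  cd <- data.frame(cell = paste0("c", seq_len(n)), mito_frac = mito)
  if (!is.null(group)) cd$group <- group
  cell_matrix(counts, cd)
}

# a cell_matrix from explicit per-group NB means
nb_cells <- function(n_per_group, means_a, means_b, dispersion = 0.1,
                     seed = 1) {
  set.seed(seed)
  n_genes <- length(means_a)
  ca <- matrix(rnbinom(n_per_group * n_genes,
                       mu = rep(means_a, each = n_per_group),
                       size = 1 / dispersion), nrow = n_per_group)
  cb <- matrix(rnbinom(n_per_group * n_genes,
                       mu = rep(means_b, each = n_per_group),
                       size = 1 / dispersion), nrow = n_per_group)
  counts <- rbind(ca, cb)
  cd <- data.frame(cell = paste0("c", seq_len(2 * n_per_group)),
                   group = rep(c("A", "B"), each = n_per_group),
                   cell_type = "t1",
                   mito_frac = 0.05)
  cell_matrix(counts, cd)
}

# independent brute-force two-sided rank-sum p by full enumeration
oracle_ranksum_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  mu <- length(x) * (n + 1) / 2
  obs <- abs(sum(r[seq_along(x)]) - mu)
  sets <- combn(n, length(x))
  hits <- 0L
  for (j in seq_len(ncol(sets)))
    if (abs(sum(r[sets[, j]]) - mu) >= obs - 1e-9) hits <- hits + 1L
  hits / ncol(sets)
}

# minimal significant-site table for the truncation stage
site_df <- function(starts) {
  n <- length(starts)
  data.frame(start = starts, score = rep(1, n), p = rep(0.01, n),
             significant = rep(TRUE, n))
}

# brute-force truncation reference: enumerate windows, count sites,
# merge runs of consecutive functional starts
oracle_truncate <- function(starts, len, window = 100, step = 1) {
  if (len < window) {
    n <- sum(starts >= 0 & starts < len)
    func <- if (n > 1) 0L else integer(0)
  } else {
    ws <- seq(0L, len - window, by = step)
    func <- ws[vapply(ws, function(s)
      sum(starts >= s & starts < s + window) > 1, logical(1))]
  }
  win_len <- min(window, len)
  cands <- list()
  iso <- integer(0)
  if (length(func)) {
    run <- split(func, cumsum(c(1L, diff(func) != step)))
    for (r in run) {
      if (length(r) >= 2)
        cands[[length(cands) + 1]] <- c(r[1], min(r[length(r)] + win_len,
                                                  len))
      else iso <- c(iso, r)
    }
  }
  list(candidates = cands, isolated = iso)
}

# deterministic bulk_counts from a plain matrix and a full 2x2 design
toy_bulk <- function(counts, n_reps = 3) {
  design <- expand.grid(replicate = seq_len(n_reps),
                        treatment = c("vehicle", "drug"),
                        fraction = c("total", "polysome"),
                        stringsAsFactors = FALSE)
  design$sample <- sprintf("%s_%s_r%d", design$fraction,
                           design$treatment, design$replicate)
  stopifnot(ncol(counts) == nrow(design))
  colnames(counts) <- design$sample
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%03d", seq_len(nrow(counts)))
  bulk_counts(counts, design[, c("sample", "fraction", "treatment",
                                 "replicate")])
}
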