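#' Quality-control filtering of cells
#'
#' Retains cells whose mitochondrial read fraction is strictly below
#' `mito_max` and whose library size (UMIs) and detected-gene count fall
#' inside closed intervals. Defaults follow common droplet-based QC
#' practice: mito < 25%, UMIs in `[700, 22000]`, genes in `[200, 6000]`.
#'
#' @param x a [cell_matrix()] with `mito_frac` metadata.
#' @param mito_max mitochondrial fraction upper bound (exclusive).
#' @param umi_range closed interval for per-cell UMI totals.
#' @param gene_range closed interval for detected genes per cell.
#' @return the filtered [cell_matrix()]; attribute `qc_removed` holds the
#'   number of cells failing each criterion (a cell may fail several).
#' @export
qc_filter_cells <- function(x, mito_max = 0.25, umi_range = c(700, 22000),
                            gene_range = c(200, 6000)) {
  cd <- x$cell_data
  if (is.null(cd$mito_frac)) abort("cell metadata lacks mito_frac")
  fail_mito <- !(cd$mito_frac < mito_max)
  fail_umi <- cd$umi < umi_range[1] | cd$umi > umi_range[2]
  fail_gene <- cd$n_genes < gene_range[1] | cd$n_genes > gene_range[2]
  keep <- !(fail_mito | fail_umi | fail_gene)
  if (!any(keep)) warning("no cells pass QC")
  out <- cell_matrix(x$counts[keep, , drop = FALSE],
                     cd[keep, , drop = FALSE], x$genes)
  attr(out, "qc_removed") <- c(mito = sum(fail_mito), umi = sum(fail_umi),
                               genes = sum(fail_gene),
                               total = sum(!keep))
  out
}

#' Library-size normalisation of single-cell counts
#'
#' Counts are scaled to `scale` per cell and log1p-transformed, the
#' conventional normalisation the downstream rank tests assume.
#'
#' @param x a [cell_matrix()].
#' @param scale target library size per cell.
#' @return sparse cell x gene matrix of log-normalised expression.
#' @export
normalize_cells <- function(x, scale = 1e4) {
  umi <- Matrix::rowSums(x$counts)
  umi[umi == 0] <- 1
  log1p(Matrix::Diagonal(x = scale / umi) %*% x$counts)
}

#' Exact two-sided Wilcoxon rank-sum p-value by enumeration
#'
#' Enumerates all `choose(n, nA)` assignments of the pooled mid-ranks and
#' returns `P(|W - E W| >= |w_obs - E W|)` under the permutation null.
#' Ties are handled exactly through mid-ranks. Intended for small groups
#' (both sizes <= 8); larger inputs should use the normal approximation.
#'
#' @param x,y numeric vectors (the two groups).
#' @return exact two-sided p-value.
#' @export
wilcox_exact_p <- function(x, y) {
  nx <- length(x)
  n <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  mu <- nx * (n + 1) / 2
  combos <- utils::combn(n, nx)
  w_all <- colSums(matrix(r[combos], nrow = nx))
  mean(abs(w_all - mu) >= abs(w_obs - mu) - 1e-9)
}

# internal: vectorised two-sided rank-sum p with mid-ranks, tie-corrected
# normal approximation and continuity correction; one p per column.
wilcox_normal_p <- function(mat, idx_a) {
  n <- nrow(mat)
  na <- length(idx_a)
  nb <- n - na
  ranks <- apply(mat, 2, rank)
  if (is.null(dim(ranks))) ranks <- matrix(ranks, nrow = n)
  w <- colSums(ranks[idx_a, , drop = FALSE])
  mu <- na * (n + 1) / 2
  ss <- colSums(ranks^2) - n * ((n + 1) / 2)^2    # sum (r - rbar)^2
  v <- na * nb / n * ss / (n - 1)
  d <- w - mu
  z <- (abs(d) - 0.5) / sqrt(v)
  z[abs(d) <= 0.5] <- 0
  p <- 2 * stats::pnorm(-z)
  p[v == 0] <- 1
  pmin(p, 1)
}

# internal: rank-sum p-values for columns of a dense matrix, dispatching on
# group size (exact enumeration when both groups <= 8)
ranksum_p <- function(mat, idx_a) {
  na <- length(idx_a)
  nb <- nrow(mat) - na
  if (max(na, nb) <= 8L) {
    apply(mat, 2, function(v) wilcox_exact_p(v[idx_a], v[-idx_a]))
  } else {
    wilcox_normal_p(mat, idx_a)
  }
}

# internal: expression summaries for a set of cells
expr_summary <- function(counts, norm, rows) {
  list(pct = Matrix::colMeans(counts[rows, , drop = FALSE] > 0),
       mean_norm = Matrix::colMeans(norm[rows, , drop = FALSE]))
}

#' Two-group Wilcoxon differential expression
#'
#' Implements the single-cell DE procedure used throughout the package:
#' genes must be detected in at least `min_frac` of cells in at least one
#' group and show at least a `min_fold` change between group means of
#' normalised expression (natural scale, pseudocount 1, boundaries
#' inclusive); surviving genes are tested with a two-sided Wilcoxon
#' rank-sum on per-cell log-normalised expression, with exact enumeration
#' for group sizes up to 8 and a tie-corrected normal approximation with
#' continuity correction otherwise. BH adjustment is over tested genes.
#'
#' @param x a [cell_matrix()] (after QC).
#' @param group_a,group_b group labels in `x$cell_data$group`; fold
#'   changes are A vs B.
#' @param min_frac detection-fraction filter.
#' @param min_fold natural-scale fold-change filter (applied in both
#'   directions).
#' @param fdr BH-adjusted significance threshold.
#' @return DE table: gene, log2FC, pct_a, pct_b, p, padj, significant.
#' @export
group_de <- function(x, group_a, group_b, min_frac = 0.10,
                     min_fold = 1.1, fdr = 0.05) {
  grp <- x$cell_data$group
  for (g in c(group_a, group_b)) {
    n_g <- sum(grp == g)
    if (n_g == 0) abort("group '", g, "' has no cells")
    if (n_g < 3) abort("group '", g, "' has fewer than 3 cells")
  }
  rows_a <- which(grp == group_a)
  rows_b <- which(grp == group_b)
  norm <- normalize_cells(x)
  sa <- expr_summary(x$counts, norm, rows_a)
  sb <- expr_summary(x$counts, norm, rows_b)
  fold <- (expm1(sa$mean_norm) + 1) / (expm1(sb$mean_norm) + 1)
  keep <- (sa$pct >= min_frac | sb$pct >= min_frac) &
    (fold >= min_fold | fold <= 1 / min_fold)
  de_from_kept(x, norm, rows_a, rows_b, keep, sa, sb, fold, fdr)
}

# internal: shared tail of group_de / cluster_markers
de_from_kept <- function(x, norm, rows_a, rows_b, keep, sa, sb, fold, fdr) {
  genes <- x$genes[keep]
  if (!length(genes)) {
    return(data.frame(gene = character(0), log2FC = numeric(0),
                      pct_a = numeric(0), pct_b = numeric(0),
                      p = numeric(0), padj = numeric(0),
                      significant = logical(0)))
  }
  sub <- as.matrix(norm[c(rows_a, rows_b), keep, drop = FALSE])
  p <- ranksum_p(sub, seq_along(rows_a))
  padj <- bh_adjust(p)
  out <- data.frame(gene = genes, log2FC = log2(fold[keep]),
                    pct_a = unname(sa$pct[keep]),
                    pct_b = unname(sb$pct[keep]),
                    p = unname(p), padj = unname(padj),
                    significant = unname(padj < fdr),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' One-vs-rest cluster marker detection
#'
#' For each cluster, genes detected in at least `min_frac` of that
#' cluster's cells and upregulated by at least `min_logfc` (log2 units)
#' relative to all other cells are tested with the same Wilcoxon
#' machinery as [group_de()]. Singleton clusters are skipped with a
#' warning.
#'
#' @param x a [cell_matrix()].
#' @param cluster_labels per-cell labels; defaults to
#'   `x$cell_data$cell_type`.
#' @param min_frac detection filter within the cluster of interest.
#' @param min_logfc minimum log2 fold change (cluster vs rest).
#' @param fdr BH threshold.
#' @return named list of DE tables, one per cluster.
#' @export
cluster_markers <- function(x, cluster_labels = x$cell_data$cell_type,
                            min_frac = 0.10, min_logfc = 0.25,
                            fdr = 0.05) {
  cl <- as.character(cluster_labels)
  lvls <- sort(unique(cl))
  if (length(lvls) < 2L) abort("need at least 2 clusters")
  norm <- normalize_cells(x)
  out <- list()
  for (k in lvls) {
    rows_a <- which(cl == k)
    if (length(rows_a) < 2L) {
      warning("cluster '", k, "' is a singleton; skipped")
      next
    }
    rows_b <- which(cl != k)
    sa <- expr_summary(x$counts, norm, rows_a)
    sb <- expr_summary(x$counts, norm, rows_b)
    fold <- (expm1(sa$mean_norm) + 1) / (expm1(sb$mean_norm) + 1)
    keep <- sa$pct >= min_frac & log2(fold) >= min_logfc
    out[[k]] <- de_from_kept(x, norm, rows_a, rows_b, keep, sa, sb, fold,
                             fdr)
  }
  out
}
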