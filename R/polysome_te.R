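#' Median-of-ratios size factors
#'
#' Per-sample normalisation factors computed against the geometric-mean
#' pseudo-reference over genes with positive counts in every sample.
#'
#' @param x a [bulk_counts()] or a gene x sample count matrix.
#' @return named numeric vector of positive size factors (geometric mean
#'   close to 1 for balanced data).
#' @export
size_factors <- function(x) {
  counts <- if (inherits(x, "bulk_counts")) x$counts else as.matrix(x)
  log_geo <- rowMeans(log(counts))
  ok <- is.finite(log_geo)
  if (!any(ok))
    abort("no gene has positive counts in all samples; ",
          "filter low-count genes or samples first")
  sf <- apply(counts, 2, function(cnt)
    exp(stats::median((log(cnt) - log_geo)[ok])))
  sf
}

# internal: method-of-moments gene-wise dispersions shrunk toward a
# parametric mean-dispersion trend alpha(mu) = a0 + a1/mu. Gene-wise
# values below the trend are replaced by the trend before averaging: at
# the few residual degrees of freedom of a 3-vs-3 design a below-trend
# moment estimate is noise, and carrying it forward makes the Wald test
# anticonservative. Above-trend estimates are partially kept so genuine
# dispersion outliers are not swamped.
estimate_dispersions <- function(counts, sf, groups, shrink_weight = 0.5,
                                 min_disp = 1e-4, max_disp = 10) {
  q <- sweep(counts, 2, sf, "/")
  lv <- unique(groups)
  mu <- vapply(lv, function(g) rowMeans(q[, groups == g, drop = FALSE]),
               numeric(nrow(q)))
  vv <- vapply(lv, function(g)
    apply(q[, groups == g, drop = FALSE], 1, stats::var),
    numeric(nrow(q)))
  mu <- matrix(mu, nrow = nrow(q))
  vv <- matrix(vv, nrow = nrow(q))
  raw <- rowSums(vv - mu) / rowSums(mu^2)
  raw[!is.finite(raw)] <- min_disp
  raw <- pmin(pmax(raw, min_disp), max_disp)
  base_mean <- rowMeans(q)
  use <- raw > min_disp & base_mean > 0
  trend <- rep(stats::median(raw), nrow(q))
  if (sum(use) >= 10) {
    fit <- stats::lm(raw[use] ~ I(1 / base_mean[use]))
    a0 <- max(unname(stats::coef(fit)[1]), min_disp)
    a1 <- max(unname(stats::coef(fit)[2]), 0)
    trend <- pmin(pmax(a0 + a1 / pmax(base_mean, 1e-8), min_disp),
                  max_disp)
  }
  trend + (1 - shrink_weight) * pmax(raw - trend, 0)
}

# internal: NB GLM fit with fixed dispersion; returns coef, SE (Wald,
# dispersion parameter of the GLM fixed at 1) and convergence flag.
fit_nb_glm <- function(y, X, offset, alpha) {
  fam <- if (alpha < 1e-6) stats::poisson()
         else MASS::negative.binomial(theta = 1 / alpha)
  fit <- suppressWarnings(
    stats::glm.fit(X, y, family = fam, offset = offset,
                   control = stats::glm.control(maxit = 50)))
  w <- fit$weights
  XtWX <- crossprod(X * sqrt(pmax(w, 0)))
  covb <- tryCatch(chol2inv(chol(XtWX)), error = function(e)
    matrix(NA_real_, ncol(X), ncol(X)))
  list(coef = fit$coefficients, se = sqrt(diag(covb)),
       converged = isTRUE(fit$converged))
}

# internal: run the per-gene NB Wald test for one coefficient
nb_wald_table <- function(counts, X, sf, alphas, coef_idx) {
  offset <- log(sf)
  n <- nrow(counts)
  beta <- se <- numeric(n)
  conv <- logical(n)
  for (i in seq_len(n)) {
    f <- fit_nb_glm(counts[i, ], X, offset, alphas[i])
    beta[i] <- f$coef[coef_idx]
    se[i] <- f$se[coef_idx]
    conv[i] <- f$converged
  }
  z <- beta / se
  p <- 2 * stats::pnorm(-abs(z))
  data.frame(base_mean = rowMeans(sweep(counts, 2, sf, "/")),
             log2FC = beta / log(2), se = se / log(2), p = p,
             converged = conv)
}

#' Negative-binomial differential expression within one fraction
#'
#' Fits, per gene, an NB log-linear model of counts on treatment with
#' median-of-ratios size-factor offsets and a method-of-moments
#' dispersion shrunk toward a parametric mean-dispersion trend, then
#' Wald-tests the treatment coefficient. A gene is significant when its
#' BH-adjusted p is below `padj_max` and `|log2FC|` exceeds `lfc_min`
#' (the fold-change criterion is applied symmetrically so down-regulated
#' genes are reported too).
#'
#' @param x a [bulk_counts()].
#' @param fraction `"total"` or `"polysome"`; the contrast is drug vs
#'   vehicle within that fraction.
#' @param padj_max,lfc_min significance thresholds (defaults 0.05 and
#'   0.2).
#' @param min_count genes with fewer total counts across the used samples
#'   are excluded before dispersion estimation.
#' @param shrink_weight shrinkage strength: gene-wise moment estimates
#'   below the mean-dispersion trend are replaced by the trend, and the
#'   excess of above-trend estimates is damped by this factor.
#' @return DE table: gene, base_mean, log2FC, se, p, padj, significant.
#'   Attribute `excluded_genes` lists genes dropped by the count filter.
#' @export
nb_de <- function(x, fraction = c("total", "polysome"), padj_max = 0.05,
                  lfc_min = 0.2, min_count = 10, shrink_weight = 0.5) {
  fraction <- match.arg(fraction)
  sel <- x$sample_data$fraction == fraction
  if (!any(sel)) abort("no samples in fraction '", fraction, "'")
  trt <- x$sample_data$treatment[sel]
  if (length(unique(trt)) < 2L)
    abort("both treatment levels must be present in fraction '",
          fraction, "'")
  counts <- x$counts[, sel, drop = FALSE]
  keep <- rowSums(counts) >= min_count
  excluded <- rownames(counts)[!keep]
  counts <- counts[keep, , drop = FALSE]
  sf <- size_factors(counts)
  alphas <- estimate_dispersions(counts, sf, trt, shrink_weight)
  X <- stats::model.matrix(~ trt_f,
                           data.frame(trt_f = factor(trt,
                                                     c("vehicle", "drug"))))
  tab <- nb_wald_table(counts, X, sf, alphas, coef_idx = 2L)
  tab$padj <- bh_adjust(tab$p)
  tab$significant <- !is.na(tab$padj) & tab$padj < padj_max &
    abs(tab$log2FC) > lfc_min
  out <- data.frame(gene = rownames(counts), tab, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded_genes") <- excluded
  out
}

#' Fraction-by-treatment interaction test for differential translation
#'
#' Per gene, fits `log mu = b0 + b_frac + b_trt + b_int` over the full
#' 2x2 polysome/total x drug/vehicle design with size-factor offsets.
#' The interaction coefficient is the drug effect in the polysome
#' fraction minus the drug effect in total RNA — i.e. the change in
#' translation efficiency, with polysome abundance normalised by total
#' mRNA abundance. Genes with BH-adjusted Wald p below `padj_max` and
#' `log2FC` above `lfc_min` (below `-lfc_min`) are classified `dtet_up`
#' (`dtet_down`).
#'
#' @param x a [bulk_counts()] with all four design cells present.
#' @param padj_max,lfc_min DTET thresholds (defaults 0.05 and 1).
#' @param min_count,shrink_weight see [nb_de()].
#' @return TE table: gene, base_mean, log2FC, se, p, padj, class.
#' @export
te_interaction <- function(x, padj_max = 0.05, lfc_min = 1,
                           min_count = 10, shrink_weight = 0.5) {
  sd_ <- x$sample_data
  for (f in c("total", "polysome")) for (t in c("vehicle", "drug"))
    if (!any(sd_$fraction == f & sd_$treatment == t))
      abort("design cell (", f, ", ", t, ") has no samples")
  counts <- x$counts
  keep <- rowSums(counts) >= min_count
  counts <- counts[keep, , drop = FALSE]
  sf <- size_factors(counts)
  cell <- paste(sd_$fraction, sd_$treatment)
  alphas <- estimate_dispersions(counts, sf, cell, shrink_weight)
  dat <- data.frame(frac = factor(sd_$fraction, c("total", "polysome")),
                    trt = factor(sd_$treatment, c("vehicle", "drug")))
  X <- stats::model.matrix(~ frac * trt, dat)
  tab <- nb_wald_table(counts, X, sf, alphas, coef_idx = 4L)
  tab$padj <- bh_adjust(tab$p)
  tab$class <- "ns"
  tab$class[!is.na(tab$padj) & tab$padj < padj_max &
              tab$log2FC > lfc_min] <- "dtet_up"
  tab$class[!is.na(tab$padj) & tab$padj < padj_max &
              tab$log2FC < -lfc_min] <- "dtet_down"
  out <- data.frame(gene = rownames(counts), tab, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "excluded_genes") <- rownames(x$counts)[!keep]
  out
}

#' Translational-mode classification from paired DE tables
#'
#' Compares significance calls between total-RNA and polysome DE tables:
#' `concordant` genes are significant in both, `buffered` in total only
#' (mRNA change not propagated to polysomes), `polysome_selective` in
#' polysome only, `unchanged` otherwise.
#'
#' @param de_total,de_poly DE tables from [nb_de()] on the two fractions.
#' @return data.frame (gene, mode); attribute `venn` carries the
#'   total-only / shared / polysome-only cardinalities.
#' @export
classify_translation_mode <- function(de_total, de_poly) {
  genes <- union(de_total$gene, de_poly$gene)
  sig_t <- genes %in% de_total$gene[de_total$significant]
  sig_p <- genes %in% de_poly$gene[de_poly$significant]
  mode <- rep("unchanged", length(genes))
  mode[sig_t & sig_p] <- "concordant"
  mode[sig_t & !sig_p] <- "buffered"
  mode[!sig_t & sig_p] <- "polysome_selective"
  out <- data.frame(gene = genes, mode = mode, stringsAsFactors = FALSE)
  attr(out, "venn") <- c(total_only = sum(sig_t & !sig_p),
                         shared = sum(sig_t & sig_p),
                         polysome_only = sum(!sig_t & sig_p))
  out
}
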