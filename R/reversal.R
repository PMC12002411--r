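#' Four-category obesity/drug reversal classification
#'
#' Splits significant genes of the disease contrast (obese vs lean) and
#' the drug contrast (drug vs disease-vehicle) by fold-change sign into
#' `ob_up`, `ob_down`, `rosi_up`, `rosi_down`, and intersects them into
#' the reversed sets: genes up in disease and down under drug
#' (`reversed_up`), and the mirror (`reversed_down`).
#'
#' @param de_ob DE table for the disease contrast (see [group_de()]).
#' @param de_rosi DE table for the drug contrast; must share the gene
#'   universe naming with `de_ob` (identifiers are checked where both
#'   tables cover a gene).
#' @param fdr BH-adjusted significance threshold for both contrasts.
#' @return list of class `reversal_sets` with the six gene-id sets.
#' @export
classify_reversal <- function(de_ob, de_rosi, fdr = 0.05) {
  for (d in list(de_ob, de_rosi))
    if (!all(c("gene", "log2FC", "padj") %in% names(d)))
      abort("DE tables need gene, log2FC and padj columns")
  if (anyDuplicated(de_ob$gene) || anyDuplicated(de_rosi$gene)) {
    dup <- unique(c(de_ob$gene[duplicated(de_ob$gene)],
                    de_rosi$gene[duplicated(de_rosi$gene)]))
    abort("inconsistent gene identifiers (duplicates): ",
          paste(utils::head(dup, 10), collapse = ", "))
  }
  sig <- function(d, up) d$gene[!is.na(d$padj) & d$padj < fdr &
                                  (if (up) d$log2FC > 0 else d$log2FC < 0)]
  sets <- list(ob_up = sig(de_ob, TRUE), ob_down = sig(de_ob, FALSE),
               rosi_up = sig(de_rosi, TRUE),
               rosi_down = sig(de_rosi, FALSE))
  sets$reversed_up <- intersect(sets$ob_up, sets$rosi_down)
  sets$reversed_down <- intersect(sets$ob_down, sets$rosi_up)
  structure(sets, class = "reversal_sets")
}

#' @export
print.reversal_sets <- function(x, ...) {
  cat("reversal_sets:",
      paste(sprintf("%s=%d", names(x), lengths(x)), collapse = " "), "\n")
  invisible(x)
}

#' Exclusive intersection counts over the four DEG categories
#'
#' Standard UpSet semantics: each gene in the union of `ob_up`, `ob_down`,
#' `rosi_up`, `rosi_down` is counted in exactly one combination, so the
#' counts sum to the union size.
#'
#' @param sets a [classify_reversal()] result (or any named list of the
#'   four categories).
#' @return data.frame: one row per non-empty combination, with logical
#'   membership columns, a `combination` label and `count`.
#' @export
upset_counts <- function(sets) {
  cats <- c("ob_up", "ob_down", "rosi_up", "rosi_down")
  univ <- unique(unlist(sets[cats]))
  if (!length(univ)) {
    out <- data.frame(matrix(logical(0), ncol = 4))
    names(out) <- cats
    out$combination <- character(0)
    out$count <- integer(0)
    return(out)
  }
  memb <- vapply(cats, function(s) univ %in% sets[[s]], logical(length(univ)))
  memb <- matrix(memb, ncol = 4, dimnames = list(NULL, cats))
  key <- apply(memb, 1, function(r) paste(cats[r], collapse = "&"))
  tab <- table(key)
  out <- data.frame(combination = names(tab),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  for (s in cats) out[[s]] <- vapply(strsplit(out$combination, "&"),
                                     function(p) s %in% p, logical(1))
  out[order(-out$count, out$combination),
      c(cats, "combination", "count")]
}

#' Scaled gene-set enrichment score
#'
#' `ES = (overlap / set_size) * scale / pathway_size`. The scale is
#' 20,000 for single-cell gene sets and the number of detected genes for
#' bulk sets.
#'
#' @param overlap genes shared by the query set and the pathway.
#' @param set_size query gene-set size (> 0).
#' @param pathway_size pathway size (> 0).
#' @param scale scale factor.
#' @return numeric enrichment score.
#' @export
enrichment_score <- function(overlap, set_size, pathway_size,
                             scale = 20000) {
  if (any(set_size <= 0) || any(pathway_size <= 0))
    abort("set_size and pathway_size must be positive")
  (overlap / set_size) * scale / pathway_size
}

#' Fisher pathway enrichment with scaled enrichment scores
#'
#' Pathways are intersected with the universe before testing; each is
#' tested one-sided (enrichment) with Fisher's exact test on the 2x2
#' in-set/in-pathway table, BH-adjusted across pathways, and annotated
#' with the [enrichment_score()] and, when DE tables are supplied, the
#' mean log2 fold change of the overlapping genes under each contrast.
#'
#' @param genes query gene set (subset of `universe`).
#' @param collection named list of pathways (see [read_gmt()]).
#' @param universe background gene universe (genes tested in the
#'   corresponding DE analysis).
#' @param fdr BH threshold for the `significant` flag.
#' @param scale scale for [enrichment_score()]; use `length(universe)`
#'   for bulk data.
#' @param de_a,de_b optional DE tables; mean log2FC over the pathway's
#'   significant DEGs is reported per table (NA when the overlap with
#'   significant DEGs is empty).
#' @return data.frame: pathway, overlap, pathway_size, p, padj, es,
#'   significant, and optional mean_log2fc_a / mean_log2fc_b.
#' @export
fisher_enrichment <- function(genes, collection, universe, fdr = 0.05,
                              scale = 20000, de_a = NULL, de_b = NULL) {
  genes <- unique(genes)
  universe <- unique(universe)
  if (!all(genes %in% universe))
    abort("genes must be a subset of the universe")
  if (!length(genes)) {
    warning("empty gene list; no enrichment computed")
    return(data.frame(pathway = character(0), overlap = integer(0),
                      pathway_size = integer(0), p = numeric(0),
                      padj = numeric(0), es = numeric(0),
                      significant = logical(0)))
  }
  n_univ <- length(universe)
  n_set <- length(genes)
  rows <- lapply(names(collection), function(nm) {
    pw <- intersect(collection[[nm]], universe)
    k <- length(pw)
    if (k == 0) return(NULL)
    ov <- length(intersect(genes, pw))
    # one-sided enrichment p: hypergeometric upper tail at the observed
    # overlap (equivalent to fisher.test alternative = "greater")
    p <- stats::phyper(ov - 1L, k, n_univ - k, n_set, lower.tail = FALSE)
    data.frame(pathway = nm, overlap = ov, pathway_size = k, p = p,
               es = enrichment_score(ov, n_set, k, scale),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) abort("no pathway overlaps the universe")
  out$padj <- bh_adjust(out$p)
  out$significant <- out$padj < fdr
  if (!is.null(de_a))
    out$mean_log2fc_a <- vapply(out$pathway, function(nm)
      pathway_mean_log2fc(collection[[nm]], de_a), numeric(1))
  if (!is.null(de_b))
    out$mean_log2fc_b <- vapply(out$pathway, function(nm)
      pathway_mean_log2fc(collection[[nm]], de_b), numeric(1))
  rownames(out) <- NULL
  out[order(out$p, out$pathway),
      c("pathway", "overlap", "pathway_size", "p", "padj", "es",
        "significant",
        intersect(c("mean_log2fc_a", "mean_log2fc_b"), names(out)))]
}

#' Mean log2 fold change of a pathway's significant DEGs
#'
#' Arithmetic mean of `log2FC` restricted to the intersection of the
#' pathway with the DE table's significant genes; `NA` when that overlap
#' is empty (missing, not zero).
#'
#' @param pathway_genes character vector of pathway members.
#' @param de DE table with `gene`, `log2FC` and `significant` columns.
#' @return numeric scalar or `NA`.
#' @export
pathway_mean_log2fc <- function(pathway_genes, de) {
  hits <- de$significant & de$gene %in% pathway_genes
  if (!any(hits)) return(NA_real_)
  mean(de$log2FC[hits])
}
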