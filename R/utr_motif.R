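BASES <- c("A", "C", "G", "T")

#' Count overlapping hexamers in a sequence set
#'
#' Slides a window of `k` nt with step `step` over every sequence and
#' tallies all 4^k words. Windows containing non-ACGT characters (e.g.
#' `N`) are skipped and reported as such; frequencies are counts over
#' valid windows and sum to 1.
#'
#' @param seqs character vector or `DNAStringSet` (lowercase tolerated).
#' @param k word length (default 6).
#' @param step window step in nt (default 1).
#' @return object of class `kmer_counts`: named count vector over all
#'   words, `n_windows` (valid), `n_skipped`, `freq`, `k`.
#' @export
count_kmers <- function(seqs, k = 6, step = 1) {
  if (length(seqs) == 0) abort("empty sequence set")
  ss <- if (inherits(seqs, "DNAStringSet")) seqs
        else Biostrings::DNAStringSet(toupper(seqs))
  m <- Biostrings::oligonucleotideFrequency(ss, width = k, step = step)
  counts <- colSums(m)
  possible <- sum(vapply(Biostrings::width(ss), function(w)
    if (w < k) 0L else length(seq.int(1L, w - k + 1L, by = step)),
    integer(1)))
  n_valid <- sum(counts)
  if (n_valid == 0) abort("sequence set yields no valid windows")
  structure(list(counts = counts, n_windows = n_valid,
                 n_skipped = possible - n_valid,
                 freq = counts / n_valid, k = k),
            class = "kmer_counts")
}

#' @export
print.kmer_counts <- function(x, ...) {
  cat("kmer_counts: k =", x$k, ",", x$n_windows, "windows (",
      x$n_skipped, "skipped )\n")
  invisible(x)
}

#' Hexamer enrichment z-test between two sequence sets
#'
#' Two-proportion z statistic on overlapping-window frequencies, with the
#' pooled estimate in the denominator:
#' `z = (p_fg - p_bg) / sqrt(phat (1 - phat) (1/N_fg + 1/N_bg))`.
#' Words absent from both sets get `z = 0` by convention. Enrichment is
#' one-sided: `z > z_min`.
#'
#' @param fg,bg [count_kmers()] results for foreground and background.
#' @param z_min enrichment threshold (default 3).
#' @return data.frame (hexamer, count_fg, count_bg, freq_fg, freq_bg, z,
#'   enriched), sorted by decreasing z.
#' @export
kmer_enrichment_z <- function(fg, bg, z_min = 3) {
  stopifnot(inherits(fg, "kmer_counts"), inherits(bg, "kmer_counts"))
  if (!identical(names(fg$counts), names(bg$counts)))
    abort("foreground and background use different word universes")
  cf <- fg$counts; cb <- bg$counts
  nf <- fg$n_windows; nb <- bg$n_windows
  pf <- cf / nf; pb <- cb / nb
  pooled <- (cf + cb) / (nf + nb)
  denom <- sqrt(pooled * (1 - pooled) * (1 / nf + 1 / nb))
  z <- (pf - pb) / denom
  z[cf + cb == 0] <- 0
  z[denom == 0 & cf + cb > 0] <- 0   # word saturates both sets
  out <- data.frame(hexamer = names(cf), count_fg = unname(cf),
                    count_bg = unname(cb), freq_fg = unname(pf),
                    freq_bg = unname(pb), z = unname(z),
                    enriched = unname(z > z_min),
                    stringsAsFactors = FALSE)
  out[order(-out$z, out$hexamer), ]
}

#' Build a position-specific scoring matrix from enriched hexamers
#'
#' Stacks the (equal-length) enriched words ungapped, tallies bases per
#' position, converts to frequencies with a background-distributed
#' pseudocount, and forms log2-odds weights against the background base
#' composition.
#'
#' @param hexamers character vector of enriched words, all the same
#'   length, over `{A,C,G,T}`.
#' @param pseudocount total pseudocount per position, spread according to
#'   the background (default 1; 0 gives raw frequencies).
#' @param background named base probabilities (default uniform).
#' @return object of class `motif_model` with `counts`, `freq`, `weights`
#'   (4 x width matrices, rows A/C/G/T), `background`, `pseudocount`,
#'   `n` (number of stacked words).
#' @export
build_pssm <- function(hexamers, pseudocount = 1,
                       background = c(A = 0.25, C = 0.25, G = 0.25,
                                      T = 0.25)) {
  if (!length(hexamers)) abort("need at least one hexamer")
  wlen <- unique(nchar(hexamers))
  if (length(wlen) != 1L)
    abort("hexamers have mixed lengths: ", paste(wlen, collapse = ", "))
  if (any(grepl("[^ACGT]", hexamers)))
    abort("hexamers must be over {A,C,G,T}")
  background <- background[BASES]
  mat <- do.call(rbind, strsplit(hexamers, ""))
  counts <- vapply(seq_len(wlen), function(j)
    vapply(BASES, function(b) sum(mat[, j] == b), numeric(1)),
    numeric(4))
  counts <- matrix(counts, nrow = 4,
                   dimnames = list(BASES, paste0("p", seq_len(wlen))))
  n <- length(hexamers)
  freq <- (counts + pseudocount * background) / (n + pseudocount)
  weights <- log2(freq / background)
  structure(list(counts = counts, freq = freq, weights = weights,
                 background = background, pseudocount = pseudocount,
                 n = n, width = wlen),
            class = "motif_model")
}

#' @export
print.motif_model <- function(x, ...) {
  cat("motif_model:", x$n, "stacked words, width", x$width, "\n")
  cat("consensus:", paste(BASES[apply(x$freq, 2, which.max)],
                          collapse = ""), "\n")
  invisible(x)
}

#' Write a motif count matrix in TRANSFAC-like text form
#' @param model a [build_pssm()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_motif_model <- function(model, path) {
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c("ID motif", "P0\tA\tC\tG\tT"), con)
  for (j in seq_len(model$width))
    writeLines(paste(c(sprintf("%02d", j), model$counts[, j]),
                     collapse = "\t"), con)
  writeLines("//", con)
  invisible(path)
}

# internal: map a sequence to base indices 1..4 (NA for anything else)
seq_to_idx <- function(s) {
  match(strsplit(toupper(s), "")[[1]], BASES)
}

# internal: score all 4^width words under the model and attach exact tail
# p-values for an order-0 background; returns list(score, p) indexed by
# word code (1-based base-4 big-endian + 1).
enumerate_words <- function(model, background) {
  w <- model$width
  n_words <- 4^w
  idx <- matrix(0L, nrow = n_words, ncol = w)
  code <- 0:(n_words - 1)
  for (j in seq_len(w))
    idx[, j] <- (code %/% 4^(w - j)) %% 4 + 1
  score <- numeric(n_words)
  prob <- rep(1, n_words)
  for (j in seq_len(w)) {
    score <- score + model$weights[cbind(idx[, j], j)]
    prob <- prob * background[idx[, j]]
  }
  # quantize so mathematically tied words share one score regardless of
  # floating-point summation order; ties then share one tail probability
  score <- round(score, 9)
  ord <- order(score)
  sorted <- score[ord]
  tails <- rev(cumsum(rev(prob[ord])))
  # p(word) = P(score >= score(word)); ties share the tail at their first
  # sorted occurrence, so equality is exact rather than float-fragile
  p <- tails[match(score, sorted)]
  list(score = score, p = p)
}

#' Scan a sequence for motif sites with exact p-values
#'
#' Scores every window by the summed log-odds weights of the model and
#' assigns each the exact tail probability `P(score >= s)` under an
#' order-0 background, computed by enumerating all 4^width words (4,096
#' for hexamers) — no approximation. Windows containing non-ACGT
#' characters are skipped.
#'
#' @param seq a single sequence (character scalar).
#' @param model a [build_pssm()] result.
#' @param p_max significance threshold on the exact p-value (default
#'   0.05, strict inequality).
#' @param background base probabilities for the null word distribution;
#'   `NULL` (default) uses the base composition of `seq` itself, falling
#'   back to the model background for degenerate sequences.
#' @return data.frame (start 0-based, score, p, significant); all scanned
#'   windows are reported, significance flags those with `p < p_max`.
#' @export
scan_sites <- function(seq, model, p_max = 0.05, background = NULL) {
  stopifnot(inherits(model, "motif_model"))
  w <- model$width
  v <- seq_to_idx(seq)
  if (length(v) < w)
    return(data.frame(start = integer(0), score = numeric(0),
                      p = numeric(0), significant = logical(0)))
  if (is.null(background)) {
    tab <- tabulate(v, 4)
    background <- if (sum(tab) > 0) stats::setNames(tab / sum(tab), BASES)
                  else model$background
    if (any(background == 0))  # keep null word probabilities proper
      background <- stats::setNames(
        (tab + 1) / (sum(tab) + 4), BASES)
  }
  background <- background[BASES]
  en <- enumerate_words(model, background)
  n_win <- length(v) - w + 1
  codes <- rep(0, n_win)
  for (j in seq_len(w))
    codes <- codes + (v[j:(j + n_win - 1)] - 1) * 4^(w - j)
  ok <- !is.na(codes)
  starts <- which(ok) - 1L
  codes <- codes[ok] + 1
  out <- data.frame(start = starts, score = en$score[codes],
                    p = en$p[codes])
  out$significant <- out$p < p_max
  out
}

#' Scan a set of transcripts
#'
#' @param seqs named character vector of sequences (e.g. 5'UTRs).
#' @param model a [build_pssm()] result.
#' @param p_max significance threshold.
#' @param background see [scan_sites()]; by default the pooled base
#'   composition of `seqs` (the scanned set) is used for every sequence.
#' @return named list of [scan_sites()] tables.
#' @export
scan_transcripts <- function(seqs, model, p_max = 0.05,
                             background = NULL) {
  if (is.null(names(seqs))) abort("seqs must be named by transcript")
  if (is.null(background)) {
    tab <- tabulate(unlist(lapply(seqs, seq_to_idx)), 4)
    background <- stats::setNames((tab + 1) / (sum(tab) + 4), BASES)
  }
  lapply(seqs, scan_sites, model = model, p_max = p_max,
         background = background)
}

#' Per-transcript feature map of significant sites
#'
#' @param sites named list of [scan_sites()] tables.
#' @return named list of sorted 0-based significant-site positions;
#'   transcripts without significant sites appear with empty vectors.
#' @export
feature_map <- function(sites) {
  lapply(sites, function(s) sort(s$start[s$significant]))
}

#' Pearson correlation of enrichment z-scores across backgrounds
#'
#' Robustness check: enrichment tables computed against two different
#' background sets are correlated over their shared hexamers.
#'
#' @param z_a,z_b [kmer_enrichment_z()] tables.
#' @return Pearson r over the shared hexamers (at least 3 required).
#' @export
score_correlation <- function(z_a, z_b) {
  shared <- intersect(z_a$hexamer, z_b$hexamer)
  if (length(shared) < 3)
    abort("need at least 3 shared hexamers, got ", length(shared))
  stats::cor(z_a$z[match(shared, z_a$hexamer)],
             z_b$z[match(shared, z_b$hexamer)])
}
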