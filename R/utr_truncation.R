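#' Sliding-window counts of significant motif sites
#'
#' Slides `window`-nt windows with `step`-nt steps along a 5'UTR and
#' counts the significant motif sites whose (0-based) start falls inside
#' each window. A window is functional when its count is strictly greater
#' than `min_sites_exclusive` (i.e. `> 1` with defaults: at least two
#' sites). UTRs shorter than the window yield a single whole-UTR window,
#' flagged `short_utr`.
#'
#' @param sites a [scan_sites()] table (or any data.frame with `start`
#'   and `significant` columns) for one transcript.
#' @param utr_length UTR length in nt.
#' @param window window length in nt (default 100).
#' @param step step size in nt (default 1).
#' @param min_sites_exclusive functional windows require strictly more
#'   sites than this (default 1).
#' @return object of class `window_set`: data.frame (start, n_sites,
#'   functional) plus attributes `utr_length`, `window`, `step`,
#'   `short_utr`.
#' @export
functional_windows <- function(sites, utr_length, window = 100, step = 1,
                               min_sites_exclusive = 1) {
  pos <- sites$start[sites$significant]
  if (any(pos < 0)) abort("negative site positions")
  short <- utr_length < window
  win_len <- if (short) utr_length else window
  starts <- if (short) 0L else seq.int(0L, utr_length - window, by = step)
  n_sites <- vapply(starts, function(s)
    sum(pos >= s & pos < s + win_len), integer(1))
  out <- data.frame(start = starts, n_sites = n_sites,
                    functional = n_sites > min_sites_exclusive)
  structure(out, class = c("window_set", "data.frame"),
            utr_length = utr_length, window = win_len, step = step,
            short_utr = short, site_starts = sort(pos))
}

#' Merge adjacent functional windows into truncated-5'UTR candidates
#'
#' Maximal runs of functional windows at consecutive start positions
#' (one `step` apart) are merged; a run spanning starts `s1..s2` yields
#' the candidate region `[s1, s2 + window)` (0-based, end-exclusive),
#' clipped to the UTR length. Runs of a single functional window do not
#' qualify as candidates (at least two adjacent functional windows are
#' required) and are reported separately as `isolated`.
#'
#' @param windows a [functional_windows()] result.
#' @return list with `candidates` (data.frame: start, end, n_windows,
#'   n_sites) and `isolated` (starts of lone functional windows).
#'   `n_sites` counts the distinct significant-site starts inside each
#'   candidate region.
#' @export
merge_windows <- function(windows) {
  stopifnot(inherits(windows, "window_set"))
  win <- attr(windows, "window")
  step <- attr(windows, "step")
  len <- attr(windows, "utr_length")
  pos <- attr(windows, "site_starts")
  fs <- sort(windows$start[windows$functional])
  empty <- data.frame(start = integer(0), end = integer(0),
                      n_windows = integer(0), n_sites = integer(0))
  if (!length(fs)) return(list(candidates = empty, isolated = integer(0)))
  run_id <- cumsum(c(1L, diff(fs) != step))
  runs <- split(fs, run_id)
  is_candidate <- lengths(runs) >= 2L
  cand <- lapply(runs[is_candidate], function(r) {
    s <- r[1]; e <- min(r[length(r)] + win, len)
    data.frame(start = s, end = e, n_windows = length(r),
               n_sites = sum(pos >= s & pos < e))
  })
  candidates <- if (length(cand)) do.call(rbind, cand) else empty
  rownames(candidates) <- NULL
  iso <- unlist(runs[!is_candidate], use.names = FALSE)
  list(candidates = candidates,
       isolated = if (is.null(iso)) integer(0) else as.integer(iso))
}

#' Design candidate truncated 5'UTRs for a set of transcripts
#'
#' Convenience wrapper running [functional_windows()] and
#' [merge_windows()] per transcript.
#'
#' @param sites named list of [scan_sites()] tables.
#' @param utr_lengths named vector of UTR lengths (nt).
#' @param window,step,min_sites_exclusive see [functional_windows()].
#' @return data.frame (tx, start, end, n_windows, n_sites, short_utr);
#'   attribute `isolated` maps transcripts to lone functional windows.
#' @export
design_truncations <- function(sites, utr_lengths, window = 100, step = 1,
                               min_sites_exclusive = 1) {
  stopifnot(all(names(sites) %in% names(utr_lengths)))
  rows <- list()
  isolated <- list()
  for (tx in names(sites)) {
    ws <- functional_windows(sites[[tx]], utr_lengths[[tx]], window, step,
                             min_sites_exclusive)
    m <- merge_windows(ws)
    if (nrow(m$candidates))
      rows[[tx]] <- data.frame(tx = tx, m$candidates,
                               short_utr = attr(ws, "short_utr"))
    if (length(m$isolated)) isolated[[tx]] <- m$isolated
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(tx = character(0), start = integer(0),
                         end = integer(0), n_windows = integer(0),
                         n_sites = integer(0), short_utr = logical(0))
  rownames(out) <- NULL
  attr(out, "isolated") <- isolated
  out
}
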