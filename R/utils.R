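#' Benjamini-Hochberg adjusted p-values
#'
#' Single FDR routine shared by every module so that multiple-testing
#' behaviour is identical across the single-cell, bulk and motif stages.
#' Implements the classical step-up procedure; `NA` p-values propagate.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return numeric vector of BH-adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  stopifnot(is.numeric(p))
  stats::p.adjust(p, method = "BH")
}

#' Derive a child seed from a master seed
#'
#' Each pipeline stage draws from its own stream so that adding or removing
#' a stage does not perturb the others. Kept below 2^31 - 1.
#'
#' @param seed master seed (integer).
#' @param stage stage name (character); hashed to an offset.
#' @return an integer seed.
#' @export
child_seed <- function(seed, stage) {
  stopifnot(length(seed) == 1L, is.finite(seed))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647)
}

# internal: stop() with the caller-facing message, no call deparse
abort <- function(...) stop(..., call. = FALSE)

# internal: validate a scalar in an open/closed range
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         closed_lower = TRUE, closed_upper = TRUE) {
  if (length(x) != 1L || !is.numeric(x) || !is.finite(x))
    abort(name, " must be a single finite number")
  lo <- if (closed_lower) x >= lower else x > lower
  hi <- if (closed_upper) x <= upper else x < upper
  if (!lo || !hi)
    abort(name, " = ", x, " is outside the allowed range")
  invisible(x)
}

#' Write a table with the standard provenance header
#'
#' Every table the pipeline emits carries one comment line
#' (`# polyselect <version> config=<hash>`) followed by a header row.
#' Files are byte-reproducible for a fixed config.
#'
#' @param x data.frame to write.
#' @param path output path.
#' @param config_hash character scalar recorded in the comment line
#'   (use [config_hash()] on the run configuration).
#' @return `path`, invisibly.
#' @export
write_tsv <- function(x, path, config_hash = "unset") {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# polyselect %s config=%s",
                     as.character(utils::packageVersion("polyselect")),
                     config_hash), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a table written by [write_tsv()]
#' @param path file path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

#' Hash a configuration object
#'
#' Serialises the object to canonical JSON and returns the md5 of that text,
#' so the hash is stable across sessions and platforms.
#'
#' @param config a list.
#' @return character md5 hash.
#' @export
config_hash <- function(config) {
  txt <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA,
                          null = "null", force = TRUE)
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(txt, tmp)
  unname(tools::md5sum(tmp))
}
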