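#' Cell-by-gene count container
#'
#' Lightweight S3 container pairing a sparse cell x gene integer count
#' matrix with per-cell metadata. Metadata columns `group`, `cell_type`,
#' `umi`, `n_genes` and `mito_frac` are required by the QC and DE stages;
#' `umi` and `n_genes` are recomputed from the matrix when missing.
#'
#' @param counts cell x gene matrix (coerced to `dgCMatrix`), non-negative
#'   integers; rows are cells.
#' @param cell_data data.frame with one row per cell.
#' @param genes character vector of gene identifiers (defaults to colnames).
#' @return an object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, cell_data, genes = colnames(counts)) {
  if (!inherits(counts, "Matrix"))
    counts <- Matrix::Matrix(counts, sparse = TRUE)
  counts <- methods::as(methods::as(counts, "CsparseMatrix"),
                        "generalMatrix")
  if (nrow(cell_data) != nrow(counts))
    abort("cell_data has ", nrow(cell_data), " rows but counts has ",
          nrow(counts), " cells")
  if (is.null(genes)) genes <- paste0("g", seq_len(ncol(counts)))
  colnames(counts) <- genes
  if (is.null(cell_data$umi)) cell_data$umi <- Matrix::rowSums(counts)
  if (is.null(cell_data$n_genes))
    cell_data$n_genes <- Matrix::rowSums(counts > 0)
  structure(list(counts = counts, cell_data = cell_data, genes = genes),
            class = "cell_matrix")
}

#' @export
print.cell_matrix <- function(x, ...) {
  cat("cell_matrix:", nrow(x$counts), "cells x", ncol(x$counts), "genes\n")
  if (!is.null(x$cell_data$group))
    print(table(x$cell_data$group))
  invisible(x)
}

#' @export
dim.cell_matrix <- function(x) dim(x$counts)

#' Gene-by-sample bulk count container
#'
#' @param counts gene x sample integer matrix.
#' @param sample_data data.frame with columns `sample`, `fraction`
#'   (`"total"`/`"polysome"`), `treatment` (`"vehicle"`/`"drug"`) and
#'   `replicate`, one row per column of `counts`.
#' @return an object of class `bulk_counts`.
#' @export
bulk_counts <- function(counts, sample_data) {
  counts <- as.matrix(counts)
  if (ncol(counts) != nrow(sample_data))
    abort("sample_data has ", nrow(sample_data), " rows but counts has ",
          ncol(counts), " samples")
  need <- c("sample", "fraction", "treatment", "replicate")
  miss <- setdiff(need, names(sample_data))
  if (length(miss))
    abort("sample_data lacks columns: ", paste(miss, collapse = ", "))
  bad_f <- setdiff(unique(sample_data$fraction), c("total", "polysome"))
  if (length(bad_f)) abort("unknown fraction level(s): ",
                           paste(bad_f, collapse = ", "))
  bad_t <- setdiff(unique(sample_data$treatment), c("vehicle", "drug"))
  if (length(bad_t)) abort("unknown treatment level(s): ",
                           paste(bad_t, collapse = ", "))
  if (anyDuplicated(rownames(counts)))
    abort("gene identifiers are not unique")
  colnames(counts) <- sample_data$sample
  structure(list(counts = counts, sample_data = sample_data),
            class = "bulk_counts")
}

#' @export
print.bulk_counts <- function(x, ...) {
  cat("bulk_counts:", nrow(x$counts), "genes x", ncol(x$counts), "samples\n")
  print(table(x$sample_data$fraction, x$sample_data$treatment))
  invisible(x)
}

#' Write a cell_matrix as MTX triplet plus label tables
#'
#' Emits `matrix.mtx` (MatrixMarket, genes as columns), `cells.tsv` and
#' `genes.tsv` under `dir`.
#'
#' @param x a [cell_matrix()].
#' @param dir output directory (created if needed).
#' @param config_hash provenance hash for the label tables.
#' @return `dir`, invisibly.
#' @export
write_cell_matrix <- function(x, dir, config_hash = "unset") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(x$counts, file.path(dir, "matrix.mtx"))
  write_tsv(x$cell_data, file.path(dir, "cells.tsv"), config_hash)
  write_tsv(data.frame(gene = x$genes), file.path(dir, "genes.tsv"),
            config_hash)
  invisible(dir)
}

#' Read a cell_matrix written by [write_cell_matrix()]
#' @param dir directory holding `matrix.mtx`, `cells.tsv`, `genes.tsv`.
#' @return a [cell_matrix()].
#' @export
read_cell_matrix <- function(dir) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  cells <- read_tsv(file.path(dir, "cells.tsv"))
  genes <- read_tsv(file.path(dir, "genes.tsv"))$gene
  cell_matrix(m, cells, genes)
}

#' Write bulk counts as TSV plus sample table
#' @param x a [bulk_counts()].
#' @param dir output directory.
#' @param config_hash provenance hash.
#' @return `dir`, invisibly.
#' @export
write_bulk_counts <- function(x, dir, config_hash = "unset") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  df <- data.frame(gene = rownames(x$counts), x$counts, check.names = FALSE)
  write_tsv(df, file.path(dir, "counts.tsv"), config_hash)
  write_tsv(x$sample_data, file.path(dir, "samples.tsv"), config_hash)
  invisible(dir)
}

#' Read bulk counts written by [write_bulk_counts()]
#' @param dir directory holding `counts.tsv` and `samples.tsv`.
#' @return a [bulk_counts()].
#' @export
read_bulk_counts <- function(dir) {
  df <- read_tsv(file.path(dir, "counts.tsv"))
  samples <- read_tsv(file.path(dir, "samples.tsv"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  bulk_counts(m, samples)
}

#' Read a GMT gene-set collection
#'
#' Standard tab-separated GMT: name, description, then member genes.
#'
#' @param path GMT file path.
#' @return named list of character vectors (pathway -> genes).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(f) < 3)
      abort("malformed GMT line (need name, description, >=1 gene): ", l)
    unique(f[-(1:2)])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], character(1))
  out
}

#' Write a GMT gene-set collection
#' @param sets named list of character vectors.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, nm, sets[[nm]]), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write intervals as BED (0-based, half-open)
#'
#' @param x data.frame with columns `chrom` (here: transcript id), `start`,
#'   `end`, and optionally `name` and `score`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end")
  if (!all(cols %in% names(x))) abort("BED needs chrom/start/end columns")
  if (is.null(x$name)) x$name <- "."
  if (is.null(x$score)) x$score <- 0
  utils::write.table(x[, c("chrom", "start", "end", "name", "score")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read transcript-region sequences from FASTA
#'
#' Record IDs follow `<transcript>|<region>` with region one of `5UTR`,
#' `CDS`, `3UTR`. Lowercase bases are mapped to uppercase.
#'
#' @param path FASTA path.
#' @return data.frame with columns `tx`, `region`, `seq`.
#' @export
read_region_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- names(ss)
  parts <- strsplit(sub("\\s.*$", "", ids), "|", fixed = TRUE)
  tx <- vapply(parts, `[`, character(1), 1L)
  region <- vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                   character(1))
  data.frame(tx = tx, region = region,
             seq = toupper(as.character(ss)), stringsAsFactors = FALSE)
}

#' Write transcript-region sequences as FASTA
#' @param regions data.frame as returned by [read_region_fasta()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_region_fasta <- function(regions, path) {
  ss <- Biostrings::DNAStringSet(regions$seq)
  names(ss) <- paste(regions$tx, regions$region, sep = "|")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}
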