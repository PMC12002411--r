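DEFAULT_THRESHOLDS <- list(fdr = 0.05, lfc_min = 0.2, te_lfc_min = 1,
                           z_min = 3, site_p_max = 0.05, window = 100)

#' Build a pipeline configuration
#'
#' @param synthetic `NULL`, or a (possibly empty) list of [sim_config()]
#'   overrides to run the pipeline on simulated inputs.
#' @param inputs `NULL`, or a list of real-input paths: `sc_dir` (MTX
#'   triplet), `bulk_dir` (counts + samples TSVs), `fasta` (transcript
#'   regions), `foreground` (file of foreground transcript ids), `gmt`.
#'   Exactly one of `synthetic` / `inputs` must be given.
#' @param thresholds named list overriding any of `fdr`, `lfc_min`
#'   (bulk), `te_lfc_min`, `z_min`, `site_p_max`, `window`; unset entries
#'   take the standard defaults (0.05, 0.2, 1, 3, 0.05, 100).
#' @param seed master seed.
#' @param out_dir output directory.
#' @return validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(synthetic = list(), inputs = NULL,
                            thresholds = list(), seed = 1L,
                            out_dir = tempfile("polyselect_run_")) {
  validate_config(list(synthetic = synthetic, inputs = inputs,
                       thresholds = thresholds, seed = seed,
                       out_dir = out_dir))
}

#' Validate a pipeline configuration
#'
#' Fills threshold defaults, rejects unknown keys and conflicting or
#' missing input modes, and reports all problems at once.
#'
#' @param config a list as assembled by [pipeline_config()] or parsed
#'   from a JSON config file.
#' @return the validated config, class `pipeline_config`.
#' @export
validate_config <- function(config) {
  errs <- character(0)
  known <- c("synthetic", "inputs", "thresholds", "seed", "out_dir")
  extra <- setdiff(names(config), known)
  if (length(extra))
    errs <- c(errs, paste0("unknown config keys: ",
                           paste(extra, collapse = ", ")))
  has_syn <- !is.null(config$synthetic)
  has_real <- !is.null(config$inputs)
  if (has_syn == has_real)
    errs <- c(errs, "exactly one of 'synthetic' and 'inputs' must be set")
  th <- config$thresholds
  if (is.null(th)) th <- list()
  bad_th <- setdiff(names(th), names(DEFAULT_THRESHOLDS))
  if (length(bad_th))
    errs <- c(errs, paste0("unknown thresholds: ",
                           paste(bad_th, collapse = ", ")))
  th <- utils::modifyList(DEFAULT_THRESHOLDS, th[names(th) %in%
                                                   names(DEFAULT_THRESHOLDS)])
  for (nm in names(DEFAULT_THRESHOLDS))
    if (!is.numeric(th[[nm]]) || length(th[[nm]]) != 1 || th[[nm]] <= 0)
      errs <- c(errs, paste0("threshold '", nm, "' must be positive"))
  if (is.null(config$seed) || !is.finite(config$seed))
    errs <- c(errs, "seed must be a finite integer")
  if (has_real) {
    need <- c("sc_dir", "bulk_dir", "fasta", "foreground", "gmt")
    miss <- setdiff(need, names(config$inputs))
    if (length(miss))
      errs <- c(errs, paste0("missing input paths: ",
                             paste(miss, collapse = ", ")))
  }
  if (length(errs))
    abort("invalid pipeline config:\n  - ",
          paste(errs, collapse = "\n  - "))
  config$thresholds <- th
  config$seed <- as.integer(config$seed)
  if (is.null(config$out_dir)) config$out_dir <- tempfile("polyselect_run_")
  structure(config, class = "pipeline_config")
}

# internal: a synthetic pathway collection over the simulated gene
# universe: random pathways plus one enriched in each planted reversed set
synthetic_gmt <- function(truth, seed, n_random = 20, size = 50) {
  set.seed(child_seed(seed, "gmt"))
  genes <- truth$gene
  sets <- lapply(seq_len(n_random), function(i)
    sample(genes, min(size, length(genes))))
  names(sets) <- sprintf("RANDOM_%02d", seq_len(n_random))
  rev_up <- truth$gene[truth$class == "reversed_up"]
  rev_dn <- truth$gene[truth$class == "reversed_down"]
  if (length(rev_up) >= 2)
    sets$PLANTED_REVERSED_UP <- unique(c(rev_up,
                                         sample(genes, 10)))
  if (length(rev_dn) >= 2)
    sets$PLANTED_REVERSED_DOWN <- unique(c(rev_dn,
                                           sample(genes, 10)))
  sets
}

# internal: record one stage in the manifest, hashing its outputs
stage_record <- function(name, status, outputs = character(0)) {
  hashes <- if (length(outputs)) as.list(tools::md5sum(outputs))
            else list()
  names(hashes) <- basename(outputs)
  list(name = name, status = status, outputs = hashes)
}

#' Run the full analysis pipeline
#'
#' Executes the stages in dependency order (simulate -> single-cell DE ->
#' reversal/enrichment; simulate -> polysome DE/TE -> motif ->
#' truncation), writing every intermediate as a declared file under
#' `config$out_dir` and returning a manifest with per-file md5 hashes.
#' Re-running with the same config and seed reproduces the hashes. A
#' failing stage is recorded and its downstream stages are skipped.
#'
#' @param config a validated [pipeline_config()].
#' @return the manifest (also written to `manifest.json`), invisibly the
#'   same list.
#' @export
run_pipeline <- function(config) {
  config <- validate_config(unclass(config))
  out <- config$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  th <- config$thresholds
  chash <- config_hash(unclass(config)[c("synthetic", "inputs",
                                         "thresholds", "seed")])
  stages <- list()
  failed <- character(0)
  run_stage <- function(name, deps, fn) {
    if (length(intersect(deps, failed))) {
      stages[[name]] <<- stage_record(name, "skipped")
      failed <<- c(failed, name)
      return(invisible(NULL))
    }
    res <- tryCatch(fn(), error = function(e) e)
    if (inherits(res, "error")) {
      stages[[name]] <<- stage_record(name, paste("failed:",
                                                  conditionMessage(res)))
      failed <<- c(failed, name)
    } else {
      stages[[name]] <<- stage_record(name, "ok", res)
    }
  }

  paths <- list(
    sc_dir = file.path(out, "sc"), bulk_dir = file.path(out, "bulk"),
    fasta = file.path(out, "transcripts.fa"),
    foreground = file.path(out, "foreground.txt"),
    gmt = file.path(out, "pathways.gmt"))

  if (!is.null(config$synthetic)) {
    run_stage("simulate", character(0), function() {
      cfg <- do.call(sim_config, utils::modifyList(
        config$synthetic, list(seed = config$seed)))
      sc <- simulate_sc_experiment(cfg)
      write_cell_matrix(sc$matrix, paths$sc_dir, chash)
      write_tsv(sc$truth, file.path(out, "truth_genes.tsv"), chash)
      bulk <- simulate_polysome_experiment(cfg)
      write_bulk_counts(bulk$counts, paths$bulk_dir, chash)
      tx <- simulate_transcripts(cfg)
      write_region_fasta(tx$regions, paths$fasta)
      writeLines(tx$truth$foreground, paths$foreground)
      write_tsv(tx$truth$sites, file.path(out, "truth_sites.tsv"), chash)
      write_gmt(synthetic_gmt(sc$truth, config$seed), paths$gmt)
      c(file.path(paths$sc_dir, c("matrix.mtx", "cells.tsv", "genes.tsv")),
        file.path(paths$bulk_dir, c("counts.tsv", "samples.tsv")),
        paths$fasta, paths$foreground, paths$gmt,
        file.path(out, c("truth_genes.tsv", "truth_sites.tsv")))
    })
  } else {
    paths[names(config$inputs)] <- config$inputs
    stages$simulate <- stage_record("simulate", "external-inputs")
  }

  de_ob_path <- file.path(out, "de_obesity.tsv")
  de_rosi_path <- file.path(out, "de_drug.tsv")
  run_stage("sc_deg", "simulate", function() {
    cm <- read_cell_matrix(paths$sc_dir)
    cm <- qc_filter_cells(cm)
    groups <- sort(unique(cm$cell_data$group))
    lean <- grep("lean", groups, value = TRUE)[1]
    obese <- setdiff(grep("vehicle", groups, value = TRUE), lean)[1]
    drug <- setdiff(groups, c(lean, obese))[1]
    de_ob <- group_de(cm, obese, lean, fdr = th$fdr)
    de_rosi <- group_de(cm, drug, obese, fdr = th$fdr)
    write_tsv(de_ob, de_ob_path, chash)
    write_tsv(de_rosi, de_rosi_path, chash)
    c(de_ob_path, de_rosi_path)
  })

  run_stage("reversal_enrichment", "sc_deg", function() {
    de_ob <- read_tsv(de_ob_path)
    de_rosi <- read_tsv(de_rosi_path)
    sets <- classify_reversal(de_ob, de_rosi, fdr = th$fdr)
    up <- upset_counts(sets)
    f_up <- file.path(out, "upset_counts.tsv")
    write_tsv(up, f_up, chash)
    gmt <- read_gmt(paths$gmt)
    universe <- de_ob$gene
    outs <- f_up
    for (set_nm in c("reversed_up", "reversed_down")) {
      g <- intersect(sets[[set_nm]], universe)
      if (!length(g)) next
      enr <- fisher_enrichment(g, gmt, universe, fdr = th$fdr,
                               scale = 20000, de_a = de_ob,
                               de_b = de_rosi)
      f <- file.path(out, paste0("enrichment_", set_nm, ".tsv"))
      write_tsv(enr, f, chash)
      outs <- c(outs, f)
    }
    outs
  })

  de_total_path <- file.path(out, "de_total.tsv")
  de_poly_path <- file.path(out, "de_polysome.tsv")
  te_path <- file.path(out, "te_interaction.tsv")
  run_stage("polysome_te", "simulate", function() {
    bulk <- read_bulk_counts(paths$bulk_dir)
    de_t <- nb_de(bulk, "total", padj_max = th$fdr, lfc_min = th$lfc_min)
    de_p <- nb_de(bulk, "polysome", padj_max = th$fdr,
                  lfc_min = th$lfc_min)
    te <- te_interaction(bulk, padj_max = th$fdr,
                         lfc_min = th$te_lfc_min)
    modes <- classify_translation_mode(de_t, de_p)
    write_tsv(de_t, de_total_path, chash)
    write_tsv(de_p, de_poly_path, chash)
    write_tsv(te, te_path, chash)
    f_modes <- file.path(out, "translation_modes.tsv")
    write_tsv(modes, f_modes, chash)
    f_venn <- file.path(out, "venn.json")
    jsonlite::write_json(as.list(attr(modes, "venn")), f_venn,
                         auto_unbox = TRUE)
    c(de_total_path, de_poly_path, te_path, f_modes, f_venn)
  })

  sites_path <- file.path(out, "sites.tsv")
  lengths_path <- file.path(out, "utr_lengths.tsv")
  run_stage("utr_motif", "simulate", function() {
    regions <- read_region_fasta(paths$fasta)
    fg_ids <- readLines(paths$foreground)
    outs <- character(0)
    enriched_5utr <- NULL
    fg_utr5 <- NULL
    for (reg in c("5UTR", "CDS", "3UTR")) {
      rr <- regions[regions$region == reg, ]
      fg <- rr$seq[rr$tx %in% fg_ids]
      bg <- rr$seq[!rr$tx %in% fg_ids]
      names(fg) <- rr$tx[rr$tx %in% fg_ids]
      zt <- kmer_enrichment_z(count_kmers(fg), count_kmers(bg),
                              z_min = th$z_min)
      f <- file.path(out, paste0("kmer_z_", reg, ".tsv"))
      write_tsv(zt, f, chash)
      outs <- c(outs, f)
      if (reg == "5UTR") {
        enriched_5utr <- zt$hexamer[zt$enriched]
        fg_utr5 <- fg
      }
    }
    if (length(enriched_5utr)) {
      model <- build_pssm(enriched_5utr)
      f_m <- file.path(out, "motif_counts.txt")
      write_motif_model(model, f_m)
      sites <- scan_transcripts(fg_utr5, model, p_max = th$site_p_max)
      site_df <- do.call(rbind, lapply(names(sites), function(tx)
        if (nrow(sites[[tx]])) data.frame(tx = tx, sites[[tx]])
        else NULL))
      write_tsv(site_df, sites_path, chash)
      fm <- feature_map(sites)
      f_fm <- file.path(out, "feature_map.json")
      jsonlite::write_json(fm, f_fm)
      write_tsv(data.frame(tx = names(fg_utr5),
                           length = nchar(fg_utr5)),
                lengths_path, chash)
      outs <- c(outs, f_m, sites_path, f_fm, lengths_path)
    } else {
      # null configuration: nothing enriched, downstream gets empty sites
      write_tsv(data.frame(tx = character(0), start = integer(0),
                           score = numeric(0), p = numeric(0),
                           significant = logical(0)),
                sites_path, chash)
      write_tsv(data.frame(tx = names(fg_utr5),
                           length = nchar(fg_utr5)),
                lengths_path, chash)
      outs <- c(outs, sites_path, lengths_path)
    }
    outs
  })

  run_stage("utr_truncation", "utr_motif", function() {
    site_df <- read_tsv(sites_path)
    lens <- read_tsv(lengths_path)
    utr_lengths <- stats::setNames(lens$length, lens$tx)
    sites <- split(site_df[, c("start", "score", "p", "significant")],
                   factor(site_df$tx, levels = lens$tx))
    trunc <- design_truncations(sites, utr_lengths, window = th$window)
    f_tsv <- file.path(out, "truncations.tsv")
    write_tsv(trunc, f_tsv, chash)
    f_bed <- file.path(out, "truncations.bed")
    write_bed(data.frame(chrom = trunc$tx, start = trunc$start,
                         end = trunc$end,
                         name = sprintf("trunc_%03d",
                                        seq_len(max(nrow(trunc), 0))),
                         score = trunc$n_sites), f_bed)
    c(f_tsv, f_bed)
  })

  manifest <- list(
    tool = "polyselect",
    version = as.character(utils::packageVersion("polyselect")),
    seed = config$seed, config_hash = chash, stages = stages)
  jsonlite::write_json(manifest, file.path(out, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

# internal: tiny --key value parser for the CLI
parse_cli_args <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    if (!startsWith(args[i], "--"))
      abort("unexpected argument: ", args[i])
    key <- gsub("-", "_", sub("^--", "", args[i]))
    out[[key]] <- args[i + 1L]
    i <- i + 2L
  }
  out
}

#' Command-line entry point
#'
#' Subcommands: `run-all` (the full pipeline; `--seed`, `--out`, optional
#' `--config` JSON with `synthetic`/`inputs`/`thresholds`), `simulate`
#' (`--seed`, `--out`), `sc-deg` (`--sc-dir`, `--group-a`, `--group-b`,
#' `--out`), `bulk-de` (`--bulk-dir`, `--fraction`, `--out`), `te`
#' (`--bulk-dir`, `--out`).
#'
#' @param args character vector, defaults to `commandArgs(TRUE)`.
#' @return exit status 0 invisibly (errors propagate).
#' @export
pipeline_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  if (!length(args))
    abort("usage: polyselect <run-all|simulate|sc-deg|bulk-de|te> ",
          "--key value ...")
  cmd <- args[1]
  opt <- parse_cli_args(args[-1])
  seed <- as.integer(opt$seed %||% 1L)
  switch(cmd,
    "run-all" = {
      base <- if (!is.null(opt$config))
        jsonlite::read_json(opt$config, simplifyVector = TRUE)
      else list(synthetic = list())
      base$seed <- seed
      base$out_dir <- opt$out %||% "polyselect_out"
      run_pipeline(validate_config(base))
    },
    "simulate" = {
      cfg <- sim_config(seed = seed)
      sc <- simulate_sc_experiment(cfg)
      write_cell_matrix(sc$matrix, file.path(opt$out, "sc"))
      bulk <- simulate_polysome_experiment(cfg)
      write_bulk_counts(bulk$counts, file.path(opt$out, "bulk"))
      tx <- simulate_transcripts(cfg)
      write_region_fasta(tx$regions, file.path(opt$out, "transcripts.fa"))
    },
    "sc-deg" = {
      cm <- qc_filter_cells(read_cell_matrix(opt$sc_dir))
      de <- group_de(cm, opt$group_a, opt$group_b)
      write_tsv(de, opt$out)
    },
    "bulk-de" = {
      de <- nb_de(read_bulk_counts(opt$bulk_dir), opt$fraction)
      write_tsv(de, opt$out)
    },
    "te" = {
      te <- te_interaction(read_bulk_counts(opt$bulk_dir))
      write_tsv(te, opt$out)
    },
    abort("unknown subcommand: ", cmd))
  invisible(0L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
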