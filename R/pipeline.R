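## End-to-end orchestration: config-driven runs with provenance records.
## Subcommand functions mirror the CLI (inst/cli/hdrquant.R): quantify,
## compare, simulate, scphase.

read_run_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    base <- dirname(normalizePath(config))
    cfg <- yaml::read_yaml(config)
    attr(cfg, "base_dir") <- base
    cfg
  } else if (is.list(config)) config
  else stop("config must be a YAML path or a list")
}

resolve_path <- function(p, cfg) {
  base <- attr(cfg, "base_dir")
  if (is.null(base) || file.exists(p)) p else file.path(base, p)
}

require_fields <- function(cfg, fields, where) {
  miss <- setdiff(fields, names(cfg))
  if (length(miss))
    stop(where, " config is missing field(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (f in fields) {
    v <- cfg[[f]]
    if (is.character(v) && length(v) == 1L && grepl("(\\.|/)", v)) {
      p <- resolve_path(v, cfg)
      if (grepl("\\.(fastq|fq|fa|fasta|tsv|yaml|yml|mtx)(\\.gz)?$", v) &&
          !file.exists(p))
        stop(where, ": input path does not exist: ", v, call. = FALSE)
    }
  }
  invisible(cfg)
}

write_provenance <- function(dir, stage, cfg, counts = list(), seed = NULL) {
  rec <- list(tool = "hdrquant", version = as.character(packageVersion("hdrquant")),
              stage = stage, seed = seed,
              config = cfg[setdiff(names(cfg), "locus")],
              counts = counts)
  jsonlite::write_json(rec, file.path(dir, paste0(stage, "_provenance.json")),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       pretty = TRUE)
}

#' Quantify editing outcomes for one sample (trim, merge, classify, count)
#'
#' Config fields: `fastq1`, `fastq2`, `locus` (a locus YAML as for
#' [load_locus_config()], or an inline list), optional `adapter1`,
#' `adapter2`, `min_overlap`, `max_mismatch_frac`, `min_identity`,
#' `sample` (output prefix). Writes per-read calls TSV, the outcome table
#' (TSV + JSON) and a provenance record into `output_dir`, and returns the
#' [quantify()] result.
#'
#' @param config YAML path or list.
#' @param output_dir output directory (created).
#' @return the `outcome_table`, invisibly.
#' @export
run_quantify <- function(config, output_dir) {
  cfg <- read_run_config(config)
  require_fields(cfg, c("fastq1", "fastq2", "locus"), "quantify")
  locus <- if (is.character(cfg$locus)) load_locus_config(resolve_path(cfg$locus, cfg))
           else cfg$locus
  stopifnot(inherits(locus, "target_locus"))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  sample_id <- cfg$sample %||% "sample"

  prep <- prep_reads(resolve_path(cfg$fastq1, cfg), resolve_path(cfg$fastq2, cfg),
                     adapter1 = cfg$adapter1 %||% TRUSEQ_R1,
                     adapter2 = cfg$adapter2 %||% TRUSEQ_R2,
                     min_overlap = cfg$min_overlap %||% 10L,
                     max_mismatch_frac = cfg$max_mismatch_frac %||% 0.1)
  merged <- prep$merged[prep$merged$merged, , drop = FALSE]
  if (nrow(merged) == 0L) stop("quantify: no pairs merged")
  calls <- classify_reads(merged$seq, locus, id = merged$id,
                          min_identity = cfg$min_identity %||% 0.60)
  outcome <- quantify(calls, n_unmerged = prep$stats$n_unmerged)

  write.table(calls, file.path(output_dir, paste0(sample_id, "_calls.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(as.data.frame(outcome),
              file.path(output_dir, paste0(sample_id, "_outcome.tsv")),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_outcome_json(outcome,
                     file.path(output_dir, paste0(sample_id, "_outcome.json")))
  write_provenance(output_dir, paste0(sample_id, "_quantify"), cfg,
                   counts = list(pairs_in = prep$stats$n_pairs,
                                 merged = prep$stats$n_merged,
                                 unmerged = prep$stats$n_unmerged,
                                 classified = outcome$n_total,
                                 discarded = outcome$n_discard))
  invisible(outcome)
}

#' Group comparison across per-sample outcome tables
#'
#' Config fields: `sample_sheet` (TSV: `sample`, `population`, `condition`,
#' `replicate`, `outcome_json`), optional `group_by` (default `condition`),
#' `metric` (default `hdr_nhej_ratio`), `welch` (default FALSE). Writes
#' summary and comparison TSVs into `output_dir`.
#'
#' @param config YAML path or list.
#' @param output_dir output directory.
#' @return the [ratio_table()] list, invisibly.
#' @export
run_compare <- function(config, output_dir) {
  cfg <- read_run_config(config)
  require_fields(cfg, "sample_sheet", "compare")
  sheet <- read.delim(resolve_path(cfg$sample_sheet, cfg),
                      stringsAsFactors = FALSE)
  if (nrow(sheet) == 0L) stop("compare: empty sample sheet")
  need <- c("sample", "population", "condition", "replicate", "outcome_json")
  miss <- setdiff(need, names(sheet))
  if (length(miss))
    stop("compare: sample sheet is missing column(s): ",
         paste(miss, collapse = ", "))
  rows <- lapply(seq_len(nrow(sheet)), function(i) {
    oc <- read_outcome_json(resolve_path(sheet$outcome_json[i], cfg))
    sample_outcome(oc, sheet$sample[i], sheet$population[i],
                   sheet$condition[i], sheet$replicate[i])
  })
  samples <- do.call(rbind, rows)
  rt <- ratio_table(samples, group_by = cfg$group_by %||% "condition",
                    metric = cfg$metric %||% "hdr_nhej_ratio",
                    var_equal = !isTRUE(cfg$welch))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(rt$summaries, file.path(output_dir, "group_summaries.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(rt$comparisons, file.path(output_dir, "group_comparisons.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write_provenance(output_dir, "compare", cfg,
                   counts = list(samples = nrow(samples),
                                 groups = nrow(rt$summaries)))
  invisible(rt)
}

#' Generate synthetic datasets from a config
#'
#' Config fields: `kind` (`"amplicon"` or `"sc"`), `seed`, and the
#' corresponding simulator parameters (see [amplicon_sim_config()] /
#' [sc_sim_config()]); fractions are given as a named map.
#'
#' @param config YAML path or list.
#' @param output_dir output directory.
#' @return the simulator result, invisibly.
#' @export
run_simulate <- function(config, output_dir) {
  cfg <- read_run_config(config)
  kind <- cfg$kind %||% "amplicon"
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  if (kind == "amplicon") {
    sc <- amplicon_sim_config(
      n_reads = cfg$n_reads %||% 10000L,
      fractions = unlist(cfg$fractions %||%
                           list(hdr = 0.25, nhej = 0.40, unmodified = 0.35)),
      error_rate = cfg$error_rate %||% 0.001,
      seed = cfg$seed %||% 1L)
    res <- simulate_amplicon_reads(sc, dir = output_dir)
  } else if (kind == "sc") {
    nc <- unlist(cfg$n_cells %||% list(G0 = 100L, G1S = 100L, G2M = 100L))
    sc <- sc_sim_config(n_cells = nc,
                        fold_change = cfg$fold_change %||% 10,
                        condition = cfg$condition %||% "sim",
                        seed = cfg$seed %||% 1L)
    res <- simulate_sc_counts(sc, dir = output_dir)
  } else stop("unknown simulation kind: ", kind)
  write_provenance(output_dir, "simulate", cfg, seed = cfg$seed %||% 1L)
  invisible(res)
}

#' Single-cell QC and cell-cycle phase calling from a count matrix
#'
#' Config fields: `mtx_dir` (Cell Ranger layout), optional `condition`
#' labels TSV (`barcode`, `condition`), `min_genes`, `max_mito`, `n_bins`,
#' `n_ctrl`, `seed`. Writes per-cell QC + scores + phases and per-condition
#' fractions TSVs.
#'
#' @param config YAML path or list.
#' @param output_dir output directory.
#' @return list with `qc`, `phases`, `fractions`, invisibly.
#' @export
run_scphase <- function(config, output_dir) {
  cfg <- read_run_config(config)
  require_fields(cfg, "mtx_dir", "scphase")
  dat <- read_cellranger_mtx(resolve_path(cfg$mtx_dir, cfg))
  qc <- qc_filter(dat$counts, min_genes = cfg$min_genes %||% 200L,
                  max_mito = cfg$max_mito %||% 0.06)
  scores <- score_phase(qc$counts, n_bins = cfg$n_bins %||% 24L,
                        n_ctrl = cfg$n_ctrl %||% 100L,
                        seed = cfg$seed %||% 1L)
  phases <- call_phase(scores)
  cond <- rep(cfg$condition %||% "all", nrow(phases))
  if (!is.null(cfg$condition_tsv)) {
    ct <- read.delim(resolve_path(cfg$condition_tsv, cfg),
                     stringsAsFactors = FALSE)
    cond <- ct$condition[match(phases$barcode, ct$barcode)]
  }
  fr <- phase_fractions(phases$phase, cond)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write.table(qc$report, file.path(output_dir, "cell_qc.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(phases, file.path(output_dir, "phase_calls.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(fr, file.path(output_dir, "phase_fractions.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write_provenance(output_dir, "scphase", cfg,
                   counts = list(cells_in = ncol(dat$counts),
                                 cells_pass = ncol(qc$counts)))
  invisible(list(qc = qc$report, phases = phases, fractions = fr))
}
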