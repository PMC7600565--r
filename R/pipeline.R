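# End-to-end pipeline: load panel -> call both channels -> reconcile ->
# annotate -> summarise, with every applied threshold logged and the
# configuration echoed into the output directory for provenance.

#' Pipeline run configuration
#'
#' Collects the file paths and tunables of one analysis run and validates
#' them. All thresholds are fractions in \[0, 1\].
#'
#' @param panel_fasta Path to the ORF panel multi-FASTA.
#' @param counts_paths Character vector of per-sample base-count TSVs.
#' @param sanger_path Path to the Sanger peak-height TSV.
#' @param out_dir Output directory (created if missing).
#' @param flank_len Flank length trimmed off each FASTA sequence
#'   (default 100).
#' @param pseudogene_ids Gene ids flagged as pseudogenes.
#' @param threshold Editing-level calling threshold, inclusive
#'   (default 0.10).
#' @param rnaseq_tolerance Allowed RNA-seq shortfall below threshold for
#'   Sanger-confirmed sites (default 0.02).
#' @param min_pass_replicates Sanger replicates required at or above
#'   threshold (default 2).
#' @param min_depth Minimum RNA-seq depth at a called site (default 1).
#' @param category_boundaries Inner boundaries of the L/M/H/EH bins.
#' @param hydrophobic Hydrophobic amino-acid set.
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(panel_fasta, counts_paths, sanger_path, out_dir,
                       flank_len = 100L, pseudogene_ids = character(),
                       threshold = 0.10, rnaseq_tolerance = 0.02,
                       min_pass_replicates = 2L, min_depth = 1L,
                       category_boundaries = c(0.30, 0.60, 0.90),
                       hydrophobic = HYDROPHOBIC_AA) {
  check_threshold(threshold)
  stopifnot(rnaseq_tolerance >= 0, rnaseq_tolerance <= 1,
            min_pass_replicates >= 1L, min_depth >= 1L, flank_len >= 0L,
            all(category_boundaries > 0 & category_boundaries < 1),
            !is.unsorted(category_boundaries))
  cfg <- list(panel_fasta = panel_fasta, counts_paths = counts_paths,
              sanger_path = sanger_path, out_dir = out_dir,
              flank_len = as.integer(flank_len),
              pseudogene_ids = pseudogene_ids,
              threshold = threshold, rnaseq_tolerance = rnaseq_tolerance,
              min_pass_replicates = as.integer(min_pass_replicates),
              min_depth = as.integer(min_depth),
              category_boundaries = category_boundaries,
              hydrophobic = hydrophobic)
  class(cfg) <- "run_config"
  cfg
}

log_line <- function(con, stage, msg, echo = TRUE) {
  line <- sprintf("[%s] %s", stage, msg)
  if (!is.null(con)) writeLines(line, con)
  if (echo) message(line)
  invisible(line)
}

config_echo <- function(cfg) {
  vals <- lapply(cfg, function(v) paste(format(v, trim = TRUE),
                                        collapse = ","))
  sprintf("%s=%s", names(vals), unlist(vals))
}

#' Run the full editing-detection pipeline
#'
#' Chains panel loading, RNA-seq and Sanger calling, reconciliation,
#' consequence annotation and summary statistics. Writes into
#' `cfg$out_dir`: `calls.tsv` (all reconciliation decisions),
#' `sites_annotated.tsv`, `consequences.tsv`, `sites.gff3`,
#' `summary.txt`, `per_gene.tsv`, `run_log.txt` and `config_echo.txt`.
#'
#' @param cfg A [run_config()].
#' @return Invisibly, a list with `panel`, `calls`, `annotated`, `summary`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  logf <- file(file.path(cfg$out_dir, "run_log.txt"), open = "wt")
  on.exit(close(logf), add = TRUE)
  writeLines(config_echo(cfg), file.path(cfg$out_dir, "config_echo.txt"))

  panel <- load_orf_panel(cfg$panel_fasta, flank_len = cfg$flank_len,
                          pseudogene_ids = cfg$pseudogene_ids)
  log_line(logf, "load", sprintf("panel of %d ORFs, flank_len=%d",
                                 length(panel), cfg$flank_len))

  counts <- lapply(cfg$counts_paths, read_counts_tsv)
  merged <- merge_samples(counts)
  log_line(logf, "rnaseq", sprintf(
    "merged %d sample(s) by count summation; %d positions", length(counts),
    nrow(merged)))
  rna <- call_rnaseq(merged, panel, threshold = cfg$threshold,
                     min_depth = cfg$min_depth)
  log_line(logf, "rnaseq", sprintf(
    "level rule T/(A+C+G+T) >= %.2f at C positions, min_depth=%d: %d candidates over %d covered C positions",
    cfg$threshold, cfg$min_depth, nrow(rna$calls), nrow(rna$levels)))

  obs <- read_sanger_tsv(cfg$sanger_path)
  sang <- call_sanger(obs, panel, threshold = cfg$threshold,
                      min_pass_replicates = cfg$min_pass_replicates)
  log_line(logf, "sanger", sprintf(
    "level rule T/(C+T) >= %.2f in >= %d replicates: %d called positions",
    cfg$threshold, cfg$min_pass_replicates, nrow(sang)))

  calls <- reconcile(sang, rna$levels, threshold = cfg$threshold,
                     rnaseq_tolerance = cfg$rnaseq_tolerance)
  for (st in unique(calls$status)) {
    for (id in calls$site_id[calls$status == st])
      log_line(logf, "reconcile", sprintf("%s: %s", id, st), echo = FALSE)
  }
  log_line(logf, "reconcile", sprintf(
    "retention tolerance: Sanger-confirmed sites kept down to RNA-seq level %.2f",
    cfg$threshold - cfg$rnaseq_tolerance))
  write_calls_tsv(calls, file.path(cfg$out_dir, "calls.tsv"))

  acc <- accepted_sites(calls)
  annotated <- annotate_sites(acc, panel, hydrophobic = cfg$hydrophobic)
  log_line(logf, "annotate", sprintf(
    "%d accepted sites -> %d edited codons (hydrophobic set: %s)",
    nrow(acc), nrow(annotated$consequences),
    paste(cfg$hydrophobic, collapse = "")))
  write_tsv(annotated$sites, file.path(cfg$out_dir, "sites_annotated.tsv"))
  write_tsv(annotated$consequences,
            file.path(cfg$out_dir, "consequences.tsv"))
  if (nrow(annotated$sites))
    export_sites_gff3(annotated$sites, file.path(cfg$out_dir, "sites.gff3"))

  summ <- summarize_sites(annotated, panel)
  writeLines(render_summary(summ), file.path(cfg$out_dir, "summary.txt"))
  write_tsv(summ$per_gene, file.path(cfg$out_dir, "per_gene.tsv"))
  log_line(logf, "summary", sprintf("%d sites summarised", summ$total_sites))

  invisible(list(panel = panel, calls = calls, annotated = annotated,
                 summary = summ))
}
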