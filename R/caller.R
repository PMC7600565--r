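# Dual-evidence editing-site calling.
#
# RNA-seq channel: editing level = T/(A+C+G+T) at each C-containing
# reference position; a candidate needs level >= threshold (default 10%).
# Sanger channel: level = T/(C+T) from peak heights; a site needs level >=
# threshold in at least 2 of 3 biological replicates.
# Reconciliation: Sanger is the primary evidence; Sanger-passed sites with
# RNA-seq support just below threshold (within a small tolerance) are
# retained, while RNA-seq-only candidates are reported but rejected.

COUNT_COLS <- c("a_count", "c_count", "g_count", "t_count")

#' RNA-seq editing level at C positions
#'
#' The editing level of a C-containing reference position is
#' `t_count / (a_count + c_count + g_count + t_count)`.
#'
#' @param counts Data frame of per-position base counts with columns `ref`,
#'   `a_count`, `c_count`, `g_count`, `t_count`. All rows must have
#'   reference base C and depth > 0.
#' @return Numeric vector of editing levels, one per row.
#' @export
rnaseq_level <- function(counts) {
  if (any(counts$ref != "C"))
    stop("rnaseq_level is defined only at C reference positions; got ref '",
         counts$ref[counts$ref != "C"][1], "'")
  depth <- rowSums(counts[COUNT_COLS])
  if (any(depth <= 0)) stop("zero-depth row in counts")
  counts$t_count / depth
}

#' Merge base-count tables from multiple samples
#'
#' Merging aligned samples is equivalent to elementwise summation of their
#' per-position counts; the merged editing level is therefore
#' depth-weighted, not a mean of per-sample levels.
#'
#' @param tables A list of count data frames on the same reference panel
#'   (columns `sample_id`, `gene`, `pos`, `ref`, counts).
#' @return A single count data frame with `sample_id = "merged"` and
#'   positions present in any input.
#' @export
merge_samples <- function(tables) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  stopifnot(is.list(tables), length(tables) >= 1L)
  all <- do.call(rbind, tables)
  key <- paste(all$gene, all$pos, sep = "\r")
  refs <- tapply(all$ref, key, function(r) length(unique(r)))
  if (any(refs > 1L)) {
    bad <- names(refs)[refs > 1L][1]
    stop("conflicting reference base at ",
         sub("\r", " position ", bad), " across samples")
  }
  agg <- stats::aggregate(all[COUNT_COLS],
                          by = list(gene = all$gene, pos = all$pos,
                                    ref = all$ref),
                          FUN = sum)
  agg <- agg[order(agg$gene, agg$pos), ]
  out <- data.frame(sample_id = "merged", agg[c("gene", "pos", "ref")],
                    agg[COUNT_COLS], stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Call editing sites from RNA-seq base counts
#'
#' Flank rows (CDS coordinates outside `1..length`) are discarded first;
#' the level is then computed at every C-containing CDS position present in
#' the counts, and a site is called where the level is at or above
#' `threshold` with depth at least `min_depth`. The per-position levels of
#' all C positions are returned alongside the calls, because the
#' reconciliation step needs sub-threshold levels too.
#'
#' @param counts Count data frame (one or more samples; multiple samples
#'   are merged by count summation first).
#' @param panel An [orf_panel()].
#' @param threshold Calling threshold on the editing level, inclusive
#'   (default 0.10).
#' @param min_depth Minimum read depth at a called site (default 1; no
#'   depth filter beyond having data).
#' @return A list with `calls` (data frame `gene`, `pos`, `rnaseq_level`,
#'   `rnaseq_depth`) and `levels` (same columns, all C positions observed).
#' @export
call_rnaseq <- function(counts, panel, threshold = 0.10, min_depth = 1L) {
  stopifnot(inherits(panel, "orf_panel"))
  check_threshold(threshold)
  unknown <- setdiff(unique(counts$gene), names(panel))
  if (length(unknown))
    stop("counts reference unknown gene(s): ", paste(unknown, collapse = ", "))
  if (length(unique(counts$sample_id)) > 1L) counts <- merge_samples(counts)
  len <- vapply(panel, `[[`, integer(1), "length")[counts$gene]
  counts <- counts[counts$pos >= 1L & counts$pos <= len, , drop = FALSE]
  counts <- counts[counts$ref == "C", , drop = FALSE]
  # cross-check the reported reference base against the panel sequence
  panel_ref <- mapply(function(g, p) ref_base_at(panel[[g]], p),
                      counts$gene, counts$pos, USE.NAMES = FALSE)
  if (any(panel_ref != "C")) {
    i <- which(panel_ref != "C")[1]
    stop("counts claim ref C at ", counts$gene[i], "-", counts$pos[i],
         " but the panel has ", panel_ref[i])
  }
  depth <- rowSums(counts[COUNT_COLS])
  levels <- data.frame(gene = counts$gene, pos = counts$pos,
                       rnaseq_level = counts$t_count / depth,
                       rnaseq_depth = as.integer(depth),
                       stringsAsFactors = FALSE)
  levels <- levels[order(levels$gene, levels$pos), ]
  rownames(levels) <- NULL
  calls <- levels[levels$rnaseq_level >= threshold &
                    levels$rnaseq_depth >= min_depth, , drop = FALSE]
  rownames(calls) <- NULL
  list(calls = calls, levels = levels)
}

#' Sanger editing level from peak heights
#'
#' The level at a double-peaked position is `peak_T / (peak_C + peak_T)`,
#' with peak heights read from the chromatogram.
#'
#' @param obs Data frame with columns `peak_c`, `peak_t` (non-negative).
#' @return Numeric vector of levels.
#' @export
sanger_level <- function(obs) {
  tot <- obs$peak_c + obs$peak_t
  if (any(tot <= 0)) stop("peak_C + peak_T must be positive at every row")
  obs$peak_t / tot
}

#' Call editing sites from Sanger replicates
#'
#' A position is called when at least `min_pass_replicates` replicates show
#' a level at or above `threshold` (extremely low levels in single
#' replicates are treated as sequencing artefacts). The reported site level
#' is the mean over all replicates with data.
#'
#' @param obs Data frame `gene`, `pos`, `replicate`, `peak_c`, `peak_t`.
#' @param panel An [orf_panel()].
#' @param threshold Level threshold, inclusive (default 0.10).
#' @param min_pass_replicates Replicates required at or above threshold
#'   (default 2 of 3).
#' @return Data frame of called sites: `gene`, `pos`, `sanger_level`
#'   (replicate mean), `sanger_pass` (replicates passing), `n_replicates`.
#' @export
call_sanger <- function(obs, panel, threshold = 0.10, min_pass_replicates = 2L) {
  stopifnot(inherits(panel, "orf_panel"))
  check_threshold(threshold)
  unknown <- setdiff(unique(obs$gene), names(panel))
  if (length(unknown))
    stop("Sanger table references unknown gene(s): ",
         paste(unknown, collapse = ", "))
  key <- paste(obs$gene, obs$pos, sep = "\r")
  dup <- tapply(obs$replicate, key, anyDuplicated)
  if (any(dup > 0L))
    stop("duplicated replicate id at ",
         sub("\r", " position ", names(dup)[dup > 0L][1]))
  lev <- sanger_level(obs)
  agg <- data.frame(gene = obs$gene, pos = obs$pos, level = lev,
                    stringsAsFactors = FALSE)
  mean_lev <- stats::aggregate(level ~ gene + pos, agg, mean)
  pass <- stats::aggregate(level ~ gene + pos, agg,
                           function(l) sum(l >= threshold))
  nrep <- stats::aggregate(level ~ gene + pos, agg, length)
  out <- data.frame(gene = mean_lev$gene, pos = mean_lev$pos,
                    sanger_level = mean_lev$level,
                    sanger_pass = as.integer(pass$level),
                    n_replicates = as.integer(nrep$level),
                    stringsAsFactors = FALSE)
  out <- out[out$sanger_pass >= min_pass_replicates, , drop = FALSE]
  out <- out[order(out$gene, out$pos), ]
  rownames(out) <- NULL
  out
}

#' Editing-extent category of an accepted site
#'
#' Extremely high (EH), high (H), middle (M) or low (L), from the editing
#' level: L = \[10%, 30%), M = \[30%, 60%), H = \[60%, 90%), EH = \[90%,
#' 100%\]. Categories are defined only for accepted sites, i.e. levels at
#' or above 10%.
#'
#' @param level Numeric vector of editing levels in \[0.10, 1\].
#' @param boundaries Inner bin boundaries (default `c(0.30, 0.60, 0.90)`).
#' @return Character vector over `{"L", "M", "H", "EH"}`.
#' @export
categorize_level <- function(level, boundaries = c(0.30, 0.60, 0.90)) {
  if (any(level < 0.10 - 1e-9 | level > 1 + 1e-9))
    stop("categories are defined only for levels in [0.10, 1]")
  as.character(cut(level, breaks = c(0.10, boundaries, 1 + 1e-9),
                   labels = c("L", "M", "H", "EH"), right = FALSE,
                   include.lowest = TRUE))
}

#' Reconcile Sanger and RNA-seq evidence into a final site set
#'
#' Sanger-called sites are accepted when their RNA-seq level is at least
#' `threshold - rnaseq_tolerance`, or when they lack RNA-seq coverage
#' altogether; the tolerance formalises the retention of Sanger-confirmed
#' sites whose RNA-seq level sits marginally under the threshold (around
#' 9% against a 10% cutoff). RNA-seq-only candidates (level at or above
#' threshold but not confirmed by Sanger) are carried in the output with
#' status `rejected_rnaseq_only` so the decision is auditable.
#'
#' @param sanger_calls Output of [call_sanger()].
#' @param rnaseq_levels The `levels` table from [call_rnaseq()] (all C
#'   positions with coverage).
#' @param threshold Editing-level threshold (default 0.10).
#' @param rnaseq_tolerance Allowed shortfall of the RNA-seq level below
#'   threshold for a Sanger-confirmed site (default 0.02).
#' @return Data frame of site calls: `site_id` ("gene-pos"), `gene`, `pos`,
#'   `sanger_level`, `sanger_pass`, `rnaseq_level`, `rnaseq_depth`,
#'   `category` (EH/H/M/L, accepted sites only), `status` (`accepted`,
#'   `rejected_rnaseq_only`, `rejected_below_threshold`) and `evidence`.
#' @export
reconcile <- function(sanger_calls, rnaseq_levels, threshold = 0.10,
                      rnaseq_tolerance = 0.02) {
  check_threshold(threshold)
  stopifnot(rnaseq_tolerance >= 0, rnaseq_tolerance <= threshold)
  m <- match(paste(sanger_calls$gene, sanger_calls$pos),
             paste(rnaseq_levels$gene, rnaseq_levels$pos))
  rl <- rnaseq_levels$rnaseq_level[m]
  rd <- rnaseq_levels$rnaseq_depth[m]
  has_rna <- !is.na(m)
  ok <- !has_rna | rl >= threshold - rnaseq_tolerance
  sang <- data.frame(
    gene = sanger_calls$gene, pos = sanger_calls$pos,
    sanger_level = sanger_calls$sanger_level,
    sanger_pass = sanger_calls$sanger_pass,
    rnaseq_level = rl, rnaseq_depth = rd,
    status = ifelse(ok, "accepted", "rejected_below_threshold"),
    evidence = ifelse(has_rna, "sanger,rnaseq", "sanger"),
    stringsAsFactors = FALSE)
  rna_only_idx <- which(rnaseq_levels$rnaseq_level >= threshold &
                          is.na(match(paste(rnaseq_levels$gene,
                                            rnaseq_levels$pos),
                                      paste(sanger_calls$gene,
                                            sanger_calls$pos))))
  rna <- if (length(rna_only_idx)) {
    data.frame(gene = rnaseq_levels$gene[rna_only_idx],
               pos = rnaseq_levels$pos[rna_only_idx],
               sanger_level = NA_real_, sanger_pass = NA_integer_,
               rnaseq_level = rnaseq_levels$rnaseq_level[rna_only_idx],
               rnaseq_depth = rnaseq_levels$rnaseq_depth[rna_only_idx],
               status = "rejected_rnaseq_only", evidence = "rnaseq",
               stringsAsFactors = FALSE)
  } else NULL
  out <- rbind(sang, rna)
  out <- out[order(out$gene, out$pos), ]
  # category from the Sanger level when present, else the RNA-seq level
  base_lev <- ifelse(is.na(out$sanger_level), out$rnaseq_level,
                     out$sanger_level)
  out$category <- NA_character_
  acc <- out$status == "accepted"
  # replicate means of borderline accepted sites can dip marginally under
  # the threshold; they belong to the lowest bin
  if (any(acc)) out$category[acc] <- categorize_level(pmax(base_lev[acc], 0.10))
  out <- data.frame(site_id = paste(out$gene, out$pos, sep = "-"), out,
                    stringsAsFactors = FALSE)
  out <- out[c("site_id", "gene", "pos", "sanger_level", "sanger_pass",
               "rnaseq_level", "rnaseq_depth", "category", "status",
               "evidence")]
  rownames(out) <- NULL
  out
}

#' Accepted sites from a reconciled call set
#'
#' @param calls Output of [reconcile()].
#' @return The accepted rows.
#' @export
accepted_sites <- function(calls) {
  calls[calls$status == "accepted", , drop = FALSE]
}

check_threshold <- function(threshold) {
  if (!is.numeric(threshold) || length(threshold) != 1L ||
      is.na(threshold) || threshold < 0 || threshold > 1)
    stop("threshold must be a single value in [0, 1], got ", threshold)
  invisible(TRUE)
}
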