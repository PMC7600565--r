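# Descriptive statistics over an annotated editing-site catalogue:
# codon-position distribution, codon bookkeeping, effect and amino-acid
# change tallies, per-gene editing density, and the Pearson correlations of
# edited-C counts against total Cs and gene length.

#' Round half-up
#'
#' Display percentages use commercial (half-up) rounding, e.g.
#' 32.515 -> 32.52, rather than R's default round-half-to-even.
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 2L) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Distribution of sites over codon positions
#'
#' @param codon_positions Integer vector over `{1, 2, 3}`, one entry per
#'   site.
#' @return Data frame with `codon_pos`, `n`, `pct` (unrounded percentage of
#'   all sites; `NA` when there are no sites) and `pct_display` (half-up,
#'   2 decimals).
#' @export
position_distribution <- function(codon_positions) {
  stopifnot(all(codon_positions %in% 1:3))
  n <- vapply(1:3, function(k) sum(codon_positions == k), integer(1))
  tot <- sum(n)
  pct <- if (tot > 0) 100 * n / tot else rep(NA_real_, 3)
  data.frame(codon_pos = 1:3, n = n, pct = pct,
             pct_display = round_half_up(pct, 2L))
}

#' Codon bookkeeping of a consequence table
#'
#' @param consequences Consequence table from [annotate_sites()] (or any
#'   data frame with an `n_sites` column, one row per edited codon).
#' @return List with `total_codons`, `codons_with_1`, `codons_with_2` and
#'   `total_sites` (`= codons_with_1 + 2 * codons_with_2`).
#' @export
codon_count_distribution <- function(consequences) {
  n <- consequences$n_sites
  stopifnot(all(n %in% 1:2))
  list(total_codons = length(n),
       codons_with_1 = sum(n == 1L),
       codons_with_2 = sum(n == 2L),
       total_sites = sum(n))
}

#' Share of the k most edited codons
#'
#' @param codon_tally Named integer vector, edited-event count per
#'   reference codon.
#' @param k Number of top codons (default 3).
#' @return List with `top` (the sorted top-k tally) and `share_pct`
#'   (their percentage of all codon-editing events, unrounded).
#' @export
top_codon_share <- function(codon_tally, k = 3L) {
  stopifnot(length(codon_tally) >= 1L, sum(codon_tally) > 0)
  srt <- sort(codon_tally, decreasing = TRUE)
  top <- srt[seq_len(min(k, length(srt)))]
  list(top = top, share_pct = 100 * sum(top) / sum(codon_tally))
}

#' Per-gene edited-C fraction
#'
#' @param sites Data frame of accepted sites (`gene`, `pos`).
#' @param panel An [orf_panel()].
#' @return Data frame over all panel genes: `gene`, `n_sites` (distinct
#'   edited C positions), `total_Cs`, `length`, `pct_C_edited`
#'   (`100 * n_sites / total_Cs`; `NA` for a gene without Cs, flagged in
#'   `no_c_flag`).
#' @export
per_gene_c_fraction <- function(sites, panel) {
  stopifnot(inherits(panel, "orf_panel"))
  genes <- names(panel)
  n_sites <- vapply(genes, function(g) {
    length(unique(sites$pos[sites$gene == g]))
  }, integer(1))
  total_c <- vapply(panel, function(o) length(c_positions(o)), integer(1))
  len <- vapply(panel, `[[`, integer(1), "length")
  pct <- ifelse(total_c > 0, 100 * n_sites / total_c, NA_real_)
  data.frame(gene = genes, n_sites = n_sites, total_Cs = total_c,
             length = len, pct_C_edited = pct, no_c_flag = total_c == 0,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Pearson product-moment correlation with t-based p-value
#'
#' Computes `r` from the product-moment formula and the two-sided p-value
#' through the t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` against a
#' t distribution with `n - 2` degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, at least 3, with non-zero
#'   variance.
#' @return List with `r`, `p`, `t`, `df`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("Pearson correlation requires non-zero variance in both vectors")
  xc <- x - mean(x)
  yc <- y - mean(y)
  r <- sum(xc * yc) / sqrt(sum(xc^2) * sum(yc^2))
  c(pearson_p_from_r(r, length(x)), list(n = length(x)))
}

#' Two-sided p-value of a Pearson r via the t transform
#'
#' @param r Correlation coefficient.
#' @param n Number of observations (at least 3).
#' @return List with `r`, `p`, `t` and `df = n - 2`.
#' @export
pearson_p_from_r <- function(r, n) {
  stopifnot(abs(r) <= 1, n >= 3L)
  df <- n - 2L
  if (abs(r) >= 1) return(list(r = r, p = 0, t = Inf * sign(r), df = df))
  t <- r * sqrt(df) / sqrt(1 - r^2)
  list(r = r, p = 2 * stats::pt(-abs(t), df), t = t, df = df)
}

#' Summarise an annotated editing-site catalogue
#'
#' @param annotated Result of [annotate_sites()]: per-site annotations and
#'   per-codon consequences.
#' @param panel The [orf_panel()] the sites were called on.
#' @return A list of class `editing_summary`: `total_sites`, `n_genes_hit`,
#'   `per_gene`, `position_distribution`, `codon_counts`, `effect_tally`
#'   (synonymous vs nonsynonymous codons; stop/start gains that change the
#'   amino acid count as nonsynonymous), `aa_change_tally`,
#'   `edited_codon_tally` (RNA alphabet, descending),
#'   `top_codons`, `hydrophobic_gain_pct` (share of nonsynonymous codon
#'   changes producing a hydrophobic residue), `special_events` (start- and
#'   stop-gain records), and `correlations` (edited Cs vs total Cs and vs
#'   gene length over genes with at least one site; `NULL` when fewer than
#'   3 such genes).
#' @export
summarize_sites <- function(annotated, panel) {
  sites <- annotated$sites
  cons <- annotated$consequences
  per_gene <- per_gene_c_fraction(sites, panel)
  n_sites <- nrow(sites)

  pos_dist <- if (n_sites)
    position_distribution(sites$codon_pos) else position_distribution(integer())
  codon_counts <- codon_count_distribution(cons)
  effect_tally <- c(synonymous = sum(!cons$nonsynonymous),
                    nonsynonymous = sum(cons$nonsynonymous))
  aa_tally <- if (nrow(cons)) {
    tab <- table(cons$aa_change[cons$nonsynonymous])
    sort(c(tab), decreasing = TRUE)
  } else integer(0)
  codon_tally <- if (nrow(cons)) {
    tab <- table(chartr("T", "U", cons$ref_codon))
    sort(c(tab), decreasing = TRUE)
  } else integer(0)
  top <- if (length(codon_tally)) top_codon_share(codon_tally, 3L) else NULL
  nonsyn_aa <- cons$edited_aa[cons$nonsynonymous & cons$edited_aa != "*"]
  hydro_pct <- if (length(nonsyn_aa))
    100 * mean(nonsyn_aa %in% HYDROPHOBIC_AA) else NA_real_

  special <- list(
    start_gain = cons[cons$effect == "start_gain", , drop = FALSE],
    stop_gain = cons[cons$effect == "stop_gain", , drop = FALSE])

  hit <- per_gene[per_gene$n_sites > 0 & !per_gene$no_c_flag, , drop = FALSE]
  correlations <- if (nrow(hit) >= 3L &&
                      stats::var(hit$n_sites) > 0 &&
                      stats::var(hit$total_Cs) > 0 &&
                      stats::var(hit$length) > 0) {
    list(edited_vs_total_c = pearson_cor(hit$n_sites, hit$total_Cs),
         edited_vs_length = pearson_cor(hit$n_sites, hit$length))
  } else NULL

  structure(list(total_sites = n_sites,
                 n_genes_hit = sum(per_gene$n_sites > 0),
                 per_gene = per_gene,
                 position_distribution = pos_dist,
                 codon_counts = codon_counts,
                 effect_tally = effect_tally,
                 aa_change_tally = aa_tally,
                 edited_codon_tally = codon_tally,
                 top_codons = top,
                 hydrophobic_gain_pct = hydro_pct,
                 special_events = special,
                 correlations = correlations),
            class = "editing_summary")
}

#' @export
print.editing_summary <- function(x, ...) {
  cat(render_summary(x), sep = "\n")
  invisible(x)
}

#' Render a summary as plain text
#'
#' @param s An `editing_summary`.
#' @return Character vector of report lines.
#' @export
render_summary <- function(s) {
  fmt_pct <- function(p) ifelse(is.na(p), "n/a",
                                sprintf("%.2f%%", round_half_up(p, 2L)))
  lines <- c(
    sprintf("C-to-U editing sites: %d (in %d ORFs)", s$total_sites,
            s$n_genes_hit),
    "",
    "Codon-position distribution:",
    sprintf("  position %d: %d (%s)", s$position_distribution$codon_pos,
            s$position_distribution$n, fmt_pct(s$position_distribution$pct)),
    "",
    sprintf("Edited codons: %d (%d with one site, %d with two sites)",
            s$codon_counts$total_codons, s$codon_counts$codons_with_1,
            s$codon_counts$codons_with_2),
    sprintf("Effects: %d synonymous, %d nonsynonymous codon alterations",
            s$effect_tally[["synonymous"]], s$effect_tally[["nonsynonymous"]]),
    sprintf("Nonsynonymous changes producing a hydrophobic residue: %s",
            fmt_pct(s$hydrophobic_gain_pct)))
  if (length(s$aa_change_tally)) {
    k <- min(3L, length(s$aa_change_tally))
    lines <- c(lines, sprintf(
      "Top amino-acid changes: %s",
      paste(sprintf("%s (%d)", names(s$aa_change_tally)[1:k],
                    s$aa_change_tally[1:k]), collapse = ", ")))
  }
  if (!is.null(s$top_codons)) {
    lines <- c(lines, sprintf(
      "Top edited codons: %s, together %s of edited codons",
      paste(sprintf("%s (%d)", names(s$top_codons$top), s$top_codons$top),
            collapse = ", "),
      fmt_pct(s$top_codons$share_pct)))
  }
  lines <- c(lines, sprintf(
    "Start gains: %d; stop gains: %d",
    nrow(s$special_events$start_gain), nrow(s$special_events$stop_gain)))
  if (!is.null(s$correlations)) {
    cc <- s$correlations
    lines <- c(lines, sprintf(
      "Pearson edited Cs vs total Cs: r = %.3f, p < %.3f; vs gene length: r = %.3f, p < %.3f",
      cc$edited_vs_total_c$r, ceiling(cc$edited_vs_total_c$p * 1000) / 1000,
      cc$edited_vs_length$r, ceiling(cc$edited_vs_length$p * 1000) / 1000))
  }
  lines
}

#' Alignment-column conservation report
#'
#' Maps an ungapped residue position of a chosen reference row of a
#' pre-computed protein multiple alignment to its alignment column, and
#' reports that column together with the fraction of sequences matching the
#' reference residue (gap rows excluded from the denominator).
#'
#' @param aligned_fasta Path to an aligned protein FASTA (gaps `-` or `.`).
#' @param reference_id FASTA id (token up to whitespace) of the reference
#'   row.
#' @param position 1-based ungapped residue position in the reference row.
#' @return List with `column` (aligned column index), `residues` (named
#'   character vector, one per sequence), `reference_residue` and
#'   `identity_fraction`.
#' @export
alignment_column_report <- function(aligned_fasta, reference_id, position) {
  aln <- Biostrings::readAAStringSet(aligned_fasta)
  ids <- sub("\\s.*$", "", names(aln))
  i <- match(reference_id, ids)
  if (is.na(i)) stop("reference row '", reference_id, "' not in alignment")
  refchars <- strsplit(as.character(aln[[i]]), "")[[1]]
  is_res <- !(refchars %in% c("-", "."))
  if (position < 1L || position > sum(is_res))
    stop("ungapped position ", position, " exceeds reference length ",
         sum(is_res))
  col <- which(cumsum(is_res) == position & is_res)[1]
  residues <- vapply(seq_along(aln),
                     function(j) substr(as.character(aln[[j]]), col, col),
                     character(1))
  names(residues) <- ids
  ref_res <- residues[[i]]
  nongap <- !(residues %in% c("-", "."))
  list(column = col, residues = residues, reference_residue = ref_res,
       identity_fraction = sum(residues == ref_res & nongap) / sum(nongap))
}
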