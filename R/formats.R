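# Tab-separated table dialects and GFF3 export. All readers validate the
# header and the first malformed line deterministically, reporting its line
# number.

read_tsv_checked <- function(path, expected_cols, int_cols = character(),
                             num_cols = character(), what = "table") {
  if (!file.exists(path)) stop(what, " file not found: ", path)
  lines <- readLines(path)
  if (!length(lines)) stop(what, " '", path, "': empty file")
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header, expected_cols))
    stop(what, " '", path, "': expected header '",
         paste(expected_cols, collapse = "\t"), "' but found '",
         lines[1], "'")
  body <- lines[-1]
  body <- body[nzchar(body)]
  parts <- strsplit(body, "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield != length(expected_cols))) {
    i <- which(nfield != length(expected_cols))[1]
    stop(what, " '", path, "': line ", i + 1L, " has ", nfield[i],
         " fields, expected ", length(expected_cols))
  }
  df <- as.data.frame(do.call(rbind, parts), stringsAsFactors = FALSE)
  names(df) <- expected_cols
  for (cl in int_cols) {
    v <- suppressWarnings(as.integer(df[[cl]]))
    bad <- which(is.na(v) & !(df[[cl]] %in% c("NA", "")))
    if (length(bad))
      stop(what, " '", path, "': line ", bad[1] + 1L, ", column '", cl,
           "': '", df[[cl]][bad[1]], "' is not an integer")
    df[[cl]] <- v
  }
  for (cl in num_cols) {
    na_in <- df[[cl]] %in% c("NA", "")
    v <- suppressWarnings(as.numeric(df[[cl]]))
    bad <- which(is.na(v) & !na_in)
    if (length(bad))
      stop(what, " '", path, "': line ", bad[1] + 1L, ", column '", cl,
           "': '", df[[cl]][bad[1]], "' is not numeric")
    df[[cl]] <- v
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read / write per-position base-count tables
#'
#' Dialect: tab-separated with header
#' `sample_id gene pos ref a_count c_count g_count t_count`. Counts must be
#' non-negative integers with positive depth; the first malformed line is
#' reported with its line number.
#'
#' @param path File path.
#' @return Data frame of counts.
#' @export
read_counts_tsv <- function(path) {
  df <- read_tsv_checked(path,
                         c("sample_id", "gene", "pos", "ref", COUNT_COLS),
                         int_cols = c("pos", COUNT_COLS), what = "counts")
  neg <- which(apply(df[COUNT_COLS] < 0L, 1L, any))
  if (length(neg))
    stop("counts '", path, "': line ", neg[1] + 1L, ": negative count")
  zero <- which(rowSums(df[COUNT_COLS]) == 0L)
  if (length(zero))
    stop("counts '", path, "': line ", zero[1] + 1L, ": zero depth")
  df
}

#' @rdname read_counts_tsv
#' @param counts Count data frame.
#' @export
write_counts_tsv <- function(counts, path) write_tsv(counts, path)

#' Read / write Sanger peak-height tables
#'
#' Dialect: tab-separated with header `gene pos replicate peak_c peak_t`;
#' peaks are non-negative reals with positive sum per row.
#'
#' @param path File path.
#' @return Data frame of observations.
#' @export
read_sanger_tsv <- function(path) {
  df <- read_tsv_checked(path, c("gene", "pos", "replicate", "peak_c",
                                 "peak_t"),
                         int_cols = c("pos", "replicate"),
                         num_cols = c("peak_c", "peak_t"), what = "sanger")
  bad <- which(df$peak_c < 0 | df$peak_t < 0 | df$peak_c + df$peak_t <= 0)
  if (length(bad))
    stop("sanger '", path, "': line ", bad[1] + 1L,
         ": peaks must be non-negative with positive sum")
  df
}

#' @rdname read_sanger_tsv
#' @param obs Sanger observation data frame.
#' @export
write_sanger_tsv <- function(obs, path) write_tsv(obs, path)

#' Read / write reconciled call tables
#'
#' Dialect: tab-separated with the columns produced by [reconcile()].
#'
#' @param path File path.
#' @return Data frame of calls.
#' @export
read_calls_tsv <- function(path) {
  read_tsv_checked(path,
                   c("site_id", "gene", "pos", "sanger_level", "sanger_pass",
                     "rnaseq_level", "rnaseq_depth", "category", "status",
                     "evidence"),
                   int_cols = c("pos", "sanger_pass", "rnaseq_depth"),
                   num_cols = c("sanger_level", "rnaseq_level"),
                   what = "calls")
}

#' @rdname read_calls_tsv
#' @param calls Call data frame from [reconcile()].
#' @export
write_calls_tsv <- function(calls, path) write_tsv(calls, path)

#' Read / write planted-truth tables
#'
#' Dialect: tab-separated with header
#' `gene pos class true_level rnaseq_level sanger_level in_rnaseq in_sanger`.
#'
#' @param path File path.
#' @return Truth data frame.
#' @export
read_truth_tsv <- function(path) {
  df <- read_tsv_checked(path,
                         c("gene", "pos", "class", "true_level",
                           "rnaseq_level", "sanger_level", "in_rnaseq",
                           "in_sanger"),
                         int_cols = "pos",
                         num_cols = c("true_level", "rnaseq_level",
                                      "sanger_level"),
                         what = "truth")
  df$in_rnaseq <- as.logical(df$in_rnaseq)
  df$in_sanger <- as.logical(df$in_sanger)
  df
}

#' @rdname read_truth_tsv
#' @param truth Truth data frame.
#' @export
write_truth_tsv <- function(truth, path) write_tsv(truth, path)

#' Export annotated sites as GFF3
#'
#' One `RNA_editing_site` feature per site on the ORF sequence, 1-based
#' `start = end = position`, with all annotation fields carried as
#' attributes. The export round-trips through [read_sites_gff3()].
#'
#' @param annotated_sites The `sites` element of [annotate_sites()].
#' @param path Output GFF3 path.
#' @param source Value of the GFF3 source column.
#' @return `path`, invisibly.
#' @export
export_sites_gff3 <- function(annotated_sites, path, source = "mitoedit") {
  s <- annotated_sites
  gr <- GenomicRanges::GRanges(
    seqnames = s$gene,
    ranges = IRanges::IRanges(start = s$pos, end = s$pos),
    strand = "+")
  GenomicRanges::mcols(gr) <- S4Vectors::DataFrame(
    source = source, type = "RNA_editing_site",
    ID = paste(s$gene, s$pos, sep = "-"),
    sanger_level = signif(s$sanger_level, 6),
    rnaseq_level = signif(s$rnaseq_level, 6),
    category = s$category,
    codon_index = s$codon_index, codon_pos = s$codon_pos,
    ref_codon = s$ref_codon, edited_codon = s$edited_codon,
    ref_aa = s$ref_aa, edited_aa = s$edited_aa,
    effect = s$effect, aa_change = s$aa_change,
    hydropathy = s$hydropathy,
    is_pseudogene = s$is_pseudogene)
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read back a GFF3 site export
#'
#' @param path GFF3 file written by [export_sites_gff3()].
#' @return Data frame with the same annotation columns.
#' @export
read_sites_gff3 <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  mc <- as.data.frame(GenomicRanges::mcols(gr))
  out <- data.frame(gene = as.character(GenomicRanges::seqnames(gr)),
                    pos = GenomicRanges::start(gr),
                    stringsAsFactors = FALSE)
  for (cl in c("sanger_level", "rnaseq_level"))
    out[[cl]] <- as.numeric(mc[[cl]])
  for (cl in c("codon_index", "codon_pos"))
    out[[cl]] <- as.integer(mc[[cl]])
  for (cl in c("category", "ref_codon", "edited_codon", "ref_aa",
               "edited_aa", "effect", "aa_change", "hydropathy"))
    out[[cl]] <- as.character(mc[[cl]])
  out$is_pseudogene <- as.logical(mc$is_pseudogene)
  out[order(out$gene, out$pos), , drop = FALSE]
}

#' Lint claimed editing-site annotations against the reference
#'
#' Database annotations of editing sites are occasionally off by one
#' nucleotide. For each claim `(gene, pos, ref_aa, edited_aa)` (three-letter
#' amino-acid names), this checks whether a single C->T edit at the claimed
#' position reproduces the claimed amino-acid change; if not, it tests the
#' neighbouring positions (+/- 1) and the other C positions of the same
#' codon, and reports the unique position that does.
#'
#' @param claims Data frame with columns `gene`, `pos`, `claimed_ref_aa`,
#'   `claimed_edited_aa`.
#' @param panel An [orf_panel()].
#' @return Data frame with the claims plus `status` (`confirmed`,
#'   `off_by_one`, `same_codon_other_c`, `unexplainable`), `corrected_pos`,
#'   and the amino-acid change actually observed at the claimed position.
#' @export
lint_annotations <- function(claims, panel) {
  stopifnot(inherits(panel, "orf_panel"))
  aa1 <- stats::setNames(names(AA3), AA3)

  change_at <- function(orf, p) {
    # amino-acid pair produced by a single C->T edit at p, or NULL
    if (p < 1L || p > orf$length) return(NULL)
    if (ref_base_at(orf, p) != "C") return(NULL)
    ctx <- tryCatch(codon_context(orf, p), error = function(e) NULL)
    if (is.null(ctx)) return(NULL)
    ed <- strsplit(ctx$ref_codon, "")[[1]]
    ed[ctx$codon_position] <- "T"
    c(ref = translate_codon(ctx$ref_codon),
      edited = translate_codon(paste(ed, collapse = "")))
  }

  rows <- lapply(seq_len(nrow(claims)), function(i) {
    g <- claims$gene[i]
    p <- as.integer(claims$pos[i])
    if (!g %in% names(panel))
      stop("claim ", i, " references unknown gene '", g, "'")
    orf <- panel[[g]]
    want_ref <- aa1[[claims$claimed_ref_aa[i]]]
    want_ed <- aa1[[claims$claimed_edited_aa[i]]]
    obs <- change_at(orf, p)
    obs_label <- if (is.null(obs)) "no C / no codon"
                 else paste0(AA3[[obs["ref"]]], "-to-", AA3[[obs["edited"]]])
    if (!is.null(obs) && obs["ref"] == want_ref && obs["edited"] == want_ed) {
      return(data.frame(claims[i, ], status = "confirmed",
                        corrected_pos = p, observed_change = obs_label,
                        stringsAsFactors = FALSE))
    }
    # candidate corrections: neighbours, then other Cs of the claimed codon
    cand <- c(p - 1L, p + 1L)
    ci <- (p + 2L) %/% 3L
    codon_range <- (ci * 3L - 2L):(ci * 3L)
    cand <- unique(c(cand, setdiff(codon_range, p)))
    hits <- Filter(function(q) {
      o <- change_at(orf, q)
      !is.null(o) && o["ref"] == want_ref && o["edited"] == want_ed
    }, cand)
    if (length(hits) == 1L) {
      status <- if (abs(hits[[1]] - p) == 1L) "off_by_one"
                else "same_codon_other_c"
      data.frame(claims[i, ], status = status,
                 corrected_pos = hits[[1]], observed_change = obs_label,
                 stringsAsFactors = FALSE)
    } else {
      data.frame(claims[i, ], status = "unexplainable",
                 corrected_pos = NA_integer_, observed_change = obs_label,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
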