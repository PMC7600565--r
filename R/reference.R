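# ORF panel: the coordinate frame for every downstream stage.
# All positions are 1-based and counted within the CDS; sequences are stored
# in DNA alphabet on the sense strand, so a C-to-U edit is always a
# reference C observed as T.

#' Construct an ORF record
#'
#' An ORF record holds one sense-strand coding sequence (CDS) and the
#' coordinate frame used by all site calls: position `p` (1-based within the
#' CDS) maps to offset `p + flank_len` in the originally stored flanked
#' sequence.
#'
#' @param gene_id Short gene identifier (e.g. `"atp1"`).
#' @param cds_seq CDS as a character string over `A/C/G/T` (sense strand, no
#'   flanks). Length must be at least 3. Ambiguity codes are rejected.
#' @param flank_len Non-negative number of flanking nucleotides that were
#'   present on each side of the CDS in the source sequence (recorded for
#'   provenance; the flanks themselves are not stored).
#' @param is_pseudogene Logical; pseudogenes are carried through all stages
#'   and annotated in their nominal reading frame.
#'
#' @return An object of class `orf_record` with fields `gene_id`, `cds_seq`,
#'   `flank_len`, `is_pseudogene` and `length` (CDS length in nt).
#' @export
orf_record <- function(gene_id, cds_seq, flank_len = 0L, is_pseudogene = FALSE) {
  stopifnot(is.character(gene_id), length(gene_id) == 1L, nzchar(gene_id))
  stopifnot(is.character(cds_seq), length(cds_seq) == 1L)
  cds_seq <- toupper(cds_seq)
  if (nchar(cds_seq) < 3L)
    stop("ORF '", gene_id, "': CDS must be at least 3 nt, got ", nchar(cds_seq))
  bad <- regexpr("[^ACGT]", cds_seq)
  if (bad > 0L)
    stop("ORF '", gene_id, "': non-ACGT character '",
         substr(cds_seq, bad, bad), "' at CDS position ", bad,
         " (ambiguity codes are not accepted)")
  flank_len <- as.integer(flank_len)
  stopifnot(length(flank_len) == 1L, !is.na(flank_len), flank_len >= 0L)
  structure(
    list(gene_id = gene_id, cds_seq = cds_seq, flank_len = flank_len,
         is_pseudogene = isTRUE(is_pseudogene), length = nchar(cds_seq)),
    class = "orf_record")
}

#' @export
print.orf_record <- function(x, ...) {
  cat(sprintf("<orf_record> %s: %d nt CDS, flank_len=%d%s\n",
              x$gene_id, x$length, x$flank_len,
              if (x$is_pseudogene) ", pseudogene" else ""))
  invisible(x)
}

#' Build an ORF panel from records
#'
#' @param records A list of [orf_record()] objects with unique gene ids.
#' @return A named list of records with class `orf_panel`.
#' @export
orf_panel <- function(records) {
  stopifnot(is.list(records), length(records) > 0L)
  ok <- vapply(records, inherits, logical(1), what = "orf_record")
  if (!all(ok)) stop("all panel entries must be orf_record objects")
  ids <- vapply(records, `[[`, character(1), "gene_id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate gene id(s) in panel: ", paste(unique(dup), collapse = ", "))
  names(records) <- ids
  structure(records, class = "orf_panel")
}

#' @export
print.orf_panel <- function(x, ...) {
  cat(sprintf("<orf_panel> %d ORFs, %d nt CDS total\n",
              length(x), sum(vapply(x, `[[`, integer(1), "length"))))
  invisible(x)
}

#' Load an ORF panel from a multi-FASTA file
#'
#' Reads sense-strand CDS sequences, optionally flanked: when `flank_len > 0`
#' the first and last `flank_len` nt of each FASTA sequence are trimmed, and
#' the remainder is stored as the CDS. The FASTA header token up to the first
#' whitespace is the gene id.
#'
#' @param fasta_path Path to a multi-FASTA file of DNA sequences.
#' @param flank_len Flanking nucleotides to trim from each end (default 0).
#' @param pseudogene_ids Character vector of gene ids to flag as pseudogenes.
#'
#' @return An [orf_panel()].
#' @export
load_orf_panel <- function(fasta_path, flank_len = 0L, pseudogene_ids = character()) {
  flank_len <- as.integer(flank_len)
  stopifnot(flank_len >= 0L)
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids)) {
    dup <- unique(ids[duplicated(ids)])
    offs <- vapply(dup, function(d) paste(which(ids == d), collapse = ","),
                   character(1))
    stop("duplicate gene id(s) in FASTA: ",
         paste(sprintf("%s (entries %s)", dup, offs), collapse = "; "))
  }
  records <- lapply(seq_along(seqs), function(i) {
    s <- as.character(seqs[[i]])
    if (nchar(s) <= 2L * flank_len)
      stop("ORF '", ids[i], "': sequence length ", nchar(s),
           " is not longer than twice the flank length (", flank_len, ")")
    cds <- substr(s, flank_len + 1L, nchar(s) - flank_len)
    orf_record(ids[i], cds, flank_len = flank_len,
               is_pseudogene = ids[i] %in% pseudogene_ids)
  })
  orf_panel(records)
}

#' Codon context of a CDS position
#'
#' Maps a 1-based CDS position to its codon: `codon_index = ceiling(p/3)` and
#' `codon_position = ((p - 1) mod 3) + 1`. Positions falling in a trailing
#' partial codon (when the CDS length is not a multiple of 3) are an error,
#' since no codon-level annotation is defined there.
#'
#' @param orf An [orf_record()].
#' @param p 1-based CDS position.
#' @return A list with `codon_index`, `codon_position` (1, 2 or 3) and
#'   `ref_codon` (3-letter DNA string).
#' @export
codon_context <- function(orf, p) {
  stopifnot(inherits(orf, "orf_record"))
  p <- as.integer(p)
  stopifnot(length(p) == 1L, !is.na(p))
  if (p < 1L || p > orf$length)
    stop("position ", p, " outside CDS of '", orf$gene_id,
         "' (length ", orf$length, ")")
  codon_index <- (p + 2L) %/% 3L
  if (codon_index * 3L > orf$length)
    stop("position ", p, " of '", orf$gene_id,
         "' lies in a trailing partial codon (", orf$length %% 3L,
         " nt remainder); codon annotation is undefined there")
  list(codon_index = codon_index,
       codon_position = ((p - 1L) %% 3L) + 1L,
       ref_codon = substr(orf$cds_seq, codon_index * 3L - 2L, codon_index * 3L))
}

#' Translate one codon with the standard genetic code
#'
#' Plant mitochondria use the standard genetic code; `U` and `T` are treated
#' identically. Ambiguity codes are rejected rather than expanded.
#'
#' @param codon A 3-letter DNA or RNA codon.
#' @return One-letter amino-acid code, or `"*"` for a stop codon.
#' @export
translate_codon <- function(codon) {
  stopifnot(is.character(codon), length(codon) == 1L)
  codon <- chartr("u", "U", toupper(codon))
  codon <- chartr("U", "T", codon)
  if (!grepl("^[ACGT]{3}$", codon))
    stop("'", codon, "' is not a 3-letter A/C/G/T(/U) codon")
  unname(Biostrings::GENETIC_CODE[[codon]])
}

#' Positions of cytidines in a CDS
#'
#' These are the only positions eligible for C-to-U editing and the
#' denominator of the per-gene percent-of-Cs-edited statistic.
#'
#' @param orf An [orf_record()].
#' @return Strictly increasing integer vector of 1-based CDS positions with
#'   reference base C (possibly empty).
#' @export
c_positions <- function(orf) {
  stopifnot(inherits(orf, "orf_record"))
  which(strsplit(orf$cds_seq, "", fixed = TRUE)[[1]] == "C")
}

# Reference base at a CDS position (internal).
ref_base_at <- function(orf, p) substr(orf$cds_seq, p, p)
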