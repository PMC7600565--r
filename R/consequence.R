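# Codon-level consequences of accepted editing sites. Sites sharing a codon
# are annotated together: the edited codon applies all of the codon's C->T
# edits simultaneously.

AA3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val", "*" = "Ter")

#' Default hydrophobic amino-acid set
#'
#' Residues with positive Kyte-Doolittle hydropathy; all others (including
#' Pro, Ser, Gly) are treated as hydrophilic. The set is a parameter of
#' [annotate_sites()] and [hydropathy_transition()] so other conventions
#' can be substituted.
#' @export
HYDROPHOBIC_AA <- c("A", "C", "F", "I", "L", "M", "V")

#' Classify the effect of C-to-U edits on one codon
#'
#' The edited codon must be reachable from the reference codon by C->T
#' substitutions only. Start gain (ACG -> ATG) and stop gain (edited codon
#' is a stop) take precedence over the synonymous/nonsynonymous dichotomy.
#'
#' @param ref_codon,edited_codon 3-letter DNA codons.
#' @return One of `"synonymous"`, `"nonsynonymous"`, `"stop_gain"`,
#'   `"start_gain"`.
#' @export
classify_effect <- function(ref_codon, edited_codon) {
  ref <- strsplit(toupper(ref_codon), "")[[1]]
  ed <- strsplit(toupper(edited_codon), "")[[1]]
  stopifnot(length(ref) == 3L, length(ed) == 3L)
  diff <- which(ref != ed)
  if (length(diff) == 0L)
    stop("edited codon is identical to the reference codon")
  if (any(ref[diff] != "C" | ed[diff] != "T"))
    stop("'", edited_codon, "' is not reachable from '", ref_codon,
         "' by C->T edits only")
  ref_aa <- translate_codon(ref_codon)
  ed_aa <- translate_codon(edited_codon)
  if (paste(ref, collapse = "") == "ACG" &&
      paste(ed, collapse = "") == "ATG") return("start_gain")
  if (ed_aa == "*" && ref_aa != "*") return("stop_gain")
  if (ref_aa == ed_aa) "synonymous" else "nonsynonymous"
}

#' Hydropathy class transition of an amino-acid change
#'
#' @param ref_aa,edited_aa One-letter amino-acid codes (stop `"*"` yields
#'   `"na"`).
#' @param hydrophobic Character vector defining the hydrophobic class
#'   (default [HYDROPHOBIC_AA]).
#' @return One of `"hydrophilic_to_hydrophobic"`,
#'   `"hydrophobic_to_hydrophilic"`, `"unchanged_class"`, `"na"`.
#' @export
hydropathy_transition <- function(ref_aa, edited_aa,
                                  hydrophobic = HYDROPHOBIC_AA) {
  if (ref_aa == "*" || edited_aa == "*") return("na")
  stopifnot(ref_aa %in% names(AA3), edited_aa %in% names(AA3))
  r <- ref_aa %in% hydrophobic
  e <- edited_aa %in% hydrophobic
  if (r == e) "unchanged_class"
  else if (e) "hydrophilic_to_hydrophobic"
  else "hydrophobic_to_hydrophilic"
}

aa_change_label <- function(ref_aa, edited_aa) {
  if (ref_aa == edited_aa) "syn"
  else paste0(AA3[[ref_aa]], "-to-", AA3[[edited_aa]])
}

#' Annotate accepted sites with codon consequences
#'
#' Sites sharing a (gene, codon) pair are grouped, and the edited codon is
#' obtained by applying all of that codon's C->T edits at once, so a codon
#' carrying two editing sites yields a single consequence record.
#'
#' @param sites Data frame of accepted sites with columns `gene`, `pos`
#'   (e.g. [accepted_sites()] of a reconciled call set, or a truth table).
#' @param panel An [orf_panel()] providing the reference codons.
#' @param hydrophobic Hydrophobic amino-acid set for the hydropathy label.
#' @return A list with
#'   `sites`: the input rows plus `codon_index`, `codon_pos`, `ref_codon`,
#'   `edited_codon`, `ref_aa`, `edited_aa`, `effect`, `aa_change`,
#'   `hydropathy`, `is_pseudogene`; and
#'   `consequences`: one row per edited codon with `gene`, `codon_index`,
#'   `positions_in_codon` (comma-joined codon offsets), `n_sites`,
#'   `ref_codon`, `edited_codon`, `ref_aa`, `edited_aa`, `effect`,
#'   `nonsynonymous` (logical; counts stop/start gains as nonsynonymous
#'   when the amino acid changes), `aa_change`, `hydropathy`.
#' @export
annotate_sites <- function(sites, panel, hydrophobic = HYDROPHOBIC_AA) {
  stopifnot(inherits(panel, "orf_panel"))
  if (nrow(sites) == 0L)
    return(list(sites = sites, consequences = empty_consequences()))
  unknown <- setdiff(unique(sites$gene), names(panel))
  if (length(unknown))
    stop("sites reference unknown gene(s): ", paste(unknown, collapse = ", "))

  ctx <- mapply(function(g, p) {
    orf <- panel[[g]]
    if (ref_base_at(orf, p) != "C")
      stop("site ", g, "-", p, " does not sit on a reference C (found ",
           ref_base_at(orf, p), "); upstream call set is corrupt")
    codon_context(orf, p)
  }, sites$gene, sites$pos, SIMPLIFY = FALSE, USE.NAMES = FALSE)
  sites$codon_index <- vapply(ctx, `[[`, integer(1), "codon_index")
  sites$codon_pos <- vapply(ctx, `[[`, integer(1), "codon_position")
  sites$ref_codon <- vapply(ctx, `[[`, character(1), "ref_codon")

  keys <- paste(sites$gene, sites$codon_index)
  groups <- split(seq_len(nrow(sites)), factor(keys, levels = unique(keys)))
  cons <- lapply(groups, function(idx) {
    g <- sites$gene[idx[1]]
    ci <- sites$codon_index[idx[1]]
    offs <- sort(sites$codon_pos[idx])
    ref <- sites$ref_codon[idx[1]]
    ed <- strsplit(ref, "")[[1]]
    ed[offs] <- "T"
    ed <- paste(ed, collapse = "")
    ref_aa <- translate_codon(ref)
    ed_aa <- translate_codon(ed)
    data.frame(gene = g, codon_index = ci,
               positions_in_codon = paste(offs, collapse = ","),
               n_sites = length(offs), ref_codon = ref, edited_codon = ed,
               ref_aa = ref_aa, edited_aa = ed_aa,
               effect = classify_effect(ref, ed),
               nonsynonymous = ref_aa != ed_aa,
               aa_change = aa_change_label(ref_aa, ed_aa),
               hydropathy = hydropathy_transition(ref_aa, ed_aa, hydrophobic),
               stringsAsFactors = FALSE)
  })
  consequences <- do.call(rbind, cons)
  consequences <- consequences[order(consequences$gene,
                                     consequences$codon_index), ]
  rownames(consequences) <- NULL

  m <- match(keys, paste(consequences$gene, consequences$codon_index))
  for (col in c("edited_codon", "ref_aa", "edited_aa", "effect",
                "aa_change", "hydropathy"))
    sites[[col]] <- consequences[[col]][m]
  sites$is_pseudogene <- vapply(panel[sites$gene], `[[`, logical(1),
                                "is_pseudogene")
  rownames(sites) <- NULL
  list(sites = sites, consequences = consequences)
}

empty_consequences <- function() {
  data.frame(gene = character(), codon_index = integer(),
             positions_in_codon = character(), n_sites = integer(),
             ref_codon = character(), edited_codon = character(),
             ref_aa = character(), edited_aa = character(),
             effect = character(), nonsynonymous = logical(),
             aa_change = character(), hydropathy = character(),
             stringsAsFactors = FALSE)
}
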