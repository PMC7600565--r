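# Independent oracles and fixture builders used across the suite.

# Hard-coded standard genetic code, written out independently of the
# implementation (classic TCAG-ordered table).
oracle_genetic_code <- local({
  b <- c("T", "C", "A", "G")
  codons <- character(64)
  aas <- strsplit(paste0(
    "FFLLSSSSYY**CC*W",
    "LLLLPPPPHHQQRRRR",
    "IIIMTTTTNNKKSSRR",
    "VVVVAAAADDEEGGGG"), "")[[1]]
  k <- 0L
  for (b1 in b) for (b2 in b) for (b3 in b) {
    k <- k + 1L
    codons[k] <- paste0(b1, b2, b3)
  }
  stats::setNames(aas, codons)
})

make_orf <- function(seq, gene = "g1", ...) orf_record(gene, seq, ...)

make_panel <- function(...) {
  seqs <- list(...)
  ids <- names(seqs)
  orf_panel(Map(function(id, s) orf_record(id, s), ids, seqs))
}

# One counts row (or several, vectorised over arguments).
counts_row <- function(gene, pos, ref, a = 0L, c = 0L, g = 0L, t = 0L,
                       sample_id = "S1") {
  data.frame(sample_id = sample_id, gene = gene, pos = pos, ref = ref,
             a_count = a, c_count = c, g_count = g, t_count = t,
             stringsAsFactors = FALSE)
}

sanger_rows <- function(gene, pos, levels, amp = 1000) {
  data.frame(gene = gene, pos = pos, replicate = seq_along(levels),
             peak_c = amp * (1 - levels), peak_t = amp * levels,
             stringsAsFactors = FALSE)
}

# Noiseless, high-depth study-like configuration: sequencing error and
# Sanger noise off, depth deep enough that observed RNA-seq levels sit
# tightly around truth.
noiseless_config <- function(seed, ...) {
  sim_config(seed = seed, n_orfs = 6L, length_range = c(300L, 900L),
             sites_per_orf = 6L, decoys_per_orf = 2L,
             rnaseq_only_per_orf = 1L, borderline_per_orf = 1L,
             flank_len = 30L, mean_coverage = 8000, coverage_dispersion = 80,
             sequencing_error_rate = 0, sanger_noise_sd = 0, ...)
}

# Run the full caller chain on a simulated panel, in memory.
call_pipeline <- function(sim, threshold = 0.10, rnaseq_tolerance = 0.02) {
  counts <- merge_samples(lapply(seq_len(sim$config$n_samples), function(i)
    simulate_rnaseq_counts(sim, sprintf("S%d", i))))
  rna <- call_rnaseq(counts, sim$panel, threshold = threshold)
  sang <- call_sanger(simulate_sanger_replicates(sim), sim$panel,
                      threshold = threshold)
  reconcile(sang, rna$levels, threshold = threshold,
            rnaseq_tolerance = rnaseq_tolerance)
}
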