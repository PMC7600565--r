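# Synthetic ORF panels with planted C-to-U editing sites, plus simulators
# for the two measurement channels (RNA-seq base counts, Sanger peak
# heights). Ground truth is recorded so every downstream stage can be
# validated without external sequencing data.

#' Simulation configuration
#'
#' Defines the study-like conditions emulated by the generator: ORF panel
#' shape, planted editing levels, read coverage, sequencing error, and
#' Sanger replicate noise. Besides "real" sites (levels in `level_range`),
#' three decoy classes exercise the caller's rejection and retention rules:
#' sub-threshold sites, RNA-seq-visible sites absent from Sanger, and
#' Sanger-positive sites whose RNA-seq level sits just below threshold.
#'
#' @param seed Integer random seed; mandatory so truth files are reproducible.
#' @param n_orfs Number of ORFs in the panel.
#' @param length_range CDS length range in nt; draws are rounded to
#'   multiples of 3.
#' @param gc_fraction Target GC fraction of generated sequence.
#' @param sites_per_orf Real planted sites per ORF: a single count, or a
#'   `c(min, max)` range drawn per ORF (editing is very unevenly
#'   distributed across genes in real organellar catalogues).
#' @param level_range Editing-level range for real sites, default
#'   `c(0.10, 1.0)`.
#' @param decoys_per_orf Sub-threshold decoy sites per ORF.
#' @param decoy_level_range Level range for sub-threshold decoys, default
#'   `c(0.01, 0.09)`.
#' @param rnaseq_only_per_orf Sites visible in RNA-seq but absent from
#'   Sanger (Sanger level 0) per ORF.
#' @param borderline_per_orf Sanger-positive sites whose RNA-seq level is
#'   pinned at `borderline_rnaseq_level`, per ORF.
#' @param borderline_rnaseq_level RNA-seq level of borderline sites
#'   (default 0.09, just under the 10% calling threshold).
#' @param flank_len Flanking nucleotides written on each side of the CDS in
#'   the panel FASTA (default 100).
#' @param mean_coverage Mean per-position read depth.
#' @param coverage_dispersion Negative-binomial size parameter for depth
#'   (larger = closer to Poisson).
#' @param sequencing_error_rate Per-base sequencing error probability;
#'   errors are split uniformly over the three non-reference bases.
#' @param sanger_noise_sd Relative (multiplicative) noise SD on each Sanger
#'   peak height.
#' @param n_replicates Number of Sanger biological replicates (default 3).
#' @param n_samples Number of RNA-seq samples (default 2).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       n_orfs = 10L,
                       length_range = c(300L, 1500L),
                       gc_fraction = 0.44,
                       sites_per_orf = c(6L, 18L),
                       level_range = c(0.10, 1.0),
                       decoys_per_orf = 2L,
                       decoy_level_range = c(0.01, 0.09),
                       rnaseq_only_per_orf = 1L,
                       borderline_per_orf = 1L,
                       borderline_rnaseq_level = 0.09,
                       flank_len = 100L,
                       mean_coverage = 1000,
                       coverage_dispersion = 5,
                       sequencing_error_rate = 0.002,
                       sanger_noise_sd = 0.05,
                       n_replicates = 3L,
                       n_samples = 2L) {
  stopifnot(length(seed) == 1L, !is.na(seed))
  seed <- as.integer(seed)
  rates <- c(gc_fraction, level_range, decoy_level_range,
             borderline_rnaseq_level, sequencing_error_rate)
  if (any(rates < 0 | rates > 1))
    stop("all fractions and rates must lie in [0, 1]")
  stopifnot(mean_coverage >= 1, coverage_dispersion > 0, sanger_noise_sd >= 0,
            n_replicates >= 1L, n_samples >= 1L, flank_len >= 0L,
            length_range[1] >= 9L, length_range[2] >= length_range[1],
            length(sites_per_orf) %in% 1:2, all(sites_per_orf >= 0L),
            !is.unsorted(sites_per_orf),
            level_range[1] <= level_range[2],
            decoy_level_range[1] <= decoy_level_range[2])
  cfg <- list(seed = seed, n_orfs = as.integer(n_orfs),
              length_range = as.integer(length_range),
              gc_fraction = gc_fraction,
              sites_per_orf = as.integer(sites_per_orf),
              level_range = level_range,
              decoys_per_orf = as.integer(decoys_per_orf),
              decoy_level_range = decoy_level_range,
              rnaseq_only_per_orf = as.integer(rnaseq_only_per_orf),
              borderline_per_orf = as.integer(borderline_per_orf),
              borderline_rnaseq_level = borderline_rnaseq_level,
              flank_len = as.integer(flank_len),
              mean_coverage = mean_coverage,
              coverage_dispersion = coverage_dispersion,
              sequencing_error_rate = sequencing_error_rate,
              sanger_noise_sd = sanger_noise_sd,
              n_replicates = as.integer(n_replicates),
              n_samples = as.integer(n_samples))
  class(cfg) <- "sim_config"
  cfg
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

# Rejecting stop codons (T/A rich) tilts the realised GC above the nominal
# per-base value; solve for the per-base GC whose stop-conditioned codon
# distribution hits the requested target.
adjust_gc_for_stop_rejection <- function(target) {
  realised <- function(g) {
    pT <- (1 - g) / 2; pA <- pT; pG <- g / 2
    p_stop <- pT * pA * pA + pT * pA * pG + pT * pG * pA
    gc_in_stops <- pT * pA * pG + pT * pG * pA  # TAG and TGA carry one G
    (3 * g - gc_in_stops) / (3 * (1 - p_stop)) - target
  }
  stats::uniroot(realised, c(0.005, 0.995), tol = 1e-10)$root
}

# Sample one codon with per-base GC tilt, rejecting stop codons.
sample_codon <- function(gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  repeat {
    cod <- paste(sample(names(p), 3L, replace = TRUE, prob = p), collapse = "")
    if (!cod %in% STOP_CODONS) return(cod)
  }
}

sample_bases <- function(n, gc) {
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

#' Generate a synthetic ORF panel with planted editing sites
#'
#' Each ORF starts with ATG, ends with a stop codon, and contains no
#' in-frame stop in its body, neither before nor after applying all planted
#' edits (so consequence annotation is always well defined). Planted sites
#' are C positions; candidates whose edit would create a premature stop are
#' skipped. The panel FASTA carries `flank_len` random nucleotides on each
#' side of every CDS, so flank trimming is exercised downstream.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_panel` with elements `panel` (an
#'   [orf_panel()] of the un-flanked CDSs), `flanked` (named character vector
#'   of flanked sequences as written to FASTA), `truth` (data frame with
#'   columns `gene`, `pos`, `class`, `true_level`, `rnaseq_level`,
#'   `sanger_level`, `in_rnaseq`, `in_sanger`) and `config`.
#' @export
generate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  gc <- adjust_gc_for_stop_rejection(config$gc_fraction)
  records <- vector("list", config$n_orfs)
  flanked <- character(config$n_orfs)
  truth_rows <- list()

  for (i in seq_len(config$n_orfs)) {
    gene <- sprintf("orf%02d", i)
    codon_choices <- seq(ceiling(config$length_range[1] / 3),
                         floor(config$length_range[2] / 3))
    n_codons <- if (length(codon_choices) == 1L) codon_choices
                else sample(codon_choices, 1L)
    body <- vapply(seq_len(n_codons - 2L), function(j) sample_codon(gc),
                   character(1))
    cds <- paste0("ATG", paste(body, collapse = ""), "TAA")
    orf <- orf_record(gene, cds, flank_len = config$flank_len)

    spo <- config$sites_per_orf
    n_real <- if (length(spo) == 1L) spo
              else spo[1] + sample.int(spo[2] - spo[1] + 1L, 1L) - 1L
    n_classes <- c(real = n_real,
                   decoy_low = config$decoys_per_orf,
                   rnaseq_only = config$rnaseq_only_per_orf,
                   borderline = config$borderline_per_orf)
    n_wanted <- sum(n_classes)
    cand <- sample(c_positions(orf))
    chosen <- integer(0)
    for (p in cand) {
      if (length(chosen) >= n_wanted) break
      ci <- (p + 2L) %/% 3L
      if (ci == n_codons) next  # leave the terminal stop codon alone
      in_codon <- c(chosen[(chosen + 2L) %/% 3L == ci], p)
      cod <- strsplit(substr(cds, ci * 3L - 2L, ci * 3L), "")[[1]]
      cod[(in_codon - 1L) %% 3L + 1L] <- "T"
      if (translate_codon(paste(cod, collapse = "")) == "*") next
      chosen <- c(chosen, p)
    }
    if (length(chosen) < n_wanted)
      stop("ORF '", gene, "': requested ", n_wanted,
           " sites but only ", length(chosen),
           " editable C positions are available")
    cls <- rep(names(n_classes), n_classes)
    pos <- sort(chosen)
    cls <- sample(cls)  # class assignment independent of position order
    lev <- numeric(length(pos))
    lev[cls == "real"] <- runif(sum(cls == "real"),
                                config$level_range[1], config$level_range[2])
    lev[cls == "decoy_low"] <- runif(sum(cls == "decoy_low"),
                                     config$decoy_level_range[1],
                                     config$decoy_level_range[2])
    lev[cls == "rnaseq_only"] <- runif(sum(cls == "rnaseq_only"),
                                       config$level_range[1],
                                       config$level_range[2])
    lev[cls == "borderline"] <- runif(sum(cls == "borderline"), 0.10, 0.15)
    if (length(pos)) {
      truth_rows[[gene]] <- data.frame(
        gene = gene, pos = pos, class = cls, true_level = lev,
        rnaseq_level = ifelse(cls == "borderline",
                              config$borderline_rnaseq_level, lev),
        sanger_level = ifelse(cls == "rnaseq_only", 0, lev),
        in_rnaseq = TRUE,
        in_sanger = cls != "rnaseq_only",
        stringsAsFactors = FALSE)
    }
    records[[i]] <- orf
    flanked[i] <- paste0(sample_bases(config$flank_len, gc), cds,
                         sample_bases(config$flank_len, gc))
    names(flanked)[i] <- gene
  }

  truth <- if (length(truth_rows)) {
    out <- do.call(rbind, truth_rows)
    rownames(out) <- NULL
    out
  } else {
    data.frame(gene = character(), pos = integer(), class = character(),
               true_level = numeric(), rnaseq_level = numeric(),
               sanger_level = numeric(), in_rnaseq = logical(),
               in_sanger = logical(), stringsAsFactors = FALSE)
  }
  structure(list(panel = orf_panel(records), flanked = flanked,
                 truth = truth, config = config),
            class = "sim_panel")
}

#' Write the generated panel FASTA
#'
#' @param sim A `sim_panel` from [generate_panel()].
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_panel_fasta <- function(sim, path) {
  stopifnot(inherits(sim, "sim_panel"))
  dna <- Biostrings::DNAStringSet(sim$flanked)
  Biostrings::writeXStringSet(dna, path, width = 70L)
  invisible(path)
}

# Vectorised multinomial draws by sequential binomial thinning:
# one draw per row of `prob` (n x 4), sizes in `size`.
rmultinom_rows <- function(size, prob) {
  n <- length(size)
  out <- matrix(0L, n, 4L)
  rem <- size
  pleft <- rep(1, n)
  for (j in 1:3) {
    pj <- ifelse(pleft > 0, pmin(1, prob[, j] / pleft), 0)
    out[, j] <- stats::rbinom(n, rem, pj)
    rem <- rem - out[, j]
    pleft <- pleft - prob[, j]
  }
  out[, 4] <- rem
  out
}

#' Simulate RNA-seq per-position base counts
#'
#' Emulates the output of a per-base nucleotide counter applied to reads
#' aligned against the flanked ORF panel. At a planted site with RNA-seq
#' level `p`, the edited fraction of reads carries T; sequencing errors
#' convert any read base to one of the three other bases uniformly. Flank
#' positions are emitted too, with CDS coordinates `<= 0` or `> length`, so
#' the caller's flank trimming is exercised.
#'
#' @param sim A `sim_panel` from [generate_panel()].
#' @param sample_id Sample label written into the table.
#' @param seed Seed for this sample's draws (defaults to the config seed
#'   plus an offset derived from `sample_id`).
#' @return Data frame with columns `sample_id`, `gene`, `pos`, `ref`,
#'   `a_count`, `c_count`, `g_count`, `t_count`; one row per position with
#'   depth at least 1.
#' @export
simulate_rnaseq_counts <- function(sim, sample_id = "S1", seed = NULL) {
  stopifnot(inherits(sim, "sim_panel"))
  cfg <- sim$config
  if (is.null(seed))
    seed <- cfg$seed + 1000L + sum(utf8ToInt(sample_id)) %% 1000L
  set.seed(as.integer(seed))
  e <- cfg$sequencing_error_rate
  bases <- c("A", "C", "G", "T")
  per_gene <- lapply(names(sim$flanked), function(gene) {
    fl <- sim$flanked[[gene]]
    L <- sim$panel[[gene]]$length
    F <- cfg$flank_len
    n <- nchar(fl)
    ref <- strsplit(fl, "", fixed = TRUE)[[1]]
    pos <- seq_len(n) - F               # CDS coordinates; flanks <= 0 or > L
    depth <- pmax(1L, stats::rnbinom(n, mu = cfg$mean_coverage,
                                     size = cfg$coverage_dispersion))
    p_edit <- numeric(n)
    tr <- sim$truth[sim$truth$gene == gene & sim$truth$in_rnaseq, ]
    if (nrow(tr)) p_edit[tr$pos + F] <- tr$rnaseq_level
    # true-base probabilities: edited fraction reads T, rest read the ref base
    ptrue <- matrix(0, n, 4L, dimnames = list(NULL, bases))
    ptrue[cbind(seq_len(n), match(ref, bases))] <- 1 - p_edit
    ptrue[, "T"] <- ptrue[, "T"] + p_edit
    pobs <- ptrue * (1 - e) + (1 - ptrue) * (e / 3)
    cnt <- rmultinom_rows(depth, pobs)
    data.frame(sample_id = sample_id, gene = gene, pos = pos, ref = ref,
               a_count = cnt[, 1], c_count = cnt[, 2],
               g_count = cnt[, 3], t_count = cnt[, 4],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, per_gene)
  rownames(out) <- NULL
  out
}

#' Simulate Sanger C/T peak heights across replicates
#'
#' For every C position of every CDS and each biological replicate, emits a
#' (peak_C, peak_T) pair whose ratio `peak_T / (peak_C + peak_T)` equals the
#' site's Sanger-channel level (0 at unedited positions) perturbed by
#' multiplicative Gaussian noise with SD `sanger_noise_sd`, truncated at 0.
#' Arbitrary fluorescence units (base amplitude 1000).
#'
#' @param sim A `sim_panel` from [generate_panel()].
#' @param seed Seed for the noise draws (defaults to config seed + 2000).
#' @return Data frame with columns `gene`, `pos`, `replicate`, `peak_c`,
#'   `peak_t`.
#' @export
simulate_sanger_replicates <- function(sim, seed = NULL) {
  stopifnot(inherits(sim, "sim_panel"))
  cfg <- sim$config
  if (is.null(seed)) seed <- cfg$seed + 2000L
  set.seed(as.integer(seed))
  amp <- 1000
  per_gene <- lapply(names(sim$panel), function(gene) {
    cpos <- c_positions(sim$panel[[gene]])
    if (!length(cpos)) return(NULL)
    lev <- numeric(length(cpos))
    tr <- sim$truth[sim$truth$gene == gene & sim$truth$in_sanger, ]
    if (nrow(tr)) {
      m <- match(tr$pos, cpos)
      lev[m[!is.na(m)]] <- tr$sanger_level[!is.na(m)]
    }
    reps <- lapply(seq_len(cfg$n_replicates), function(r) {
      noise_t <- pmax(0, 1 + stats::rnorm(length(cpos), 0, cfg$sanger_noise_sd))
      noise_c <- pmax(0, 1 + stats::rnorm(length(cpos), 0, cfg$sanger_noise_sd))
      data.frame(gene = gene, pos = cpos, replicate = r,
                 peak_c = amp * (1 - lev) * noise_c,
                 peak_t = amp * lev * noise_t,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, reps)
  })
  out <- do.call(rbind, per_gene)
  rownames(out) <- NULL
  out
}
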