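test_that("generation is deterministic under a fixed seed", {
  cfg <- sim_config(seed = 21, n_orfs = 3, flank_len = 20)
  a <- generate_panel(cfg)
  b <- generate_panel(cfg)
  expect_identical(a$flanked, b$flanked)
  expect_identical(a$truth, b$truth)
  expect_identical(simulate_rnaseq_counts(a, "S1"),
                   simulate_rnaseq_counts(b, "S1"))
  expect_identical(simulate_sanger_replicates(a),
                   simulate_sanger_replicates(b))
})

test_that("a panel with no requested sites has an empty truth table", {
  cfg <- sim_config(seed = 5, n_orfs = 2, sites_per_orf = 0,
                    decoys_per_orf = 0, rnaseq_only_per_orf = 0,
                    borderline_per_orf = 0)
  sim <- generate_panel(cfg)
  expect_equal(nrow(sim$truth), 0L)
})

test_that("generated ORFs are translatable with and without their edits", {
  sim <- generate_panel(sim_config(seed = 9, n_orfs = 5, flank_len = 0))
  for (g in names(sim$panel)) {
    cds <- sim$panel[[g]]$cds_seq
    expect_equal(substr(cds, 1, 3), "ATG")
    n <- nchar(cds) / 3
    codons <- substring(cds, 3 * (1:n) - 2, 3 * (1:n))
    aas <- vapply(codons, translate_codon, character(1))
    expect_true(aas[n] == "*")
    expect_false(any(aas[-n] == "*"))
    # apply every planted edit simultaneously: still no premature stop
    ed <- strsplit(cds, "")[[1]]
    ed[sim$truth$pos[sim$truth$gene == g]] <- "T"
    ed <- paste(ed, collapse = "")
    codons_ed <- substring(ed, 3 * (1:n) - 2, 3 * (1:n))
    aas_ed <- vapply(codons_ed, translate_codon, character(1))
    expect_false(any(aas_ed[-n] == "*"))
  }
  # every planted site sits on a C of its CDS
  ref <- mapply(function(g, p) substr(sim$panel[[g]]$cds_seq, p, p),
                sim$truth$gene, sim$truth$pos)
  expect_true(all(ref == "C"))
})

test_that("observed GC tracks the target within 4 percentage points", {
  for (seed in 1:20) {
    sim <- generate_panel(sim_config(seed = seed, n_orfs = 1,
                                     length_range = c(1500, 1500),
                                     gc_fraction = 0.44, sites_per_orf = 0,
                                     decoys_per_orf = 0,
                                     rnaseq_only_per_orf = 0,
                                     borderline_per_orf = 0, flank_len = 0))
    chars <- strsplit(sim$panel[[1]]$cds_seq, "")[[1]]
    gc <- mean(chars %in% c("G", "C"))
    expect_lt(abs(gc - 0.44), 0.04)
  }
})

test_that("requesting more sites than editable Cs fails loudly", {
  cfg <- sim_config(seed = 2, n_orfs = 1, length_range = c(300, 300),
                    sites_per_orf = 200)
  expect_error(generate_panel(cfg), "editable C positions")
})

test_that("noiseless RNA-seq counts follow the planted truth exactly", {
  cfg <- sim_config(seed = 13, n_orfs = 2, sites_per_orf = 0,
                    decoys_per_orf = 0, rnaseq_only_per_orf = 0,
                    borderline_per_orf = 0, sequencing_error_rate = 0,
                    flank_len = 10)
  sim <- generate_panel(cfg)
  counts <- simulate_rnaseq_counts(sim, "S1")
  # no planted sites + no errors: T counts vanish at C positions
  ccounts <- counts[counts$ref == "C", ]
  expect_true(all(ccounts$t_count == 0))
  expect_true(all(ccounts$a_count == 0 & ccounts$g_count == 0))
  # flank coordinates are emitted (<= 0 or > CDS length)
  expect_true(any(counts$pos <= 0))

  # saturation: a planted level-1 site converts its whole depth to T
  sim2 <- generate_panel(cfg)
  g <- names(sim2$panel)[1]
  p <- c_positions(sim2$panel[[g]])[1]
  sim2$truth <- data.frame(gene = g, pos = p, class = "real",
                           true_level = 1, rnaseq_level = 1,
                           sanger_level = 1, in_rnaseq = TRUE,
                           in_sanger = TRUE, stringsAsFactors = FALSE)
  counts2 <- simulate_rnaseq_counts(sim2, "S1")
  row <- counts2[counts2$gene == g & counts2$pos == p, ]
  depth <- row$a_count + row$c_count + row$g_count + row$t_count
  expect_equal(row$t_count, depth)
})

test_that("simulated levels concentrate around truth at binomial scale", {
  # 200 sites at level 0.5, depth ~1000: SE of T/depth is ~0.016
  cfg <- sim_config(seed = 31, n_orfs = 4, length_range = c(1200, 1500),
                    sites_per_orf = 50, decoys_per_orf = 0,
                    rnaseq_only_per_orf = 0, borderline_per_orf = 0,
                    mean_coverage = 1000, coverage_dispersion = 1e6,
                    sequencing_error_rate = 0, flank_len = 0)
  sim <- generate_panel(cfg)
  sim$truth$true_level <- sim$truth$rnaseq_level <- 0.5
  counts <- simulate_rnaseq_counts(sim, "S1")
  key <- paste(counts$gene, counts$pos)
  rows <- counts[match(paste(sim$truth$gene, sim$truth$pos), key), ]
  lev <- rows$t_count / (rows$a_count + rows$c_count + rows$g_count +
                           rows$t_count)
  expect_equal(nrow(rows), 200L)
  expect_lt(mean(abs(lev - 0.5)), 0.02)
})

test_that("Sanger peaks encode the planted level with replicate noise", {
  cfg0 <- sim_config(seed = 17, n_orfs = 2, sanger_noise_sd = 0,
                     flank_len = 0)
  sim0 <- generate_panel(cfg0)
  g <- names(sim0$panel)[1]
  p <- c_positions(sim0$panel[[g]])[1]
  sim0$truth <- data.frame(gene = g, pos = p, class = "real",
                           true_level = 0.5, rnaseq_level = 0.5,
                           sanger_level = 0.5, in_rnaseq = TRUE,
                           in_sanger = TRUE, stringsAsFactors = FALSE)
  obs <- simulate_sanger_replicates(sim0)
  at <- obs[obs$gene == g & obs$pos == p, ]
  expect_equal(at$peak_c, at$peak_t)
  other <- obs[!(obs$gene == g & obs$pos == p), ]
  expect_true(all(other$peak_t == 0))

  # level 0.2 with 5% multiplicative noise: replicate-mean recovery
  cfg <- sim_config(seed = 23, n_orfs = 2, length_range = c(1200, 1500),
                    sites_per_orf = 50, decoys_per_orf = 0,
                    rnaseq_only_per_orf = 0, borderline_per_orf = 0,
                    sanger_noise_sd = 0.05, flank_len = 0)
  sim <- generate_panel(cfg)
  sim$truth$sanger_level <- 0.2
  obs2 <- simulate_sanger_replicates(sim)
  obs2 <- obs2[paste(obs2$gene, obs2$pos) %in%
                 paste(sim$truth$gene, sim$truth$pos), ]
  lev <- sanger_level(obs2)
  per_site <- tapply(lev, paste(obs2$gene, obs2$pos), mean)
  expect_equal(length(per_site), 100L)
  expect_lt(abs(mean(per_site) - 0.2), 0.02)
})
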