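test_that("RNA-seq editing level is T over total depth at C positions", {
  expect_equal(rnaseq_level(counts_row("g", 1, "C", a = 0, c = 50, t = 50)),
               0.5)
  expect_equal(rnaseq_level(counts_row("g", 1, "C", c = 100)), 0)
  expect_equal(rnaseq_level(counts_row("g", 1, "C", a = 2, c = 70, g = 1,
                                       t = 27)), 0.27)
  expect_error(rnaseq_level(counts_row("g", 1, "A", a = 100)), "C reference")
})

test_that("sample merging sums counts, so merged levels are depth-weighted", {
  t1 <- counts_row("g", 1:2, "C", c = c(90, 10), t = c(10, 90))
  doubled <- merge_samples(list(t1, t1))
  expect_equal(doubled$c_count, c(180L, 20L))
  expect_equal(doubled$t_count, c(20L, 180L))
  expect_equal(doubled$a_count + doubled$g_count, c(0L, 0L))
  one <- merge_samples(list(t1))
  expect_equal(one$c_count, t1$c_count)
  expect_equal(one$t_count, t1$t_count)

  # per-sample levels 10/100 and 40/200 merge to 50/300, not mean(0.10, 0.20)
  s1 <- counts_row("g", 5, "C", c = 90, t = 10, sample_id = "A")
  s2 <- counts_row("g", 5, "C", c = 160, t = 40, sample_id = "B")
  m <- merge_samples(list(s1, s2))
  expect_equal(rnaseq_level(m), 50 / 300)

  bad <- counts_row("g", 5, "T", t = 10, sample_id = "B")
  expect_error(merge_samples(list(s1, bad)), "conflicting reference base")
})

test_that("RNA-seq calling applies the inclusive 10% threshold after flank discard", {
  panel <- make_panel(g1 = "ATGCCCCCATAA")  # Cs at 4,5,6,7,8
  counts <- rbind(
    counts_row("g1", 4, "C", c = 95, t = 5),    # 0.05: below
    counts_row("g1", 5, "C", c = 90, t = 10),   # 0.10: called (inclusive)
    counts_row("g1", 6, "C", c = 50, t = 50),   # 0.50: called
    counts_row("g1", 0, "C", t = 100),          # flank: never called
    counts_row("g1", 13, "C", t = 100))         # flank: never called
  res <- call_rnaseq(counts, panel)
  expect_equal(res$calls$pos, c(5L, 6L))
  expect_equal(res$levels$pos, c(4L, 5L, 6L))
  expect_equal(res$levels$rnaseq_level, c(0.05, 0.10, 0.50))
  expect_equal(res$levels$rnaseq_depth, c(100L, 100L, 100L))

  expect_error(call_rnaseq(counts_row("nope", 1, "C", c = 1), panel),
               "unknown gene")
  # counts claiming C where the panel has another base are corrupt
  expect_error(call_rnaseq(counts_row("g1", 1, "C", c = 9, t = 1), panel),
               "panel has A")
})

test_that("deeply covered planted sites above threshold are always called", {
  cfg <- sim_config(seed = 41, n_orfs = 10, length_range = c(900, 1200),
                    sites_per_orf = 50, decoys_per_orf = 0,
                    rnaseq_only_per_orf = 0, borderline_per_orf = 0,
                    level_range = c(0.12, 0.95), mean_coverage = 500,
                    coverage_dispersion = 1e6,
                    sequencing_error_rate = 0.002, flank_len = 0)
  sim <- generate_panel(cfg)
  res <- call_rnaseq(simulate_rnaseq_counts(sim, "S1"), sim$panel)
  called <- paste(res$calls$gene, res$calls$pos)
  planted <- paste(sim$truth$gene, sim$truth$pos)
  expect_equal(sum(planted %in% called), 500L)
})

test_that("Sanger level is T over C plus T peak heights", {
  expect_equal(sanger_level(data.frame(peak_c = 30, peak_t = 70)), 0.7)
  expect_equal(sanger_level(data.frame(peak_c = 0, peak_t = 5)), 1.0)
  expect_equal(sanger_level(data.frame(peak_c = 9, peak_t = 1)), 0.10)
  expect_error(sanger_level(data.frame(peak_c = 0, peak_t = 0)), "positive")
})

test_that("Sanger calling needs the threshold in two of three replicates", {
  panel <- make_panel(g1 = strrep("GCT", 40))
  called <- call_sanger(sanger_rows("g1", 2, c(0.15, 0.12, 0.04)), panel)
  expect_equal(nrow(called), 1L)
  expect_equal(called$sanger_pass, 2L)
  expect_equal(called$sanger_level, mean(c(0.15, 0.12, 0.04)))

  notcalled <- call_sanger(sanger_rows("g1", 2, c(0.15, 0.08, 0.04)), panel)
  expect_equal(nrow(notcalled), 0L)

  dup <- sanger_rows("g1", 2, c(0.5, 0.5))
  dup$replicate <- c(1L, 1L)
  expect_error(call_sanger(dup, panel), "duplicated replicate")
})

test_that("noiseless Sanger simulation is recovered exactly by the caller", {
  cfg <- sim_config(seed = 47, n_orfs = 2, length_range = c(1200, 1500),
                    sites_per_orf = 50, decoys_per_orf = 0,
                    rnaseq_only_per_orf = 0, borderline_per_orf = 0,
                    sanger_noise_sd = 0, flank_len = 0)
  sim <- generate_panel(cfg)
  sim$truth$sanger_level <- 0.5
  called <- call_sanger(simulate_sanger_replicates(sim), sim$panel)
  expect_equal(nrow(called), 100L)
  expect_true(all(called$sanger_level == 0.5))
  expect_true(all(called$sanger_pass == 3L))
})

test_that("editing-extent categories partition [10%, 100%]", {
  expect_equal(categorize_level(c(0.95, 0.30, 0.10, 0.60, 0.90, 1.0,
                                  0.299, 0.599, 0.899)),
               c("EH", "M", "L", "H", "EH", "EH", "L", "M", "H"))
  expect_error(categorize_level(0.05), "0.10")
  # every accepted level lands in exactly one bin
  lv <- seq(0.10, 1, by = 0.001)
  expect_false(any(is.na(categorize_level(lv))))
})

test_that("reconciliation retains borderline Sanger sites and rejects RNA-seq-only ones", {
  sanger <- data.frame(gene = "g", pos = c(10L, 30L),
                       sanger_level = c(0.12, 0.50),
                       sanger_pass = c(2L, 3L), n_replicates = 3L,
                       stringsAsFactors = FALSE)
  rna <- data.frame(gene = "g", pos = c(10L, 20L, 30L),
                    rnaseq_level = c(0.09, 0.11, 0.50),
                    rnaseq_depth = c(200L, 300L, 400L),
                    stringsAsFactors = FALSE)
  out <- reconcile(sanger, rna)
  expect_equal(out$status[out$pos == 10], "accepted")       # 9% vs 10% rule
  expect_equal(out$status[out$pos == 20], "rejected_rnaseq_only")
  expect_equal(out$status[out$pos == 30], "accepted")
  expect_equal(out$evidence[out$pos == 30], "sanger,rnaseq")
  expect_equal(out$category[out$pos == 30], "M")
  expect_equal(out$site_id, c("g-10", "g-20", "g-30"))

  # a Sanger site with no RNA-seq coverage stays accepted
  out2 <- reconcile(sanger, rna[rna$pos != 10, ])
  expect_equal(out2$status[out2$pos == 10], "accepted")
  expect_equal(out2$evidence[out2$pos == 10], "sanger")

  # a Sanger site well below the tolerance is dropped
  rna3 <- rna; rna3$rnaseq_level[1] <- 0.03
  out3 <- reconcile(sanger, rna3)
  expect_equal(out3$status[out3$pos == 10], "rejected_below_threshold")
})

test_that("levels are invariant under uniform scaling of counts and peaks", {
  row <- counts_row("g", 1, "C", a = 2, c = 70, g = 1, t = 27)
  row10 <- row
  row10[c("a_count", "c_count", "g_count", "t_count")] <-
    row[c("a_count", "c_count", "g_count", "t_count")] * 10L
  expect_equal(rnaseq_level(row), rnaseq_level(row10))
  obs <- data.frame(peak_c = 30, peak_t = 70)
  expect_equal(sanger_level(obs),
               sanger_level(data.frame(peak_c = 300, peak_t = 700)))
})

test_that("raising the threshold never yields more accepted sites", {
  sim <- generate_panel(sim_config(seed = 53, n_orfs = 4, flank_len = 10))
  counts <- merge_samples(list(simulate_rnaseq_counts(sim, "S1"),
                               simulate_rnaseq_counts(sim, "S2")))
  obs <- simulate_sanger_replicates(sim)
  n_accepted <- vapply(c(0.10, 0.20, 0.30, 0.50), function(th) {
    rna <- call_rnaseq(counts, sim$panel, threshold = th)
    sang <- call_sanger(obs, sim$panel, threshold = th)
    sum(reconcile(sang, rna$levels, threshold = th)$status == "accepted")
  }, numeric(1))
  expect_true(all(diff(n_accepted) <= 0))
})

test_that("noiseless end-to-end calls match the planted truth oracle", {
  for (seed in c(61, 62)) {
    sim <- generate_panel(noiseless_config(seed))
    counts <- merge_samples(lapply(1:2, function(i)
      simulate_rnaseq_counts(sim, sprintf("S%d", i))))
    rna <- call_rnaseq(counts, sim$panel)
    sang <- call_sanger(simulate_sanger_replicates(sim), sim$panel)
    out <- reconcile(sang, rna$levels)
    accepted <- paste(accepted_sites(out)$gene, accepted_sites(out)$pos)

    # oracle: Sanger-visible planted sites at level >= 0.10 whose observed
    # RNA-seq level (if covered) is at least threshold - tolerance
    tr <- sim$truth[sim$truth$in_sanger & sim$truth$sanger_level >= 0.10, ]
    key <- paste(tr$gene, tr$pos)
    m <- match(key, paste(rna$levels$gene, rna$levels$pos))
    obs_rna <- rna$levels$rnaseq_level[m]
    oracle <- key[is.na(obs_rna) | obs_rna >= 0.08]
    expect_setequal(accepted, oracle)

    # RNA-seq-only planted sites surface as rejected candidates
    ro <- sim$truth[!sim$truth$in_sanger & sim$truth$rnaseq_level >= 0.10, ]
    rejected <- out[out$status == "rejected_rnaseq_only", ]
    expect_true(all(paste(ro$gene, ro$pos) %in%
                      paste(rejected$gene, rejected$pos)))
  }
})
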