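#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study — an ORF panel with planted C-to-U
# editing sites, two RNA-seq count samples, and three Sanger replicates.
# Everything downstream works from the files written here.

library(mitoedit)

out <- "results/sim"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

cfg <- sim_config(seed = 2020)  # defaults: 10 ORFs, 12 real sites each,
                                # decoys in all three discordance classes,
                                # 100-nt flanks, ~1000x coverage, 0.2% error
sim <- generate_panel(cfg)

write_panel_fasta(sim, file.path(out, "panel.fasta"))
write_truth_tsv(sim$truth, file.path(out, "truth.tsv"))
write_counts_tsv(simulate_rnaseq_counts(sim, "S1"),
                 file.path(out, "counts_S1.tsv"))
write_counts_tsv(simulate_rnaseq_counts(sim, "S2"),
                 file.path(out, "counts_S2.tsv"))
write_sanger_tsv(simulate_sanger_replicates(sim),
                 file.path(out, "sanger.tsv"))

cat(sprintf("panel: %d ORFs, %d nt CDS total\n", length(sim$panel),
            sum(vapply(sim$panel, `[[`, integer(1), "length"))))
cat("planted sites by class:\n")
print(table(sim$truth$class))
cat(sprintf("written to %s/\n", out))
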