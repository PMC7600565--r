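#!/usr/bin/env Rscript
# Stage 4: descriptive statistics of the annotated catalogue — codon
# position distribution, codon bookkeeping, effect and codon tallies,
# per-gene editing density, and the Pearson correlations of edited Cs
# against total Cs and gene length.

library(mitoedit)

panel <- load_orf_panel("results/sim/panel.fasta", flank_len = 100)
calls <- read_calls_tsv("results/run/calls.tsv")
ann <- annotate_sites(accepted_sites(calls), panel)

s <- summarize_sites(ann, panel)
writeLines(render_summary(s), "results/run/summary.txt")
write.table(s$per_gene, "results/run/per_gene.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

print(s)
cat("\nper-gene editing density (percent of Cs edited):\n")
pg <- s$per_gene[order(-s$per_gene$pct_C_edited), ]
print(head(pg, 5), row.names = FALSE)
cat("\nreport written to results/run/summary.txt\n")
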