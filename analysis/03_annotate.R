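#!/usr/bin/env Rscript
# Stage 3: codon-consequence annotation of the accepted sites. Sites that
# share a codon are annotated together (the edited codon applies both
# edits), and each codon change is classified as synonymous,
# nonsynonymous, stop gain or start gain, with its hydropathy transition.

library(mitoedit)

panel <- load_orf_panel("results/sim/panel.fasta", flank_len = 100)
calls <- read_calls_tsv("results/run/calls.tsv")
acc <- accepted_sites(calls)

ann <- annotate_sites(acc, panel)
write.table(ann$sites, "results/run/sites_annotated.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(ann$consequences, "results/run/consequences.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
export_sites_gff3(ann$sites, "results/run/sites.gff3")

cat(sprintf("%d accepted sites -> %d edited codons\n", nrow(ann$sites),
            nrow(ann$consequences)))
cat("\neffects:\n")
print(table(ann$consequences$effect))
cat("\nmost frequent amino-acid changes:\n")
tab <- sort(table(ann$consequences$aa_change[ann$consequences$nonsynonymous]),
            decreasing = TRUE)
print(head(tab, 5))
cat("\nGFF3 export: results/run/sites.gff3\n")
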