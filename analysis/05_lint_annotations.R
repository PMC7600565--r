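#!/usr/bin/env Rscript
# Stage 5: annotation linting. Database records of editing sites are
# sometimes off by one nucleotide; for each claimed (position, amino-acid
# change) this checks whether a C->T edit at the claimed position explains
# the change, and otherwise searches the neighbouring positions and the
# other Cs of the same codon for the unique position that does.

library(mitoedit)

panel <- load_orf_panel("results/sim/panel.fasta", flank_len = 100)
ann <- read_sites_gff3("results/run/sites.gff3")
nonsyn <- ann[ann$effect == "nonsynonymous", ]

aa3 <- c(A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln",
         E = "Glu", G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys",
         M = "Met", F = "Phe", P = "Pro", S = "Ser", T = "Thr", W = "Trp",
         Y = "Tyr", V = "Val")

# claims: the true annotations, plus copies shifted by one nucleotide to
# emulate the off-by-one database errors the linter is built to catch
set.seed(2020)
take <- nonsyn[sample(nrow(nonsyn), min(10L, nrow(nonsyn))), ]
claims <- data.frame(gene = take$gene, pos = take$pos,
                     claimed_ref_aa = unname(aa3[take$ref_aa]),
                     claimed_edited_aa = unname(aa3[take$edited_aa]),
                     stringsAsFactors = FALSE)
shifted <- claims[1:min(4L, nrow(claims)), ]
shifted$pos <- shifted$pos - 1L
claims <- rbind(claims, shifted)

report <- lint_annotations(claims, panel)
write.table(report, "results/run/lint_report.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
cat("lint outcomes:\n")
print(table(report$status))
cat("\ncorrected claims:\n")
print(report[report$status != "confirmed", ], row.names = FALSE)
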