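# mitoedit

Detection and annotation of C-to-U RNA editing sites in plant
mitochondria-encoded open reading frames (ORFs).

Plant mitochondrial transcripts are extensively edited: specific cytidines
are converted to uridines, usually at the first or second codon position,
changing the encoded amino acid. A site catalogue is built by comparing cDNA
against the genomic reference through two complementary measurements, and
this package implements the complete analysis between those measurements and
an annotated catalogue — for anyone building or auditing an organellar
editing catalogue without wanting to re-derive the bookkeeping every time:

* **RNA-seq channel** — per-position base counts from aligned reads; at each
  C-containing reference position the editing level is
  `T / (A + C + G + T)`, and a candidate needs level ≥ 10%.
* **Sanger channel** — C/T peak heights from chromatograms of three
  biological replicates; the level is `T / (C + T)`, and a site needs
  level ≥ 10% in at least 2 of 3 replicates.
* **Reconciliation** — Sanger evidence is primary: a Sanger-confirmed site
  whose RNA-seq level falls marginally below threshold (within a 2-point
  tolerance, the "around 9%" case) is retained; RNA-seq-only candidates are
  reported but rejected.
* **Consequences** — sites are mapped to codons
  (`codon_index = ceiling(p/3)`), co-located edits are applied together, and
  each edited codon is classified as synonymous, nonsynonymous, stop gain
  (CAA→UAA and friends) or start gain (ACG→AUG), with its hydropathy
  transition.
* **Summary** — codon-position distribution, codon bookkeeping
  (`sites = singles + 2 × doubles`), amino-acid-change and edited-codon
  tallies, per-gene percent-of-Cs-edited, and Pearson correlations of edited
  Cs against total Cs and gene length.

A seeded synthetic-data generator plants sites with known levels — including
the discordant decoy classes the reconciler must handle — and simulates both
channels, so the whole pipeline is validated against ground truth. A linter
(`lint_annotations()`) re-derives the codon arithmetic of claimed sites and
corrects the off-by-one annotation errors that creep into databases.

Read alignment itself is out of scope: the RNA-seq contract is the
per-position count table a base counter emits.

## Worked example

```r
library(mitoedit)

cfg <- sim_config(seed = 7, n_orfs = 4, length_range = c(300, 900),
                  flank_len = 50)
sim <- generate_panel(cfg)

counts <- merge_samples(list(simulate_rnaseq_counts(sim, "S1"),
                             simulate_rnaseq_counts(sim, "S2")))
rna   <- call_rnaseq(counts, sim$panel)
sang  <- call_sanger(simulate_sanger_replicates(sim), sim$panel)
calls <- reconcile(sang, rna$levels)
table(calls$status)
#>             accepted rejected_rnaseq_only
#>                   64                    4

ann <- annotate_sites(accepted_sites(calls), sim$panel)
head(ann$consequences[, c("gene", "codon_index", "ref_codon",
                          "edited_codon", "aa_change", "effect")], 4)
#>    gene codon_index ref_codon edited_codon  aa_change        effect
#> 1 orf01           2       ACT          ATT Thr-to-Ile nonsynonymous
#> 2 orf01           3       CAT          TAT His-to-Tyr nonsynonymous
#> 3 orf01           8       CCC          CCT        syn    synonymous
#> 4 orf01          13       CCT          CTT Pro-to-Leu nonsynonymous

summarize_sites(ann, sim$panel)
#> C-to-U editing sites: 64 (in 4 ORFs)
#>
#> Codon-position distribution:
#>   position 1: 24 (37.50%)
#>   position 2: 26 (40.63%)
#>   position 3: 14 (21.88%)
#>
#> Edited codons: 61 (58 with one site, 3 with two sites)
#> Effects: 16 synonymous, 45 nonsynonymous codon alterations
#> Nonsynonymous changes producing a hydrophobic residue: 66.67%
#> Top amino-acid changes: Pro-to-Ser (9), Pro-to-Leu (7), Thr-to-Ile (6)
#> Top edited codons: CAC (5), CCC (5), CCG (5), together 24.59% of edited codons
#> Start gains: 1; stop gains: 0
#> Pearson edited Cs vs total Cs: r = -0.732, p < 0.269; vs gene length: r = -0.678, p < 0.323
```

The 64 accepted sites are the planted sites the two channels agree on; the
4 rejected candidates are the planted RNA-seq-only decoys. A site's
`site_id` is `gene-position` in the 1-based CDS frame (so `atp1-1292` is
codon 431, position 2), annotated sites export to GFF3
(`export_sites_gff3()`), and `run_pipeline()` chains the same stages from
files on disk, logging every threshold applied.

## Analysis workflow

The `analysis/` scripts run the stages as a narrative, writing under
`results/`:

```sh
Rscript analysis/01_simulate.R          # panel FASTA, truth, counts, peaks
Rscript analysis/02_call_sites.R        # dual-channel calls + reconciliation
Rscript analysis/03_annotate.R          # codon consequences + GFF3
Rscript analysis/04_summarize.R         # catalogue statistics
Rscript analysis/05_lint_annotations.R  # off-by-one annotation linting
```

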