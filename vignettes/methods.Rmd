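---
title: "Detecting and annotating C-to-U RNA editing in plant mitochondrial ORFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and annotating C-to-U RNA editing in plant mitochondrial ORFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitoedit)
```

## The problem

Plant mitochondrial transcripts undergo extensive cytidine-to-uridine (C-to-U)
RNA editing, mostly inside protein-coding regions. On the sense strand an
editing event appears as a reference C observed as T in cDNA, so a site is
characterised by its 1-based position within the CDS and by its *editing
level*: the fraction of molecules edited at that position. Catalogues of
editing sites are usually built from two complementary measurements:

* **Sanger chromatograms** of RT-PCR products, where a partially edited
  position shows a double C/T peak; the level is estimated as
  `T / (C + T)` from the two peak heights.
* **RNA-seq base counts**, where aligned reads are piled up per reference
  position; at each C-containing position the level is
  `T / (A + C + G + T)`.

This package implements the full chain from those two inputs to an annotated
catalogue: dual-channel site calling, cross-method reconciliation, codon
consequence annotation, and catalogue statistics. Because the real sequencing
data behind such studies live in external archives, the package also ships a
synthetic-data generator that plants sites with known levels and simulates
both channels, so the entire pipeline can be validated against ground truth.

## Calling rules and their parameters

**Threshold (default 0.10, inclusive).** A level of 10% is the conventional
floor below which apparent editing is difficult to distinguish from
sequencing error and tends not to be conserved across species. Published
phrasings alternate between "above 10%" and "equal to or greater than 10%";
we adopt a single inclusive rule for both channels, exposed as the
`threshold` argument throughout.

**Sanger replication rule (default 2 of 3).** A position is called from
chromatograms when at least `min_pass_replicates` biological replicates show
a level at or above threshold; isolated low-level double peaks are treated
as artefacts of sequencing quality. The level reported per site is the mean
over all replicates with data (a representative-replicate convention would
also be defensible; the mean is less sensitive to a single bad trace).

**Reconciliation tolerance (default 0.02).** Sanger evidence is treated as
primary. A Sanger-confirmed site whose RNA-seq level falls marginally short
of threshold — the classic "around 9% against a 10% cutoff" situation — is
retained when its RNA-seq level is at least `threshold - rnaseq_tolerance`,
or when it has no RNA-seq coverage at all. The source studies state the
outcome of such cases, not a rule; the tolerance formalises the decision and
is echoed into the run log and configuration echo so it is auditable.
Conversely, RNA-seq-only candidates (mostly third-position, synonymous,
just-over-threshold) are *not* accepted; they are emitted with status
`rejected_rnaseq_only` rather than dropped silently.

**Depth filter (default `min_depth = 1`).** Real catalogues report coverage
down to below a hundred reads without applying an explicit cutoff, so the
default imposes none beyond having data; the argument exists for stricter
reanalyses.

**Editing-extent categories.** Accepted sites are binned as
L = \[10%, 30%), M = \[30%, 60%), H = \[60%, 90%), EH = \[90%, 100%].
Published "60–90%" style ranges leave the boundary membership ambiguous; we
use half-open-on-the-left bins with the top bin closed, and expose the inner
boundaries. A borderline accepted site whose replicate-mean level dips just
under 10% is assigned to L.

**Merging RNA-seq samples.** Samples are merged by elementwise summation of
base counts — the in-silico equivalent of merging alignment files — so the
merged level is depth-weighted, not a mean of per-sample levels.

## Codon consequences

Positions map to codons by `codon_index = ceiling(p / 3)`,
`codon_position = ((p - 1) mod 3) + 1`. Two sites in one codon are annotated
together: the edited codon applies all of the codon's C→T changes
simultaneously, and contributes a single codon-alteration record (so a
catalogue's site count equals `singles + 2 × doubles` over its codons).
Translation uses the standard genetic code, which plant mitochondria follow.

The single `effect` field gives precedence to start gain (ACG→ATG) and stop
gain over the synonymous/nonsynonymous dichotomy; a separate `nonsynonymous`
boolean records whether the amino acid changed, so syn/nonsyn tallies can
count stop gains as nonsynonymous. By the structure of the standard code,
every third-position C→T edit is synonymous, single-edit stop gains arise
only from CAA, CAG and CGA, and the only start gain is ACG→ATG; the test
suite verifies all of this by exhaustive enumeration of the 64 codons.

Hydropathy transitions use the hydrophobic set {A, C, F, I, L, M, V}
(positive Kyte–Doolittle hydropathy; Pro, Ser and Gly count as hydrophilic).
Published analyses of editing-induced hydrophobicity never state their set
explicitly but classify Ser→Leu, Pro→Leu and Ser→Phe as
hydrophilic→hydrophobic, which this choice reproduces. The set is a
parameter, and the choice is recorded in the pipeline's configuration echo.

Trailing partial codons (a CDS length not divisible by 3) raise an error in
codon operations rather than being silently truncated: printed site
identifiers use the CDS frame, and guessing a frame for a ragged tail would
corrupt every downstream tally.

## The synthetic study

`generate_panel()` builds ORFs that start with ATG, end with a stop codon,
and contain no in-frame stop either before or after applying all planted
edits, so consequence annotation is always well defined (candidate sites
whose edit would create a premature stop are skipped during planting).
Interior codons are drawn with a per-base GC tilt; because rejecting the
T/A-rich stop codons would bias the realised GC upward by about 1.4
percentage points, the per-base GC is first adjusted by solving for the
value whose stop-conditioned codon distribution hits the requested target
(default 0.44, typical of plant mitochondrial coding sequence).

Default conditions emulate a leaf-tissue organellar study: 10 ORFs of
300–1500 nt carrying 100-nt flanks (read coverage is unreliable at CDS ends,
so references are extended and the flanks discarded before calling — the
simulator emits flank rows with coordinates outside `1..length` precisely so
that discard step is exercised); per-ORF real site counts drawn from 6–18
with levels uniform on \[0.10, 1.0]; negative-binomial read depth around
1000× (real per-site coverages span roughly 74–9500×); per-base sequencing
error 0.002 split uniformly over the three non-reference bases; two RNA-seq
samples; three Sanger replicates with 5% multiplicative peak noise.

Three decoy classes are planted alongside the real sites because the
reconciler must be tested in both discordance directions: sub-threshold
sites (levels 0.01–0.09), RNA-seq-visible sites absent from Sanger (which
must end as `rejected_rnaseq_only`), and Sanger-positive sites whose RNA-seq
level is pinned at 0.09 (which must be retained by the tolerance rule).

RNA-seq counts are generated directly at the count-table contract — at a
site of level *p* the T count is binomial in the edited fraction, with the
error model layered on top — rather than via read simulation and alignment.
Alignment, duplicate filtering and the like are external tooling concerns;
generating counts keeps the tested surface exactly the computation this
package owns. Consequently, passing tests say nothing about alignment
artefacts (mis-mapping, NUMT contamination, soft-clipping, strand bias) in
real data, and quality scores, tissue-specific editing and U-to-C events are
out of scope by construction.

## Numerical and validation choices

* Display percentages are rounded half-up to two decimals, matching the
  catalogue style (e.g. 32.51%); machine outputs keep full precision.
* Pearson correlations (edited Cs vs total Cs, edited Cs vs gene length)
  are computed from the product-moment formula with the two-sided p-value
  from the t transform on `n - 2` degrees of freedom; the implementation is
  cross-checked against `stats::cor.test` in the tests. p-values are
  reported as computed; the text report renders them in the conventional
  "p < x" style.
* The exact-recovery validation runs the whole pipeline on noiseless
  simulations (error rate 0, peak noise 0) at ~8000× coverage — deep enough
  that observed RNA-seq levels sit within a fraction of a percentage point
  of truth — and requires the accepted set to equal the planted truth
  exactly. Statistical recovery is validated at 500× with 0.2% error on
  5000 planted sites (10 seeds × 500 sites, levels 0.12–0.95), requiring
  ≥99% recall and level estimates within four binomial standard errors for
  ≥99% of sites. These sizes run in seconds and give binomial tail bounds
  far below the asserted rates.
* All generator draws are seeded; a given configuration reproduces its
  FASTA, truth table, counts and peak tables byte-for-byte.

## Annotation linting

Database annotations of editing sites are occasionally shifted by one
nucleotide (the recorded amino-acid change then disagrees with the codon
arithmetic at the recorded position). `lint_annotations()` re-derives the
consequence of a C→T edit at each claimed position; when it does not match
the claimed change, it searches the two neighbouring positions and the other
Cs of the same codon for the unique position that does, and reports the
correction — mirroring how such errors are resolved by inspection of the
chromatogram. Claims nothing nearby can explain are flagged
`unexplainable` rather than guessed at.

## Known limitations

* Only C-to-U events on sense-strand CDS are modelled; U-to-C editing,
  introns, UTRs, tRNA/rRNA and reverse-strand handling are out of scope.
* The Sanger noise model is multiplicative Gaussian on peak heights; real
  chromatogram artefacts (dye blobs, mobility shifts, primer proximity) are
  not emulated, so replicate-rule behaviour on pathological traces is
  untested.
* The reconciliation tolerance is a formalisation of published practice,
  not a published rule; runs record it explicitly so downstream users can
  tighten it to 0 for a strict-threshold reanalysis.
* Pseudogenes are annotated in their nominal reading frame and flagged;
  their "consequences" are hypothetical by nature.
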