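---
title: "Detecting mega-NUMTs that mimic biparental mtDNA inheritance: methods and design"
author: "meganumt"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting mega-NUMTs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(meganumt)
```

## The two competing hypotheses

A trio in which father and child share a set of sub-homoplasmic mtDNA
variants absent from the mother admits two explanations: genuine
paternal transmission of mitochondria, or a large nuclear insertion of
mtDNA-derived sequence (a NUMT) on one of the father's autosomes.
Sequencing reads originating from the insertion align to the
mitochondrial reference and are indistinguishable, site by site, from
heteroplasmy. The two hypotheses separate on three observable axes,
each implemented as a pipeline stage:

1. **Homoplasmy bookkeeping.** Mitochondria travel as a genome: if the
   father's mtDNA reached the child, *all* of his homoplasmic variants
   (allele fraction > 95%) must be detectable in the child. A NUMT
   carries only the fragments that were inserted, so paternal
   homoplasmies outside the insertion are absent from the child.
   `classify_trio()` excludes a trio when three or more paternal
   homoplasmies are missing (child AF ≤ 5%).
2. **Read evidence.** An insertion leaves discordant read pairs (one
   end nuclear, mate on the mt contig) and split reads crossing its
   junctions. A *concatemer* of repeated fragments additionally
   produces junctions between two mtDNA locations (mt–mt junctions)
   that no circular mitochondrial genome can generate at high support.
3. **Allele-fraction arithmetic.** An autosomal insertion of `Nmt`
   fragment copies is sequenced at `DPnu/2` per copy, diluted by the
   true mtDNA depth `DPmt`:
   `HTF = (DPnu/2 · Nmt) / (DPnu/2 · Nmt + DPmt)`. This predicts a
   *uniform* fraction across all insertion-derived alleles, bounded
   well below homoplasmy for realistic depths, and *decreasing* in
   mtDNA content — all three of which the pipeline checks.

## Thresholds and their readings

All thresholds follow the strict reading of their verbal definitions
and are exposed as arguments with these defaults:

| parameter | default | comparison | stage |
|---|---|---|---|
| AF floor | 1% | strictly above | variant filter |
| variant depth | 200× | at least | variant filter |
| minor-allele strand support | 2 reads | at least, each strand | variant filter |
| homoplasmy | 95% | strictly above | classification |
| screening AF | 5% | strictly above | trio screen |
| trio mean mtDNA depth | 500× | below fails | QC |
| missing homoplasmies | 3 | at least | exclusion |
| discordant pairs per cluster | 5 | at least | NUMT detection |
| clustering gap | 500 bp | at most | NUMT detection |
| split-read window | 1000 bp | within | NUMT detection |
| mapping quality | 20 | below discarded | NUMT detection |
| junction tolerance | ±5 bp | within | junction calling |
| mt–mt split support for mega evidence | 2 | strictly above | grouping |
| father heteroplasmy count | 12 | strictly above | father screen |
| NUMT cohort frequency | 0.1% | strictly below | father screen |
| mtDNA breakpoint span | 500 bp | strictly above | father screen |

Two readings deserve comment. The strand rule targets the *minor*
allele: when the alternate allele is the major one (AF > 50%) the rule
is applied to the reference-supporting strand counts, which the input
therefore carries (`ref_fwd`/`ref_rev`); without them the rule falls
back to alt counts with a warning. A site with zero minor-allele reads
(a pure homoplasmy) has no minor allele to test and passes. Second,
"not detected in the mother" means absent from the mother's *filtered*
callset — the callset is the unit of detection and filtering precedes
the trio search — whereas detection in the child uses the 5% screening
threshold.

The father screen's frequency ceiling is a *rarity* rule: at study
scale (tens of thousands of individuals) 0.1% admits dozens of
carriers. A desk-scale cohort of 1,500 individuals cannot express the
same rule — two carriers already exceed 0.1% — so analyses at reduced
scale should pass the carriers-per-individuals equivalent (e.g.
`numt_freq_max = 0.005` admits 7 of 1,500, as the package's own tests
do). The data-driven alternative to the fixed count of 12
heteroplasmies is the Tukey fence `Q3 + 1.5·IQR`
(`iqr_outlier_threshold()`, type-7 linear-interpolation quantiles).

## Split-read realignment

BLAT-style realignment is replaced by a deterministic two-piece scan
(`realign_split()`): every breakpoint position partitions the read into
a prefix and suffix, and each piece is fitted at *every* placement on
every target strand — the nuclear window on both strands, and the
mitochondrial reference on both strands of a circularly extended copy
(the first 149 bases appended), so junctions across the 16569/1 origin
are found. The best split maximises total matching bases, equivalent to
a match +1 / mismatch −1 alignment score.

Pieces are scored **without gaps**. At 150 bp scale, junction-spanning
reads differ from their source references by substitutions; an
affine-gap model adds parameters and run time without changing any call
on such reads (a gap costs more than the mismatch it could absorb), and
the gapless formulation makes the exhaustive scan exactly computable —
which in turn lets an independent dense oracle verify the
implementation read for read (the package's oracle-equivalence tests).
Indels are likewise outside the simulator's scope. This is the one
place the package intentionally trades alignment generality for
exactness and reproducibility; reads from indel-rich junctions would
need an external realigner.

Numerical conventions: a read whose full length fits one target at the
identity floor (default 0.9) is never split; both pieces must be at
least 20 bases at that identity; score ties resolve to the leftmost
breakpoint and the first target in construction order, so
micro-homologous junction bases shift the reported breakpoint left by
up to a few bases — junction clustering at ±5 bp absorbs this, and
tests compare breakpoints at that tolerance. The per-read scan is the
package's single compiled kernel (Rcpp).

Junction identity is canonicalised before clustering: reading the
opposite strand of one junction molecule swaps the sides and flips both
strands, so junctions are stored nuclear-side-first (mt–mt: smaller
coordinate first) with strands flipped accordingly; support from both
read orientations therefore accumulates on one record.

## Copy number and the haplotype-fraction grid

`DPadjnumt` — the nuclear depth "flanking the NUMT" — is computed as
mean per-base depth over 1 kb on each side of the insertion point,
excluding ±200 bp around the junction where clipped reads distort
coverage. The per-NUMT summary of `Nmt = Altmt/(DPadjnumt/2)` is the
*median* over informative variants, which resists junction-proximal
outliers. The `htf_grid()` confidence band uses exact binomial
quantiles on `n = round(DPnu/2·Nmt + DPmt)` trials rather than a normal
approximation, because at one copy the insertion-derived read counts
are small.

The anti-correlation between apparent heteroplasmy and mtDNA content is
reported as the Pearson product-moment coefficient *r* with a
two-sided test (`af_depth_correlation()`); a signed "R²" is not a
defined quantity, and the implementation says so in its output naming.

## What the synthetic cohorts emulate

`simulate_cohort()` generates the conditions the analysis targets:
150 bp reads; nuclear depth uniform on 30–99×; true mtDNA depth uniform
on 200–4500×; exact maternal transmission (the child's true haplotype
*is* the mother's); father–mother haplotype divergence in a
same-haplogroup regime (1–5 differing sites) and a different-haplogroup
regime (20–40); planted autosomal mega-NUMTs of 2–20 concatenated
copies of one or two fragments (each spanning ≥ 1 kb of mtDNA, outer
breakpoints > 600 bp apart), transmitted with probability 1/2, with a
recurrent NUMT shared between the first two carrier families; binomial
sampling of allele fractions with 50/50 strand splitting and Poisson
depth; and Poisson-distributed discordant (rate `dp_nu/3` per junction
side) and split reads (rate `dp_nu/5` per junction occurrence, capped
at 30 per junction type), with read sequences constructed literally
from the two reference sides. Background heteroplasmies (Poisson mean 2
per sample, AF 1.5–4%) provide a realistic floor for the heteroplasmy-
count statistics.

The NUMT source haplotype is an independent mitochondrial lineage plus
14–25 divergent sites inside the inserted fragments; what any carrier
observes is exactly the set of differences between that source and
their own mtDNA, which is the mechanism that turns a nuclear insertion
into an apparent second haplotype. Three generator choices keep planted
labels deterministic ground truth rather than noisy outcomes, chosen
once as study conditions: carrier depths are drawn so the expected
haplotype fraction lies in 0.08–0.35 (inside the observed 5–25% band,
with ≥ 3σ separation from the 5% screening threshold at the depths
involved); members of carrier families draw mtDNA depth ≥ 600× (clear
of the 500× QC floor); and transmitting carriers constrain
father-private homoplasmies to ≤ 1 outside the fragments in the
same-haplogroup regime (candidate-intent) or ≥ 5 placed outside them in
the different-haplogroup regime (excluded-intent). Expected labels are
computed from noise-free allele fractions by an explicit set-arithmetic
classifier inside the generator, independent of the screening code it
validates.

The generator does **not** emulate: sequencing error beyond binomial
allele sampling, indels, strand bias, repeat or segmental-duplication
context at insertion sites (where real NUMTs are enriched and
mappability suffers), chimeric artefacts, or contamination. Passing
tests therefore demonstrate that the *logic* of the screen is correct
and robust to counting noise at realistic depths — not that the
detector's sensitivity transfers to repeat-embedded insertions in real
genomes, where mapping-quality filters will cost evidence.

## Problem sizes

The test suite runs the end-to-end screen on cohorts of 10–25 trios and
a 500-trio cohort with five planted carrier fathers (three
transmitting) for the full-recovery check; copy-number recovery uses
500 replicates per (K, depth) cell over K ∈ {2, 5, 10, 20} and mtDNA
depth ∈ {500, 1500, 4000}; oracle equivalence uses 1,000 constructed
150-mers over compact references (0.8–1 kb nuclear, 1 kb circular mt
surrogate) plus in-suite checks against the full-length mt reference.
`scripts/acceptance.R` re-runs the same computations from scratch with
a caller-supplied seed. Synthetic nuclear contigs are 100 kb — large
enough for flank-depth estimation and well-separated multiple
insertions, small enough to keep the exhaustive realignment scan fast.

## Known limitations

* The gapless alignment model (above) is deliberate; junctions with
  indels or with pieces shorter than 20 bp are not called.
* The linear mtDNA breakpoint span (`mt_span()`) matches how breakpoint
  pairs are printed; an origin-spanning NUMT's span is not computed on
  the circle.
* The father screen's frequency rule needs rescaling below a few
  thousand individuals, as discussed.
* Pedigrees are trusted (no relatedness verification) and haplogroups
  are never assigned; the divergence regimes stand in for haplogroup
  structure.
* `group_numts()` refuses to mix reference builds; coordinate liftover
  is out of scope.
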