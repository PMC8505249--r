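---
title: "Methods: cell-type-specific promoter methylation analysis with celldmr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cell-type-specific promoter methylation analysis with celldmr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Scope and model of the data

`celldmr` implements a promoter-wide DNA methylation analysis for
enrichment-array data from sorted brain nuclei: neuronal (NeuN+) and
nonneuronal (NeuN-) fractions from patients and controls, assayed on a
promoter tiling array (each promoter covered from 7.5 kb upstream to
2.5 kb downstream of the TSS by 25-mer probes at 35 bp spacing), with
methylated DNA captured by methyl-CpG-binding-domain (MBD) enrichment and
every experiment performed in duplicate. The probe-level quantity is an
enrichment score of a sample against a whole-genome-amplified (fully
unmethylated) reference on a log-ratio-like scale.

All genomic coordinates at the user surface are 0-based, half-open (BED
convention); 1-based arithmetic exists only inside the
GenomicRanges/IRanges calls that do the interval work.

## The synthetic study generator

Because the analysis is exercised end to end without external data, the
package generates a toy study with known truth. The generator emulates the
*design* of the emulated cohort, not its measurements:

* **Geometry.** Promoter tiles are exactly TSS-7500..TSS+2500 (mirrored on
  the minus strand; the strand convention is a package choice, the assay
  does not define one), placed without overlap on configurable
  chromosomes; probes of 25 bp tile each promoter at 35 bp spacing with
  `floor(width / spacing)` probes per tile (the trailing remainder is
  uncovered — the convention is asserted in the tests).
* **Cohort.** Default 34 patients and 35 controls, two cell fractions per
  subject, two technical replicate experiments per sample that share the
  biological truth and the per-(sample, cell type) random intercept but
  not the probe noise. Covariates (age, PMI, pH, onset, duration, lifetime
  antipsychotics) follow documented arbitrary distributions — fixtures,
  not estimates of any cohort — with illness covariates missing for
  controls. An optional knob correlates one covariate with global signal
  for confounder-analysis fixtures.
* **Signal model.** Additive Gaussian on the enrichment scale:
  methylated-baseline amplitude (default 3 noise SD) + planted case shift
  inside DMR subregions (sign by direction, magnitude from the configured
  effect grid, in noise-SD units) + sample intercept + probe noise. The
  MAT-style probe-behaviour model of the original array software is
  deliberately not reproduced: downstream inference only needs a monotone
  enrichment score.
* **Planted structure.** Per cell type, a configurable fraction of
  promoters is methylated at baseline (defaults 10% neuronal / 15%
  nonneuronal: promoters are mostly CpG-island promoters and largely
  unmethylated, and neurons carry fewer methylated promoters than
  nonneurons at promoters). DMRs are drawn without replacement with a
  configurable hypomethylated fraction (default 0.7, reflecting
  hypomethylation-dominant disease changes); hypo DMRs are drawn from the
  methylated-baseline pool and hyper DMRs from the unmethylated pool so
  the marginal methylated fraction stays at its configured value
  (baselines are flipped only if a pool is exhausted). Drug-responsive
  regions coincide with disease DMRs for a configured concordance
  fraction and flip direction with a configured probability (default
  0.35 / 0.9, emulating opposite-direction mood-stabilizer effects), and
  background drug regions fall only on non-DMR promoters. GWAS-locus
  membership is Bernoulli per promoter with the odds multiplied by the
  configured enrichment odds for DMR promoters; the base rate is solved
  numerically so the expected number of locus promoters matches the
  configured count, and each selected promoter tile becomes one locus
  interval. This keeps the planted promoter-level odds exactly
  interpretable downstream.

What the generator does **not** emulate: probe-sequence effects and
GC-dependent hybridization behaviour, spatial autocorrelation of real
methylation domains beyond the promoter tile, LD structure in GWAS loci,
cell-composition mixtures, batch effects. Passing tests on this generator
therefore demonstrate correctness of the pipeline's logic and calibration
of its statistics under the stated model — not robustness to array
artefacts.

## MR calling

The original study counted methylated regions with the array vendor's MAT
software, whose parameter settings are not reported; absolute MR counts
are therefore not reproducible and the package defines a transparent
caller instead:

1. Per sample, the two replicate columns are averaged and the mean
   reference column subtracted per probe.
2. The per-probe differences are smoothed with a 10%-trimmed mean over all
   probes within a 300 bp bandwidth on the same tile (truncated windows at
   tile edges). The inner loop is compiled (Rcpp) — it touches every
   (probe, column) pair.
3. Probes with smoothed score at or above a per-sample threshold are
   merged into regions: sub-threshold gaps up to `max_gap = 110` bp
   (about three probe spacings, measured from the end of one selected
   probe to the start of the next) are bridged, and runs with fewer than
   `min_probes = 4` selected probes are dropped.

The threshold keeps a z >= 2 semantics against the per-sample score
distribution but estimates centre and spread robustly (median + 2 MAD).
The plain mean + 2 SD rule fails on this kind of zero-inflated
enrichment distribution: with methylated fraction *f* and amplitude *A*
the threshold is approximately *A(f + 2 sqrt(f(1-f)))*, which exceeds the
methylated mode whenever *f* > 0.2, so calls fragment or vanish as the
methylated fraction grows. The median/MAD variant anchors the threshold
to the unmethylated bulk; the classical rule remains available via
`mr_threshold(robust = FALSE)`.

Two caveats the user should know. First, at z = 2 the caller is liberal:
smoothing makes neighbouring window scores strongly correlated, so noise
excursions produce runs of four or more above-threshold probes at an
appreciable rate, and per-sample MR counts include a noise-floor component
on top of the truly methylated promoters. Within a cell type this floor is
common to both groups and cancels from the Mann-Whitney comparison;
across cell types the adaptive threshold couples weakly to the
methylated fraction itself, so cross-fraction count differences at toy
scale partly reflect the caller, not only the biology. Second, the region
*count* is not monotone in the threshold: raising the threshold can split
one gap-bridged run into two. Covered base pairs and selected probes are
monotone, and that is what the property tests assert.

MR-count statistics follow the study design: two-sided Mann-Whitney tests
(exact conditional permutation distribution, ties kept, for combined
n <= 12; tie-corrected normal approximation with continuity correction
otherwise) for the four cell-type/diagnosis comparisons, and Spearman
correlations (average ranks) of counts with covariates. The exact and
approximate branches agree to about 0.015 in P at the branch boundary on
continuous data; on heavily tied integer data the exact branch conditions
on the tie pattern and the two can differ by several hundredths, which is
inherent, not a defect.

## DMR calling

Per cell type and replicate experiment, a Welch t statistic compares case
and control window scores probe-wise (at least 3 samples per group).
Each sample's window-score column is median-centred first: a per-sample
global offset (array intensity, enrichment efficiency — modelled by the
generator's sample intercept) would otherwise shift every probe of that
sample and, when it happens to be imbalanced between the groups, surface
as narrow same-direction false DMRs genome-wide. Median centring is the
minimal shift-invariance a production pipeline obtains from
normalization, without bringing array normalization itself into scope.
Thereafter,
probes with |t| >= 3 are merged into candidate regions by the same
run/gap/min-probe logic as the MR caller, labelled hyper or hypo by the
sign of the mean statistic. The two replicate candidate sets are then
intersected at base-pair level within direction; overlaps of opposite
direction are dropped and counted. DMRs associate with every gene whose
promoter tile they overlap by at least 1 bp. Gene-level overlap
percentages between cell types use the smaller set as denominator (the
convention is recorded in the output, since the field reports such ranges
without defining one).

## Context annotation and gene-set enrichment

CpG context uses island > shore > shelf > open-sea precedence with shores
as the 2 kb island flanks and shelves as the next 2 kb, measured from
island boundaries after merging; labels are invariant to island
fragmentation by construction. Gene context uses promoter > 5'UTR > exon >
intron > 3'UTR > intergenic on >= 1 bp overlap; a midpoint mode exists
behind a flag because the assay literature does not state which convention
applies. Context composition between two DMR sets is tested per label
with the two-sided exact test; no multiplicity correction by default
(matching the P < 0.05 reporting style of the emulated analysis),
Benjamini-Hochberg optionally.

Gene-set enrichment is a one-sided hypergeometric test per GMT term
against a user-supplied background (default: all genes on the array),
with gene sets intersected with the background first. With strata (cell
types), each term's hits are partitioned into stratum-exclusive and
common genes and results sort by ascending first-stratum percentage,
reproducing the stratified GO-style presentation.

## Track overlap, concordance, validation

Overlap with auxiliary tracks (drug-induced DMRs per condition, HMRs) is
counted at the region level — a DMR either does or does not intersect the
track by >= 1 bp — because the emulated analysis reports percentages of
DMRs, not base pairs. The `any_condition` mode unions the condition
tracks first. Directional concordance builds, per track direction, the
2x2 table of disease-DMR direction against overlap with that track
direction and applies the two-sided exact test; DMRs overlapping both
track directions count in both tables and are flagged ambiguous rather
than silently resolved.

Per-CpG validation takes a bisulfite-style count table, tests each CpG
inside a DMR with the two-sided exact test on pooled
(methylated, unmethylated) x (patients, controls) counts, and calls a DMR
validated when at least one CpG is significant with a difference sign
matching the DMR direction; significant CpGs of the wrong sign are
flagged discordant. DMRs without covered CpGs leave the denominator.
Validated counts are monotone in alpha by construction.

## Promoter-based GWAS-locus enrichment

The 2x2 promoter table cross-tabulates DMR overlap against locus overlap
over the promoter universe and is tested with the exact test (implemented
by hypergeometric summation with the conventional relative tie tolerance;
the test suite checks it against full enumeration for every table with
total <= 40 and against the reference implementation). The empirical P
resamples, per iteration, a promoter set of the same size as the observed
DMR-overlapped set uniformly without replacement and recounts the joint
overlaps; with the +1-corrected convention
P = (1 + #{null >= obs}) / (1 + n_iter) for enrichment and the mirror
for depletion, the smaller one reported as the direction. Resampling
promoters (rather than shuffling intervals) preserves the universe and
the observed set size, which is the natural null for a promoter-based
statistic; a length-preserving interval-shuffle mode exists behind a flag
for sensitivity analysis. The default 10,000 iterations match the
emulated analysis; calibration checks run at 2,000.

Because the statistic is discrete, the empirical P is slightly
conservative at small universes; the calibration test uses a
1,000-promoter universe with ~150 DMR promoters and ~300 locus promoters,
where the null support is wide enough that the P-values are
indistinguishable from uniform (KS) and the type-I error at 0.05 sits in
its binomial interval over 200 independently generated null studies.

## Problem sizes and numerical choices

The test suite and the acceptance script run everything at desk scale,
chosen as the package's own study sizes: module fixtures use 60-promoter
genomes with 6+6 samples; the calibration study uses 200 seeds at 2,000
iterations; recovery uses 50 fixtures (plus 15 per effect level for the
monotonicity curve); concordance power uses 100 studies of 400 promoters
(sized for ~95% power at the planted 0.35/0.9 concordance); the
determinism check runs the full pipeline twice at 1,000 promoters with
10+10 subjects and compares outputs byte for byte. Degenerate inputs are
flagged, not thrown: all-identical count vectors (degenerate
Mann-Whitney), zero Fisher margins, concordance tables with no overlaps,
and DMRs without covered CpGs all return results with explicit flags.
Every random step derives from a recorded seed through an RNG-state-
preserving wrapper, so identical configurations reproduce identical
outputs bit for bit.

## Known limitations

* Absolute MR/DMR counts are parameterization-dependent (the original
  array software's settings are unreported); only comparative structure
  is meaningful.
* The caller's noise floor at z = 2 and the adaptive threshold's coupling
  to the enrichment landscape (above) mean cross-cell-type MR-count
  contrasts at toy scale should be read with care.
* No probe-level multiple-testing correction is applied in DMR calling
  (matching the emulated analysis); the replicate intersection is the
  false-positive control, and the tests verify it never degrades the
  false-discovery proportion.
* GWAS loci are treated as published intervals (locus level); gene-level
  overlap is reported descriptively through the gene association step,
  and no LD-aware expansion is attempted.
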