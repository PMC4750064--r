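---
title: "Digital sorting of pure FFPE cell populations: models and methods"
author: "puresort"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Digital sorting of pure FFPE cell populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(puresort)
```

## The problem

Bulk sequencing of formalin-fixed paraffin-embedded (FFPE) tumor tissue
mixes tumor and stromal DNA. A somatic variant present at 100% in the
tumor cells of a 3%-cellularity biopsy surfaces at ~3% allele frequency
in the bulk library — indistinguishable from the background of
formalin-induced C>T artifacts. Image-based dielectrophoretic sorting
sidesteps the problem: stained single cells are trapped in field cages,
classified by keratin/vimentin immunofluorescence and DAPI DNA content,
and recovered as 100%-pure pools of exactly counted cells. Sequencing
those pure pools turns variant interpretation into pattern reading:
every locus sits at an analytic frequency anchor determined by its
allele dosage.

`puresort` implements the downstream analysis of that workflow —
cytometry-style gating, DNA-index estimation, cross-population variant
classification, ploidy-anchored low-pass copy-number calling, and FFPE
noise quantification — together with a synthetic-cohort generator that
produces every input the pipeline consumes.

## The allele-dosage model

In a pure population, a locus with `m` mutant copies out of `N` total
copies has expected variant allele frequency (VAF) `m/N`
(`expected_vaf()`). Comparing the mean VAF of pure stromal cells (`s`)
and pure tumor cells (`t`) assigns each locus a genetic variant class
(GVC):

| stromal `s` | tumor `t` | class | tumor dosage |
|---|---|---|---|
| ~1/2 | ~1/2 | germline heterozygous | (1, 2) |
| ~1 | ~1 | germline homozygous | (N, N) |
| ~1/2 | ~0 | LOH, variant allele lost | (0, 1) |
| ~1/2 | ~1 | LOH, wild-type allele lost | (1, 1) |
| ~0 | ~1 | somatic, homozygous | (1, 1) |
| ~0 | ~1/2 | somatic, heterozygous | (1, 2) |
| ~0 or ~1/2 | off-anchor | copy-number gain | best-fit (m, N) |

A 66% tumor VAF at a germline het site is a one-copy gain of the mutant
allele (2 of 3 copies); 25% is a two-copy gain of the wild type (1 of
4). Gains are oriented by comparing the fitted dosage with the germline
dosage: more mutant copies means a gain of the mutant allele, more
wild-type copies a gain of the wild type. A variant below 10% in every
population is background noise. Loci that fit no pattern — contradictory
replicates, or a stromal mean off every anchor (the signature of
allele-specific amplification bias at primer-site SNPs) — are reported
`ambiguous`, never forced into a class.

### Anchor membership and the effective number of trials

How close is "~1/2"? A binomial interval at the read depth (2000x reads
give a ±3% interval) is badly overconfident here, because reads are not
independent observations of the cell pool: a 100-cell FFPE recovery
offers on the order of 50–100 amplifiable template molecules per
amplicon, and all reads descend from them. `classify_variant()` therefore
uses an *effective* number of trials — the smaller of the summed read
depth and the estimated template count (`cells × templates_per_cell`,
default 0.5 per cell, matching a recent FFPE sample in which about a
quarter of a diploid cell's copies survive fixation and capture) — and
blends that model variance with the observed replicate scatter, so
template-poor amplicons get the wider band they deserve.

Anchors and candidate dosage ratios then compete on a penalized score:
the squared distance in units of that variance, plus `copy_penalty`
(default 0.75) per total copy for non-anchor dosages. The penalty
encodes parsimony — a 57% mean VAF is a noisy heterozygote, not a 4-of-7
dosage — while leaving genuine 66% / 25% gains cheap to accept. When no
depth information exists at all, a fixed ±0.12 band around each anchor
is used. The penalty and the template-aware variance were calibrated on
simulated cohorts of the generator's default noise; the classification
itself remains a deterministic decision table on top of them.

`infer_dosage()` is deliberately simpler: an exhaustive arg-min of
`|vaf − m/N|` over all dosages up to `N_max` (default 8, covering DNA
indices up to ~2.7 with headroom), with residual ties broken toward the
hinted `N` (ploidy baseline or covering copy-number segment), then the
smallest `N`, then the smallest `m`. Tests pin it to a brute-force
oracle.

## Gating and DNA index

Events are filtered to those captured in field cages, then labelled in
the (keratin, vimentin) mean-intensity plane. Thresholds are chosen *a
posteriori*, after the whole sample is scanned: each channel's
log-intensity is density-smoothed and the threshold placed at the
minimum-density valley between the two largest modes
(`auto_gate_thresholds()`); analyst-drawn rectangles can be supplied
instead. Gates are validated to be disjoint, and every event receives
exactly one label (`K+V-`, `V+K-`, `K+V+`, or ungated).

DNA content histograms are built per gated population from the DAPI
integral intensity, which is stoichiometric with DNA mass. Peaks are
detected on a Gaussian-kernel smoothing of the histogram (Silverman
bandwidth by default) with a topographic-prominence filter at 5% of the
tallest mode. The reported peak position is the count-weighted median of
the valley-bounded peak region — far more stable than the raw mode when
a recovery contains only a few dozen events, which is what keeps the
DNA-index relative standard deviation at the few-percent level on
100-event scans. A peak at 2.0 ± 0.1 times another peak's position is
flagged as a G2/M candidate rather than an independent population; the
vimentin-positive fraction serves as the internal diploid reference, and
when it is multimodal the tallest peak is taken and flagged for review.

The DNA index is the simple ratio of peak positions (`compute_dna_index()`,
reported to 2 decimals); the copy-number baseline downstream is
`ploidy = 2 × DI`, rounded half-up for plotting and integer calls
(`set_baseline()`: DI 1.53 → ploidy 3.06 → baseline 3).

Doublet and clump exclusion replaces visual image review with two rules:
DAPI within ±10% of twice the reference peak *and* area above the 90th
percentile, or roundness below 0.65. Recovery selection enforces the
hardware limits — 507 cells per recovery (Exit Chamber) and 680 parked
cells across pending groups (Park Chamber).

## Report filtering and singletons

`filter_variants()` applies the three reporting rules, independently per
(sample, population) group: mean VAF ≥ 10% across called replicates;
confirmation by ≥ 20% of replicates; recoveries of ≥ 60 cells only.
No-call replicates (amplicon dropout, "Absent") are excluded from both
the mean and the confirmation denominator — a deliberate reading of an
ambiguous rule, flagged here: a variant called at 100% in the one
usable replicate of four is retained. A locus is kept if it passes in
any group, and a kept locus keeps all populations' calls, so a somatic
variant's 0% stromal VAF remains visible to the classifier. Every drop
is written to an audit log with its rule id. Filtering is monotone:
tightening any rule never adds a reported variant.

Double-positive (K+V+) recoveries are typically below the 60-cell
limit; they are reported descriptively only, and a somatic/LOH/gain
variant seen in them *and* in the pure tumor cells is tagged
`confirmed_in_tumor`.

The false-positive proxy is the *singleton*: a variant present exactly
once among the libraries of (sample, population) groups that have
replicates, and nowhere else in the run. A variant in one of two
replicates but present in any other library is not a singleton (a
low-coverage amplicon can miss a true variant); populations without
replicates are outside the universe. `singleton_distribution()` bins
singleton VAFs by recovered cell count (width 20) and reports Tukey
upper fences as outlier thresholds.

## Low-pass copy number

Binned read counts are normalized to a median ratio of 1, optionally
after a GC-decile correction (decile medians, pooled monotone). Integer
copies are `round(ploidy × ratio)` (half-up, floored at 0) with the
ploidy anchored at `2 × DI` from the cytometry stage — the step that
lets a triploid profile center at 3 instead of being misread as diploid.
Segmentation is deterministic run-merging: maximal runs of equal copy
number, with runs shorter than `min_bins` absorbed into the larger
flank. Fixed 1-Mb bins are the default at 0.1–0.3× coverage;
`bin_width_for_cv()` reproduces adaptive sizing by choosing the width
whose expected Poisson CV matches a target (0.06 gives ~139 kb at
0.2×). Mappability enters as an optional per-bin weight column.
`cross_check()` compares panel-inferred total copies against the
covering segment, and recognises the copy-neutral LOH signature: binary
(0%/100%) VAFs in a 2-copy segment are concordant, noted as loss plus
reduplication.

## The synthetic cohort generator

The generator emulates the statistical structure the analysis assumes,
from one declarative truth object (`cohort_truth()`): populations with
fractions, DNA indices, marker levels and G2/M fractions; loci with
per-population `(m, N)` dosages tied to copy-number segments (validated
to tile each chromosome and to agree with locus `N`); and a damage
model.

*Particles.* DAPI integral ∝ DNA index (doubled for G2/M), log-normal
channel noise at the population's CV (default 10%, a typical FFPE
DAPI-histogram spread), doublets as summed pairs with low roundness,
debris at low DAPI, and an in-cage Bernoulli flag.

*Panel reads.* The FFPE bottleneck is modelled as two-stage sampling.
Available templates per amplicon are
`Poisson(cells × N × amplifiable_fraction × capture_efficiency × e)`,
with a fixed per-amplicon capture efficiency `e` (log-sd 0.25).
Mutant templates are binomial with the allele-bias weight
`β·m / (β·m + (N − m))` applied at capture — the primer-site SNP
mechanism; β defaults to 1, and the demo's biased locus uses β = 0.2.
Each wild-type template converts to the artifact allele with probability
`artifact_rate` at artifact-eligible (C>T/G>A) sites. Reads are then
Poisson at `depth_mean`, scaled by a per-amplicon readout efficiency
(log-sd 0.5) and a saturation factor `1 − exp(−T/20)`; zero templates
mean dropout (no-call), and a library whose mean templates fall below 2
per amplicon is marked failed. Splitting amplicon variability into
capture (which drives VAF dispersion) and readout (which drives coverage
non-uniformity) is what lets the same defaults produce both tight VAF
anchors at 100-cell recoveries and the observed decay of coverage
uniformity below ~50 cells.

*Defaults as study conditions.* `amplifiable_fraction` 0.5 and
`capture_efficiency` 0.5 put ~25 templates per 100 cells per copy —
chosen so that artifact singletons cross the 10% VAF line right around
the 60-cell mark while germline anchors at 100+ cells scatter by only a
few percent, the regime the method is designed for. `artifact_rate` 0.01
per template and `read_error` 0.001 per read are plausible FFPE
deamination and sequencer rates; neither is measured directly in the
source material, so they are calibrated to reproduce the qualitative
noise-versus-cell-count behaviour, not any printed number. Storage age
enters only through a decay table on the amplifiable fraction (0.5 up to
3 years, ~0.02–0.03 at 14+ years) with log-normal per-sample scatter
(sd 1.2) — failure concentrates in specific old blocks rather than
spreading uniformly, and recent-cohort success lands in the
mid-90s-percent range.

*Low-pass bins.* Poisson counts proportional to segment copy number ×
bin width × coverage, with optional smooth GC bias; mixtures combine
linearly in the copy dimension, which is why a 40% tumor fraction
attenuates losses toward 1.

*Determinism.* Every output table draws from its own stream, derived
from the master seed and a stream name; generation is bit-reproducible,
and fixed panel properties (amplicon efficiencies) are drawn before the
library stream is seeded so replicate libraries stay independent.

What the generator does **not** model: read-level errors in sequence
context (no FASTQ, no alignment), PCR cycle-by-cycle jackpots,
mappability structure, subclonal heterogeneity within a sorted
population, segmentation-confounding focal events below bin size, and
image formation. Passing tests therefore demonstrate that the analysis
recovers the truth *under this statistical model of the assay* — they
bound algorithmic error, not wet-lab error on real tissue.

## Numerical choices

Rounding is half-up wherever a printed convention exists (ploidy
baselines, report percentages: 93.5% renders "94%"), since banker's
rounding would send 2.5 to 2. Ratios are renormalized to an exact
median of 1 after GC correction. Degenerate inputs are defined, not
special-cased: a constant DAPI vector occupies one histogram bin; a
single singleton yields a fence equal to its value; an all-in-cage
table filters to itself; an empty call set gives a header-only report.
Histogram peak ties and dosage ties break deterministically (hint,
then smallest `N`, then smallest `m`; valley split at the leftmost
minimum). VAFs are proportions in [0, 1] internally and percentages
only in rendered reports.

## Problem sizes used in the test suite

The packaged checks run at desk scale, chosen to exercise every code
path with comfortable statistical margins: 200-locus cohorts at 2000×
depth and 100-cell recoveries for class recovery (observed accuracy
96–98% against a ≥95% requirement); a 20-chromosome, 2000-bin genome at
0.2× for copy-number recovery; 30 cell-count bins × 2 replicates over
2000 artifact-eligible sites for the singleton study; 10 replicates of
100-event scans for DNA-index precision. The singleton fence is compared
across adjacent bins with 0.5 percentage points of slack: past ~300
cells the fence sits on the flat sequencer-noise plateau where its true
decrement per 20-cell bin is smaller than the Monte-Carlo jitter of a
per-bin quantile.

## Known limitations

* Classification treats populations independently per tumor peak; it
  does not build a joint clonal model across peaks, and cross-peak
  disagreement is only reported.
* The binomial-template variance model is an approximation; extremely
  damaged libraries (a handful of templates) can still produce
  off-anchor means that land in `ambiguous` rather than their true
  class — by design, since forcing a class there would be a guess.
* Copy-number calls assume the DNA index is correct; an aliased DI
  (e.g. a tetraploid G2/M peak taken as a population) shifts the whole
  integer profile. The G2/M candidate flag mitigates but cannot resolve
  every case.
* The singleton definition needs replicates; single-library designs
  have no false-positive proxy.
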