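---
title: "Constraint analysis of variants in ultraconserved elements: models and methods"
author: "ucevar authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Constraint analysis of variants in ultraconserved elements: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ucevar)
```

## The scientific question

Ultraconserved elements (UCEs) are stretches of at least 200 bp that are
essentially identical across human, mouse and rat. Whether such elements are
constrained as indivisible blocks, or whether selective pressure acts base by
base, can be read off population sequence variation: if individual positions
differ in their contribution to function, variants at the less-constrained
positions should be tolerated and may rise in frequency, while variants at
critical positions should stay rare.

`ucevar` implements that test. Single-nucleotide variants inside a catalogue
of conserved elements are stratified by minor allele frequency (MAF) into
**rare** (MAF < 0.5%), **intermediate** and **prevalent** (MAF > 5%) classes
(strict inequalities; boundary values are intermediate, keeping the named
classes conservative). Three signals are then assessed:

1. **Per-base conservation.** The distribution of per-base conservation
   scores (phyloP-style: positive = conserved, negative = accelerated) at
   variant positions is compared across MAF classes, and against random
   element positions matched for base composition, using two-sided
   Kolmogorov–Smirnov (KS) tests and bootstrap confidence envelopes around
   empirical CDFs.
2. **Regulatory overlap.** Overlap of variant positions with a binary
   regulatory annotation (clustered transcription-factor binding sites,
   TFBS) is contrasted against equal-sized composition-matched random
   position sets with Pearson chi-squared tests, and summarised as overlap
   per 1000 positions via repeated resampling with Mann–Whitney
   comparisons.
3. **Position within the element.** Variant coordinates are mapped to
   percent-along-element (0% = start, 100% = end, flanks of one element
   length mapped to [−100, 0) and [100, 200)) to exclude boundary artefacts,
   and the scores of the three bases on either side of each variant are
   pooled to ask whether a variant's neighbourhood stays constrained.

## Composition-matched null positions

Variant positions are G/C-enriched relative to the AT-rich element
background, and composition correlates with conservation, so naive random
positions would confound the comparisons. The null used throughout is a
**G/C-matched sample**: positions drawn without replacement from the element
universe, stratified on the binary class of the reference base
({G,C} vs {A,T}) so the sample composition equals the query set's. Class
counts are fixed by largest-remainder apportionment, making every draw's
composition identical rather than merely correct in expectation. A binary
base class is the only correction applied; dinucleotide or mappability
corrections are out of scope.

## ECDF bootstrap envelopes

The envelope around a null ECDF is the pointwise 2.5/97.5 percentile of
`B = 1000` bootstrap replicate ECDFs. Replicates are generated by
multinomial re-weighting of the sorted sample — distributionally identical
to resampling with replacement but evaluated in one cumulative-sum pass per
replicate, which keeps coverage simulations cheap. The point ECDF is the
standard right-continuous estimator; for testing, ECDFs are compared on the
pooled sorted values (exact supremum), while plotting uses a 512-point grid
augmented with the sample values. Pointwise 95% envelopes cover the true
CDF at roughly 95% of grid points; the test suite checks ≥90% average
pointwise coverage at n = 500.

## Overlap testing

`overlap_chi2()` forms the 2×2 table (overlap / non-overlap × query / null)
and applies Pearson's chi-squared test **without** continuity correction —
at the sample sizes in scope the correction is immaterial, and the
uncorrected statistic is the named test. Results carry a `low_expected`
flag when any expected cell is below 5 and a `degenerate` flag when a
margin is zero (e.g. an empty feature track); degenerate results are
reported, not silently dropped. `resample_overlap()` draws `n_sets = 100`
sets of `set_size = 1000` positions, without replacement within a set and
independently across sets (a position may recur across sets; independence
keeps the per-set counts i.i.d. for the rank test). Mann–Whitney
comparisons use `stats::wilcox.test`, i.e. the normal approximation with
tie correction at these set counts. No multiple-testing correction is
applied across classes or populations by default, mirroring per-set
testing; `class_depletion_report(..., p_adjust = "bonferroni")` adds a
family-wise-adjusted column when one is wanted.

## Interval conventions

All tabular surfaces are BED-convention 0-based half-open; `GRanges` is the
in-memory container and conversion happens only at I/O boundaries. Merging
coalesces book-ended intervals (`[100,200)` + `[200,300)` → `[100,300)`),
matching the interval-merge defaults used to assemble element catalogues.
Shuffles preserve the interval-length multiset exactly, place uniformly at
random (same chromosome by default, any sufficiently long chromosome
optionally), avoid an exclusion track by bounded rejection sampling, and are
seed-reproducible. No default exclusion track (e.g. assembly gaps) is
shipped; callers pass one when their genome build needs it. Strand is
ignored throughout.

## Variant ingestion

VCFs are read with `VariantAnnotation`, multiallelic records decomposed,
and only single-nucleotide records retained (indels/MNVs are counted and
dropped). The alternate-allele frequency is taken from a configurable INFO
field (default `AF`) and folded to a MAF (`f > 0.5` → `1 − f`); records
lacking the field are counted and skipped. For pooled-cohort designs the
MAF is the pooled estimate carried in the VCF — allele frequencies are
never recomputed from read counts. Variant identity is `(chrom, pos, alt)`;
conflicting reference alleles at one site raise an error rather than
merging silently. When two call sets are intersected ("called by both
programs"), frequencies are taken from the first set, reflecting designs in
which one caller's pooled frequency estimates are authoritative. MAF
classes for multi-population references default to global frequencies; a
per-population field name can be supplied instead.

Pooled-design arithmetic is exposed directly: a pool of `n/k` diploid
individuals carries `2n/k` chromosome copies, so per-allele depth is
`pool coverage / (2 n / k)`. Full precision is returned; printed cohort
summaries conventionally truncate to whole folds.

## The synthetic scenario

The generator exists so the entire pipeline — ingestion, matching, testing,
reporting — runs and can be calibrated with no external data. Defaults
describe one fixed scenario:

| parameter | default | meaning |
|---|---|---|
| genome | 2 × 5 Mb | i.i.d. background at 41% G/C |
| elements | 300 × 200–600 bp | AT-rich interiors (62% A/T), ≥1.2 kb apart |
| score inside | N(2, 0.8²) | phyloP-like conservation |
| relaxed patches | 15% of element bases, 40 bp runs | N(0, 0.8²) |
| score outside | N(0, 1) | neutral flanks |
| variants/class | 2000 rare, 1000 intermediate, 2000 prevalent | per population |
| `beta` | 2.5 | prevalent placement log-odds decrease per score unit |
| `gc_bias` | 2 | placement odds of G/C vs A/T bases, all classes |
| sparse features | 25% of element bases, 20 bp sites | log-odds +3 per score unit |
| dense features | 60% of element bases | uniform slots |

Rare variants are placed uniformly over element bases (up to the shared
G/C placement bias); prevalent variants are accepted with probability
logistic in `−beta × (score − 1)`, intermediate with slope `−beta/2`. With
`beta = 0` placement is score-independent, which is the null used for
calibration. MAFs are drawn uniformly within each class's range — they are
drawn, not evolved; no demographic model is implied. Scores are Gaussian
mixtures rather than alignment-derived: the analyses consume only ranks and
ECDFs, so the distributional family is immaterial, but this is a modelling
simplification and passing tests say nothing about alignment artefacts,
mappability, or score-track gaps in real data.

Two design choices deserve emphasis. First, relaxed positions come in
contiguous 40-bp patches, not scattered single bases: functional units
(binding sites) occupy runs of sequence, and patch-scale relaxation is what
lets feature placement couple to the score at feature scale. Second,
feature placement is score-coupled (`feature_score_coupling = 3`): binding
sites preferentially occupy conserved bases. That coupling is the causal
mechanism behind the prevalent-variant TFBS depletion; without it (set the
coupling to 0) prevalent variants avoid conserved bases yet show no feature
depletion. `beta = 2.5` (a score-SD-scaled effect of 2) and coupling 3 put
the scenario in a strong-selection regime where all three headline
contrasts — the prevalent-vs-rare KS shift, prevalent TFBS depletion
against the G/C-matched null, and the dense-track > sparse-track per-1000
ordering — are decisive in essentially every seeded run, which is the
regime the analyses are designed to detect. Cross-population sharing is
emulated by a master prevalent catalogue observed at 80% per population,
with rare variants drawn privately: prevalent variants are then mostly
shared and rare variants essentially private, without any population
genetics.

All randomness flows from one top-level seed through named substreams
(`derive_seed(seed, stage)`), so any stage can be re-run in isolation and
reproduce its output bit-for-bit.

## Numerical and degenerate-input choices

- ECDF envelopes are clipped to contain the point estimate (guarding
  against quantile interpolation at extreme grid points); a single-valued
  sample yields a legitimate collapsed band.
- KS p-values use the asymptotic two-sided distribution (`exact = FALSE`);
  with thousands of observations the exact computation adds nothing.
- Positions on chromosomes absent from a feature track count as
  non-overlapping; positions missing from a score track are explicit
  misses, warned about above 5% and an error when total.
- A variant reachable by two elements' flanks is assigned to the nearer
  element; exact ties go to the upstream element.
- Shuffle placement errors out after 1000 rejections per interval rather
  than looping forever on over-fragmented allowed space.

## Problem sizes

The default scenario (10 Mb genome, ~120 kb of elements, 5000 variants per
population) runs in a few seconds per full draw. The repeated-run studies
are sized to hold Monte-Carlo error well below the margins they check:
1000 null draws for KS calibration, 200 for depletion calibration, 200
simulations for band coverage, and 100 scenario draws for headline
recovery; calibration studies reuse one genome/score realization and
redraw variants, which is the quantity the null concerns.

## Known limitations

- The G/C correction is mononucleotide; real SNV ascertainment has finer
  composition structure.
- The generator's MAFs are class-uniform draws; allele-frequency spectra,
  linkage and demography are not modelled.
- Score tracks are held at single-base resolution over the analysis
  universe only; genome-wide scans should use a universe-restricted read.
- The caller-concordance operation is a key intersection; it does not model
  caller error processes.
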