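---
title: "Reference-relative CNV calling and population diversity analysis"
author: "cnvDiversity"
output: rmarkdown::html_document
vignette: >
  %\VignetteIndexEntry{Reference-relative CNV calling and population diversity analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cnvDiversity)
```

# The model and its assumptions

The package analyses copy number variation in a structured cohort from SNP
array summary signals alone: per-marker total intensity and B-allele
frequency (BAF). It assumes that

1. total intensity at a marker scales (noisily) with local copy number:
   for copy number $c$ the expected intensity is $(c/2)\,b_m$, where $b_m$
   is the marker's diploid baseline;
2. one breed in the cohort can serve as a *reference population*: large
   enough for a stable per-marker mean, with low signal variance, and with
   few CNVs of its own, so that its mean intensity $\bar x_m$ approximates
   the diploid baseline;
3. markers are dense enough that a real CNV covers several consecutive
   markers, so single-marker calls can be filtered by a run-length rule
   rather than by modelling the intensity distribution.

Calling is therefore a per-marker threshold on the log2 ratio
$\mathrm{LRR}_{im}=\log_2(x_{im}/\bar x_m)$, and all multi-marker evidence
is enforced in a separate segmentation stage. This deliberately replaces
the undocumented internals of commercial array-CNV callers with a fully
specified, testable procedure; it makes no claim to reproduce any
particular commercial algorithm's output.

Note that the reference breed is *also called against its own mean*. A CNV
segregating in the reference breed at frequency $f$ shifts $\bar x_m$ by a
factor $1 \pm f/2$; carriers and non-carriers then both move relative to
the contaminated mean. With the default thresholds this remains
well-behaved up to roughly $f = 0.3$ (see "Numerical choices").

# Pipeline stages and their parameters

| parameter | default | meaning |
|---|---|---|
| `gainThreshold`, `lossThreshold` | 0.3, 0.3 | log2-ratio call cutoffs (dimensionless); 0.3 ≈ 2.46 / 1.62 copies. Ties at the threshold are calls, so the decision boundary is deterministic. |
| `minMarkers` | 3 | minimum called markers per segment; 3 probes is a conventional array-CNV floor. |
| `maxGapMarkers` | 0 | uncalled markers tolerated inside a run. 0 reads "consecutive" literally; the parameter exists because segment definitions differ between tools. |
| `minFraction` | 0.01 | within-group carrier fraction a *(position, state)* needs to be *reported* for that group (boundary inclusive). |
| `highlightThreshold` | 20 | carrier percentage (strict `>`) above which a private position is highlighted. |
| copy-state cutpoints | 0.25 / 0.75 / 1.25 | qPCR fold-change bins centred on the expectations 0, 0.5, 1 and 1.5 of the four copy states; lower-inclusive. |

Two rules deserve emphasis because several counts depend on them:

- **Segment states.** A segment is `gain` or `loss` only when *every*
  contributing call agrees; any mixture yields `mixed`. Mixed segments
  count toward total, gain *and* loss in genome-percentage summaries, and
  force state `both` at the CNVR level.
- **Sharing vs reporting.** The `minFraction` filter decides which
  positions a group *reports*; it plays no role in deciding whether a CNV
  is *shared*. A position retained in group $g$ is unique private to $g$
  iff no other group has even one carrier of that (position, state).
  `positionFrequency()` therefore returns all carrier-bearing rows with a
  logical `retained` flag instead of dropping sub-threshold rows — the
  privacy decision needs them.

The per-individual "bracketed average" in the group summary tables is
`nPositions / groupSize`. An alternative reading — the mean of raw
per-individual call counts — is deliberately kept as a separate diagnostic
(`averageCallsPerIndividual()`) rather than silently substituted, because
the two disagree whenever carriers overlap.

# The synthetic cohort generator

`simulateCohort()` exists because real multi-breed array datasets of this
kind are owner-restricted. Its defaults define the emulated study design,
scaled to desk size:

- **Cohort**: 8 breeds in 3 ancestry clusters, 601 individuals, with
  relative breed sizes preserved from the emulated design and
  `BelgianDraught` (n = 103) as the reference breed.
- **Genome**: 10 autosomes × 50 Mb, 500 uniformly spaced markers each
  (5,000 markers, 100 kb spacing). Uniform spacing keeps coverage
  expectations analytic in tests; random spacing is available.
- **Intensity**: $x = b_m \cdot \max(c, 0.1)/2 \cdot e^{\varepsilon}$ with
  $\varepsilon \sim N(0, \sigma \ln 2)$ and $\sigma = 0.05$, so log2
  ratios are Normal with sd 0.05 around $\log_2(c/2)$. The floor 0.1
  models residual background signal in homozygous deletions and keeps
  intensities positive. The reference breed's $\sigma$ is halved
  (`referenceNoiseFactor = 0.5`): the emulated design states only that the
  reference breed had the lowest variance, never a value, so the factor is
  a parameter.
- **BAF**: breed allele frequencies drift hierarchically from an ancestral
  frequency (Balding–Nichols, cluster $F_{ST}$ 0.1, breed $F_{ST}$ 0.05);
  genotypes are binomial at the local copy number, giving BAF clusters
  {0, ½, 1} in diploid state, {0, 1} in hemizygous deletions and
  {0, ⅓, ⅔, 1} in single-copy gains, plus truncated Gaussian noise
  (sd 0.03). This is what gives the BAF PCA its breed-separating
  structure.
- **Planted regions**: 1 Mb regions (10 markers each) comprising two
  shared CNVRs carried by every non-reference breed, two breed-private
  regions (a gain private to the Friesian, a loss private to the Exmoor
  pony — echoing the breed-private signals this kind of survey reports),
  and three cluster-private regions per cluster. Carriers are drawn
  binomially at the configured frequency, and the realized carrier set is
  recorded in a truth table.

Two defaults are consequences of the reference-contamination arithmetic
above, chosen at design time: the reference breed carries no shared or
breed-private planted CNVRs (mirroring why a CNV-quiet breed is chosen as
reference), and planted frequencies for carrier groups that *include* the
reference breed (the Draught cluster) are capped at 0.3. At $f = 0.3$ a
copy-3 carrier still shows $\log_2(1.5/1.15) = 0.38 > 0.3$ and a
non-carrier $-0.20 > -0.3$, so calls stay on the correct side of both
thresholds; at $f = 0.5$ carrier evidence ($0.26$) would drop below the
gain threshold.

Because carriers are drawn binomially, the ground truth of a simulated
cohort is the *realized* carrier set in the truth table, not the nominal
rate: at a group size of 295 and $f = 0.5$ the realized frequency has
sd ≈ 0.03 before the pipeline ever sees a marker. Recovery tests
accordingly compare the pipeline's frequency estimates against the truth
table; the nominal rate is a sampling parameter of the generator.

**What the generator does not emulate** — and hence what passing tests do
not demonstrate about real data: raw probe-level artefacts (batch, plate
and wave effects), genotype-clustering failures, call-rate-based sample
QC (exclusions are an input list), linkage disequilibrium between
markers, overlapping CNVs of different copy number on one haplotype, and
mosaicism. Real intensity noise is also heavier-tailed than lognormal, so
real-data false-call rates will exceed the synthetic ones at equal
thresholds.

# Numerical and interface choices

- **Coordinates.** All in-memory intervals are `GRanges`, i.e. 1-based
  inclusive; BED input/output converts to 0-based half-open in
  `readBed()`/`writeBed()` only. Keeping the container's native convention
  confines off-by-one risk to two functions.
- **Merging.** CNVR construction is `GenomicRanges::reduce()` with
  `min.gapwidth = 0`, which merges on ≥ 1 shared base and leaves bookended
  segments separate — the "at least 1 bp" rule, verified against an
  all-pairs union-find oracle in the tests.
- **PCA.** `runPca()` wraps `stats::prcomp` and fixes each component's
  sign by making its largest-magnitude loading positive; results are then
  deterministic and comparable across runs and algebraic routes. Variance
  fractions are reported over all components and sum to 1. Defaults are
  `center = TRUE, scale = FALSE`, since intensity-derived features share a
  scale and zero-variance features would make scaling blow up. The
  segment-signal PCA encodes each individual × CNVR cell as a signed
  indicator (+1 all-gain, −1 all-loss, 0 otherwise, mixed included); the
  exact feature encoding of such plots is rarely published, so the mean
  per-segment log2 ratio is available as an alternative
  (`encoding = "log2"`).
- **Enrichment.** Hypergeometric tails via `stats::phyper`, both
  directions; Bonferroni is `min(1, p × nTerms)` over tested terms and
  BH-FDR is reported alongside. The tests cross-check against one-sided
  Fisher exact tests.
- **qPCR.** Exact-doubling efficiency is assumed, as the
  $2^{-\Delta\Delta C_t}$ method requires; replicate Ct values are
  averaged before any difference is formed; the calibrator's fold change
  is exactly 1 by construction.
- **Degenerate inputs.** Empty call sets produce empty (typed) segment
  sets; empty segment sets produce empty CNVR sets and zero coverage;
  chromosome shares on an empty segment set are an error (undefined
  ratio), as is novelty of an empty region set.

# Problem sizes used in validation

The test suite validates each interval/counting operation against
brute-force oracles on 100+ random instances apiece, and runs the full
pipeline on the default 601 × 5,000 synthetic cohort (noise sd 0.05, fixed
seed), checking that all 13 planted CNVRs are recovered with compatible
state, that breed- and cluster-private regions are classified unique
private to the correct group at every planted marker, that within-group
carrier-frequency estimates sit within 0.05 of the truth table, and that
the segment-signal PCA separates the three planted clusters (positive mean
silhouette on PC1–2). These sizes were chosen so the whole suite runs in a
few minutes on one core; the generator scales to larger designs if needed.

# Known limitations

- The log2-ratio threshold caller has no per-marker variance model; a
  marker with unusually variable reference intensity is as trustworthy as
  any other. The reference profile's per-marker sd is computed and stored
  for downstream filtering, but no default filter is applied.
- CNVR state `both` does not distinguish "two overlapping unidirectional
  polymorphisms" from "one bidirectional locus".
- Unique-private classification is presence/absence based; a single
  miscalled individual in another group destroys privacy. This is the
  intended literal definition, but it makes privacy counts sensitive to
  the false-call rate at low thresholds.
- No V_ST/F_ST-style differentiation statistics on CNVs are computed;
  the sharing analysis reports counts and percentages only.
- Sample-level QC is an exclusion-list input; the package neither
  recomputes call rates nor models batch structure.
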