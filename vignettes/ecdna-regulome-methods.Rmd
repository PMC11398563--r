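---
title: "Differential chromatin activation and ecDNA contact-map reassembly: methods"
author: "ecRegulome authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential chromatin activation and ecDNA contact-map reassembly: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ecRegulome)
```

# Scientific background

Human-papillomavirus-positive oropharyngeal cancers can carry *hybrid
ecDNA*: extrachromosomal circular DNA whose cycle interleaves amplified
human genomic segments with integrated HPV genome segments. Two
computational questions dominate the analysis of the regulatory landscape
of such elements:

1. **Which chromatin regions change activation state under a
   perturbation** (here, a BET-bromodomain inhibitor versus vehicle),
   measured by H3K27ac ChIP-seq with only two biological replicates per
   condition — far too few for per-region *t*-tests across ~10^4 peak
   regions.
2. **What does chromatin contact structure look like *along the circle***,
   i.e. how to re-index a genome-wide binned Hi-C contact matrix along the
   ordered, oriented segments of the reconstructed ecDNA cycle (human
   chromosomes plus the viral contig treated as an ordinary extra
   chromosome), and normalize the result.

ecRegulome implements both as a tested, reusable pipeline, together with
seeded synthetic-data generators whose recorded ground truth lets every
stage be benchmarked without access to protected patient sequencing data.

# The differential-activation statistic

## Size factors on the tallest peaks

Raw read counts in peak regions are normalized under the assumption that
the *tallest* peaks should be comparable across samples — low-level
background can differ between samples for technical reasons, so it is
deliberately excluded from the normalization reference. The reference set
is the intersection, across samples, of each sample's top-30% of peaks by
raw count (`topPercentileSubset()`, `q = 0.30`). The per-sample threshold
is the `k`-th largest count with `k = ceiling(q * n)`; ties at the
threshold are included. We read "top percentile for each sample" as the
*intersection* of per-sample top sets because median-of-ratios
normalization needs one common reference subset; a union reading would
admit peaks that are background in some samples, defeating the purpose.

On this subset, Relative Log Expression (RLE, median-of-ratios) size
factors are computed (`rleSizeFactors()`): each peak's reference is its
geometric mean across samples, a sample's factor is the median over
subset peaks of count/reference, and factors are rescaled to geometric
mean 1. Subset peaks with a zero in any sample are dropped before the
geometric mean. The factors are then applied to **all** peaks
(`normalizeCounts()`), not only the reference subset. We take the
arithmetic median of ratios; an alternative implementation interpolating
the even-*n* median on the log scale differs only in the 7th significant
digit on realistic data, which the test suite verifies against an
independent implementation.

## The mean–SD trend and approximate z-scores

With two replicates per condition, per-peak variance estimates are
essentially noise. Instead, the standard deviation of normalized signal
is modelled as a smooth function of mean signal: per peak, the mean and
sample SD are computed across *all* samples pooled as if they were
replicates — including between-condition signal, which slightly inflates
the SD of truly differential peaks and makes the statistic conservative
for them. A within-condition-residual variant would be less conservative
but is not the default because pooling all samples is the more robust
choice at *n* = 8.

The trend is a degree-1 loess (tricube weights, span 0.5) of SD on mean
(`fitSDTrend()`), tabulated on a 256-point grid with linear interpolation
between grid points and constant extrapolation beyond the observed mean
range. Fitted values are floored at
`max(1e-8, 5th percentile of the fitted values at the data points)`;
the floor is computed at the data points rather than on the uniform grid
so that it tracks the data's own (typically right-skewed) mean
distribution. None of span/grid/floor is dictated by the statistic
itself; they were chosen once for stability and are exposed as arguments.

The per-peak statistic (`zScores()`) is

$$ z_p \;=\; \frac{\bar{x}_{p,\mathrm{trt}} - \bar{x}_{p,\mathrm{ctrl}}}
   {\hat\sigma(m_p)\,\sqrt{1/n_1 + 1/n_2}} $$

where $m_p$ is the peak's mean over the samples being compared. The
$\sqrt{1/n_1+1/n_2}$ factor treats $\hat\sigma$ as a per-observation SD,
the standard two-sample form; `scaleBySampleSize = FALSE` gives the raw
mean difference over $\hat\sigma$ instead. Both are exposed because the
choice only rescales all z-scores by a constant — and the empirical-null
step below absorbs exactly such global rescalings, so downstream calls
are insensitive to it.

## Empirical-Bayes local false discovery rate

`localFdr()` follows Efron's two-group empirical-Bayes recipe. The
mixture density $f(z)$ is estimated by Poisson regression of histogram
counts (120 equal-width bins spanning the z range) on a natural cubic
spline basis with 7 df. The null component $N(\delta, \sigma_0^2)$ is fit
by *central matching*: a quadratic in $z$ is fitted to $\log \hat f(z)$
over bin midpoints within the central 50% of the z distribution, giving
$\sigma_0 = \sqrt{-1/(2c_2)}$ and $\delta = c_1 \sigma_0^2$. The null
mass is the proportion matching the null density at its mode,
$\pi_0 = \min\!\big(1,\ \hat f(\delta)\,\sigma_0\sqrt{2\pi}\big)$, and

$$ \mathrm{lfdr}(z) \;=\; \min\!\Big(1,\
   \pi_0\,\varphi\big((z-\delta)/\sigma_0\big) \,/\,
   \big(\sigma_0 \hat f(z)\big)\Big). $$

`nullMode = "theoretical"` fixes $\delta = 0, \sigma_0 = 1$. If the
spline fit fails or the central log-density is not concave (e.g. hollow
bimodal z), the estimator falls back to the theoretical null with a
warning rather than producing an undefined fit. Empirical mode requires
at least 200 z-scores; central matching carries a small finite-bin bias
(roughly ±0.1 in $\delta$ and $\sigma_0$ at n = 10^4), which the tests
document.

## Calling and mark intersection

`callDifferential()` combines the pieces: fold change
$(\bar{x}_\mathrm{trt}+c)/(\bar{x}_\mathrm{ctrl}+c)$ with pseudocount
$c = 1$ guarding zero means, and a call when FC > 2 *and* lfdr < 0.3
(both thresholds are the study defaults and are configurable), restricted
to $z > 0$ for the default "up" direction, since the target of inference
is differentially *up*-regulated acetylation. Whether the original
fold-change screen used means, medians, or a pseudocount is not
derivable from the statistic itself; means with $c = 1$ is our
documented choice, and $c$ only matters for peaks with near-zero control
signal.

Called H3K27ac peaks are then intersected (`intersectMarks()`; ≥ 1 bp
overlap, half-open abutment excluded) with H3K4me3-defined promoter
regions or H3K4me1-defined enhancer regions, and `commonPeaks()` reports
cross-sample common peaks under the same overlap rule.

# Pooled peak-calling input and seed segments

`poolReads()` reproduces the construction of the unbiased peak-calling
input: a union of reads sampled randomly, without replacement, with equal
weight per sample — `floor(total/k)` reads per sample, remainder assigned
in input order so runs are reproducible. `countReadsInPeaks()` quantifies
peaks per sample by any-overlap counting (a read overlapping *n* peaks
contributes to all *n*); whether the original quantitation used read
midpoints or any-overlap is not stated anywhere we can check, so
any-overlap — the common default of peak-quantitation tools — is the
documented choice. Peak calling itself (HOMER) is out of scope; this
module builds its input and consumes its output regions.

`selectSeedSegments()` applies the copy-number seed rule for amplicon
reconstruction: non-viral segments with CN ≥ arm ploidy + 2.5, viral
segments with CN ≥ 1, both inclusive.

# Hi-C reassembly along the cycle

## Bin mapping and assembly

A cycle is an ordered list of oriented segments; `binsForSegment()` maps
a segment onto the bin grid as bins `floor(start/b) … ceiling(end/b)−1`,
keeping partial edge bins (inclusive snapping loses no signal), reversed
for `'-'` orientation. `assembleCycleMatrix()` concatenates these per
segment into a cycle bin map and fills
`assembled[i, j] = M[binmap[i], binmap[j]]` — including *trans* blocks
between segments on different contigs, which is what makes the
human–viral junction visible. The genome-wide matrix is therefore the
canonical input; a required bin missing from it is zero-filled and
flagged (`found = FALSE`) rather than an error. A junction-spanning bin
shared by adjacent segments appears once per occurrence; duplicated
genome bins are permitted in the map. Cycles files use the
AmpliconArchitect text dialect, read as 1-based inclusive coordinates and
converted at the boundary (the dialect's base convention is not
documented by its authors; this assumption is a single switch in
`readCycles()`).

## ICE balancing

`iceBalance()` performs symmetric iterative correction: bins with zero
raw marginal are masked; each iteration divides rows and columns by their
marginals rescaled to mean 1 over unmasked bins, until the coefficient of
variation of unmasked marginals is ≤ `tol` (default 1e-5) or `maxIter`
(200) is reached; a final global rescale sets the mean unmasked marginal
to 1. The cumulative bias vector satisfies
`balanced = bias_i * raw_ij * bias_j` exactly. No percentile coverage
filter is applied beyond zero-marginal masking — appropriate at the
matrix sizes this package targets. Balancing is idempotent to < 1e-8 and
the 2×2 zero-diagonal case has the closed form the tests assert.

A planted-bias caveat the tests encode: ICE weights of a biased matrix
$b_i b_j T_{ij}$ equal (weights of $T$)$/b_i$ up to scale, so bias
*recovery* is scored as `bias(biased) * b / bias(unbiased)` being
constant — not as proportionality to $1/b$ alone, which would only hold
if the bias-free matrix already had flat marginals.

## Condition comparison

`compareMatrices()` is descriptive, not inferential (no distributional
claims are available for two balanced matrices): per circular-distance
stratum (minimum of clockwise/counter-clockwise separation) it reports
the Pearson correlation of off-diagonal entries, plus a global log2-ratio
matrix and the mean absolute log2 ratio with a pseudocount. Balancing is
required first so the comparison is not dominated by per-bin visibility.

# What the generators emulate — and what they do not

`simulatePeakCounts()` draws baseline means log-uniform over
`[100, 10000]` (the lower end chosen so the Gamma-Poisson construction
below is exact), true size factors log-uniform over `[0.5, 2]`, and a
two-condition design with 2 replicates per condition by default
(`replicates = 4` gives the 8-sample layout used in the benchmark
properties, matching a two-cell-line × two-condition × two-replicate
design pooled as one comparison). Counts are Gamma-Poisson with the
Gamma shape set per peak so that normalized signal has SD exactly
`kappa * mean^gamma` (defaults κ = 0.15, γ = 1); when that target is
below the Poisson floor (mean < 1/κ²) the draw degrades to pure Poisson.
A fraction `pi1` of peaks is differential with the treated mean
multiplied by `2^log2fc` (default log2FC = 2, i.e. 4-fold — a strong,
unambiguous spike).

`simulateMarkRegions()` places non-overlapping enhancer/promoter regions
and puts each H3K27ac peak fully inside a region of one mark or in
mark-free background per the target fractions, so realized memberships
are exact truth for overlap counts. `simulateReads()` places fixed-length
reads in peaks versus background at a configurable per-bp enrichment.
`simulateHic()` builds intra-contig `(d+1)^-alpha` distance decay, a
constant trans floor, an *additive* cycle signal decaying with circular
distance (additive so junction trans blocks are strictly positive and the
monotone-decay property is well defined), multiplicative planted bin
biases, and optional Poisson noise.

All generators are pure functions of configuration and seed, and restore
the caller's RNG state.

Deliberate non-realisms: no read-level error or GC model, no
restriction-fragment structure, no TADs/loops beyond smooth distance
decay, mark regions on a single contig, and no between-replicate batch
structure. Passing benchmarks therefore demonstrate correctness of the
*statistics and transformations* under their stated assumptions, not
robustness to every artefact of real sequencing data.

# Benchmark properties and problem sizes

The test suite pins the pipeline to the following properties, at sizes
chosen to characterise behaviour well while keeping the default test run
fast (5,000 peaks × 8 samples; a ~300-bin three-contig Hi-C genome with a
78-bin cycle):

- size factors recovered within 5% (max relative error, 10 seeds) under
  a pure null;
- pure-null call rate at FC > 2 & lfdr < 0.3 at most 5% over 20 seeds
  (observed: ~0), and at most 2% of N(0,1) z-scores below lfdr 0.3 under
  the theoretical null;
- recall ≥ 70% for 4-fold spikes among above-median-mean peaks with
  false-discovery proportion ≤ 0.45 over 10 seeds (observed: ~100% and
  ~0 — the 4-fold effect is large relative to κ = 0.15 dispersion);
- loess trend within 5% of a noiseless proportional SD law over the
  central 80% of the mean range;
- all interval operations exactly equal to quadratic brute-force
  oracles (200 random instances), and cycle assembly equal to an
  explicit index-mapping double loop (100 instances, mixed
  orientations, trans blocks, rotation equivalence);
- ICE: marginal CV ≤ 1e-4, idempotence < 1e-8, planted-bias recovery
  within 1%, exact 2×2 closed form;
- balanced contact versus circular distance monotone
  (Spearman ρ ≤ −0.8) on the embedded-cycle simulation;
- the shipped demo configuration byte-identical across runs and
  matching committed checksums.

# Known limitations

- The empirical-null central matching assumes a unimodal, null-dominated
  z distribution; heavy contamination (> ~30% alternatives) biases
  $\sigma_0$ upward and the fallback to the theoretical null is the only
  guard.
- The SD trend pools conditions, so very large true effects inflate
  their own denominator; the provided within-condition option trades
  robustness for power.
- `compareMatrices()` makes no significance statement; differential
  contact testing is explicitly out of scope.
- The cycles parser handles the single-cycle dialect subset it
  documents; amplicon-graph reconstruction itself belongs to upstream
  tools.
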