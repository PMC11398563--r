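# ecRegulome

Differential chromatin activation and contact-map reassembly for
human–HPV **hybrid ecDNA**.

HPV-positive oropharyngeal cancers can carry extrachromosomal circular
DNA whose cycle interleaves amplified human segments with integrated HPV
genome segments. Studying the regulatory landscape of these elements
poses two computational problems that standard tooling does not cover
well:

- **Low-replicate differential ChIP-seq.** With two biological
  replicates per condition and ~10⁴ peak regions, per-peak *t*-tests
  have almost no power. ecRegulome implements a trend-based statistic:
  RLE (median-of-ratios) size factors restricted to the peaks in every
  sample's top 30% (the tallest peaks are assumed comparable across
  samples), a loess model of standard deviation versus mean fitted with
  all samples pooled as replicates, approximate z-scores

  *z* = (x̄₍trt₎ − x̄₍ctrl₎) / (σ̂(m)·√(1/n₁ + 1/n₂)),

  and an empirical-Bayes local false discovery rate (spline-Poisson
  density estimate, central-matching empirical null). Peaks are called
  at FC > 2 and lfdr < 0.3 and intersected with H3K4me3 (promoter) or
  H3K4me1 (enhancer) regions.

- **Contact maps along a circle.** Given an AmpliconArchitect-style
  cycle (ordered, oriented segments over human chromosomes plus the
  viral contig as an extra chromosome), ecRegulome extracts the
  corresponding submatrices of a binned genome-wide Hi-C matrix —
  including human–viral trans blocks — assembles them into one matrix
  over cycle bins, ICE-balances it, and compares conditions by
  circular-distance stratum.

Because the underlying patient sequencing data are protected, the
package ships seeded generators (`simulatePeakCounts()`,
`simulateMarkRegions()`, `simulateReads()`, `simulateHic()`) that
produce all inputs with recorded ground truth, so every stage is
benchmarked end to end.

## Worked example

```r
library(ecRegulome)

## simulated 8-sample H3K27ac design: 10% of peaks 4-fold up in treated
sim <- simulatePeakCounts(nPeaks = 5000, replicates = 4,
                          pi1 = 0.1, log2fc = 2, seed = 42)
pc <- sim$counts
pc
#> PeakCounts: 5000 peaks x 8 samples (treated n=4, vehicle n=4)
#> assays: counts

subset <- topPercentileSubset(pc, q = 0.30)   # 1178 reference peaks
f <- rleSizeFactors(pc, subset)
round(f, 3)
#> vehicle_r1 vehicle_r2 vehicle_r3 vehicle_r4 treated_r1 treated_r2 treated_r3 treated_r4
#>      1.461      1.510      0.607      1.291      1.055      0.887      1.193      0.518

pc  <- normalizeCounts(pc, f)
res <- callDifferential(pc)          # FC > 2 & lfdr < 0.3, up-regulated
S4Vectors::metadata(res)$null
#> EmpiricalNull (empirical): N(-0.4492, 0.7781^2), pi0 = 0.9182
sum(res$called)
#> [1] 536
head(as.data.frame(res[res$called, ]), 3)
#>        mean_ctrl  mean_trt       fc   log2fc        z         lfdr called
#> peak_2 3015.4222 12332.493 4.088782 2.031671 8.166037 2.052116e-26   TRUE
#> peak_6  383.6781  1516.735 3.945469 1.980197 8.487482 2.073984e-28   TRUE
#> peak_8 9471.9698 33660.905 3.553469 1.829228 2.631314 3.029176e-02   TRUE
```

Against the recorded truth this run recovers every spiked peak
(recall 1.00) with no false discoveries (FDP 0). The null fit absorbs
the global scale of the z-scores, so calls do not depend on the z-score
scaling convention.

```r
## Hi-C: assemble along the cycle, balance, inspect distance decay
hic <- simulateHic(noise = TRUE, seed = 42)
bal <- iceBalance(assembleCycleMatrix(hic$matrix, hic$cycle, hic$segments))
bal
#> AssembledMatrix: 78 cycle bins @ 1000 bp, ICE-balanced (17 iterations, CV 7.63e-06)

head(compareMatrices(bal, bal)$strata, 3)
#>   distance correlation nPairs      meanA      meanB
#> 1        1           1     78 0.07146423 0.07146423
#> 2        2           1     78 0.04757289 0.04757289
#> 3        3           1     78 0.03514087 0.03514087
```

Mean balanced contact falls monotonically with circular distance
(Spearman ρ ≈ −1 on this simulation), the signature of a genuinely
circular element.

`runPipeline(outdir, seed)` orchestrates both branches end to end —
simulate → normalize → call → intersect marks, and simulate Hi-C →
assemble → balance → compare — writing every artifact plus a manifest
with per-file checksums; identical configuration and seed give
byte-identical outputs.

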