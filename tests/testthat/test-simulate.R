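test_that("generators are pure functions of config and seed", {
    a <- simulatePeakCounts(nPeaks = 200, seed = 5)
    b <- simulatePeakCounts(nPeaks = 200, seed = 5)
    expect_identical(SummarizedExperiment::assay(a$counts, "counts"),
                     SummarizedExperiment::assay(b$counts, "counts"))
    expect_identical(a$truth, b$truth)
    h1 <- simulateHic(noise = TRUE, seed = 5)
    h2 <- simulateHic(noise = TRUE, seed = 5)
    expect_identical(contactValues(h1$matrix), contactValues(h2$matrix))
    m1 <- simulateMarkRegions(nK27ac = 100, seed = 5)
    m2 <- simulateMarkRegions(nK27ac = 100, seed = 5)
    expect_identical(as.data.frame(regions(m1$k27ac)),
                     as.data.frame(regions(m2$k27ac)))
    # the generator leaves the global RNG stream untouched
    set.seed(1); before <- runif(1)
    set.seed(1); invisible(simulatePeakCounts(nPeaks = 50, seed = 99))
    expect_identical(runif(1), before)
})

test_that("pi1 = 0 yields no differential flags and pi1 > 0 about n*pi1", {
    sim0 <- simulatePeakCounts(nPeaks = 500, pi1 = 0, seed = 1)
    expect_equal(sum(sim0$truth$isDiff), 0L)
    expect_true(all(sim0$truth$log2fc == 0))
    sim1 <- simulatePeakCounts(nPeaks = 4000, pi1 = 0.1, seed = 2)
    expect_equal(mean(sim1$truth$isDiff), 0.1, tolerance = 0.25)
    expect_true(all(sim1$truth$log2fc[sim1$truth$isDiff] == 2))
})

test_that("simulated counts follow the configured SD-vs-mean law", {
    sim <- simulatePeakCounts(nPeaks = 8000, replicates = 4, pi1 = 0,
                              kappa = 0.15, gamma = 1, seed = 13)
    norm <- sweep(SummarizedExperiment::assay(sim$counts, "counts"), 2,
                  sim$truth$sizeFactors, "/")
    m <- rowMeans(norm)
    s <- apply(norm, 1, sd)
    # bin by mean; pooled SD within a bin tracks kappa * m within 15%
    bins <- cut(log(m), breaks = 8)
    mid <- tapply(m, bins, mean)
    sdEmp <- tapply(s^2, bins, function(v) sqrt(mean(v)))
    relErr <- abs(sdEmp / (0.15 * mid) - 1)
    expect_lt(max(relErr[!is.na(relErr)][2:7]), 0.15)
})

test_that("mark-region truth matches pipeline overlap counts exactly", {
    sim <- simulateMarkRegions(nK27ac = 500, fracK4me1 = 0.6,
                               fracK4me3 = 0.2, seed = 3)
    gotE <- intersectMarks(sim$k27ac, sim$k4me1)
    gotP <- intersectMarks(sim$k27ac, sim$k4me3)
    expect_identical(gotE$count, sum(sim$truth$inK4me1))
    expect_identical(gotP$count, sum(sim$truth$inK4me3))
    # realized fraction within binomial 99% bounds of the target
    ci <- qbinom(c(0.005, 0.995), 500, 0.6)
    expect_gte(gotE$count, ci[1]); expect_lte(gotE$count, ci[2])
    # degenerate fractions
    all1 <- simulateMarkRegions(nK27ac = 80, fracK4me1 = 1, fracK4me3 = 0,
                                seed = 4)
    expect_equal(intersectMarks(all1$k27ac, all1$k4me1)$count, 80L)
    none <- simulateMarkRegions(nK27ac = 80, fracK4me1 = 0, fracK4me3 = 0,
                                seed = 5)
    expect_equal(intersectMarks(none$k27ac, none$k4me1)$count, 0L)
    expect_equal(intersectMarks(none$k27ac, none$k4me3)$count, 0L)
})

test_that("simulated reads land in peaks at the configured enrichment", {
    sim <- simulateMarkRegions(nK27ac = 200, seed = 6)
    rr <- simulateReads(sim$k27ac, depth = 5000, enrichment = Inf, seed = 7)
    # every read overlaps a peak (peaks may overlap, so summed counts
    # can exceed the depth)
    expect_equal(sum(IRanges::overlapsAny(rr$readsets[[1]]@reads,
                                          regions(sim$k27ac))), 5000L)
    expect_gte(sum(countReadsInPeaks(rr$readsets[[1]], sim$k27ac)), 5000L)
    wide <- simulateMarkRegions(nK27ac = 200, peakLength = c(200, 1000),
                                seed = 6)
    rr2 <- simulateReads(wide$k27ac, depth = 100000, enrichment = 10,
                         seed = 8)
    counts2 <- countReadsInPeaks(rr2$readsets[[1]], wide$k27ac)
    expect_gte(cor(counts2, rr2$expected), 0.9)
})

test_that("hic generator plants the documented background and signal", {
    hic <- simulateHic(noise = FALSE, biasRange = c(1, 1),
                       copyAmplitude = 0, seed = 9)
    V <- contactValues(hic$matrix)
    bins <- contactBins(hic$matrix)
    i20 <- which(bins$chrom == "chr20")
    # pure background: exact (d+1)^-1 decay within a contig
    expect_equal(V[i20[1], i20[4]], 100 * 4^-1)
    expect_equal(V[i20[2], i20[2]], 100)
    # constant trans floor
    iH <- which(bins$chrom == "HPV16")
    expect_true(all(V[i20, iH] == 1))
    # with the cycle signal, junction trans blocks are strictly elevated
    hic2 <- simulateHic(noise = FALSE, biasRange = c(1, 1), seed = 9)
    V2 <- contactValues(hic2$matrix)
    bm <- hic2$binMap
    gH <- bm[bm$chrom == "HPV16", "start"]
    g20 <- bm[bm$chrom == "chr20", "start"][1]
    iH1 <- which(bins$chrom == "HPV16" & bins$start == gH[1])
    i201 <- which(bins$chrom == "chr20" & bins$start == g20)
    expect_gt(V2[i201, iH1], 1)
})
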