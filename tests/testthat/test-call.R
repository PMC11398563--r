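test_that("differential calls require both FC and lfdr criteria", {
    sim <- simulatePeakCounts(nPeaks = 2000, replicates = 2, pi1 = 0.1,
                              log2fc = 2, seed = 21)
    pc <- normalizeCounts(sim$counts, rleSizeFactors(
        sim$counts, topPercentileSubset(sim$counts)))
    res <- callDifferential(pc)
    expect_s4_class(res, "DataFrame")
    expect_equal(nrow(res), 2000)
    # call flag is exactly the conjunction of its criteria
    expect_equal(res$called, res$fc > 2 & res$lfdr < 0.3 & res$z > 0)
    # log2fc sign is consistent with z sign (pseudocount preserves order)
    nz <- abs(res$z) > 1e-8
    expect_true(all(sign(res$log2fc[nz]) == sign(res$z[nz])))
    expect_true(all(res$lfdr >= 0 & res$lfdr <= 1))
    # thresholds are honoured when changed
    res4 <- callDifferential(pc, fcThreshold = 4, lfdrThreshold = 0.1)
    expect_true(all(res4$fc[res4$called] > 4))
    expect_true(all(res4$lfdr[res4$called] < 0.1))
    expect_true(all(which(res4$called) %in% which(res$called)))
})

test_that("spiked differential peaks are recovered with controlled error", {
    recalls <- fdps <- numeric(5)
    for (i in seq_len(5)) {
        sim <- simulatePeakCounts(nPeaks = 3000, replicates = 2, pi1 = 0.1,
                                  log2fc = 2, seed = 300 + i)
        pc <- normalizeCounts(sim$counts, rleSizeFactors(
            sim$counts, topPercentileSubset(sim$counts)))
        res <- callDifferential(pc)
        hiMean <- sim$truth$mu > median(sim$truth$mu)
        spiked <- sim$truth$isDiff
        recalls[i] <- mean(res$called[spiked & hiMean])
        fdps[i] <- if (sum(res$called))
            mean(!spiked[res$called]) else 0
    }
    expect_gte(mean(recalls), 0.7)
    expect_lte(mean(fdps), 0.45)
})

test_that("mark intersection honours half-open overlap semantics", {
    called <- PeakSet(GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(101, 1001), c(200, 1100))))
    # mark [150,300) overlaps the first peak; [200,300)+[1100,1200) abut only
    marks <- PeakSet(GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(c(151, 1101), c(300, 1200))),
        mark = "H3K4me1")
    hit <- intersectMarks(called, marks)
    expect_equal(hit$count, 1L)
    expect_equal(unname(GenomicRanges::start(regions(hit$peaks))), 101)
    abut <- PeakSet(GenomicRanges::GRanges(
        "chr1", IRanges::IRanges(201, 300)), mark = "H3K4me1")
    expect_equal(intersectMarks(called, abut)$count, 0L)
})

test_that("intersection and common peaks match brute-force oracles", {
    set.seed(61)
    for (i in 1:50) {
        a <- randomPeakSet(sample(3:25, 1), prefix = "a")
        b <- randomPeakSet(sample(3:25, 1), mark = "H3K4me1", prefix = "b")
        oracleA <- bruteOverlapAny(a, b)
        got <- intersectMarks(a, b)
        expect_equal(got$count, sum(oracleA))
        expect_setequal(names(regions(got$peaks)),
                        names(regions(a))[oracleA])
        cp <- commonPeaks(a, b)
        expect_equal(cp$countA, sum(oracleA))
        expect_equal(cp$countB, sum(bruteOverlapAny(b, a)))
    }
})

test_that("common peaks handle identical and disjoint sets", {
    a <- randomPeakSet(10, chroms = "chr1")
    expect_equal(commonPeaks(a, a)$countA, 10L)
    b <- randomPeakSet(10, chroms = "chr9", prefix = "b")
    expect_equal(commonPeaks(a, b)$countA, 0L)
    expect_equal(length(commonPeaks(a, b)$peaks), 0L)
})

test_that("calledPeaks extracts the called subset by name", {
    sim <- simulateMarkRegions(nK27ac = 50, seed = 8)
    res <- S4Vectors::DataFrame(called = rep(c(TRUE, FALSE), each = 25),
                                row.names = names(regions(sim$k27ac)))
    sub <- calledPeaks(res, sim$k27ac)
    expect_equal(length(sub), 25L)
    expect_true(all(names(regions(sub)) %in% rownames(res)[res$called]))
})
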