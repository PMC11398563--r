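test_that("top-percentile subset keeps each sample's tallest peaks", {
    m <- cbind(s1 = 1:10, s2 = 1:10)
    rownames(m) <- paste0("p", 1:10)
    expect_setequal(topPercentileSubset(m, 0.30), c("p8", "p9", "p10"))
    # identical rankings across samples reduce to the single-sample case
    m2 <- cbind(s1 = 1:10, s2 = 2 * (1:10))
    rownames(m2) <- rownames(m)
    expect_setequal(topPercentileSubset(m2, 0.30), c("p8", "p9", "p10"))
    # ties at the threshold are included
    m3 <- cbind(s1 = c(1, 2, 3, 8, 8, 8, 8, 8, 9, 10))
    rownames(m3) <- rownames(m)
    expect_setequal(topPercentileSubset(cbind(m3, m3), 0.30),
                    paste0("p", 4:10))
})

test_that("anti-correlated samples give the brute-force set intersection", {
    set.seed(5)
    for (i in 1:25) {
        n <- sample(20:60, 1)
        m <- cbind(a = sample(n), b = rev(sample(n)) + runif(n))
        rownames(m) <- paste0("p", seq_len(n))
        got <- topPercentileSubset(m, 0.30)
        k <- ceiling(0.30 * n)
        oracle <- Reduce(intersect, lapply(1:2, function(j) {
            thr <- sort(m[, j], decreasing = TRUE)[k]
            rownames(m)[m[, j] >= thr]
        }))
        expect_setequal(got, oracle)
        expect_lte(length(got), k + 1)  # intersection no larger than a top set
    }
    expect_error(topPercentileSubset(cbind(a = c(10, 1), b = c(1, 10)), 0.3),
                 "increase 'q'")
})

test_that("RLE factors reproduce hand-computed and identity cases", {
    m <- matrix(rep(c(10, 20, 40, 80), 3), ncol = 3)
    rownames(m) <- paste0("p", 1:4)
    expect_equal(unname(rleSizeFactors(m)), rep(1, 3))
    # sample B = 2 x sample A on every peak: factors (2^-1/2, 2^1/2)
    m2 <- cbind(a = c(10, 20, 40), b = c(20, 40, 80))
    rownames(m2) <- paste0("p", 1:3)
    f <- rleSizeFactors(m2)
    expect_equal(unname(f), c(2^-0.5, 2^0.5), tolerance = 1e-12)
    expect_equal(exp(mean(log(f))), 1, tolerance = 1e-12)
    # zero-containing subset peaks are excluded before the geometric mean
    m3 <- rbind(m2, p4 = c(0, 5))
    expect_equal(rleSizeFactors(m3), f)
    expect_error(rleSizeFactors(rbind(p1 = c(0, 1), p2 = c(1, 0))),
                 "positive")
})

test_that("RLE agrees with an independent median-of-ratios implementation", {
    skip_if_not_installed("DESeq2")
    set.seed(77)
    m <- matrix(rnbinom(400 * 6, mu = 200, size = 10), ncol = 6)
    m <- sweep(m, 2, c(0.6, 0.9, 1, 1.2, 1.5, 2), "*")
    rownames(m) <- paste0("p", seq_len(nrow(m)))
    ours <- rleSizeFactors(m)
    ref <- DESeq2::estimateSizeFactorsForMatrix(m)
    ref <- ref / exp(mean(log(ref)))
    # the reference interpolates the even-n median on the log scale,
    # ours on the ratio scale: identical up to that interpolation
    expect_equal(unname(ours), unname(ref), tolerance = 1e-4)
})

test_that("size factors recover simulated truth and are scale-equivariant", {
    sim <- simulatePeakCounts(nPeaks = 3000, replicates = 4, pi1 = 0,
                              seed = 42)
    f <- rleSizeFactors(sim$counts, topPercentileSubset(sim$counts))
    truth <- sim$truth$sizeFactors
    truth <- truth / exp(mean(log(truth)))
    expect_lt(max(abs(f / truth - 1)), 0.05)
    # multiplying one sample by lambda multiplies its factor by lambda
    # (up to geometric-mean renormalization)
    cts <- SummarizedExperiment::assay(sim$counts, "counts")
    lambda <- 3
    cts2 <- cts; cts2[, 1] <- cts2[, 1] * lambda
    f2 <- rleSizeFactors(cts2, topPercentileSubset(cts2))
    adj <- lambda^(1 / ncol(cts))     # renormalization shift
    expect_equal(unname(f2[1] / f[1]), lambda / adj, tolerance = 1e-6)
    expect_equal(unname(f2[-1] / f[-1]), rep(1 / adj, ncol(cts) - 1),
                 tolerance = 1e-6)
})

test_that("normalization divides all peaks and round-trips exactly", {
    sim <- simulatePeakCounts(nPeaks = 100, replicates = 2, seed = 3)
    cts <- SummarizedExperiment::assay(sim$counts, "counts")
    f <- setNames(c(1, 2, 0.5, 4), colnames(cts))
    norm <- normalizeCounts(cts, f)
    expect_equal(norm[, 2], cts[, 2] / 2)
    expect_equal(sweep(norm, 2, f, "*"), cts)          # exact recovery
    expect_equal(normalizeCounts(cts, setNames(rep(1, 4), colnames(cts))),
                 cts)
    expect_error(normalizeCounts(cts, c(1, -1, 1, 1)), "positive")
    # PeakCounts input gains assay + colData column
    pc <- normalizeCounts(sim$counts, f)
    expect_true("normalized" %in% SummarizedExperiment::assayNames(pc))
    expect_equal(SummarizedExperiment::colData(pc)$sizeFactor, unname(f))
})
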