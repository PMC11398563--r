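test_that("segment binning snaps partial bins and reverses on '-'", {
    b <- binsForSegment("chr1", 0, 4000, "+", 1000)
    expect_equal(b$start, c(0, 1000, 2000, 3000))
    expect_equal(binsForSegment("chr1", 0, 4000, "-", 1000)$start,
                 c(3000, 2000, 1000, 0))
    # off-grid ends: partial edge bins are kept
    expect_equal(binsForSegment("chr1", 1500, 3500, "+", 1000)$start,
                 c(1000, 2000, 3000))
})

test_that("a single forward segment extracts the submatrix identically", {
    hic <- simulateHic(noise = FALSE, seed = 1)
    segs <- data.frame(id = 1L, chrom = "chr20", start = 0, end = 4000)
    cyc <- CycleStructure(1L, 2, data.frame(segment = 1L, orientation = "+"))
    am <- assembleCycleMatrix(hic$matrix, cyc, segs)
    expect_equal(contactValues(am), contactValues(hic$matrix)[1:4, 1:4])
    expect_true(all(binMap(am)$found))
})

test_that("assembly matches the index-mapping oracle on random cycles", {
    set.seed(71)
    for (i in 1:40) {
        inst <- randomHicInstance()
        am <- assembleCycleMatrix(inst$cm, inst$cycle, inst$segments)
        expect_equal(contactValues(am),
                     bruteAssemble(inst$cm, inst$cycle, inst$segments))
    }
})

test_that("assembly respects cyclic rotation and full reversal", {
    hic <- simulateHic(noise = FALSE, seed = 2)
    am <- assembleCycleMatrix(hic$matrix, hic$cycle, hic$segments)
    # rotating the circular path start permutes rows/columns accordingly
    path <- hic$cycle@path
    rot <- CycleStructure(1L, hic$cycle@copyCount,
                          path[c(2, 3, 1), ])
    amRot <- assembleCycleMatrix(hic$matrix, rot, hic$segments)
    # positions of segment 1's bins move to the end after rotation
    n1 <- sum(binMap(am)$segment == path$segment[1])
    perm <- c((n1 + 1):nrow(binMap(am)), 1:n1)
    expect_equal(contactValues(amRot),
                 contactValues(am)[perm, perm])
    # reversing every orientation and the path order flips both axes
    rev_path <- path[rev(seq_len(nrow(path))), ]
    rev_path$orientation <- ifelse(rev_path$orientation == "+", "-", "+")
    amRev <- assembleCycleMatrix(hic$matrix,
                                 CycleStructure(1L, 2, rev_path),
                                 hic$segments)
    n <- nrow(binMap(am))
    expect_equal(contactValues(amRev),
                 contactValues(am)[n:1, n:1])
})

test_that("bins absent from the matrix are zero-filled and flagged", {
    hic <- simulateHic(noise = FALSE, seed = 3)
    segs <- rbind(hic$segments,
                  data.frame(id = 9L, chrom = "chrUn",
                             start = 0, end = 3000))
    cyc <- CycleStructure(1L, 2, data.frame(segment = c(1L, 9L),
                                            orientation = c("+", "+")))
    am <- assembleCycleMatrix(hic$matrix, cyc, segs)
    bm <- binMap(am)
    expect_false(any(bm$found[bm$segment == 9]))
    expect_true(all(contactValues(am)[!bm$found, ] == 0))
    # balanced input is rejected
    bal <- iceBalance(assembleCycleMatrix(hic$matrix, hic$cycle,
                                          hic$segments))
    expect_error(compareMatrices(bal, am), "balanced")
})

test_that("ICE reaches the 2x2 closed form and fixed points", {
    res <- iceBalance(matrix(c(0, 2, 2, 0), 2))
    expect_equal(contactValues(res), matrix(c(0, 1, 1, 0), 2))
    expect_equal(biasVector(res), rep(2^-0.5, 2))
    # already-balanced input returns unchanged without iterating
    A <- matrix(c(0.2, 0.8, 0.8, 0.2), 2)
    res2 <- iceBalance(A)
    expect_equal(res2@iterations, 0)
    expect_equal(contactValues(res2), A)
    expect_error(iceBalance(matrix(0, 3, 3)), "zero marginal")
})

test_that("ICE converges, masks empty bins, and is idempotent", {
    set.seed(81)
    for (i in 1:10) {
        n <- sample(20:50, 1)
        A <- matrix(runif(n * n), n, n); A <- A + t(A)
        b <- exp(runif(n, log(0.3), log(3)))
        A <- A * outer(b, b)
        A[2, ] <- 0; A[, 2] <- 0            # a dead bin
        res <- iceBalance(A, tol = 1e-6)
        live <- !res@masked
        marg <- rowSums(contactValues(res))[live]
        expect_lt(sd(marg) / mean(marg), 1e-4)
        expect_equal(mean(marg), 1, tolerance = 1e-6)
        expect_true(res@masked[2] && res@bias[2] == 0)
        # balanced = bias_i * raw_ij * bias_j
        expect_equal(contactValues(res),
                     A * outer(res@bias, res@bias), tolerance = 1e-9)
        # idempotence
        res2 <- iceBalance(contactValues(res), tol = 1e-6)
        expect_lt(max(abs(contactValues(res2) - contactValues(res))), 1e-8)
    }
})

test_that("planted multiplicative biases are recovered by balancing", {
    hic <- simulateHic(noise = FALSE, biasRange = c(0.5, 2), seed = 17)
    hic0 <- simulateHic(noise = FALSE, biasRange = c(1, 1), seed = 17)
    am <- iceBalance(assembleCycleMatrix(hic$matrix, hic$cycle,
                                         hic$segments))
    am0 <- iceBalance(assembleCycleMatrix(hic0$matrix, hic0$cycle,
                                          hic0$segments))
    bins <- contactBins(hic$matrix)
    g <- match(paste(binMap(am)$chrom, binMap(am)$start),
               paste(bins$chrom, bins$start))
    ratio <- biasVector(am) * hic$biases[g] / biasVector(am0)
    expect_lt(max(ratio) / min(ratio) - 1, 0.01)
    # the balanced matrices themselves agree: biases fully removed
    expect_equal(contactValues(am), contactValues(am0), tolerance = 1e-4)
})

test_that("balanced cycle contacts decay with circular distance", {
    hic <- simulateHic(noise = TRUE, seed = 23)
    bal <- iceBalance(assembleCycleMatrix(hic$matrix, hic$cycle,
                                          hic$segments))
    cmp <- compareMatrices(bal, bal)
    st <- cmp$strata
    expect_true(all(cmp$strata$correlation == 1))
    expect_equal(cmp$meanAbsLog2Ratio, 0)
    expect_lte(cor(st$distance, st$meanA, method = "spearman"), -0.8)
})

test_that("matrix comparison separates scaling from decorrelation", {
    hic <- simulateHic(noise = FALSE, seed = 29)
    bal <- iceBalance(assembleCycleMatrix(hic$matrix, hic$cycle,
                                          hic$segments))
    # B = 2A: correlations 1; log-ratio reflects only the pseudocount,
    # and equals exactly 1 with pseudocount 0
    two <- initialize(bal, values = 2 * contactValues(bal),
                      bias = biasVector(bal))
    cmp <- compareMatrices(two, bal, pseudocount = 0)
    expect_true(all(abs(cmp$strata$correlation - 1) < 1e-12))
    expect_equal(cmp$meanAbsLog2Ratio, 1)
    # independent random matrices: stratum correlations near 0
    set.seed(30)
    mkRand <- function() {
        n <- nrow(binMap(bal))
        A <- matrix(runif(n * n), n, n); A <- A + t(A)
        iceBalance(initialize(bal, values = A, balanced = FALSE,
                              bias = numeric(0)))
    }
    cmpR <- compareMatrices(mkRand(), mkRand())
    big <- cmpR$strata$nPairs >= 30
    expect_lt(mean(abs(cmpR$strata$correlation[big])), 0.25)
})
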