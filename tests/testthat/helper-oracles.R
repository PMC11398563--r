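# Brute-force oracles and random-instance generators shared by the unit
# and acceptance tests. Oracles are deliberately quadratic and independent
# of the implementation paths they check.

# random named, sorted PeakSet on a toy genome
randomPeakSet <- function(n, chroms = c("chr1", "chr2", "HPV16"),
                          genomeLength = 100000, maxWidth = 500,
                          mark = "H3K27ac", prefix = "p") {
    chrom <- sample(chroms, n, replace = TRUE)
    s <- sample.int(genomeLength - maxWidth, n, replace = TRUE)
    w <- sample.int(maxWidth, n, replace = TRUE)
    gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(s, s + w - 1))
    names(gr) <- paste0(prefix, "_", seq_len(n))
    PeakSet(gr, mark = mark)
}

randomReadSet <- function(n, chroms = c("chr1", "chr2", "HPV16"),
                          genomeLength = 100000, readLength = 100) {
    chrom <- sample(chroms, n, replace = TRUE)
    s <- sample.int(genomeLength - readLength, n, replace = TRUE)
    ReadSet("rnd", GenomicRanges::GRanges(
        chrom, IRanges::IRanges(s, width = readLength)))
}

# 1-based closed intervals overlap by >= 1 bp
.ovl1 <- function(c1, s1, e1, c2, s2, e2) {
    c1 == c2 & pmax(s1, s2) <= pmin(e1, e2)
}

.grvecs <- function(gr) {
    list(c = as.character(GenomicRanges::seqnames(gr)),
         s = GenomicRanges::start(gr), e = GenomicRanges::end(gr))
}

# all-pairs read-in-peak counting
bruteCountReads <- function(reads, peaks) {
    p <- .grvecs(regions(peaks)); r <- .grvecs(reads@reads)
    out <- integer(length(p$s))
    for (i in seq_along(p$s)) {
        for (j in seq_along(r$s)) {
            if (.ovl1(p$c[i], p$s[i], p$e[i], r$c[j], r$s[j], r$e[j]))
                out[i] <- out[i] + 1L
        }
    }
    names(out) <- names(regions(peaks))
    out
}

# all-pairs overlap membership of set a against set b
bruteOverlapAny <- function(a, b) {
    ga <- .grvecs(regions(a)); gb <- .grvecs(regions(b))
    hit <- logical(length(ga$s))
    for (i in seq_along(ga$s)) {
        for (j in seq_along(gb$s)) {
            if (.ovl1(ga$c[i], ga$s[i], ga$e[i], gb$c[j], gb$s[j], gb$e[j])) {
                hit[i] <- TRUE
                break
            }
        }
    }
    hit
}

# explicit index-mapping construction of an assembled matrix
bruteAssemble <- function(cm, cycle, segments) {
    binSize <- binSize(cm)
    rows <- list()
    for (i in seq_len(nrow(cycle@path))) {
        seg <- segments[segments$id == cycle@path$segment[i], ]
        b <- seq(floor(seg$start / binSize), ceiling(seg$end / binSize) - 1)
        if (cycle@path$orientation[i] == "-") b <- rev(b)
        for (bb in b)
            rows[[length(rows) + 1L]] <- c(seg$chrom, bb * binSize)
    }
    key <- paste(contactBins(cm)$chrom, contactBins(cm)$start)
    idx <- vapply(rows, function(r) {
        m <- match(paste(r[1], as.numeric(r[2])), key)
        if (is.na(m)) 0L else m
    }, integer(1))
    n <- length(idx)
    M <- matrix(0, n, n)
    V <- contactValues(cm)
    for (i in seq_len(n)) {
        for (j in seq_len(n)) {
            if (idx[i] > 0L && idx[j] > 0L)
                M[i, j] <- V[idx[i], idx[j]]
        }
    }
    M
}

# random symmetric contact matrix over a small multi-contig genome,
# plus a random cycle over random segments (mixed orientations)
randomHicInstance <- function(binSize = 1000) {
    contigs <- c(chrA = sample(8:15, 1) * binSize,
                 chrB = sample(5:10, 1) * binSize,
                 HPV16 = sample(3:5, 1) * binSize)
    nb <- contigs / binSize
    bins <- data.frame(chrom = rep(names(contigs), nb),
                       start = unlist(lapply(nb, function(k)
                           (seq_len(k) - 1) * binSize), use.names = FALSE))
    n <- nrow(bins)
    A <- matrix(stats::runif(n * n, 0, 50), n, n)
    A <- (A + t(A)) / 2
    cm <- ContactMatrix(A, bins, binSize)
    nSeg <- sample(2:3, 1)
    segs <- do.call(rbind, lapply(seq_len(nSeg), function(i) {
        chrom <- sample(names(contigs), 1)
        k <- nb[[chrom]]
        a <- sample.int(k, 1) - 1L
        b <- if (a + 1L >= k) k else sample((a + 1L):k, 1)
        # off-grid ends on some segments exercise the snapping rule
        jig <- sample(c(0, 137), 2, replace = TRUE)
        data.frame(id = i, chrom = chrom,
                   start = a * binSize + jig[1],
                   end = b * binSize - jig[2])
    }))
    cyc <- CycleStructure(1L, 2,
        data.frame(segment = seq_len(nSeg),
                   orientation = sample(c("+", "-"), nSeg, replace = TRUE)))
    list(cm = cm, cycle = cyc, segments = segs)
}
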