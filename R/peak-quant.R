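#' @include AllClasses.R
NULL

#' ReadSet: aligned-read footprints for one sample
#'
#' A lightweight container pairing a sample identifier with the genomic
#' footprints of its aligned reads.
#'
#' @slot sample sample identifier.
#' @slot reads `GRanges` of read footprints.
#' @export
setClass("ReadSet", representation(sample = "character", reads = "GRanges"))

#' @rdname ReadSet-class
#' @param sample sample id.
#' @param reads `GRanges` of read footprints.
#' @export
ReadSet <- function(sample, reads) {
    new("ReadSet", sample = as.character(sample), reads = reads)
}

#' @describeIn ReadSet-class number of reads.
#' @param x a ReadSet.
#' @export
setMethod("length", "ReadSet", function(x) length(x@reads))

setMethod("show", "ReadSet", function(object) {
    cat(sprintf("ReadSet '%s': %d reads\n", object@sample, length(object)))
})

## run a block under a temporary RNG state seeded with `seed`
.with_seed <- function(seed, expr) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        old <- get(".Random.seed", envir = globalenv())
        on.exit(assign(".Random.seed", old, envir = globalenv()))
    } else {
        on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(seed)
    expr
}

#' Pool reads across samples with equal weight per sample
#'
#' Builds the pooled input for unbiased peak calling: a union of reads
#' sampled randomly, without replacement and with equal weight, from
#' every sample of the same assay type. Each of the `k` samples
#' contributes `floor(total/k)` reads, the first `total %% k` samples
#' (in input order) one more. A sample with fewer reads than its quota
#' contributes all of them, with a warning. Reproducible given `seed`.
#'
#' @param readsets list of [ReadSet-class] objects.
#' @param total target pooled read count (positive).
#' @param seed RNG seed.
#' @return a [ReadSet-class] with sample id `"pooled"`.
#' @export
poolReads <- function(readsets, total, seed = 1L) {
    if (!length(readsets)) stop("empty readset list")
    stopifnot(all(vapply(readsets, is, logical(1), "ReadSet")))
    total <- as.integer(total)
    if (total <= 0) stop("'total' must be positive")
    k <- length(readsets)
    quota <- rep(total %/% k, k) + (seq_len(k) <= total %% k)
    picked <- .with_seed(seed, lapply(seq_len(k), function(i) {
        rs <- readsets[[i]]
        n <- length(rs)
        if (n < quota[i]) {
            warning(sprintf("sample '%s' has %d reads < quota %d; taking all",
                            rs@sample, n, quota[i]))
            rs@reads
        } else {
            rs@reads[sort(sample.int(n, quota[i]))]
        }
    }))
    ReadSet("pooled", do.call(c, picked))
}

#' Count reads overlapping each peak
#'
#' Per-sample peak quantitation: the count for a peak is the number of
#' reads overlapping it by at least 1 bp; a read overlapping several
#' peaks contributes to each of them. Half-open abutment (a read ending
#' exactly where a peak begins) does not count as overlap.
#'
#' @param reads a [ReadSet-class].
#' @param peaks a [PeakSet-class] (sorted, named).
#' @return named integer vector of counts, one per peak.
#' @examples
#' peaks <- PeakSet(GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200)))
#' rs <- ReadSet("s1", GenomicRanges::GRanges("chr1", IRanges::IRanges(151, 160)))
#' countReadsInPeaks(rs, peaks)
#' @export
countReadsInPeaks <- function(reads, peaks) {
    stopifnot(is(reads, "ReadSet"), is(peaks, "PeakSet"))
    cts <- suppressWarnings(   # disjoint contig sets are a valid 0-overlap
        countOverlaps(peaks@regions, reads@reads, minoverlap = 1L))
    names(cts) <- names(peaks@regions)
    cts
}

#' Select copy-number seed segments for amplicon reconstruction
#'
#' Applies the seed-extraction rule: non-viral segments are kept when
#' their copy number is at least 2.5 copies above the chromosome-arm
#' ploidy; viral segments are kept when copy number is at least 1.
#' Both thresholds are inclusive; input order is preserved and the
#' operation is idempotent.
#'
#' @param segments `data.frame` with columns `chrom`, `start`, `end`,
#'   `cn`, `arm_ploidy`, `is_viral`.
#' @param cnMargin copies above arm ploidy required for non-viral
#'   segments (default 2.5).
#' @param viralMin minimum viral copy number (default 1).
#' @return the kept rows of `segments`.
#' @export
selectSeedSegments <- function(segments, cnMargin = 2.5, viralMin = 1) {
    need <- c("chrom", "start", "end", "cn", "is_viral")
    miss <- setdiff(need, colnames(segments))
    if (length(miss))
        stop("segment table misses column(s): ", paste(miss, collapse = ", "))
    if (!"arm_ploidy" %in% colnames(segments))
        segments$arm_ploidy <- NA_real_
    nv <- !segments$is_viral
    if (any(nv & (is.na(segments$arm_ploidy) | segments$arm_ploidy <= 0)))
        stop("non-viral segment without a positive arm_ploidy")
    keep <- ifelse(segments$is_viral,
                   segments$cn >= viralMin,
                   segments$cn >= segments$arm_ploidy + cnMargin)
    segments[keep, , drop = FALSE]
}
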