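#' @include diff-trend.R diff-lfdr.R
NULL

#' Call differentially activated peaks
#'
#' The full differential-activation statistic: condition means of
#' normalized signal, fold change with a pseudocount, trend-modelled
#' z-score ([zScores()]) and empirical-Bayes lfdr ([localFdr()]). A peak
#' is called when `fc > fcThreshold` and `lfdr < lfdrThreshold` (both
#' paper defaults: 2 and 0.3) and, for `direction = "up"`, `z > 0`. The
#' full table is returned regardless of call status.
#'
#' @param x a [PeakCounts-class] carrying a `"normalized"` assay (see
#'   [normalizeCounts()]).
#' @param trend optional [MeanSDTrend-class]; fitted with `span` when
#'   absent.
#' @param treated,control condition labels.
#' @param fcThreshold fold-change threshold (default 2).
#' @param lfdrThreshold lfdr threshold (default 0.3).
#' @param pseudocount added to both condition means before the ratio
#'   (default 1).
#' @param direction `"up"` (treated over control; default) or `"any"`.
#' @param nullMode,bins,df passed to [localFdr()].
#' @param span loess span when `trend` is fitted here.
#' @param scaleBySampleSize passed to [zScores()].
#' @return a [S4Vectors::DataFrame] with one row per peak and columns
#'   `mean_ctrl`, `mean_trt`, `fc`, `log2fc`, `z`, `lfdr`, `called`;
#'   the fitted null is attached as `metadata(x)$null` and the trend as
#'   `metadata(x)$trend`.
#' @export
callDifferential <- function(x, trend = NULL,
                             treated = "treated", control = "vehicle",
                             fcThreshold = 2, lfdrThreshold = 0.3,
                             pseudocount = 1,
                             direction = c("up", "any"),
                             nullMode = c("empirical", "theoretical"),
                             bins = 120L, df = 7L, span = 0.5,
                             scaleBySampleSize = TRUE) {
    direction <- match.arg(direction)
    nullMode <- match.arg(nullMode)
    stopifnot(is(x, "PeakCounts"))
    norm <- .normalized_matrix(x)
    condition <- colData(x)$condition
    if (is.null(trend)) trend <- fitSDTrend(x, span = span)
    meanC <- rowMeans(norm[, condition == control, drop = FALSE])
    meanT <- rowMeans(norm[, condition == treated, drop = FALSE])
    fc <- (meanT + pseudocount) / (meanC + pseudocount)
    z <- zScores(x, trend, treated = treated, control = control,
                 scaleBySampleSize = scaleBySampleSize)
    lf <- localFdr(z, nullMode = nullMode, bins = bins, df = df)
    called <- fc > fcThreshold & lf$lfdr < lfdrThreshold
    if (direction == "up") called <- called & z > 0
    res <- DataFrame(mean_ctrl = meanC, mean_trt = meanT,
                     fc = fc, log2fc = log2(fc), z = unname(z),
                     lfdr = lf$lfdr, called = called,
                     row.names = rownames(norm))
    metadata(res)$null <- lf$null
    metadata(res)$trend <- trend
    res
}

#' Restrict called peaks to promoter/enhancer mark regions
#'
#' Keeps the called peaks that overlap (by at least 1 bp) any interval
#' of a mark region set — e.g. differentially activated H3K27ac peaks
#' within H3K4me3-defined promoters or H3K4me1-defined enhancers.
#'
#' @param called a [PeakSet-class] of called peaks.
#' @param marks a [PeakSet-class] of mark regions (same assembly).
#' @return list with `peaks` (the overlapping subset of `called`) and
#'   `count`.
#' @export
intersectMarks <- function(called, marks) {
    stopifnot(is(called, "PeakSet"), is(marks, "PeakSet"))
    hit <- suppressWarnings(   # disjoint contig sets are a valid 0-overlap
        IRanges::overlapsAny(called@regions, marks@regions, minoverlap = 1L))
    list(peaks = called[which(hit)], count = sum(hit))
}

#' Peaks common to two peak sets
#'
#' A peak of `a` is common when it overlaps (>= 1 bp) any peak of `b`.
#' The overlap relation is symmetric but the counts need not be (several
#' peaks of one set can hit a single peak of the other), so both
#' directions are reported.
#'
#' @param a,b [PeakSet-class] objects on the same assembly.
#' @return list with `peaks` (subset of `a` overlapping `b`), `countA`
#'   (peaks of `a` overlapping `b`) and `countB` (peaks of `b`
#'   overlapping `a`).
#' @export
commonPeaks <- function(a, b) {
    stopifnot(is(a, "PeakSet"), is(b, "PeakSet"))
    hitA <- suppressWarnings(
        IRanges::overlapsAny(a@regions, b@regions, minoverlap = 1L))
    hitB <- suppressWarnings(
        IRanges::overlapsAny(b@regions, a@regions, minoverlap = 1L))
    list(peaks = a[which(hitA)], countA = sum(hitA), countB = sum(hitB))
}

#' Extract the called peaks of a differential result as a PeakSet
#'
#' @param result table from [callDifferential()].
#' @param peaks the [PeakSet-class] the counts were quantified on.
#' @return a [PeakSet-class] restricted to called peaks.
#' @export
calledPeaks <- function(result, peaks) {
    stopifnot(is(peaks, "PeakSet"))
    nm <- rownames(result)[result$called]
    peaks[which(names(peaks@regions) %in% nm)]
}
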