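#' @include AllClasses.R
NULL

.counts_matrix <- function(x) {
    if (is(x, "PeakCounts")) assay(x, "counts") else as.matrix(x)
}

#' Peaks in the top percentile of every sample
#'
#' Normalization rests on the assumption that the tallest peaks are
#' comparable across samples, so the size-factor reference set is the
#' intersection, across samples, of each sample's top-`q` fraction of
#' peaks by raw count. The per-sample threshold is the `k`-th largest
#' value with `k = ceiling(q * n_peaks)`; ties at the threshold are
#' included, so a sample's top set can exceed `k` peaks.
#'
#' @param x a [PeakCounts-class] or counts matrix.
#' @param q fraction of peaks to keep per sample, in (0, 1); default 0.30.
#' @return character vector of peak names in every sample's top set,
#'   in row order.
#' @examples
#' m <- cbind(s1 = 1:10, s2 = 1:10)
#' rownames(m) <- paste0("p", 1:10)
#' topPercentileSubset(m, q = 0.30)   # p8, p9, p10
#' @export
topPercentileSubset <- function(x, q = 0.30) {
    if (q <= 0 || q >= 1) stop("'q' must be in (0, 1)")
    cts <- .counts_matrix(x)
    if (is.null(rownames(cts)))
        rownames(cts) <- paste0("peak_", seq_len(nrow(cts)))
    k <- max(1L, as.integer(ceiling(q * nrow(cts))))
    inTop <- apply(cts, 2L, function(v) v >= sort(v, decreasing = TRUE)[k])
    keep <- rowSums(inTop) == ncol(cts)
    if (!any(keep))
        stop("no peak is in the top ", q * 100,
             "-percentile of every sample; increase 'q'")
    rownames(cts)[keep]
}

#' RLE (median-of-ratios) size factors on a peak subset
#'
#' Relative Log Expression normalization restricted to a reference peak
#' subset (typically [topPercentileSubset()]): each peak's reference is
#' its geometric mean across samples; a sample's raw factor is the
#' median, over subset peaks, of its counts divided by the reference.
#' Subset peaks with a zero in any sample are excluded before the
#' geometric mean. Factors are rescaled so their geometric mean is 1.
#'
#' @param x a [PeakCounts-class] or counts matrix.
#' @param subset peak names forming the reference set (default: all
#'   peaks).
#' @return named numeric vector of positive size factors, geometric
#'   mean 1.
#' @export
rleSizeFactors <- function(x, subset = NULL) {
    cts <- .counts_matrix(x)
    if (is.null(rownames(cts)))
        rownames(cts) <- paste0("peak_", seq_len(nrow(cts)))
    if (is.null(subset)) subset <- rownames(cts)
    miss <- setdiff(subset, rownames(cts))
    if (length(miss)) stop("unknown peak in subset: ", miss[1L])
    sub <- cts[subset, , drop = FALSE]
    sub <- sub[rowSums(sub <= 0) == 0L, , drop = FALSE]
    if (!nrow(sub))
        stop("no subset peak has positive counts in every sample")
    logGeo <- rowMeans(log(sub))
    raw <- apply(sub, 2L, function(v) stats::median(exp(log(v) - logGeo)))
    f <- raw / exp(mean(log(raw)))
    names(f) <- colnames(cts)
    f
}

#' Apply size factors to all peaks
#'
#' Divides every sample's raw counts by its size factor — the factors
#' are estimated on the reference subset but applied to all peak
#' regions. For a [PeakCounts-class] input, the result carries a new
#' `"normalized"` assay and a `sizeFactor` column in `colData`;
#' a matrix input yields the normalized matrix.
#'
#' @param x a [PeakCounts-class] or counts matrix.
#' @param factors named positive size factors, one per sample.
#' @return same class as `x`, normalized.
#' @export
normalizeCounts <- function(x, factors) {
    cts <- .counts_matrix(x)
    if (length(factors) != ncol(cts))
        stop("need one size factor per sample")
    if (any(factors <= 0)) stop("size factors must be positive")
    if (!is.null(names(factors)) && !is.null(colnames(cts)))
        factors <- factors[colnames(cts)]
    norm <- sweep(cts, 2L, factors, "/")
    if (is(x, "PeakCounts")) {
        assays(x)$normalized <- norm
        colData(x)$sizeFactor <- unname(factors)
        x
    } else norm
}

.normalized_matrix <- function(x) {
    if (is(x, "PeakCounts")) {
        if (!"normalized" %in% assayNames(x))
            stop("no 'normalized' assay; run normalizeCounts() first")
        assay(x, "normalized")
    } else as.matrix(x)
}
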