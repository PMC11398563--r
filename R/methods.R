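#' @include AllGenerics.R
NULL

## -- PeakSet ----------------------------------------------------------------

#' @rdname accessors
#' @export
setMethod("regions", "PeakSet", function(x) x@regions)

#' @rdname accessors
#' @export
setMethod("mark", "PeakSet", function(x) x@mark)

#' @describeIn PeakSet-class number of peaks.
#' @param x a PeakSet.
#' @export
setMethod("length", "PeakSet", function(x) length(x@regions))

#' @describeIn PeakSet-class subset by index or peak name.
#' @param i index or names.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "PeakSet", function(x, i, j, ..., drop = TRUE) {
    initialize(x, regions = x@regions[i])
})

setMethod("show", "PeakSet", function(object) {
    cat(sprintf("PeakSet of %d %s peak(s) on %d contig(s)\n",
                length(object), object@mark,
                length(unique(as.character(seqnames(object@regions))))))
    if (length(object)) show(utils::head(object@regions, 3))
})

## -- PeakCounts -------------------------------------------------------------

setMethod("show", "PeakCounts", function(object) {
    cat(sprintf("PeakCounts: %d peaks x %d samples (%s)\n",
                nrow(object), ncol(object),
                paste(sprintf("%s n=%d",
                              names(table(colData(object)$condition)),
                              as.integer(table(colData(object)$condition))),
                      collapse = ", ")))
    cat("assays:", paste(assayNames(object), collapse = ", "), "\n")
})

## -- MeanSDTrend ------------------------------------------------------------

#' Evaluate a fitted SD-versus-mean trend
#'
#' Linear interpolation between grid points, constant extrapolation
#' outside the fitted mean range, floored at the trend's `sdFloor`.
#'
#' @param trend a [MeanSDTrend-class].
#' @param m mean-signal values at which to evaluate.
#' @return fitted standard deviations, same length as `m`.
#' @export
evalTrend <- function(trend, m) {
    stopifnot(is(trend, "MeanSDTrend"))
    y <- stats::approx(trend@grid, trend@fitted, xout = m, rule = 2)$y
    pmax(y, trend@sdFloor)
}

setMethod("show", "MeanSDTrend", function(object) {
    cat(sprintf(
        "MeanSDTrend: loess span %.2f over means [%.4g, %.4g], floor %.3g\n",
        object@span, min(object@grid), max(object@grid), object@sdFloor))
})

## -- EmpiricalNull ----------------------------------------------------------

setMethod("show", "EmpiricalNull", function(object) {
    cat(sprintf("EmpiricalNull (%s): N(%.4f, %.4f^2), pi0 = %.4f\n",
                object@mode, object@delta, object@sigma0, object@pi0))
})

## -- CycleStructure ---------------------------------------------------------

setMethod("length", "CycleStructure", function(x) nrow(x@path))

setMethod("show", "CycleStructure", function(object) {
    cat(sprintf("CycleStructure %d: copy count %.2f, path %s\n",
                object@cycleId, object@copyCount,
                paste0(object@path$segment, object@path$orientation,
                       collapse = ",")))
})

## -- ContactMatrix / AssembledMatrix ----------------------------------------

#' @rdname accessors
#' @export
setMethod("contactValues", "ContactMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("contactValues", "AssembledMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("contactValues", "IceResult", function(x) x@values)

#' @rdname accessors
#' @export
setMethod("contactBins", "ContactMatrix", function(x) x@bins)

#' @rdname accessors
#' @export
setMethod("binSize", "ContactMatrix", function(x) x@binSize)

#' @rdname accessors
#' @export
setMethod("binSize", "AssembledMatrix", function(x) x@binSize)

#' @rdname accessors
#' @export
setMethod("isBalanced", "ContactMatrix", function(x) x@balanced)

#' @rdname accessors
#' @export
setMethod("isBalanced", "AssembledMatrix", function(x) x@balanced)

#' @rdname accessors
#' @export
setMethod("biasVector", "ContactMatrix", function(x) x@bias)

#' @rdname accessors
#' @export
setMethod("biasVector", "AssembledMatrix", function(x) x@bias)

#' @rdname accessors
#' @export
setMethod("biasVector", "IceResult", function(x) x@bias)

#' @rdname accessors
#' @export
setMethod("binMap", "AssembledMatrix", function(x) x@binMap)

setMethod("show", "ContactMatrix", function(object) {
    cat(sprintf("ContactMatrix: %d bins @ %g bp (%s), %s\n",
                nrow(object@bins), object@binSize,
                paste(unique(object@bins$chrom), collapse = ", "),
                if (object@balanced) "balanced" else "raw"))
})

setMethod("show", "AssembledMatrix", function(object) {
    cat(sprintf("AssembledMatrix: %d cycle bins @ %g bp, %s\n",
                nrow(object@binMap), object@binSize,
                if (object@balanced)
                    sprintf("ICE-balanced (%d iterations, CV %.2e)",
                            as.integer(object@iceIterations), object@iceCV)
                else "raw"))
})

setMethod("show", "IceResult", function(object) {
    cat(sprintf(
        "IceResult: %d bins (%d masked), %d iteration(s), marginal CV %.2e\n",
        nrow(object@values), sum(object@masked),
        as.integer(object@iterations), object@cv))
})
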