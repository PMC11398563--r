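#' @include AllClasses.R
NULL

#' Accessors for ecRegulome classes
#'
#' `regions()` and `mark()` access a [PeakSet-class]; `contactValues()`,
#' `contactBins()`, `binSize()`, `isBalanced()` and `biasVector()` access
#' contact matrices; `binMap()` accesses an [AssembledMatrix-class].
#'
#' @param x an ecRegulome object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("regions", function(x) standardGeneric("regions"))

#' @rdname accessors
#' @export
setGeneric("mark", function(x) standardGeneric("mark"))

#' @rdname accessors
#' @export
setGeneric("contactValues", function(x) standardGeneric("contactValues"))

#' @rdname accessors
#' @export
setGeneric("contactBins", function(x) standardGeneric("contactBins"))

#' @rdname accessors
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))

#' @rdname accessors
#' @export
setGeneric("isBalanced", function(x) standardGeneric("isBalanced"))

#' @rdname accessors
#' @export
setGeneric("biasVector", function(x) standardGeneric("biasVector"))

#' @rdname accessors
#' @export
setGeneric("binMap", function(x) standardGeneric("binMap"))

#' ICE matrix balancing
#'
#' Iterative correction of a symmetric non-negative contact matrix:
#' rows and columns are repeatedly divided by their marginals (rescaled to
#' mean 1 over unmasked bins each iteration) until the coefficient of
#' variation of the unmasked marginals drops to `tol` or `maxIter` is
#' reached. Bins whose raw marginal is zero are masked and excluded.
#'
#' @param x a symmetric non-negative `matrix` or an
#'   [AssembledMatrix-class].
#' @param tol convergence tolerance on the marginal CV (default `1e-5`).
#' @param maxIter iteration cap (default 200).
#' @return for a `matrix`, an [IceResult-class]; for an
#'   `AssembledMatrix`, the balanced `AssembledMatrix` (bias stored,
#'   `balanced = TRUE`, diagnostics in `iceIterations` / `iceCV`).
#' @examples
#' res <- iceBalance(matrix(c(0, 2, 2, 0), 2))
#' contactValues(res)   # [[0,1],[1,0]]
#' @export
setGeneric("iceBalance", function(x, tol = 1e-5, maxIter = 200L)
    standardGeneric("iceBalance"))

#' Write pipeline results to TSV
#'
#' Writes a differential-result table, or an assembled matrix plus its
#' bin map, as deterministic tab-separated text: fixed column order,
#' floating-point values at 6 significant digits, rows ordered by peak
#' name (results) or cycle bin position (matrices). Writing the same
#' object twice yields byte-identical files.
#'
#' @param x a differential result (`DataFrame`/`data.frame` as returned
#'   by [callDifferential()]) or an [AssembledMatrix-class].
#' @param path output file. For an `AssembledMatrix`, `path` receives
#'   the matrix and a sibling file (suffix `_bins.tsv`) the bin map,
#'   unless `binsPath` is given.
#' @param ... further arguments (`binsPath` for assembled matrices).
#' @return invisibly, the path(s) written.
#' @export
setGeneric("writeResults", function(x, path, ...)
    standardGeneric("writeResults"))
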