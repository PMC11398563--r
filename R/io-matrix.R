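#' @include AllClasses.R
NULL

#' Read a dense contact matrix with its bin table
#'
#' Reads a dense tab-separated matrix of contact counts (no header, no
#' row names) together with a sidecar bin table (`chrom`, `start` header;
#' 0-based bin starts). The matrix must be square, non-negative, match
#' the bin table's length, and be symmetric to within `1e-9` (it is then
#' symmetrised exactly). The result is unbalanced with no bias vector.
#'
#' @param matrixPath dense matrix TSV.
#' @param binsPath bin table TSV.
#' @param binSize bin size in bp (default: inferred from the bin table
#'   as the smallest start difference within a contig).
#' @return a [ContactMatrix-class].
#' @export
readContactMatrix <- function(matrixPath, binsPath, binSize = NULL) {
    vals <- as.matrix(utils::read.table(matrixPath, sep = "\t",
                                        header = FALSE,
                                        colClasses = "numeric"))
    dimnames(vals) <- NULL
    bins <- utils::read.table(binsPath, sep = "\t", header = TRUE,
                              colClasses = c("character", "numeric"))
    if (!all(c("chrom", "start") %in% colnames(bins)))
        stop("bins table needs 'chrom' and 'start' columns")
    if (nrow(vals) != ncol(vals))
        stop("contact matrix must be square, got ",
             nrow(vals), "x", ncol(vals))
    if (nrow(vals) != nrow(bins))
        stop("matrix dimension (", nrow(vals),
             ") does not match bin table (", nrow(bins), " bins)")
    if (any(vals < 0)) stop("negative contact values")
    if (nrow(vals) && max(abs(vals - t(vals))) > 1e-9)
        stop("contact matrix is not symmetric (tolerance 1e-9)")
    vals <- (vals + t(vals)) / 2
    if (is.null(binSize)) {
        d <- unlist(lapply(split(bins$start, bins$chrom),
                           function(s) diff(sort(s))))
        binSize <- if (length(d)) min(d) else 1
    }
    ContactMatrix(vals, bins, binSize)
}

#' Write a contact matrix and its bin table
#'
#' Full-precision writer (`%.17g`), so `readContactMatrix()` of the
#' written pair reproduces the object's values to better than `1e-12`.
#'
#' @param x a [ContactMatrix-class].
#' @param matrixPath output matrix TSV.
#' @param binsPath output bin-table TSV.
#' @return invisibly, the two paths.
#' @export
writeContactMatrix <- function(x, matrixPath, binsPath) {
    stopifnot(is(x, "ContactMatrix"))
    lines <- apply(x@values, 1L,
                   function(r) paste(sprintf("%.17g", r), collapse = "\t"))
    writeLines(lines, matrixPath)
    writeLines(c("chrom\tstart",
                 sprintf("%s\t%d", x@bins$chrom, as.integer(x@bins$start))),
               binsPath)
    invisible(c(matrixPath, binsPath))
}
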