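#' @include AllClasses.R
NULL

#' Circular bin distance on a cycle of n bins
#'
#' The minimum of clockwise and counter-clockwise bin separation.
#'
#' @param i,j cycle positions (1-based).
#' @param n number of cycle bins.
#' @return integer distances.
#' @export
circularDistance <- function(i, j, n) {
    d <- abs(i - j)
    pmin(d, n - d)
}

#' Compare two balanced assembled matrices
#'
#' A descriptive (not inferential) comparison of two conditions along
#' the same cycle: per circular-distance stratum, the Pearson
#' correlation of off-diagonal entries at that distance; globally, the
#' log2 ratio matrix and the mean absolute log2 ratio over unmasked
#' entries (with a pseudocount guarding zeros). Comparing a matrix with
#' itself gives stratum correlations of exactly 1 and a mean absolute
#' log2 ratio of 0.
#'
#' @param a,b balanced [AssembledMatrix-class] objects with identical
#'   bin maps and bin size.
#' @param pseudocount added to both matrices in the ratio (default 1).
#' @return list with `strata` (`data.frame`: `distance`, `correlation`,
#'   `nPairs`, `meanA`, `meanB`), `log2Ratio` (matrix) and
#'   `meanAbsLog2Ratio`.
#' @export
compareMatrices <- function(a, b, pseudocount = 1) {
    stopifnot(is(a, "AssembledMatrix"), is(b, "AssembledMatrix"))
    if (!a@balanced || !b@balanced)
        stop("both matrices must be ICE-balanced")
    keyCols <- c("segment", "chrom", "start", "orientation")
    if (a@binSize != b@binSize ||
        !identical(a@binMap[, keyCols], b@binMap[, keyCols]))
        stop("bin maps differ; matrices are not comparable")
    n <- nrow(a@binMap)
    live <- a@bias > 0 & b@bias > 0
    ij <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
    keep <- live[ij[, 1L]] & live[ij[, 2L]]
    ij <- ij[keep, , drop = FALSE]
    d <- circularDistance(ij[, 1L], ij[, 2L], n)
    va <- a@values[ij]
    vb <- b@values[ij]
    strata <- lapply(sort(unique(d)), function(dd) {
        sel <- d == dd
        x <- va[sel]; y <- vb[sel]
        r <- if (isTRUE(all.equal(x, y))) 1
             else if (stats::sd(x) == 0 || stats::sd(y) == 0) NA_real_
             else stats::cor(x, y)
        data.frame(distance = dd, correlation = r, nPairs = sum(sel),
                   meanA = mean(x), meanB = mean(y))
    })
    strata <- do.call(rbind, strata)
    lr <- log2((a@values + pseudocount) / (b@values + pseudocount))
    lr[!live, ] <- NA_real_
    lr[, !live] <- NA_real_
    list(strata = strata, log2Ratio = lr,
         meanAbsLog2Ratio = mean(abs(log2((va + pseudocount) /
                                          (vb + pseudocount)))))
}
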