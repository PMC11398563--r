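#' @include AllClasses.R
NULL

#' Genome bins covered by an oriented segment
#'
#' Maps a segment (0-based half-open coordinates) onto the bin grid:
#' bins `floor(start/b) ... ceiling(end/b) - 1`, so partial edge bins
#' are included. A `'-'` orientation reverses the bin order.
#'
#' @param chrom contig name.
#' @param start,end 0-based half-open segment coordinates (bp).
#' @param orientation `"+"` or `"-"`.
#' @param binSize bin size in bp.
#' @return `data.frame` with columns `chrom`, `start` (genome bin start,
#'   0-based), in cycle traversal order.
#' @examples
#' binsForSegment("chr1", 1500, 3500, "+", 1000)   # bins 1000, 2000, 3000
#' @export
binsForSegment <- function(chrom, start, end, orientation = "+",
                           binSize = 1000) {
    stopifnot(binSize > 0, start < end,
              orientation %in% c("+", "-"))
    b <- seq(floor(start / binSize), ceiling(end / binSize) - 1L)
    if (orientation == "-") b <- rev(b)
    data.frame(chrom = chrom, start = b * binSize)
}

.cycle_bin_map <- function(cycle, segments, binSize) {
    stopifnot(is(cycle, "CycleStructure"))
    if (!nrow(cycle@path)) stop("empty cycle path")
    pieces <- lapply(seq_len(nrow(cycle@path)), function(i) {
        sid <- cycle@path$segment[i]
        row <- segments[segments$id == sid, , drop = FALSE]
        if (nrow(row) != 1L)
            stop("cycle references undefined segment id ", sid)
        bm <- binsForSegment(row$chrom, row$start, row$end,
                             cycle@path$orientation[i], binSize)
        bm$segment <- sid
        bm$orientation <- cycle@path$orientation[i]
        bm
    })
    bm <- do.call(rbind, pieces)
    bm$pos <- seq_len(nrow(bm))
    bm[, c("pos", "segment", "chrom", "start", "orientation")]
}

#' Assemble a contact matrix along an ecDNA cycle
#'
#' Extracts, from the genome-wide binned matrix, the submatrix over the
#' cycle's bins in cycle order and orientation — including trans blocks
#' between segments on different contigs (e.g. human-viral junctions).
#' Genome bins absent from the source matrix are zero-filled and flagged
#' (`found = FALSE` in the bin map) rather than erroring. A genome bin
#' shared by adjacent segments appears once per occurrence.
#'
#' @param cm an unbalanced [ContactMatrix-class].
#' @param cycle a [CycleStructure-class].
#' @param segments segment table (`id`, `chrom`, `start`, `end`;
#'   0-based half-open), as from [readCycles()].
#' @return an [AssembledMatrix-class] (unbalanced).
#' @export
assembleCycleMatrix <- function(cm, cycle, segments) {
    stopifnot(is(cm, "ContactMatrix"))
    if (cm@balanced)
        stop("assemble from the raw matrix; balance after assembly")
    bm <- .cycle_bin_map(cycle, segments, cm@binSize)
    key <- paste(cm@bins$chrom, cm@bins$start)
    idx <- match(paste(bm$chrom, bm$start), key)
    bm$found <- !is.na(idx)
    n <- nrow(bm)
    vals <- matrix(0, n, n)
    ok <- which(bm$found)
    vals[ok, ok] <- cm@values[idx[ok], idx[ok]]
    new("AssembledMatrix", values = vals, binMap = bm,
        binSize = cm@binSize, balanced = FALSE, bias = numeric(0))
}
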