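#' @include AllClasses.R
NULL

## Internal strict BED3+ reader. rtracklayer's importer is deliberately not
## used here: the contract requires line-numbered parse errors and hard
## failure on start >= end, which a bespoke reader can guarantee.

#' Read a BED3/BED4 file of peak regions
#'
#' Reads tab-separated BED (0-based, half-open) into a [PeakSet-class].
#' Column 4 supplies peak names; when absent, peaks are auto-named
#' `peak_1 ... peak_n` in position-sorted order. Track/browser/comment
#' lines are skipped. Malformed lines and intervals with `start >= end`
#' raise errors naming the offending line; duplicate names are an error,
#' never silently de-duplicated.
#'
#' @param path BED file path.
#' @param mark mark label for the resulting [PeakSet-class].
#' @return a [PeakSet-class].
#' @examples
#' f <- tempfile(fileext = ".bed")
#' writeLines("chr1\t100\t200", f)
#' readPeakBed(f, mark = "H3K4me1")
#' @export
readPeakBed <- function(path, mark = "H3K27ac") {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
    idx <- which(keep)
    if (!length(idx))
        return(PeakSet(GRanges(), mark = mark))
    fields <- strsplit(lines[idx], "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 3L))
        stop(sprintf("malformed BED line %d: fewer than 3 tab-separated fields",
                     idx[which(nf < 3L)[1L]]))
    chrom <- vapply(fields, `[`, character(1), 1L)
    s <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
    e <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
    bad <- which(is.na(s) | is.na(e) | chrom == "")
    if (length(bad))
        stop(sprintf("malformed BED line %d: non-numeric coordinates",
                     idx[bad[1L]]))
    bad <- which(s < 0 | s >= e)
    if (length(bad))
        stop(sprintf("invalid interval at line %d: need 0 <= start < end",
                     idx[bad[1L]]))
    nm <- vapply(seq_along(fields), function(i)
        if (nf[i] >= 4L) fields[[i]][4L] else NA_character_, character(1))
    gr <- GRanges(chrom, IRanges(s + 1, e))     # BED -> 1-based closed
    # sort first so auto-names reflect position order
    o <- order(as.character(seqnames(gr)), start(gr), end(gr))
    gr <- gr[o]; nm <- nm[o]
    nm[is.na(nm)] <- paste0("peak_", which(is.na(nm)))
    if (anyDuplicated(nm))
        stop("duplicate peak name in ", path, ": ",
             nm[anyDuplicated(nm)][1L])
    names(gr) <- nm
    PeakSet(gr, mark = mark)
}

#' Write a PeakSet as BED4
#'
#' Inverse of [readPeakBed()]: coordinates are converted back to the
#' 0-based half-open BED convention, one peak per line in the set's
#' sorted order. `readPeakBed(writePeakBed(x))` is the identity on valid
#' peak sets.
#'
#' @param x a [PeakSet-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writePeakBed <- function(x, path) {
    stopifnot(is(x, "PeakSet"))
    gr <- x@regions
    lines <- sprintf("%s\t%d\t%d\t%s",
                     as.character(seqnames(gr)),
                     start(gr) - 1L, end(gr), names(gr))
    writeLines(lines, path)
    invisible(path)
}
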