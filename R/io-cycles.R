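#' @include AllClasses.R
NULL

#' Read an AmpliconArchitect-style cycles file
#'
#' Parses the cycles text dialect: `Segment <id> <chrom> <start> <end>`
#' lines (1-based, inclusive coordinates) followed by
#' `Cycle=<n>;Copy_count=<c>;Segments=<id><+|->,...` lines. Segment
#' coordinates are converted to the package's 0-based half-open
#' convention; path order and orientations are preserved. The segment id
#' `0` is the source/sink sentinel of linear paths: leading/trailing `0`
#' entries are dropped, an interior `0` is an error, as is a reference to
#' an undefined segment.
#'
#' @param path cycles file path.
#' @return a list with `segments` (a `data.frame` of `id`, `chrom`,
#'   `start`, `end`; 0-based half-open) and `cycles` (a list of
#'   [CycleStructure-class]).
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines(c("Segment\t1\tchr20\t45300000\t45310000",
#'              "Cycle=1;Copy_count=4.1;Segments=1+"), f)
#' readCycles(f)$cycles[[1]]
#' @export
readCycles <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- trimws(readLines(path))
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    segLines <- grep("^Segment\\b", lines, value = TRUE)
    cycLines <- grep("^Cycle=", lines, value = TRUE)

    segs <- data.frame(id = integer(0), chrom = character(0),
                       start = numeric(0), end = numeric(0))
    if (length(segLines)) {
        parts <- strsplit(segLines, "[ \t]+")
        if (any(lengths(parts) < 5L))
            stop("malformed Segment line: need 'Segment <id> <chrom> <start> <end>'")
        segs <- data.frame(
            id    = as.integer(vapply(parts, `[`, character(1), 2L)),
            chrom = vapply(parts, `[`, character(1), 3L),
            start = as.numeric(vapply(parts, `[`, character(1), 4L)) - 1,
            end   = as.numeric(vapply(parts, `[`, character(1), 5L)))
        if (any(is.na(segs$id)) || any(is.na(segs$start)) || any(is.na(segs$end)))
            stop("malformed Segment line: non-numeric field")
        if (anyDuplicated(segs$id))
            stop("duplicate segment id: ", segs$id[anyDuplicated(segs$id)][1L])
        if (any(segs$start >= segs$end))
            stop("segment with start >= end: id ",
                 segs$id[which(segs$start >= segs$end)[1L]])
    }

    cycles <- lapply(cycLines, function(ln) {
        kv <- strsplit(strsplit(ln, ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
        keys <- vapply(kv, `[`, character(1), 1L)
        vals <- vapply(kv, `[`, character(1), 2L)
        need <- c("Cycle", "Copy_count", "Segments")
        if (!all(need %in% keys))
            stop("malformed Cycle line (need Cycle=, Copy_count=, Segments=): ", ln)
        toks <- strsplit(vals[match("Segments", keys)], ",", fixed = TRUE)[[1]]
        ok <- grepl("^[0-9]+[+-]$", toks)
        if (!all(ok)) stop("malformed segment token '", toks[!ok][1L], "' in: ", ln)
        id  <- as.integer(sub("[+-]$", "", toks))
        ori <- substr(toks, nchar(toks), nchar(toks))
        # source/sink sentinel: allowed only at the ends of a path
        zero <- which(id == 0L)
        if (length(zero)) {
            if (!all(zero %in% c(1L, length(id))))
                stop("segment id 0 (source/sink sentinel) at path interior: ", ln)
            id  <- id[-zero]
            ori <- ori[-zero]
        }
        if (!length(id)) stop("empty cycle path: ", ln)
        undef <- setdiff(id, segs$id)
        if (length(undef))
            stop("cycle references undefined segment id ", undef[1L])
        CycleStructure(cycleId = as.integer(vals[match("Cycle", keys)]),
                       copyCount = as.numeric(vals[match("Copy_count", keys)]),
                       path = data.frame(segment = id, orientation = ori))
    })
    list(segments = segs, cycles = cycles)
}

#' Write segments and cycles in the cycles-file dialect
#'
#' Inverse of [readCycles()]: segment coordinates are converted back to
#' the dialect's 1-based inclusive convention, so a parsed file is
#' reproduced verbatim (modulo whitespace normalisation).
#'
#' @param segments segment table as returned by [readCycles()].
#' @param cycles list of [CycleStructure-class].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
writeCycles <- function(segments, cycles, path) {
    segLines <- sprintf("Segment\t%d\t%s\t%d\t%d",
                        as.integer(segments$id), segments$chrom,
                        as.integer(segments$start + 1),
                        as.integer(segments$end))
    cycLines <- vapply(cycles, function(cy) {
        sprintf("Cycle=%d;Copy_count=%g;Segments=%s",
                cy@cycleId, cy@copyCount,
                paste0(cy@path$segment, cy@path$orientation, collapse = ","))
    }, character(1))
    writeLines(c(segLines, cycLines), path)
    invisible(path)
}
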