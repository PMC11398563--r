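#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importFrom IRanges IRanges
#' @importFrom GenomicRanges GRanges seqnames start end width strand
#'   countOverlaps findOverlaps
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays
#'   assays<- assayNames colData colData<- rowData
NULL

.VALID_MARKS <- c("H3K27ac", "H3K4me1", "H3K4me3", "ATAC")

## ---------------------------------------------------------------------------
## PeakSet: a named, position-sorted set of peak regions carrying a mark label
## ---------------------------------------------------------------------------

#' PeakSet: peak regions for one chromatin mark
#'
#' A `PeakSet` holds the peak regions called for a single chromatin mark
#' (H3K27ac, H3K4me1, H3K4me3 or ATAC) as a named, position-sorted
#' [GenomicRanges::GRanges]. Peak names are unique and serve as row keys
#' in count tables and differential-result tables.
#'
#' Coordinates follow the GRanges convention (1-based, closed); BED input
#' and output is converted at the file boundary.
#'
#' @slot mark single mark label, one of `"H3K27ac"`, `"H3K4me1"`,
#'   `"H3K4me3"`, `"ATAC"`.
#' @slot regions named `GRanges`, sorted by (chromosome, start).
#'
#' @examples
#' gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(101, 501), c(200, 700)))
#' ps <- PeakSet(gr, mark = "H3K27ac")
#' length(ps)
#' @export
setClass("PeakSet", representation(mark = "character", regions = "GRanges"))

setValidity("PeakSet", function(object) {
    msg <- NULL
    if (length(object@mark) != 1L || !object@mark %in% .VALID_MARKS)
        msg <- c(msg, sprintf("'mark' must be one of %s",
                              paste(.VALID_MARKS, collapse = ", ")))
    gr <- object@regions
    if (length(gr)) {
        nm <- names(gr)
        if (is.null(nm) || any(is.na(nm)) || any(nm == ""))
            msg <- c(msg, "all peaks must be named")
        else if (anyDuplicated(nm))
            msg <- c(msg, sprintf("duplicate peak names (e.g. '%s')",
                                  nm[anyDuplicated(nm)][1L]))
        o <- order(as.character(seqnames(gr)), start(gr), end(gr))
        if (!identical(o, seq_along(gr)))
            msg <- c(msg, "peaks must be sorted by (chrom, start)")
    }
    if (is.null(msg)) TRUE else msg
})

#' Construct a PeakSet
#'
#' Sorts the regions by (chromosome, start), auto-names unnamed regions
#' `peak_1 ... peak_n` in sorted order, and validates uniqueness.
#'
#' @param regions a `GRanges` of peak regions.
#' @param mark mark label.
#' @return a [PeakSet-class] object.
#' @export
PeakSet <- function(regions, mark = "H3K27ac") {
    stopifnot(is(regions, "GRanges"))
    GenomeInfoDb::seqlevels(regions) <-
        sort(GenomeInfoDb::seqlevels(regions))   # determinism across inputs
    o <- order(as.character(seqnames(regions)), start(regions), end(regions))
    regions <- regions[o]
    if (length(regions) && is.null(names(regions)))
        names(regions) <- paste0("peak_", seq_along(regions))
    new("PeakSet", mark = mark, regions = regions)
}

## ---------------------------------------------------------------------------
## PeakCounts: raw per-peak, per-sample read counts + design metadata
## ---------------------------------------------------------------------------

#' PeakCounts: per-peak read counts across samples
#'
#' Extends [SummarizedExperiment::SummarizedExperiment]. The `"counts"`
#' assay holds raw (non-negative) read counts, rows are peaks, columns are
#' samples; `colData` carries the two-condition design (`condition`,
#' `replicate`). After [normalizeCounts()] a `"normalized"` assay and a
#' `sizeFactor` column are added.
#'
#' @examples
#' counts <- matrix(rpois(20, 50), nrow = 5,
#'                  dimnames = list(paste0("peak_", 1:5), NULL))
#' pc <- PeakCounts(counts,
#'                  condition = c("vehicle", "vehicle", "treated", "treated"),
#'                  replicate = c(1, 2, 1, 2))
#' @export
setClass("PeakCounts", contains = "SummarizedExperiment")

setValidity("PeakCounts", function(object) {
    msg <- NULL
    if (!"counts" %in% assayNames(object))
        msg <- c(msg, "assay 'counts' is required")
    else {
        cts <- assay(object, "counts")
        if (any(is.na(cts)) || any(cts < 0))
            msg <- c(msg, "counts must be non-negative and non-missing")
    }
    if (ncol(object) < 2L)
        msg <- c(msg, "at least 2 samples are required")
    cd <- colData(object)
    if (!all(c("condition", "replicate") %in% colnames(cd)))
        msg <- c(msg, "colData must contain 'condition' and 'replicate'")
    else if (any(is.na(cd$condition)))
        msg <- c(msg, "every sample must have a condition")
    if (is.null(rownames(object)) || anyDuplicated(rownames(object)))
        msg <- c(msg, "peaks (rownames) must be uniquely named")
    if (is.null(msg)) TRUE else msg
})

#' Construct a PeakCounts object
#'
#' @param counts peaks x samples matrix of raw counts; rownames are peak
#'   names (auto-generated when absent).
#' @param condition per-sample condition labels (e.g. `"vehicle"` /
#'   `"treated"`).
#' @param replicate per-sample replicate index.
#' @param sampleIds optional sample identifiers (default
#'   `<condition>_r<replicate>`).
#' @return a [PeakCounts-class] object.
#' @export
PeakCounts <- function(counts, condition, replicate,
                       sampleIds = paste0(condition, "_r", replicate)) {
    counts <- as.matrix(counts)
    if (is.null(rownames(counts)))
        rownames(counts) <- paste0("peak_", seq_len(nrow(counts)))
    colnames(counts) <- sampleIds
    cd <- DataFrame(condition = as.character(condition),
                    replicate = as.integer(replicate),
                    row.names = sampleIds)
    se <- SummarizedExperiment(assays = list(counts = counts), colData = cd)
    new("PeakCounts", se)
}

## ---------------------------------------------------------------------------
## MeanSDTrend: the loess-fitted SD-versus-mean function
## ---------------------------------------------------------------------------

#' MeanSDTrend: fitted standard deviation as a function of mean signal
#'
#' Stores the loess fit of per-peak standard deviation against per-peak
#' mean (all samples pooled as replicates), tabulated on an equispaced
#' grid. Evaluation ([evalTrend()]) interpolates linearly between grid
#' points, extrapolates as a constant beyond the fitted mean range, and
#' never returns less than `sdFloor`.
#'
#' @slot grid mean-signal grid (ascending).
#' @slot fitted fitted SD at each grid point (already floored).
#' @slot sdFloor positive lower clamp on the fitted SD.
#' @slot span loess span used for the fit.
#' @export
setClass("MeanSDTrend",
         representation(grid = "numeric", fitted = "numeric",
                        sdFloor = "numeric", span = "numeric"))

setValidity("MeanSDTrend", function(object) {
    msg <- NULL
    if (length(object@grid) != length(object@fitted))
        msg <- c(msg, "grid and fitted lengths differ")
    if (is.unsorted(object@grid, strictly = FALSE))
        msg <- c(msg, "grid must be ascending")
    if (length(object@sdFloor) != 1L || object@sdFloor <= 0)
        msg <- c(msg, "sdFloor must be a single positive number")
    if (any(object@fitted < object@sdFloor - 1e-12))
        msg <- c(msg, "fitted values must respect the floor")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## EmpiricalNull: the fitted null component of the z-score mixture
## ---------------------------------------------------------------------------

#' EmpiricalNull: fitted null distribution of the z-score mixture
#'
#' The null component N(delta, sigma0^2) with mass pi0, fitted by central
#' matching on the central half of the z distribution (or fixed at the
#' theoretical N(0,1) null).
#'
#' @slot delta null center.
#' @slot sigma0 null scale (> 0).
#' @slot pi0 null proportion in (0, 1].
#' @slot mode `"empirical"` or `"theoretical"`.
#' @export
setClass("EmpiricalNull",
         representation(delta = "numeric", sigma0 = "numeric",
                        pi0 = "numeric", mode = "character"))

setValidity("EmpiricalNull", function(object) {
    msg <- NULL
    if (object@sigma0 <= 0) msg <- c(msg, "sigma0 must be positive")
    if (object@pi0 <= 0 || object@pi0 > 1) msg <- c(msg, "pi0 must be in (0, 1]")
    if (!object@mode %in% c("empirical", "theoretical"))
        msg <- c(msg, "mode must be 'empirical' or 'theoretical'")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## CycleStructure: ordered, oriented segments of a circular ecDNA
## ---------------------------------------------------------------------------

#' CycleStructure: an ordered, oriented circular ecDNA path
#'
#' A cycle is an ordered list of oriented genomic segments whose circular
#' concatenation (last segment adjoining the first) describes one ecDNA
#' species. Segment coordinates live in a separate segment table
#' (0-based, half-open, as in the bins table of a contact matrix); the
#' path references segments by id.
#'
#' @slot cycleId integer cycle identifier.
#' @slot copyCount estimated copy count of the cycle (positive).
#' @slot path `data.frame` with columns `segment` (integer id) and
#'   `orientation` (`"+"` or `"-"`), in cycle order.
#' @export
setClass("CycleStructure",
         representation(cycleId = "integer", copyCount = "numeric",
                        path = "data.frame"))

setValidity("CycleStructure", function(object) {
    msg <- NULL
    p <- object@path
    if (nrow(p) == 0L) msg <- c(msg, "path must be non-empty")
    if (!all(c("segment", "orientation") %in% colnames(p)))
        msg <- c(msg, "path needs columns 'segment' and 'orientation'")
    else if (!all(p$orientation %in% c("+", "-")))
        msg <- c(msg, "orientations must be '+' or '-'")
    if (length(object@copyCount) != 1L || object@copyCount <= 0)
        msg <- c(msg, "copyCount must be a single positive number")
    if (is.null(msg)) TRUE else msg
})

#' @rdname CycleStructure-class
#' @param cycleId integer id.
#' @param copyCount positive copy count.
#' @param path data.frame with `segment`, `orientation` columns.
#' @export
CycleStructure <- function(cycleId, copyCount, path) {
    path$segment <- as.integer(path$segment)
    path$orientation <- as.character(path$orientation)
    new("CycleStructure", cycleId = as.integer(cycleId),
        copyCount = as.numeric(copyCount),
        path = path[, c("segment", "orientation")])
}

## ---------------------------------------------------------------------------
## ContactMatrix: a binned genome-wide symmetric contact matrix
## ---------------------------------------------------------------------------

#' ContactMatrix: binned symmetric Hi-C contact counts
#'
#' Genome-wide binned contact counts at a fixed bin size. The bin table
#' gives each bin's contig and 0-based start coordinate; rows/columns of
#' the value matrix are in bin-table order. A freshly read or simulated
#' matrix is unbalanced (`balanced = FALSE`, empty bias).
#'
#' @slot values symmetric non-negative matrix, bins x bins.
#' @slot bins `data.frame` with columns `chrom`, `start` (0-based bp).
#' @slot binSize bin size in bp.
#' @slot balanced logical flag; `TRUE` after ICE balancing.
#' @slot bias per-bin balancing weights (length 0 when unbalanced;
#'   masked bins carry 0).
#' @export
setClass("ContactMatrix",
         representation(values = "matrix", bins = "data.frame",
                        binSize = "numeric", balanced = "logical",
                        bias = "numeric"))

.check_contact_core <- function(values, nbins, balanced, bias) {
    msg <- NULL
    if (nrow(values) != ncol(values)) msg <- c(msg, "matrix must be square")
    if (nrow(values) != nbins)
        msg <- c(msg, "matrix dimension must match the bin table")
    if (any(is.na(values)) || any(values < 0))
        msg <- c(msg, "contact values must be non-negative and non-missing")
    else if (nrow(values) && max(abs(values - t(values))) > 1e-9)
        msg <- c(msg, "matrix must be symmetric (tolerance 1e-9)")
    if (balanced && length(bias) != nbins)
        msg <- c(msg, "balanced matrix must carry a per-bin bias vector")
    msg
}

setValidity("ContactMatrix", function(object) {
    msg <- .check_contact_core(object@values, nrow(object@bins),
                               object@balanced, object@bias)
    if (length(object@binSize) != 1L || object@binSize <= 0)
        msg <- c(msg, "binSize must be a single positive number")
    if (!all(c("chrom", "start") %in% colnames(object@bins)))
        msg <- c(msg, "bins need columns 'chrom' and 'start'")
    if (is.null(msg)) TRUE else msg
})

#' @rdname ContactMatrix-class
#' @param values symmetric matrix of counts.
#' @param bins bin table (`chrom`, `start`).
#' @param binSize bin size in bp.
#' @param balanced logical.
#' @param bias per-bin weights (balanced matrices only).
#' @export
ContactMatrix <- function(values, bins, binSize, balanced = FALSE,
                          bias = numeric(0)) {
    values <- as.matrix(values)
    dimnames(values) <- NULL
    bins <- data.frame(chrom = as.character(bins$chrom),
                       start = as.numeric(bins$start))
    new("ContactMatrix", values = values, bins = bins,
        binSize = as.numeric(binSize), balanced = balanced, bias = bias)
}

## ---------------------------------------------------------------------------
## AssembledMatrix: the contact matrix re-indexed along a cycle
## ---------------------------------------------------------------------------

#' AssembledMatrix: contact matrix assembled along an ecDNA cycle
#'
#' The genome-wide matrix re-indexed along the cycle's ordered, oriented
#' bins. `binMap` records, for each cycle bin position, the originating
#' segment, contig, genome bin start and orientation, and whether the bin
#' was present in the source matrix (`found`; absent bins are zero-filled).
#' The same genome bin may occur at several cycle positions (junction bins
#' and multi-visit cycles).
#'
#' @slot values symmetric matrix over cycle bin positions.
#' @slot binMap `data.frame` with columns `pos`, `segment`, `chrom`,
#'   `start`, `orientation`, `found`.
#' @slot binSize bin size in bp.
#' @slot balanced logical; `TRUE` after [iceBalance()].
#' @slot bias per-bin weights when balanced (masked bins carry 0).
#' @slot iceIterations,iceCV diagnostics of the last balancing run.
#' @export
setClass("AssembledMatrix",
         representation(values = "matrix", binMap = "data.frame",
                        binSize = "numeric", balanced = "logical",
                        bias = "numeric", iceIterations = "numeric",
                        iceCV = "numeric"),
         prototype(iceIterations = NA_real_, iceCV = NA_real_))

setValidity("AssembledMatrix", function(object) {
    msg <- .check_contact_core(object@values, nrow(object@binMap),
                               object@balanced, object@bias)
    need <- c("pos", "segment", "chrom", "start", "orientation", "found")
    if (!all(need %in% colnames(object@binMap)))
        msg <- c(msg, "binMap misses required columns")
    if (is.null(msg)) TRUE else msg
})

## ---------------------------------------------------------------------------
## IceResult: output of ICE balancing on a bare matrix
## ---------------------------------------------------------------------------

#' IceResult: ICE-balanced matrix with bias vector and diagnostics
#'
#' Balanced values satisfy `balanced[i, j] = bias[i] * raw[i, j] * bias[j]`
#' with the global scale chosen so the mean marginal over unmasked bins is
#' 1. Bins with zero raw marginal are masked (`bias = 0`, rows/columns
#' zero).
#'
#' @slot values balanced symmetric matrix.
#' @slot bias per-bin multiplicative weights (0 for masked bins).
#' @slot masked logical per-bin mask.
#' @slot iterations iterations used.
#' @slot cv final coefficient of variation of unmasked marginals.
#' @export
setClass("IceResult",
         representation(values = "matrix", bias = "numeric",
                        masked = "logical", iterations = "numeric",
                        cv = "numeric"))
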