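#' @include simulate.R diff-call.R io-results.R io-bed.R io-matrix.R io-cycles.R
NULL

#' Default pipeline configuration
#'
#' All stage parameters in one flat list, with the study thresholds as
#' defaults (top 30-percentile reference subset, FC > 2, lfdr < 0.3) and
#' desk-scale simulation sizes. Unknown keys passed to [runPipeline()]
#' are rejected.
#'
#' @return named list of parameters.
#' @export
demoConfig <- function() {
    list(
        q = 0.30, fcThreshold = 2, lfdrThreshold = 0.3,
        span = 0.5, nullMode = "empirical", pseudocount = 1,
        direction = "up",
        nPeaks = 2000L, replicates = 2L,
        meanRange = c(100, 10000), factorRange = c(0.5, 2),
        kappa = 0.15, gamma = 1, pi1 = 0.1, log2fc = 2,
        markGenomeLength = 5e7, nK4me1 = 800L, nK4me3 = 500L,
        fracK4me1 = 0.4, fracK4me3 = 0.3,
        binSize = 1000, iceTol = 1e-5, iceMaxIter = 200L,
        hicNoise = TRUE, hicPseudocount = 1
    )
}

#' Run the demonstration pipeline end to end
#'
#' Orchestrates simulate -> normalize -> differential calling ->
#' mark intersection, and simulate Hi-C -> cycle assembly -> ICE
#' balancing -> condition comparison, writing every artifact plus a run
#' manifest (package version, configuration, derived seeds, and an MD5
#' checksum per output file) to `outdir`. The top-level `seed` fans out
#' to fixed per-stage seeds (`seed + 1` peaks, `+ 2` marks, `+ 3` / `+ 4`
#' the two Hi-C conditions), so identical `config` and `seed` give
#' byte-identical outputs.
#'
#' @param outdir output directory (created if needed).
#' @param seed top-level seed (default 1).
#' @param config parameter list as from [demoConfig()]; partial lists
#'   are completed with defaults, unknown keys are an error.
#' @return invisibly, a list with the differential table, intersection
#'   counts, matrix comparison, and the manifest.
#' @export
runPipeline <- function(outdir, seed = 1L, config = demoConfig()) {
    defaults <- demoConfig()
    unknown <- setdiff(names(config), names(defaults))
    if (length(unknown))
        stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    cfg <- utils::modifyList(defaults, config)
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    pth <- function(f) file.path(outdir, f)
    seeds <- c(peaks = seed + 1L, marks = seed + 2L,
               hicVehicle = seed + 3L, hicTreated = seed + 4L)

    ## -- differential branch ------------------------------------------------
    sim <- simulatePeakCounts(nPeaks = cfg$nPeaks,
                              replicates = cfg$replicates,
                              meanRange = cfg$meanRange,
                              factorRange = cfg$factorRange,
                              kappa = cfg$kappa, gamma = cfg$gamma,
                              pi1 = cfg$pi1, log2fc = cfg$log2fc,
                              seed = seeds[["peaks"]])
    pc <- sim$counts
    .write_tsv_det(data.frame(peak = rownames(pc),
                              as.data.frame(assay(pc, "counts"))),
                   pth("counts.tsv"))
    .write_tsv_det(data.frame(sample = colnames(pc),
                              condition = colData(pc)$condition,
                              replicate = colData(pc)$replicate),
                   pth("samples.tsv"))
    subset <- topPercentileSubset(pc, q = cfg$q)
    factors <- rleSizeFactors(pc, subset)
    pc <- normalizeCounts(pc, factors)
    res <- callDifferential(pc, fcThreshold = cfg$fcThreshold,
                            lfdrThreshold = cfg$lfdrThreshold,
                            pseudocount = cfg$pseudocount,
                            direction = cfg$direction,
                            nullMode = cfg$nullMode, span = cfg$span)
    writeResults(res, pth("differential.tsv"))

    ## -- mark intersection --------------------------------------------------
    marks <- simulateMarkRegions(genomeLength = cfg$markGenomeLength,
                                 nK4me1 = cfg$nK4me1, nK4me3 = cfg$nK4me3,
                                 nK27ac = cfg$nPeaks,
                                 fracK4me1 = cfg$fracK4me1,
                                 fracK4me3 = cfg$fracK4me3,
                                 seed = seeds[["marks"]])
    writePeakBed(marks$k27ac, pth("k27ac.bed"))
    writePeakBed(marks$k4me1, pth("k4me1.bed"))
    writePeakBed(marks$k4me3, pth("k4me3.bed"))
    # identify counted peaks with the simulated K27ac regions: the i-th
    # counted peak is the i-th K27ac region in sorted order
    universe <- marks$k27ac
    names(universe@regions) <- rownames(res)
    calledSet <- calledPeaks(res, universe)
    inEnh <- intersectMarks(calledSet, marks$k4me1)
    inProm <- intersectMarks(calledSet, marks$k4me3)
    writePeakBed(inEnh$peaks, pth("called_in_k4me1.bed"))
    writePeakBed(inProm$peaks, pth("called_in_k4me3.bed"))

    ## -- Hi-C branch --------------------------------------------------------
    hicV <- simulateHic(noise = cfg$hicNoise, binSize = cfg$binSize,
                        seed = seeds[["hicVehicle"]])
    hicT <- simulateHic(noise = cfg$hicNoise, binSize = cfg$binSize,
                        seed = seeds[["hicTreated"]])
    writeContactMatrix(hicV$matrix, pth("hic_vehicle.tsv"),
                       pth("hic_bins.tsv"))
    writeCycles(hicV$segments, list(hicV$cycle), pth("cycles.txt"))
    balV <- iceBalance(assembleCycleMatrix(hicV$matrix, hicV$cycle,
                                           hicV$segments),
                       tol = cfg$iceTol, maxIter = cfg$iceMaxIter)
    balT <- iceBalance(assembleCycleMatrix(hicT$matrix, hicT$cycle,
                                           hicT$segments),
                       tol = cfg$iceTol, maxIter = cfg$iceMaxIter)
    writeResults(balV, pth("ecdna_matrix_vehicle.tsv"))
    writeResults(balT, pth("ecdna_matrix_treated.tsv"))
    cmp <- compareMatrices(balV, balT, pseudocount = cfg$hicPseudocount)
    .write_tsv_det(cmp$strata, pth("hic_comparison_strata.tsv"))

    ## -- manifest -----------------------------------------------------------
    # radix = C-locale byte order, independent of the session's collation
    files <- sort(setdiff(list.files(outdir), "manifest.json"),
                  method = "radix")
    manifest <- list(
        package = "ecRegulome",
        version = as.character(utils::packageVersion("ecRegulome")),
        seed = seed, seeds = as.list(seeds), config = cfg,
        nCalled = sum(res$called),
        calledInK4me1 = inEnh$count, calledInK4me3 = inProm$count,
        meanAbsLog2Ratio = signif(cmp$meanAbsLog2Ratio, 6),
        checksums = as.list(tools::md5sum(file.path(outdir, files)))
    )
    names(manifest$checksums) <- files
    jsonlite::write_json(manifest, pth("manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
    invisible(list(result = res, truth = sim$truth,
                   intersections = list(k4me1 = inEnh$count,
                                        k4me3 = inProm$count),
                   comparison = cmp, manifest = manifest))
}
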