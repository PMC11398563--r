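#' @include peak-quant.R hic-assemble.R hic-compare.R
NULL

#' Simulate a peak count table with recorded ground truth
#'
#' Emulates the H3K27ac quantitation input: a two-condition, replicated
#' design (default 2 conditions x 2 replicates; use `replicates = 4`
#' for an 8-sample design) with sample-specific size factors, a smooth
#' SD-versus-mean trend and an optional fraction of truly differential
#' peaks. Baseline means are log-uniform over `meanRange`; true size
#' factors log-uniform over `factorRange`; counts are Gamma-Poisson with
#' the Gamma shape chosen so the normalized signal has
#' `SD = kappa * mean^gamma` exactly (pure Poisson where that SD is
#' below the Poisson floor). Differential peaks (fraction `pi1`) have
#' their treated-condition mean multiplied by `2^log2fc`.
#'
#' @param nPeaks number of peaks (default 5000).
#' @param replicates replicates per condition (default 2).
#' @param conditions two condition labels (control first).
#' @param meanRange baseline-mean range (log-uniform; default
#'   `c(100, 10000)`).
#' @param factorRange true size-factor range (log-uniform; default
#'   `c(0.5, 2)`).
#' @param kappa,gamma SD model `s = kappa * m^gamma` (defaults 0.15, 1).
#' @param pi1 differential fraction in `[0, 1)` (default 0).
#' @param log2fc true log2 fold change of differential peaks (default 2).
#' @param seed RNG seed.
#' @return list with `counts` (a [PeakCounts-class]) and `truth`
#'   (`sizeFactors`, `isDiff`, `log2fc`, `mu`, `kappa`, `gamma`).
#' @export
simulatePeakCounts <- function(nPeaks = 5000L, replicates = 2L,
                               conditions = c("vehicle", "treated"),
                               meanRange = c(100, 10000),
                               factorRange = c(0.5, 2),
                               kappa = 0.15, gamma = 1,
                               pi1 = 0, log2fc = 2, seed = 1L) {
    stopifnot(length(conditions) == 2L, replicates >= 1L,
              kappa > 0, pi1 >= 0, pi1 < 1)
    .with_seed(seed, {
        nS <- 2L * replicates
        cond <- rep(conditions, each = replicates)
        repl <- rep(seq_len(replicates), 2L)
        f <- exp(stats::runif(nS, log(factorRange[1]), log(factorRange[2])))
        mu <- exp(stats::runif(nPeaks, log(meanRange[1]), log(meanRange[2])))
        isDiff <- stats::runif(nPeaks) < pi1
        lfc <- ifelse(isDiff, log2fc, 0)
        cts <- matrix(0, nPeaks, nS)
        for (s in seq_len(nS)) {
            muC <- mu * 2^(lfc * (cond[s] == conditions[2L]))
            me <- muC * f[s]
            vTarget <- f[s]^2 * kappa^2 * muC^(2 * gamma)
            excess <- vTarget - me
            nb <- excess > 0
            cts[nb, s] <- stats::rnbinom(sum(nb), mu = me[nb],
                                         size = me[nb]^2 / excess[nb])
            cts[!nb, s] <- stats::rpois(sum(!nb), me[!nb])
        }
        rownames(cts) <- paste0("peak_", seq_len(nPeaks))
        list(counts = PeakCounts(cts, condition = cond, replicate = repl),
             truth = list(sizeFactors = f, isDiff = isDiff, log2fc = lfc,
                          mu = mu, kappa = kappa, gamma = gamma))
    })
}

#' Simulate promoter/enhancer mark regions and H3K27ac peaks
#'
#' Places non-overlapping H3K4me1 (enhancer) and H3K4me3 (promoter)
#' regions uniformly on a single contig, then places H3K27ac peaks
#' either fully inside a region of one mark or in mark-free background,
#' according to the target fractions. Realized memberships are recorded
#' as ground truth, so overlap counts downstream can be scored exactly.
#'
#' @param genomeLength contig length in bp.
#' @param chrom contig name.
#' @param nK4me1,nK4me3 region counts.
#' @param regionLength min/max region length (uniform).
#' @param nK27ac H3K27ac peak count.
#' @param peakLength min/max K27ac peak length (uniform; must fit in the
#'   smallest region).
#' @param fracK4me1,fracK4me3 target fractions of K27ac peaks inside
#'   each mark (sum must be <= 1).
#' @param seed RNG seed.
#' @param maxTries rejection-sampling cap before an infeasible-packing
#'   error.
#' @return list with `k27ac`, `k4me1`, `k4me3` ([PeakSet-class]) and
#'   `truth` (`data.frame`: `peak`, `inK4me1`, `inK4me3`).
#' @export
simulateMarkRegions <- function(genomeLength = 5e6, chrom = "chr1",
                                nK4me1 = 300L, nK4me3 = 200L,
                                regionLength = c(1500, 4000),
                                nK27ac = 500L, peakLength = c(400, 800),
                                fracK4me1 = 0.4, fracK4me3 = 0.3,
                                seed = 1L, maxTries = 10000L) {
    stopifnot(fracK4me1 >= 0, fracK4me3 >= 0, fracK4me1 + fracK4me3 <= 1,
              peakLength[2] <= regionLength[1])
    .with_seed(seed, {
        placed <- matrix(numeric(0), ncol = 2)   # 0-based half-open
        placeRegions <- function(nReg) {
            out <- matrix(0, nReg, 2)
            for (i in seq_len(nReg)) {
                for (t in seq_len(maxTries)) {
                    w <- round(stats::runif(1, regionLength[1], regionLength[2]))
                    s <- floor(stats::runif(1, 0, genomeLength - w))
                    if (!nrow(placed) ||
                        all(s + w <= placed[, 1] | s >= placed[, 2])) {
                        out[i, ] <- c(s, s + w)
                        placed <<- rbind(placed, c(s, s + w))
                        break
                    }
                    if (t == maxTries)
                        stop("infeasible packing: cannot place region ", i)
                }
            }
            out
        }
        me1 <- placeRegions(nK4me1)
        me3 <- placeRegions(nK4me3)
        cat1 <- sample(c("me1", "me3", "bg"), nK27ac, replace = TRUE,
                       prob = c(fracK4me1, fracK4me3,
                                1 - fracK4me1 - fracK4me3))
        peaks <- matrix(0, nK27ac, 2)
        for (i in seq_len(nK27ac)) {
            w <- round(stats::runif(1, peakLength[1], peakLength[2]))
            if (cat1[i] == "bg") {
                ok <- FALSE
                for (t in seq_len(maxTries)) {
                    s <- floor(stats::runif(1, 0, genomeLength - w))
                    if (all(s + w <= placed[, 1] | s >= placed[, 2])) {
                        ok <- TRUE; break
                    }
                }
                if (!ok) stop("infeasible packing: background peak ", i)
            } else {
                reg <- if (cat1[i] == "me1") me1 else me3
                r <- reg[sample.int(nrow(reg), 1L), ]
                s <- floor(stats::runif(1, r[1], r[2] - w))
            }
            peaks[i, ] <- c(s, s + w)
        }
        mkSet <- function(m, mark, prefix) {
            gr <- GRanges(chrom, IRanges(m[, 1] + 1, m[, 2]))
            names(gr) <- paste0(prefix, "_", seq_len(nrow(m)))
            PeakSet(gr, mark = mark)
        }
        k27 <- mkSet(peaks, "H3K27ac", "k27ac")
        truth <- data.frame(peak = paste0("k27ac_", seq_len(nK27ac)),
                            inK4me1 = cat1 == "me1",
                            inK4me3 = cat1 == "me3")
        # report truth in the PeakSet's sorted order
        truth <- truth[match(names(k27@regions),
                             paste0("k27ac_", seq_len(nK27ac))), ]
        rownames(truth) <- NULL
        list(k27ac = k27,
             k4me1 = mkSet(me1, "H3K4me1", "k4me1"),
             k4me3 = mkSet(me3, "H3K4me3", "k4me3"),
             truth = truth)
    })
}

#' Simulate per-sample reads enriched in peaks
#'
#' Fixed-length reads are placed inside peak regions with probability
#' proportional to `enrichment` (per-bp rate inside peaks relative to
#' background) and uniformly on the contig otherwise. Expected per-peak
#' counts are recorded so the counting stage can be scored.
#'
#' @param peaks a single-contig [PeakSet-class].
#' @param depth reads per sample (positive).
#' @param enrichment per-bp enrichment of in-peak placement (`Inf` puts
#'   every read inside a peak).
#' @param readLength read footprint length (default 100).
#' @param genomeLength contig length (default: last peak end + 10 kb).
#' @param sampleIds sample identifiers (one [ReadSet-class] each).
#' @param seed RNG seed.
#' @return list with `readsets` (list of [ReadSet-class]) and
#'   `expected` (named expected counts per peak, one sample).
#' @export
simulateReads <- function(peaks, depth = 10000L, enrichment = 5,
                          readLength = 100L, genomeLength = NULL,
                          sampleIds = "sample_1", seed = 1L) {
    stopifnot(is(peaks, "PeakSet"), depth > 0, enrichment >= 0)
    gr <- peaks@regions
    chr <- unique(as.character(seqnames(gr)))
    if (length(chr) != 1L)
        stop("simulateReads supports a single-contig PeakSet")
    if (is.null(genomeLength)) genomeLength <- max(end(gr)) + 10000
    w <- width(gr)
    Lp <- sum(w)
    pIn <- if (is.infinite(enrichment)) 1 else
        enrichment * Lp / (enrichment * Lp + (genomeLength - Lp))
    .with_seed(seed, {
        readsets <- lapply(sampleIds, function(sid) {
            inPeak <- stats::runif(depth) < pIn
            nIn <- sum(inPeak)
            starts <- numeric(depth)
            if (nIn) {
                pk <- sample.int(length(gr), nIn, replace = TRUE,
                                 prob = w)
                lo <- start(gr)[pk]
                hi <- pmax(lo, end(gr)[pk] - readLength + 1L)
                starts[inPeak] <- floor(stats::runif(nIn, lo, hi + 1))
            }
            nBg <- depth - nIn
            if (nBg)
                starts[!inPeak] <-
                    floor(stats::runif(nBg, 1, genomeLength - readLength + 1))
            ReadSet(sid, GRanges(chr, IRanges(starts,
                                              width = readLength)))
        })
        expected <- depth * (pIn * w / Lp +
                             (1 - pIn) * (w + readLength - 1) / genomeLength)
        names(expected) <- names(gr)
        list(readsets = readsets, expected = expected)
    })
}

#' Simulate a binned Hi-C contact matrix with an embedded ecDNA cycle
#'
#' Builds a genome-wide matrix over the given contigs (including a small
#' viral contig): intra-contig background decaying as
#' `(d + 1)^-alpha` in bin distance `d`, a constant trans background,
#' and — added on top — a cycle contact signal between every pair of
#' cycle bins decaying with circular cycle distance and scaled by
#' `copyAmplitude`. Multiplicative per-bin biases (log-uniform over
#' `biasRange`) are planted last; optional Poisson sampling adds
#' counting noise. All truths (cycle, bin map, biases) are returned.
#'
#' @param contigs named contig sizes in bp (include the viral contig).
#' @param binSize bin size in bp.
#' @param alpha intra-contig distance-decay exponent (default 1).
#' @param backgroundScale intra-contig contact scale (default 100).
#' @param transLevel constant inter-contig background (default 1).
#' @param segments segment table (`id`, `chrom`, `start`, `end`;
#'   0-based half-open); default: two human segments plus the full
#'   viral contig.
#' @param path cycle path (`segment`, `orientation`); default
#'   `1+, 2-, 3+`.
#' @param copyCount cycle copy count recorded on the structure.
#' @param copyAmplitude amplitude of the cycle contact signal.
#' @param circAlpha circular-distance decay exponent of the cycle
#'   signal.
#' @param biasRange planted per-bin bias range (log-uniform).
#' @param noise logical; Poisson-sample the matrix (default `FALSE`).
#' @param seed RNG seed.
#' @return list with `matrix` ([ContactMatrix-class]), `segments`,
#'   `cycle` ([CycleStructure-class]), `biases` (planted per-bin
#'   vector) and `binMap` (cycle bin map truth).
#' @export
simulateHic <- function(contigs = c(chr20 = 192000, chr4 = 100000,
                                    HPV16 = 8000),
                        binSize = 1000, alpha = 1,
                        backgroundScale = 100, transLevel = 1,
                        segments = NULL, path = NULL, copyCount = 4.1,
                        copyAmplitude = 200, circAlpha = 1,
                        biasRange = c(0.5, 2), noise = FALSE, seed = 1L) {
    if (is.null(segments))
        segments <- data.frame(id = 1:3,
                               chrom = c("chr20", "chr20", "HPV16"),
                               start = c(20000, 120000, 0),
                               end = c(60000, 150000, 8000))
    if (is.null(path))
        path <- data.frame(segment = 1:3,
                           orientation = c("+", "-", "+"))
    stopifnot(all(segments$chrom %in% names(contigs)),
              all(segments$end <= contigs[segments$chrom]))
    cycle <- CycleStructure(1L, copyCount, path)
    nb <- ceiling(contigs / binSize)
    bins <- data.frame(
        chrom = rep(names(contigs), nb),
        start = unlist(lapply(nb, function(k) (seq_len(k) - 1) * binSize),
                       use.names = FALSE))
    n <- nrow(bins)
    .with_seed(seed, {
        M <- matrix(transLevel, n, n)
        off <- 0L
        for (ci in seq_along(contigs)) {
            k <- nb[ci]
            idx <- off + seq_len(k)
            d <- abs(outer(seq_len(k), seq_len(k), "-"))
            M[idx, idx] <- backgroundScale * (d + 1)^(-alpha)
            off <- off + k
        }
        bm <- .cycle_bin_map(cycle, segments, binSize)
        key <- paste(bins$chrom, bins$start)
        g <- match(paste(bm$chrom, bm$start), key)
        if (any(is.na(g))) stop("cycle bin outside the simulated contigs")
        L <- nrow(bm)
        for (p in seq_len(L)) {
            for (q in seq_len(L)) {
                dc <- circularDistance(p, q, L)
                M[g[p], g[q]] <- M[g[p], g[q]] +
                    copyAmplitude * (dc + 1)^(-circAlpha)
            }
        }
        b <- exp(stats::runif(n, log(biasRange[1]), log(biasRange[2])))
        M <- M * outer(b, b)
        if (noise) {
            up <- upper.tri(M, diag = TRUE)
            M[up] <- stats::rpois(sum(up), M[up])
            M[lower.tri(M)] <- t(M)[lower.tri(M)]
        }
        list(matrix = ContactMatrix(M, bins, binSize),
             segments = segments, cycle = cycle, biases = b, binMap = bm)
    })
}
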