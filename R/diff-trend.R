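#' @include diff-normalize.R
NULL

#' Fit the loess SD-versus-mean trend
#'
#' With only two replicates per condition, per-peak variance estimates
#' are useless; instead the standard deviation is modelled as a smooth
#' function of mean signal. All samples are pooled as if they were
#' replicates: per peak, the mean and sample SD across every sample are
#' computed, and a degree-1 loess (tricube weights) of SD on mean is
#' fitted. The fit is tabulated on a 256-point grid spanning the
#' observed mean range; evaluation interpolates linearly and
#' extrapolates as a constant, floored at
#' `max(1e-8, 5th percentile of fitted values)`.
#'
#' @param x a [PeakCounts-class] with a `"normalized"` assay, or a
#'   normalized matrix (peaks x samples).
#' @param span loess span (default 0.5).
#' @param nGrid grid resolution (default 256).
#' @return a [MeanSDTrend-class].
#' @export
fitSDTrend <- function(x, span = 0.5, nGrid = 256L) {
    norm <- .normalized_matrix(x)
    if (ncol(norm) < 3L) stop("need at least 3 samples to pool an SD")
    if (nrow(norm) < 30L) stop("need at least 30 peaks to fit a trend")
    m <- rowMeans(norm)
    s <- apply(norm, 1L, stats::sd)
    if (diff(range(m)) == 0) stop("degenerate input: all peak means equal")
    fit <- stats::loess(s ~ m, span = span, degree = 1,
                        family = "gaussian",
                        control = stats::loess.control(surface = "direct"))
    grid <- seq(min(m), max(m), length.out = nGrid)
    fitted <- stats::predict(fit, newdata = data.frame(m = grid))
    # floor from the fit at the data points, so it tracks the data's own
    # mean distribution rather than the (uniform) evaluation grid
    sdFloor <- max(1e-8, stats::quantile(fit$fitted, 0.05, names = FALSE))
    new("MeanSDTrend", grid = grid, fitted = pmax(fitted, sdFloor),
        sdFloor = sdFloor, span = span)
}

#' Approximate z-scores with a trend-modelled denominator
#'
#' For each peak, the difference of condition means of normalized signal
#' divided by the trend-fitted SD at that peak's mean:
#' `z = (mean_trt - mean_ctrl) / (sd_hat(m) * sqrt(1/n1 + 1/n2))`,
#' where `m` is the peak's mean over the samples being compared. The
#' `sqrt(1/n1 + 1/n2)` standard-error scaling treats the fitted SD as a
#' per-observation SD; set `scaleBySampleSize = FALSE` to use the raw
#' mean difference over the fitted SD instead.
#'
#' @param x a [PeakCounts-class] with a `"normalized"` assay, or a
#'   normalized matrix.
#' @param trend a [MeanSDTrend-class] from [fitSDTrend()].
#' @param condition per-sample condition labels (taken from `colData`
#'   for a `PeakCounts`).
#' @param treated,control condition labels being compared.
#' @param scaleBySampleSize logical (default `TRUE`), see above.
#' @return named numeric vector of z-scores.
#' @export
zScores <- function(x, trend, condition = NULL,
                    treated = "treated", control = "vehicle",
                    scaleBySampleSize = TRUE) {
    norm <- .normalized_matrix(x)
    if (is.null(condition)) {
        if (!is(x, "PeakCounts"))
            stop("'condition' is required for matrix input")
        condition <- colData(x)$condition
    }
    iT <- which(condition == treated)
    iC <- which(condition == control)
    if (!length(iT) || !length(iC))
        stop("both condition groups must be non-empty")
    sel <- c(iC, iT)
    m <- rowMeans(norm[, sel, drop = FALSE])
    delta <- rowMeans(norm[, iT, drop = FALSE]) -
             rowMeans(norm[, iC, drop = FALSE])
    denom <- evalTrend(trend, m)
    if (scaleBySampleSize)
        denom <- denom * sqrt(1 / length(iT) + 1 / length(iC))
    z <- delta / denom
    names(z) <- rownames(norm)
    z
}
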