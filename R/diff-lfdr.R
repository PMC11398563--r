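#' @include AllClasses.R
NULL

#' Empirical-Bayes local false discovery rate
#'
#' Assigns each z-score the posterior probability of arising from the
#' null component of a two-group mixture, following the empirical-Bayes
#' recipe of Efron. The mixture density `f(z)` is estimated by Poisson
#' regression of histogram counts (`bins` equal-width bins spanning the
#' z range) on a natural cubic spline basis (`df` degrees of freedom).
#' The null is `N(delta, sigma0^2)`: in `"empirical"` mode its center and
#' scale are obtained by central matching — a quadratic fit to
#' `log f(z)` over the central 50% of the z distribution — while
#' `"theoretical"` mode fixes `delta = 0, sigma0 = 1`. The null mass is
#' `pi0 = min(1, f(delta) * sigma0 * sqrt(2*pi))`, i.e. the proportion
#' that matches the null density at its mode. Then
#' `lfdr(z) = min(1, pi0 * dnorm(z, delta, sigma0) / f(z))`.
#'
#' If the spline fit or the central matching degenerates (e.g. a
#' non-concave central log-density), the estimator falls back to the
#' theoretical null with a warning.
#'
#' @param z numeric vector of z-scores (at least 200 for empirical
#'   mode).
#' @param nullMode `"empirical"` (default) or `"theoretical"`.
#' @param bins histogram bins for the density fit (default 120).
#' @param df spline degrees of freedom (default 7).
#' @return list with `lfdr` (values in `[0, 1]`, same order as `z`) and
#'   `null` (an [EmpiricalNull-class]).
#' @examples
#' z <- c(rnorm(1900), rnorm(100, 4))
#' fit <- localFdr(z)
#' fit$null
#' @export
localFdr <- function(z, nullMode = c("empirical", "theoretical"),
                     bins = 120L, df = 7L) {
    nullMode <- match.arg(nullMode)
    z <- as.numeric(z)
    if (any(!is.finite(z))) stop("z-scores must be finite")
    n <- length(z)
    if (nullMode == "empirical" && n < 200L)
        stop("empirical null needs >= 200 z-scores; use nullMode = 'theoretical'")

    rng <- range(z)
    if (diff(rng) == 0) rng <- rng + c(-1, 1)
    breaks <- seq(rng[1], rng[2], length.out = bins + 1L)
    mid <- (breaks[-1L] + breaks[-length(breaks)]) / 2
    counts <- as.integer(table(cut(z, breaks, include.lowest = TRUE)))
    width <- diff(breaks)[1L]

    basis <- splines::ns(mid, df = df)
    fit <- tryCatch(
        stats::glm(counts ~ basis, family = stats::poisson()),
        error = function(e) NULL, warning = function(w) {
            suppressWarnings(stats::glm(counts ~ basis,
                                        family = stats::poisson()))
        })
    if (is.null(fit) || !fit$converged) {
        warning("spline density fit failed; using kernel density and the ",
                "theoretical null")
        dens <- stats::density(z, n = 512)
        fhat <- function(zz) pmax(stats::approx(dens$x, dens$y, xout = zz,
                                                rule = 2)$y, 1e-12)
        nullMode <- "theoretical"
        delta <- 0; sigma0 <- 1
    } else {
        co <- stats::coef(fit)
        fhat <- function(zz) {
            eta <- cbind(1, stats::predict(basis, zz)) %*% co
            pmax(exp(as.numeric(eta)) / (n * width), 1e-12)
        }
        if (nullMode == "empirical") {
            qs <- stats::quantile(z, c(0.25, 0.75), names = FALSE)
            ctr <- mid >= qs[1] & mid <= qs[2]
            if (sum(ctr) < 5L) ctr <- rank(abs(mid - stats::median(z))) <= 5
            lf <- log(fhat(mid[ctr]))
            quad <- stats::lm(lf ~ mid[ctr] + I(mid[ctr]^2))
            c2 <- stats::coef(quad)[3L]
            if (!is.finite(c2) || c2 >= 0) {
                warning("central matching degenerate; ",
                        "falling back to the theoretical null")
                nullMode <- "theoretical"
                delta <- 0; sigma0 <- 1
            } else {
                sigma0 <- sqrt(-1 / (2 * c2))
                delta <- as.numeric(stats::coef(quad)[2L]) * sigma0^2
            }
        }
        if (nullMode == "theoretical") { delta <- 0; sigma0 <- 1 }
    }

    pi0 <- min(1, fhat(delta) * sigma0 * sqrt(2 * pi))
    lfdr <- pmin(1, pi0 * stats::dnorm(z, delta, sigma0) / fhat(z))
    list(lfdr = pmax(lfdr, 0),
         null = new("EmpiricalNull", delta = as.numeric(delta),
                    sigma0 = as.numeric(sigma0), pi0 = pi0,
                    mode = nullMode))
}
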