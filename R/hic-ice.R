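#' @include AllGenerics.R
NULL

## core iterative-correction loop on a bare symmetric matrix
.ice_core <- function(A, tol, maxIter) {
    n <- nrow(A)
    if (n != ncol(A)) stop("matrix must be square")
    if (any(A < 0)) stop("matrix must be non-negative")
    if (max(abs(A - t(A))) > 1e-9) stop("matrix must be symmetric")
    marg <- rowSums(A)
    masked <- marg == 0
    if (all(masked)) stop("all bins have zero marginal; nothing to balance")
    live <- !masked
    bias <- as.numeric(live)          # masked bins carry weight 0
    it <- 0L
    cv <- .marginal_cv(A, live)
    while (cv > tol && it < maxIter) {
        s <- rowSums(A)
        sHat <- rep(1, n)
        sHat[live] <- s[live] / mean(s[live])
        A <- A / outer(sHat, sHat)
        bias[live] <- bias[live] / sHat[live]
        it <- it + 1L
        cv <- .marginal_cv(A, live)
    }
    # fix the global scale: mean unmasked marginal = 1
    sc <- mean(rowSums(A)[live])
    A <- A / sc
    bias[live] <- bias[live] / sqrt(sc)
    list(values = A, bias = bias, masked = masked,
         iterations = it, cv = .marginal_cv(A, live))
}

.marginal_cv <- function(A, live) {
    s <- rowSums(A)[live]
    m <- mean(s)
    if (m == 0) return(0)
    stats::sd(s) / m
}

#' @rdname iceBalance
#' @export
setMethod("iceBalance", "matrix", function(x, tol = 1e-5, maxIter = 200L) {
    res <- .ice_core(x, tol, maxIter)
    new("IceResult", values = res$values, bias = res$bias,
        masked = res$masked, iterations = as.numeric(res$iterations),
        cv = res$cv)
})

#' @rdname iceBalance
#' @export
setMethod("iceBalance", "AssembledMatrix",
          function(x, tol = 1e-5, maxIter = 200L) {
    res <- .ice_core(x@values, tol, maxIter)
    initialize(x, values = res$values, bias = res$bias, balanced = TRUE,
               iceIterations = as.numeric(res$iterations), iceCV = res$cv)
})
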