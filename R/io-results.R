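#' @include AllGenerics.R
NULL

.fmt6 <- function(x) {
    # fixed 6-significant-digit rendering; integers and flags pass through
    if (is.numeric(x) && !is.integer(x)) signif(x, 6) else x
}

.write_tsv_det <- function(df, path) {
    df[] <- lapply(df, .fmt6)
    con <- file(path, open = "wb")   # binary mode: stable newlines
    on.exit(close(con))
    utils::write.table(df, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE, eol = "\n")
    invisible(path)
}

#' @describeIn writeResults differential-result table: columns
#'   `peak, mean_ctrl, mean_trt, fc, log2fc, z, lfdr, called`, rows
#'   ordered by peak name; an empty table yields a header-only file.
#' @export
setMethod("writeResults", "DataFrame", function(x, path, ...) {
    writeResults(as.data.frame(x), path, ...)
})

#' @describeIn writeResults data.frame method (same contract).
#' @export
setMethod("writeResults", "data.frame", function(x, path, ...) {
    cols <- c("mean_ctrl", "mean_trt", "fc", "log2fc", "z", "lfdr", "called")
    miss <- setdiff(cols, colnames(x))
    if (length(miss))
        stop("not a differential result table; missing column(s): ",
             paste(miss, collapse = ", "))
    peak <- if ("peak" %in% colnames(x)) as.character(x$peak)
            else rownames(x)
    if (is.null(peak)) stop("result rows must carry peak names")
    out <- data.frame(peak = peak, x[, cols, drop = FALSE])
    out <- out[order(out$peak, method = "radix"), , drop = FALSE]
    .write_tsv_det(out, path)
})

#' @describeIn writeResults assembled matrix: writes the value matrix to
#'   `path` and the bin map to `binsPath` (default: `path` with a
#'   `_bins.tsv` suffix).
#' @param binsPath bin-map output path (AssembledMatrix only).
#' @export
setMethod("writeResults", "AssembledMatrix",
          function(x, path, binsPath = NULL, ...) {
    if (is.null(binsPath))
        binsPath <- paste0(sub("\\.tsv$", "", path), "_bins.tsv")
    lines <- apply(x@values, 1L,
                   function(r) paste(sprintf("%.6g", r), collapse = "\t"))
    con <- file(path, open = "wb"); writeLines(lines, con); close(con)
    bm <- x@binMap
    if (x@balanced) bm$bias <- signif(x@bias, 6)
    con <- file(binsPath, open = "wb")
    utils::write.table(bm, con, sep = "\t", quote = FALSE,
                       row.names = FALSE, eol = "\n")
    close(con)
    invisible(c(path, binsPath))
})
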