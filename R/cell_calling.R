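## Knee-point cell calling. Cell labels are sorted by descending read
## count; the cumulative read sum is log10-transformed and its curvature
## with respect to log10(rank) is estimated by wide-stencil secant
## differencing (slopes over a half-window on each side). The rank of the
## curvature minimum is the inflection point; labels at or left of it are
## called as cells, the rest are noise.

#' Build the cumulative read-count knee curve
#'
#' @param reads_per_label Named numeric vector (or two-column
#'   data.frame/data.table `label`, `reads`) of total reads per cell label;
#'   at least 10 labels with positive counts.
#' @return A `knee_curve` object: data.table with `rank`, `label`, `reads`,
#'   `cum_reads`, `log10_rank`, `log10_cum`. Labels are sorted by
#'   descending reads, ties broken lexicographically for determinism.
#' @export
build_knee_curve <- function(reads_per_label) {
    if (is.data.frame(reads_per_label)) {
        labels <- as.character(reads_per_label[[1]])
        reads <- as.numeric(reads_per_label[[2]])
    } else {
        labels <- names(reads_per_label)
        reads <- as.numeric(reads_per_label)
    }
    if (is.null(labels)) stop("reads_per_label must be named")
    pos <- reads > 0
    labels <- labels[pos]; reads <- reads[pos]
    if (length(labels) < 10L) {
        stop("need at least 10 labels with positive counts to locate a knee")
    }
    ord <- order(-reads, labels)
    curve <- data.table::data.table(
        rank = seq_along(ord),
        label = labels[ord],
        reads = reads[ord])
    curve[, cum_reads := cumsum(reads)]
    curve[, `:=`(log10_rank = log10(rank), log10_cum = log10(cum_reads))]
    structure(list(curve = curve, inflection_rank = NA_integer_,
                   called = character(0), degenerate = NA),
              class = "knee_curve")
}

#' @export
print.knee_curve <- function(x, ...) {
    cat("knee_curve:", nrow(x$curve), "labels,",
        format(max(x$curve$cum_reads), big.mark = ","), "reads\n")
    if (!is.na(x$inflection_rank)) {
        cat("  inflection rank:", x$inflection_rank, "->",
            length(x$called), "called cells",
            if (isTRUE(x$degenerate)) "(degenerate curve!)" else "", "\n")
    }
    invisible(x)
}

#' Call cells at the knee of the cumulative read curve
#'
#' Estimates the second derivative of log10 cumulative reads with respect
#' to log10 rank by secant slopes over a half-window of
#' `floor(smooth_window / 2)` ranks on each side (a noise-robust
#' wide-stencil central difference), then places the inflection at the
#' curvature minimum. Ranks within `smooth_window` of either end are
#' excluded from the search to avoid boundary artifacts. Labels with rank
#' at or below the inflection are called.
#'
#' @param knee A `knee_curve` from [build_knee_curve()].
#' @param smooth_window Window (ranks) controlling the derivative stencil
#'   and the excluded margins.
#' @param mode `"second"` (default) places the inflection at the minimum
#'   second derivative; `"first"` at the minimum first derivative.
#' @param tol Curvature range below which the curve is declared degenerate
#'   (no calls made).
#' @return The `knee_curve` with `inflection_rank`, `called` (labels),
#'   `degenerate`, and per-rank `d1`/`d2` columns added to the curve table.
#' @export
call_cells <- function(knee, smooth_window = 15L, mode = c("second", "first"),
                       tol = 1e-9) {
    stopifnot(inherits(knee, "knee_curve"))
    mode <- match.arg(mode)
    curve <- knee$curve
    n <- nrow(curve)
    h <- max(1L, smooth_window %/% 2L)
    x <- curve$log10_rank
    y <- curve$log10_cum
    d1 <- rep(NA_real_, n)
    d2 <- rep(NA_real_, n)
    i <- (h + 1L):(n - h)
    sb <- (y[i] - y[i - h]) / (x[i] - x[i - h])
    sf <- (y[i + h] - y[i]) / (x[i + h] - x[i])
    d1[i] <- (y[i + h] - y[i - h]) / (x[i + h] - x[i - h])
    d2[i] <- (sf - sb) / ((x[i + h] - x[i - h]) / 2)
    curve[, `:=`(d1 = d1, d2 = d2)]

    lo <- max(2L, smooth_window + 1L)
    hi <- min(n - 1L, n - smooth_window)
    if (lo > hi) stop("too few labels for smooth_window = ", smooth_window)
    stat <- if (mode == "second") d2 else d1
    window <- stat[lo:hi]
    degenerate <- all(is.na(window)) ||
        diff(range(window, na.rm = TRUE)) < tol
    if (!degenerate) {
        m <- min(window, na.rm = TRUE)
        at <- which(window == m)
        if (length(at) > 1L) degenerate <- TRUE  # minimum not unique
        knee$inflection_rank <- lo + at[1] - 1L
        knee$called <- curve$label[seq_len(knee$inflection_rank)]
    } else {
        knee$inflection_rank <- NA_integer_
        knee$called <- character(0)
    }
    knee$degenerate <- degenerate
    knee$curve <- curve
    knee
}
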