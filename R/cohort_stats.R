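#' Per-group cluster proportions
#'
#' @param assignments data.table/data.frame with one row per cell and
#'   columns `cell_id`, `group`, `cluster` (cluster membership is consumed
#'   as an input column, e.g. from an external clustering or the
#'   simulator's true subpopulations).
#' @return data.table with `group`, `cluster`, `n`, `total`, `prop`
#'   (exact proportion) and `pct` (percentage rounded to 2 decimals);
#'   proportions within each group sum to 1.
#' @export
cluster_proportions <- function(assignments) {
    dt <- data.table::as.data.table(assignments)
    stopifnot(all(c("cell_id", "group", "cluster") %in% names(dt)))
    if (anyDuplicated(dt$cell_id)) stop("a cell has more than one assignment")
    if (nrow(dt) == 0L) stop("empty assignment table")
    tab <- dt[, .(n = .N), by = .(group, cluster)]
    tab[, total := sum(n), by = group]
    tab[, prop := n / total]
    tab[, pct := round(100 * prop, 2)]
    data.table::setorder(tab, group, cluster)
    tab[]
}

#' Fold change between two group percentages
#'
#' @param p_case,p_control Percentages (or proportions, any common scale).
#' @param digits Decimals to round the ratio to (1, as conventionally
#'   reported); `NULL` for the unrounded ratio.
#' @return `p_case / p_control`, rounded; `NA` (with a warning) when the
#'   control percentage is zero.
#' @examples
#' fold_change(30.35, 9.38)  # 3.2
#' fold_change(2.11, 0.62)   # 3.4
#' @export
fold_change <- function(p_case, p_control, digits = 1) {
    if (any(p_control == 0)) {
        warning("zero control proportion: fold change undefined")
        out <- ifelse(p_control == 0, NA_real_, p_case / p_control)
    } else {
        out <- p_case / p_control
    }
    if (is.null(digits)) out else round(out, digits)
}

#' Two-group proportion test for one cluster
#'
#' Compares a cluster's frequency between case and control. The default is
#' the two-proportion z-test (chi-square without continuity correction);
#' Fisher's exact test is available as an alternative. Symmetric in group
#' exchange.
#'
#' @param n_case_k,n_control_k Cells of the cluster in each group.
#' @param n_case,n_control Total cells per group.
#' @param method `"z"` or `"fisher"`.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
proportion_test <- function(n_case_k, n_case, n_control_k, n_control,
                            method = c("z", "fisher")) {
    method <- match.arg(method)
    stopifnot(n_case > 0L, n_control > 0L,
              n_case_k <= n_case, n_control_k <= n_control,
              n_case_k >= 0L, n_control_k >= 0L)
    if (method == "z") {
        if (n_case_k + n_control_k == 0L ||
            n_case_k == n_case && n_control_k == n_control) {
            return(1)  # identical degenerate proportions
        }
        suppressWarnings(
            stats::prop.test(c(n_case_k, n_control_k), c(n_case, n_control),
                             correct = FALSE)$p.value)
    } else {
        stats::fisher.test(matrix(c(n_case_k, n_case - n_case_k,
                                    n_control_k, n_control - n_control_k),
                                  nrow = 2))$p.value
    }
}

#' Case/control cluster comparison table
#'
#' Per-cluster cell counts, percentages, fold changes (case over control)
#' and two-sided p-values.
#'
#' @param assignments See [cluster_proportions()]; `group` must contain
#'   exactly the two named groups.
#' @param case,control Group labels.
#' @param method Test passed to [proportion_test()].
#' @param p_adjust Multiple-testing correction (`"none"` by default;
#'   `"BH"` for Benjamini-Hochberg).
#' @return data.table with `cluster`, `n_case`, `n_control`, `pct_case`,
#'   `pct_control`, `fold_change`, `p_value` (and `p_adj` when adjusted),
#'   plus a `test` attribute naming the test used.
#' @export
compare_clusters <- function(assignments, case = "case", control = "control",
                             method = c("z", "fisher"), p_adjust = "none") {
    method <- match.arg(method)
    props <- cluster_proportions(assignments)
    if (!all(c(case, control) %in% props$group)) {
        stop("groups not found: ", case, " / ", control)
    }
    clusters <- sort(unique(props$cluster))
    tot <- props[, .(total = total[1]), by = group]
    n_case_tot <- tot[group == case, total]
    n_ctrl_tot <- tot[group == control, total]
    out <- data.table::rbindlist(lapply(clusters, function(k) {
        nk_case <- props[group == case & cluster == k, sum(n)]
        nk_ctrl <- props[group == control & cluster == k, sum(n)]
        pct_case <- round(100 * nk_case / n_case_tot, 2)
        pct_ctrl <- round(100 * nk_ctrl / n_ctrl_tot, 2)
        data.table::data.table(
            cluster = k, n_case = nk_case, n_control = nk_ctrl,
            pct_case = pct_case, pct_control = pct_ctrl,
            fold_change = if (pct_ctrl > 0)
                fold_change(pct_case, pct_ctrl) else NA_real_,
            p_value = proportion_test(nk_case, n_case_tot,
                                      nk_ctrl, n_ctrl_tot, method = method))
    }))
    if (p_adjust != "none") out[, p_adj := p.adjust(p_value, method = p_adjust)]
    data.table::setattr(out, "test",
                        c(z = "two-proportion z-test",
                          fisher = "Fisher's exact test")[[method]])
    out[]
}
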