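## Molecule collapsing and UMI error correction.
##
## Reads sharing (cell label, UMI, feature) collapse into one raw molecule
## whose depth ("raw adjusted sequencing depth") is the contributing read
## count. Two corrections follow:
##   RSEC (recursive substitution error correction): within each
##   (cell, feature) group, a UMI with a strictly deeper Hamming-1
##   neighbour is merged into its deepest such neighbour, depths added,
##   recursively until no such UMI remains. Equal-depth pairs are left
##   alone (no defensible parent).
##   DBEC (distribution-based error correction): per feature, molecule
##   depths are fit with a two-component mixture (signal vs error), each
##   side modelled as geometric with its sample mean, by brute-force search
##   over all split thresholds; if the component means separate by at least
##   `min_fold`, molecules at or below the threshold are removed.

#' Collapse annotated valid read pairs into raw molecules
#'
#' @param valid_pairs data.table (or data.frame) with one row per valid
#'   read pair and columns `cell_label`, `umi`, `feature`.
#' @return A data.table of molecules (`cell_label`, `umi`, `feature`,
#'   `depth`), one row per distinct (cell label, UMI, feature); the sum of
#'   depths equals the number of input pairs.
#' @export
collapse_to_molecules <- function(valid_pairs) {
    dt <- data.table::as.data.table(valid_pairs)
    if (nrow(dt) == 0L) {
        return(data.table::data.table(cell_label = character(0),
                                      umi = character(0),
                                      feature = character(0),
                                      depth = integer(0)))
    }
    mols <- dt[, .(depth = .N), by = .(cell_label, umi, feature)]
    data.table::setorder(mols, cell_label, feature, umi)
    mols[]
}

## RSEC merge for one (cell, feature) group. umis/depths are parallel
## vectors; returns the corrected depths with merged children set to 0.
rsec_group <- function(umis, depths) {
    pairs <- hamming1_pairs(umis)
    if (nrow(pairs) == 0L) return(list(depth = depths, merged = 0L))
    alive <- rep(TRUE, length(umis))
    merged <- 0L
    repeat {
        ## children: alive UMIs with a strictly deeper alive H1 neighbour
        p <- pairs[alive[pairs[, 1]] & alive[pairs[, 2]], , drop = FALSE]
        if (nrow(p) == 0L) break
        deeper1 <- depths[p[, 1]] > depths[p[, 2]]
        deeper2 <- depths[p[, 2]] > depths[p[, 1]]
        child <- c(p[deeper1, 2], p[deeper2, 1])
        if (length(child) == 0L) break
        child <- unique(child)
        ## process the lowest-depth child, ties broken lexicographically
        ord <- order(depths[child], umis[child])
        c_i <- child[ord[1]]
        nb <- c(p[p[, 1] == c_i, 2], p[p[, 2] == c_i, 1])
        nb <- nb[depths[nb] > depths[c_i]]
        nb <- nb[order(-depths[nb], umis[nb])]
        parent <- nb[1]
        depths[parent] <- depths[parent] + depths[c_i]
        depths[c_i] <- 0L
        alive[c_i] <- FALSE
        merged <- merged + 1L
    }
    list(depth = depths, merged = merged)
}

#' Recursive substitution error correction (RSEC)
#'
#' @param mols Molecule table from [collapse_to_molecules()].
#' @return List with `molecules` (corrected table; children absorbed into
#'   parents, total depth conserved) and `report` (`n_in`,
#'   `n_rsec_merged`, `n_out`).
#' @export
rsec_correct <- function(mols) {
    mols <- data.table::as.data.table(mols)
    n_in <- nrow(mols)
    if (n_in == 0L) {
        return(list(molecules = mols,
                    report = list(n_in = 0L, n_rsec_merged = 0L, n_out = 0L)))
    }
    out <- data.table::copy(mols)
    out[, depth := {
        if (.N > 1L) rsec_group(umi, depth)$depth else depth
    }, by = .(cell_label, feature)]
    out <- out[depth > 0L]
    list(molecules = out[],
         report = list(n_in = n_in,
                       n_rsec_merged = n_in - nrow(out),
                       n_out = nrow(out)))
}

## Maximum-likelihood split of a depth vector into two geometric
## components. Returns NULL when no split exists, else list(threshold,
## mean_low, mean_high, loglik).
dbec_fit <- function(depths) {
    cand <- sort(unique(depths))
    cand <- cand[-length(cand)]          # both sides must be non-empty
    if (length(cand) == 0L) return(NULL)
    geom_ll <- function(d) {
        p <- 1 / mean(d)
        sum(stats::dgeom(d - 1L, prob = p, log = TRUE))
    }
    fits <- lapply(cand, function(t) {
        low <- depths[depths <= t]
        high <- depths[depths > t]
        list(threshold = t, mean_low = mean(low), mean_high = mean(high),
             loglik = geom_ll(low) + geom_ll(high))
    })
    fits[[which.max(vapply(fits, `[[`, numeric(1), "loglik"))]]
}

#' Distribution-based error correction (DBEC)
#'
#' Applied after RSEC. For every feature with at least `min_group`
#' molecules, depths are split at the likelihood-maximizing threshold into
#' a putative error component and a signal component (each geometric with
#' its sample mean). When the component means separate by at least
#' `min_fold`, molecules at or below the threshold are removed; otherwise
#' the depth distribution is treated as unimodal and nothing is removed.
#' Features with fewer than `min_group` molecules pass through untouched.
#'
#' @param mols Molecule table (post-RSEC).
#' @param min_group Minimum molecules per feature for the fit.
#' @param min_fold Required mean separation between components.
#' @return List with `molecules` (surviving molecules, depths untouched)
#'   and `report` (`n_in`, `n_dbec_removed`, `n_out`,
#'   `per_feature_threshold`: named vector, NA when no removal).
#' @export
dbec_filter <- function(mols, min_group = 20L, min_fold = 4) {
    mols <- data.table::as.data.table(mols)
    n_in <- nrow(mols)
    feats <- unique(mols$feature)
    thresholds <- stats::setNames(rep(NA_real_, length(feats)), feats)
    keep <- rep(TRUE, n_in)
    for (f in feats) {
        idx <- which(mols$feature == f)
        if (length(idx) < min_group) next
        fit <- dbec_fit(mols$depth[idx])
        if (is.null(fit)) next
        if (fit$mean_high / fit$mean_low >= min_fold) {
            thresholds[f] <- fit$threshold
            keep[idx[mols$depth[idx] <= fit$threshold]] <- FALSE
        }
    }
    out <- mols[keep]
    list(molecules = out[],
         report = list(n_in = n_in,
                       n_dbec_removed = n_in - nrow(out),
                       n_out = nrow(out),
                       per_feature_threshold = thresholds))
}
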