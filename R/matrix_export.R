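#' Build the called-cells x features count matrix
#'
#' Each entry is the number of surviving (post-correction) molecules for
#' that cell and feature. Molecules belonging to uncalled labels are
#' dropped and counted; decoy features never appear.
#'
#' @param mols Surviving molecule table (`cell_label`, `umi`, `feature`,
#'   `depth`).
#' @param called Character vector of called cell labels (row order is
#'   preserved).
#' @param panel A `panel_ref`; column order follows the panel's countable
#'   features.
#' @param provenance Optional list of run metadata stored on the object.
#' @return A `count_matrix`: list with `counts` (sparse dgCMatrix,
#'   cells x features), `feature_types` (named), `n_dropped_uncalled`, and
#'   `provenance`.
#' @export
build_matrix <- function(mols, called, panel, provenance = list()) {
    if (length(called) == 0L) stop("empty called cell set")
    mols <- data.table::as.data.table(mols)
    feats <- countable_features(panel)
    if (nrow(mols) > 0L && !all(mols$feature %in% feats)) {
        stop("molecule table contains features absent from the panel")
    }
    in_called <- mols$cell_label %in% called
    kept <- mols[in_called]
    agg <- kept[, .(n = .N), by = .(cell_label, feature)]
    counts <- Matrix::sparseMatrix(
        i = match(agg$cell_label, called),
        j = match(agg$feature, feats),
        x = agg$n,
        dims = c(length(called), length(feats)),
        dimnames = list(called, feats))
    ft <- panel$features$feature_type[match(feats, panel$features$name)]
    structure(list(counts = counts,
                   feature_types = stats::setNames(ft, feats),
                   n_dropped_uncalled = sum(!in_called),
                   provenance = provenance),
              class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
    cat("count_matrix:", nrow(x$counts), "cells x", ncol(x$counts),
        "features (", paste(names(table(x$feature_types)),
                            table(x$feature_types),
                            sep = "=", collapse = ", "), "),",
        sum(x$counts), "molecules\n")
    invisible(x)
}

#' Write a count matrix as an MTX triplet directory
#'
#' Writes `matrix.mtx` (Matrix Market coordinate format), `features.tsv`
#' (name, feature type), `barcodes.tsv` (cell labels as
#' `idx1_idx2_idx3` whitelist-index triples) and `provenance.json`.
#'
#' @param m A `count_matrix`.
#' @param outdir Output directory (created).
#' @return `outdir`, invisibly.
#' @export
write_matrix <- function(m, outdir) {
    stopifnot(inherits(m, "count_matrix"))
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    Matrix::writeMM(m$counts, file.path(outdir, "matrix.mtx"))
    write.table(data.frame(name = colnames(m$counts),
                           type = unname(m$feature_types[colnames(m$counts)])),
                file.path(outdir, "features.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    writeLines(rownames(m$counts), file.path(outdir, "barcodes.tsv"))
    jsonlite::write_json(
        c(m$provenance, list(n_dropped_uncalled = m$n_dropped_uncalled)),
        file.path(outdir, "provenance.json"), auto_unbox = TRUE, digits = NA,
        null = "null")
    invisible(outdir)
}

#' Read back a count matrix written by [write_matrix()]
#'
#' @param dir Directory holding `matrix.mtx`, `features.tsv`,
#'   `barcodes.tsv` (and optionally `provenance.json`).
#' @return A `count_matrix`; bit-exact round-trip with [write_matrix()].
#' @export
read_matrix <- function(dir) {
    counts <- Matrix::readMM(file.path(dir, "matrix.mtx"))
    ## writeMM emits "pattern"/"symmetric" variants when the values allow;
    ## normalize back to a general numeric sparse matrix
    if (methods::is(counts, "symmetricMatrix")) {
        counts <- methods::as(counts, "generalMatrix")
    }
    if (methods::is(counts, "nMatrix")) {
        counts <- methods::as(counts, "dMatrix")
    }
    counts <- methods::as(counts, "CsparseMatrix")
    feats <- read.table(file.path(dir, "features.tsv"), sep = "\t",
                        header = FALSE, col.names = c("name", "type"),
                        colClasses = "character")
    barcodes <- readLines(file.path(dir, "barcodes.tsv"))
    dimnames(counts) <- list(barcodes, feats$name)
    prov_path <- file.path(dir, "provenance.json")
    prov <- if (file.exists(prov_path)) jsonlite::read_json(prov_path) else list()
    n_drop <- prov$n_dropped_uncalled %||% NA_integer_
    prov$n_dropped_uncalled <- NULL
    structure(list(counts = counts,
                   feature_types = stats::setNames(feats$type, feats$name),
                   n_dropped_uncalled = n_drop,
                   provenance = prov),
              class = "count_matrix")
}
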