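#' Load a targeted panel reference from FASTA
#'
#' Reads the panel of target feature sequences (mRNA amplicons and
#' antibody-tag sequences) plus any decoy records, normalizes sequences to
#' upper case, and validates the alphabet. Decoy features participate in
#' alignment (reads hitting them are discarded) but are excluded from count
#' matrices.
#'
#' @param fasta_path Path to a multi-record FASTA file (wrapped or
#'   unwrapped). Record names are taken as the first whitespace-delimited
#'   token of each header and must be unique.
#' @param feature_type_map Optional mapping from record name to feature type
#'   (`"mrna"`, `"abtag"` or `"decoy"`). Either a named character vector or
#'   the path to a two-column TSV (`name<TAB>type`, no header). Unmapped
#'   records default to `"mrna"`.
#' @return A `panel_ref` object: list with a `features` data.table
#'   (`name`, `feature_type`, `sequence`, `length`) and (after
#'   [build_kmer_index()]) a k-mer index.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">g1", strrep("ACGT", 20), ">tag1", strrep("GATTACA", 10),
#'              ">decoy1", strrep("TTGACC", 30)), fa)
#' panel <- load_panel(fa, c(tag1 = "abtag", decoy1 = "decoy"))
#' panel
#' @export
load_panel <- function(fasta_path, feature_type_map = NULL) {
    if (!file.exists(fasta_path)) {
        stop("panel FASTA not found: ", fasta_path)
    }
    seqs <- Biostrings::readDNAStringSet(fasta_path)
    if (length(seqs) == 0L) stop("empty panel: ", fasta_path)
    nms <- sub("\\s.*$", "", names(seqs))
    if (anyDuplicated(nms)) {
        stop("duplicate record names in panel: ",
             paste(unique(nms[duplicated(nms)]), collapse = ", "))
    }
    seq_chr <- toupper(as.character(seqs))
    bad <- grepl("[^ACGTN]", seq_chr)
    if (any(bad)) {
        stop("panel sequences contain characters outside A/C/G/T/N: ",
             paste(nms[bad], collapse = ", "))
    }
    types <- resolve_feature_types(nms, feature_type_map)
    short <- types != "decoy" & nchar(seq_chr) < 61L
    if (any(short)) {
        stop("mrna/abtag features shorter than 61 nt (no read could pass the ",
             ">60 alignment-length rule): ", paste(nms[short], collapse = ", "))
    }
    new_panel_ref(data.table::data.table(
        name = nms, feature_type = types, sequence = seq_chr,
        length = nchar(seq_chr)))
}

resolve_feature_types <- function(names, feature_type_map) {
    types <- rep("mrna", length(names))
    if (is.null(feature_type_map)) return(types)
    if (is.character(feature_type_map) && length(feature_type_map) == 1L &&
        is.null(names(feature_type_map)) && file.exists(feature_type_map)) {
        tab <- read.table(feature_type_map, sep = "\t", header = FALSE,
                          col.names = c("name", "type"),
                          colClasses = "character")
        feature_type_map <- stats::setNames(tab$type, tab$name)
    }
    if (is.null(names(feature_type_map))) {
        stop("feature_type_map must be a named vector or a two-column TSV path")
    }
    ok <- feature_type_map %in% c("mrna", "abtag", "decoy")
    if (!all(ok)) {
        stop("unknown feature types: ",
             paste(unique(feature_type_map[!ok]), collapse = ", "))
    }
    hit <- match(names, names(feature_type_map))
    types[!is.na(hit)] <- unname(feature_type_map[hit[!is.na(hit)]])
    types
}

new_panel_ref <- function(features, kmer_index = NULL, k = NA_integer_) {
    structure(list(features = features, kmer_index = kmer_index, k = k),
              class = "panel_ref")
}

#' @export
print.panel_ref <- function(x, ...) {
    tab <- table(x$features$feature_type)
    cat("panel_ref:", nrow(x$features), "features (",
        paste(names(tab), tab, sep = "=", collapse = ", "), ")\n")
    if (!is.na(x$k)) {
        cat("  k-mer index: k =", x$k, ",",
            nrow(x$kmer_index), "postings\n")
    }
    invisible(x)
}

#' Countable features of a panel
#'
#' mRNA and antibody-tag features, in panel order; decoys are excluded.
#' @param panel A `panel_ref`.
#' @return Character vector of feature names.
#' @export
countable_features <- function(panel) {
    panel$features[panel$features$feature_type != "decoy", ]$name
}

#' Build the panel k-mer seed index
#'
#' Indexes every k-mer of every feature (decoys included, so decoy hits can
#' be detected) as (feature, offset) postings. k-mers containing N are never
#' indexed and never match a seed.
#'
#' @param panel A `panel_ref` from [load_panel()].
#' @param k Seed length; `8 <= k <= 32` and not larger than the shortest
#'   feature. Default 18: shorter than the 61-nt minimum alignment span so
#'   every valid read carries at least one seed, long enough that chance
#'   k-mer collisions on a panel of a few hundred features are negligible.
#' @return The `panel_ref` with a `kmer_index` data.table (keyed by `kmer`,
#'   columns `feat` = feature row index, `off` = 0-based offset).
#' @export
build_kmer_index <- function(panel, k = 18L) {
    stopifnot(inherits(panel, "panel_ref"))
    k <- as.integer(k)
    if (k < 8L || k > 32L) stop("k must be in [8, 32], got ", k)
    if (k > min(panel$features$length)) {
        stop("k = ", k, " larger than shortest feature (",
             min(panel$features$length), " nt)")
    }
    posts <- lapply(seq_len(nrow(panel$features)), function(i) {
        s <- panel$features$sequence[i]
        L <- panel$features$length[i]
        off <- 0:(L - k)
        data.table::data.table(
            kmer = substring(s, off + 1L, off + k),
            feat = i, off = off)
    })
    idx <- data.table::rbindlist(posts)
    idx <- idx[!grepl("N", idx$kmer, fixed = TRUE)]
    data.table::setkey(idx, kmer)
    new_panel_ref(panel$features, kmer_index = idx, k = k)
}

#' Query the k-mer index
#'
#' @param panel An indexed `panel_ref`.
#' @param kmers Character vector of k-mers (length-k strings).
#' @return data.table with columns `kmer`, `feat` (feature row index),
#'   `off` (0-based offset); zero rows for absent k-mers.
#' @export
query_kmers <- function(panel, kmers) {
    if (is.null(panel$kmer_index)) stop("panel is not indexed; run build_kmer_index()")
    hits <- panel$kmer_index[data.table::data.table(kmer = kmers),
                             on = "kmer", nomatch = NULL]
    hits[]
}

#' Write a panel to FASTA plus a feature-type TSV
#'
#' @param panel A `panel_ref`.
#' @param fasta_path Output FASTA path.
#' @param types_path Optional output path for the two-column
#'   name/feature-type TSV.
#' @return `fasta_path`, invisibly.
#' @export
write_panel_fasta <- function(panel, fasta_path, types_path = NULL) {
    dss <- Biostrings::DNAStringSet(panel$features$sequence)
    names(dss) <- panel$features$name
    Biostrings::writeXStringSet(dss, fasta_path)
    if (!is.null(types_path)) {
        write.table(panel$features[, c("name", "feature_type")], types_path,
                    sep = "\t", quote = FALSE, row.names = FALSE,
                    col.names = FALSE)
    }
    invisible(fasta_path)
}
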