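## R2 panel alignment: seed-and-extend, ungapped. Seeds of length k are
## taken at read offsets 0..4 (so alignments required to start in the first
## five bases are always seeded) and every floor(k/2) thereafter; each
## (feature, diagonal) candidate is extended ungapped over the full
## read/feature overlap with leading and trailing mismatch runs trimmed
## (the soft-clip analogue: `read_start` reports where the alignment
## actually begins). A candidate is viable when its aligned span is at
## least `min_overlap` columns with a mismatch fraction <= `max_mismatch`.
## Validity then applies, in order: no decoy hit, unique feature (within a
## score margin), alignment start within the first five read bases,
## aligned span > 60 columns.

#' Align one R2 read to the panel
#'
#' @param seq R2 nucleotide string (>= 61 nt).
#' @param panel An indexed `panel_ref` (see [build_kmer_index()]).
#' @param max_mismatch Maximum mismatch fraction over the aligned span for
#'   a candidate to be viable.
#' @param uniq_margin Score margin: features whose best score comes within
#'   this of the overall best count as competing candidates (guards against
#'   near-tie misassignment).
#' @param min_overlap Minimum aligned span (columns) for viability.
#' @param seed_stride Offset step between seeds after the first five
#'   positions; default `k/2`. A stride of 1 with `k = 8` makes detection
#'   of every viable alignment of 40+ columns provable (pigeonhole on
#'   mismatch-free runs) at the cost of denser lookups.
#' @return An `alignment_result` list: `feature` (name or `NA`),
#'   `feature_type`, `read_start` (0-based), `aln_len` (match+mismatch
#'   columns), `mismatches`, `n_candidates`, `decoy_hit`, `valid`,
#'   `reason` (`NA` when valid).
#' @export
align_r2 <- function(seq, panel, max_mismatch = 0.1, uniq_margin = 3L,
                     min_overlap = 30L, seed_stride = NULL) {
    stopifnot(length(seq) == 1L)
    res <- align_r2_batch(seq, panel, max_mismatch = max_mismatch,
                          uniq_margin = uniq_margin, min_overlap = min_overlap,
                          seed_stride = seed_stride)
    res <- validate_alignment(res)
    out <- as.list(res[1, !"read"])
    class(out) <- "alignment_result"
    out
}

#' @export
print.alignment_result <- function(x, ...) {
    cat("alignment_result:",
        if (is.na(x$feature)) "(no feature)" else x$feature,
        "read_start =", x$read_start, "aln_len =", x$aln_len,
        "mismatches =", x$mismatches, "candidates =", x$n_candidates, "\n")
    cat("  ", if (x$valid) "valid" else paste0("invalid (", x$reason, ")"), "\n")
    invisible(x)
}

## Vectorized alignment of many reads; returns one row per read.
align_r2_batch <- function(seqs, panel, max_mismatch = 0.1, uniq_margin = 3L,
                           min_overlap = 30L, seed_stride = NULL) {
    if (is.null(panel$kmer_index)) stop("panel is not indexed; run build_kmer_index()")
    k <- panel$k
    n <- length(seqs)
    len <- nchar(seqs)
    stride <- if (is.null(seed_stride)) max(1L, k %/% 2L) else as.integer(seed_stride)
    offs <- unique(c(0:4, seq.int(stride, max(len) - k, by = stride)))

    seed_tabs <- lapply(offs, function(o) {
        sel <- which(len >= o + k)
        if (!length(sel)) return(NULL)
        data.table::data.table(read = sel, roff = o,
                               kmer = substr(seqs[sel], o + 1L, o + k))
    })
    seeds <- data.table::rbindlist(seed_tabs)
    hits <- panel$kmer_index[seeds, on = "kmer", nomatch = NULL]
    empty <- data.table::data.table(
        read = seq_len(n), feature = NA_character_,
        feature_type = NA_character_, read_start = 0L, aln_len = 0L,
        mismatches = 0L, n_candidates = 0L, decoy_hit = FALSE,
        score = NA_integer_)
    if (nrow(hits) == 0L) return(empty)

    cand <- unique(hits[, .(read, feat, diag = off - roff)])
    ext <- extend_ungapped(seqs[cand$read],
                           panel$features$sequence[cand$feat],
                           cand$diag)
    cand[, `:=`(read_start = ext[, "read_start"],
                aln_len = ext[, "aln_len"],
                mismatches = ext[, "mismatches"])]
    cand <- cand[aln_len >= min_overlap & mismatches <= max_mismatch * aln_len]
    if (nrow(cand) == 0L) return(empty)
    cand[, score := aln_len - 2L * mismatches]
    cand[, `:=`(ftype = panel$features$feature_type[feat],
                fname = panel$features$name[feat])]

    decoy <- cand[ftype == "decoy", .(decoy_hit = TRUE), by = read]
    cand <- cand[ftype != "decoy"]
    per_read <- if (nrow(cand)) {
        best_feat <- cand[order(read, fname),
                          .SD[which.max(score)],
                          by = .(read, fname)]
        best_feat[, {
            b <- max(score)
            within <- score >= b - uniq_margin
            top <- which(score == b)[1]  # fname-ordered: lexicographic tie-break
            .(feature = fname[top],
              feature_type = ftype[top],
              read_start = read_start[top],
              aln_len = aln_len[top],
              mismatches = mismatches[top],
              n_candidates = sum(within),
              score = b)
        }, by = read]
    } else NULL

    out <- empty[, !"decoy_hit"]
    if (!is.null(per_read)) {
        out <- out[!read %in% per_read$read]
        out <- rbind(out, per_read[, names(out), with = FALSE])
    }
    out <- merge(out, decoy, by = "read", all.x = TRUE)
    out[is.na(decoy_hit), decoy_hit := FALSE]
    data.table::setorder(out, read)
    out[]
}

#' Validate an alignment against the four R2 validity rules
#'
#' Rules, applied in fixed order with the first failure reported: the read
#' must not align to the decoy, must align to exactly one feature (within
#' the uniqueness margin), the alignment must begin within the first five
#' read bases (0-based start <= 4), and the aligned span must exceed 60
#' match-or-mismatch columns.
#'
#' @param aln An `alignment_result` from [align_r2()] (or the batch table).
#' @param max_read_start Largest admissible 0-based alignment start (4).
#' @param min_aln_len Aligned span must be strictly greater than this (60).
#' @return The input with `valid` (logical) and `reason` (`NA`, `decoy`,
#'   `unaligned`, `multimapped`, `start` or `aln_len`).
#' @export
validate_alignment <- function(aln, max_read_start = 4L, min_aln_len = 60L) {
    single <- inherits(aln, "alignment_result")
    tab <- if (single) data.table::as.data.table(unclass(aln)[
        c("feature", "feature_type", "read_start", "aln_len",
          "mismatches", "n_candidates", "decoy_hit")]) else aln
    reason <- rep(NA_character_, nrow(tab))
    hit <- function(cond, lab) {
        sel <- is.na(reason) & cond
        reason[sel] <<- lab
    }
    hit(tab$decoy_hit, "decoy")
    hit(tab$n_candidates == 0L, "unaligned")
    hit(tab$n_candidates > 1L, "multimapped")
    hit(tab$read_start > max_read_start, "start")
    hit(tab$aln_len <= min_aln_len, "aln_len")
    if (single) {
        aln$valid <- is.na(reason)
        aln$reason <- reason
        return(aln)
    }
    tab <- data.table::copy(tab)
    tab[, `:=`(valid = is.na(reason), reason = reason)]
    tab[]
}
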