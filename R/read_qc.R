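#' Read-level quality-control thresholds
#'
#' Defaults are the pipeline's standard filters: drop a pair when R1 is
#' shorter than 66 nt or R2 shorter than 64 nt, when either mate's mean
#' Phred score is below 20, or when a mate is low-complexity — R1
#' single-nucleotide frequency (SNF) >= 0.55 or R2 SNF >= 0.80 (the SNF
#' boundary itself fails, as the thresholds are stated inclusively).
#'
#' @param min_r1_len,min_r2_len Minimum mate lengths (nt).
#' @param min_mean_qual Minimum mean Phred score, tested per mate.
#' @param max_r1_snf,max_r2_snf SNF at or above which a mate is dropped.
#' @return A `qc_thresholds` list.
#' @export
qc_thresholds <- function(min_r1_len = 66L, min_r2_len = 64L,
                          min_mean_qual = 20, max_r1_snf = 0.55,
                          max_r2_snf = 0.80) {
    stopifnot(min_r1_len > 0L, min_r2_len > 0L,
              max_r1_snf > 0, max_r1_snf <= 1,
              max_r2_snf > 0, max_r2_snf <= 1)
    structure(list(min_r1_len = as.integer(min_r1_len),
                   min_r2_len = as.integer(min_r2_len),
                   min_mean_qual = min_mean_qual,
                   max_r1_snf = max_r1_snf,
                   max_r2_snf = max_r2_snf),
              class = "qc_thresholds")
}

#' Single-nucleotide frequency (SNF) of a read
#'
#' Fraction of the read occupied by its most frequent base (maximum over
#' A/C/G/T/N of count divided by read length): a low-complexity measure.
#' Computed over the full read, poly(T) tail included.
#'
#' @param seq Character vector of nucleotide strings.
#' @return Numeric vector of SNF values in (0, 1].
#' @examples
#' snf(c("AAAAAAAA", "ACGTACGT", "AACCCGTT"))  # 1, 0.25, 0.375
#' @export
snf <- function(seq) {
    if (any(nchar(seq) == 0L)) stop("snf undefined for empty sequence")
    counts <- Biostrings::letterFrequency(Biostrings::DNAStringSet(seq),
                                          c("A", "C", "G", "T", "N"))
    apply(counts, 1, max) / nchar(seq)
}

#' Mean base quality of a read
#'
#' @param qual Either a numeric vector of Phred scores (one read) or a
#'   character vector of Phred+33 quality strings (one value per string).
#' @return Arithmetic mean Phred score(s).
#' @export
mean_quality <- function(qual) {
    if (is.numeric(qual)) {
        if (length(qual) == 0L) stop("mean_quality undefined for empty input")
        return(mean(qual))
    }
    if (any(nchar(qual) == 0L)) stop("mean_quality undefined for empty input")
    mean_phred(qual)
}

## Vectorized QC over a read-pair table; returns the table with `kept`
## (logical) and `drop_reason` (NA when kept). Reasons are assigned in a
## fixed order: length, quality, SNF (R1 before R2 within each rule).
qc_filter <- function(pairs, th = qc_thresholds()) {
    r1_len <- nchar(pairs$r1_seq)
    r2_len <- nchar(pairs$r2_seq)
    q1 <- mean_phred(pairs$r1_qual)
    q2 <- mean_phred(pairs$r2_qual)
    s1 <- snf(pairs$r1_seq)
    s2 <- snf(pairs$r2_seq)
    reason <- rep(NA_character_, nrow(pairs))
    hit <- function(cond, lab) {
        sel <- is.na(reason) & cond
        reason[sel] <<- lab
    }
    hit(r1_len < th$min_r1_len, "r1_length")
    hit(r2_len < th$min_r2_len, "r2_length")
    hit(q1 < th$min_mean_qual, "r1_quality")
    hit(q2 < th$min_mean_qual, "r2_quality")
    hit(s1 >= th$max_r1_snf, "r1_snf")
    hit(s2 >= th$max_r2_snf, "r2_snf")
    out <- data.table::copy(pairs)
    out[, `:=`(kept = is.na(reason), drop_reason = reason)]
    out[]
}

#' Filter one read pair
#'
#' Applies the read-level filters to a single R1/R2 pair and reports the
#' verdict with the first failing rule as the reason. Rules, in order:
#' mate length (R1 then R2), mean quality per mate, SNF per mate.
#'
#' @param r1_seq,r2_seq Mate sequences.
#' @param r1_qual,r2_qual Phred+33 quality strings (or numeric Phred
#'   vectors) matching the mate lengths.
#' @param th A [qc_thresholds()].
#' @return List with `kept` (logical) and `reason` (`NA` if kept; otherwise
#'   one of `r1_length`, `r2_length`, `r1_quality`, `r2_quality`, `r1_snf`,
#'   `r2_snf`).
#' @export
filter_read_pair <- function(r1_seq, r2_seq, r1_qual, r2_qual,
                             th = qc_thresholds()) {
    to_str <- function(q, len) {
        if (is.numeric(q)) rawToChar(as.raw(as.integer(q) + 33L)) else q
    }
    r1_qual <- to_str(r1_qual)
    r2_qual <- to_str(r2_qual)
    if (nchar(r1_qual) != nchar(r1_seq) || nchar(r2_qual) != nchar(r2_seq)) {
        stop("sequence and quality lengths differ")
    }
    v <- qc_filter(data.table::data.table(
        r1_seq = r1_seq, r2_seq = r2_seq,
        r1_qual = r1_qual, r2_qual = r2_qual), th)
    list(kept = v$kept, reason = v$drop_reason)
}
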