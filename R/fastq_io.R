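#' Write a FASTQ file
#'
#' @param ids Read identifiers (without the leading `@`).
#' @param seqs Nucleotide strings.
#' @param quals Phred+33 quality strings, same lengths as `seqs`.
#' @param path Output path; `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(ids, seqs, quals, path) {
    stopifnot(length(ids) == length(seqs), length(seqs) == length(quals))
    ## construction re-wraps the DNAStringSet and warns about dropping its
    ## (empty) metadata columns; nothing is lost
    qs <- suppressWarnings(Biostrings::QualityScaledDNAStringSet(
        Biostrings::DNAStringSet(seqs),
        Biostrings::PhredQuality(quals)))
    names(qs) <- ids
    Biostrings::writeQualityScaledXStringSet(
        qs, path, compress = grepl("\\.gz$", path))
    invisible(path)
}

#' Read a paired FASTQ into a read-pair table
#'
#' @param r1_path,r2_path Paths to the R1/R2 FASTQ files (optionally
#'   gzipped). Mates are paired by file order; identifiers must agree.
#' @return data.table with columns `read_id`, `r1_seq`, `r2_seq`,
#'   `r1_qual`, `r2_qual` (quality strings, Phred+33).
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
    ## the reader wraps its parsed records into a quality-scaled set and
    ## warns about dropping the (empty) per-record metadata; nothing is lost
    r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1_path))
    r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2_path))
    if (length(r1) != length(r2)) stop("R1/R2 read counts differ")
    id1 <- sub("\\s.*$", "", names(r1))
    id2 <- sub("\\s.*$", "", names(r2))
    if (!identical(id1, id2)) stop("R1/R2 read identifiers do not pair up")
    ## the DNAStringSet coercion warns about dropping the (empty) metadata
    ## columns that the FASTQ reader attaches; nothing is lost
    suppressWarnings(data.table::data.table(
        read_id = id1,
        r1_seq = as.character(r1),
        r2_seq = as.character(r2),
        r1_qual = as.character(Biostrings::quality(r1)),
        r2_qual = as.character(Biostrings::quality(r2))))
}

## mean Phred score per quality string, vectorized
mean_phred <- function(qual_strings) {
    out <- vapply(qual_strings, function(q) {
        if (nchar(q) == 0L) return(NA_real_)
        mean(as.integer(charToRaw(q))) - 33
    }, numeric(1), USE.NAMES = FALSE)
    out
}
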