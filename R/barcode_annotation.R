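## R1 annotation: recover the three cell-label sections (CLS1/2/3), the UMI
## and the poly(T) verdict from each quality-passing R1 read.
##
## Read anatomy (1-based): CLS1 1-9 | L1 10-21 | CLS2 22-30 | L2 31-43 |
## CLS3 44-52 | UMI 53-60 | poly(T). Three passes:
##   1. perfect: all three 9-mers found verbatim at their fixed offsets;
##   2. substitution: each unmatched section assigned to the unique
##      whitelist entry at Hamming distance <= 1 (ambiguity => invalid);
##   3. indel: exactly one single-base insertion or deletion anywhere in the
##      52-nt label region. Candidate frames place the indel in one of the
##      five segments; sections downstream shift by +-1, and a CLS segment
##      carrying the indel itself is matched at Levenshtein distance 1 over
##      its 8- or 10-nt window. A frame wins only if all three sections
##      resolve uniquely; disagreeing frames => invalid (never guess).
## The UMI is the 8 bases immediately after the end of the identified CLS3.

SEGMENT_STARTS <- c(1L, 10L, 22L, 31L, 44L)   # 1-based starts of the 5 segments
CLS_SEGMENTS <- c(1L, 3L, 5L)                 # which segments are CLS sections

#' Check the poly(T) tail after the UMI
#'
#' The window is the `min(8, bases remaining)` bases after the UMI; the
#' read passes when the window holds at least 6 bases and all but at most
#' `slack` of them are T. The default `slack = 1` encodes the "more than 6
#' of 8" rule (7 of 8 passes, 6 of 8 fails).
#'
#' @param seq R1 sequence.
#' @param umi_end 0-based offset one past the UMI's last base.
#' @param min_window Minimum window size; shorter tails fail.
#' @param max_window Bases inspected (8).
#' @param slack Number of non-T bases tolerated in the window.
#' @return Logical.
#' @export
check_polyt <- function(seq, umi_end, min_window = 6L, max_window = 8L,
                        slack = 1L) {
    n <- nchar(seq)
    if (any(umi_end > n)) stop("umi_end beyond end of sequence")
    w <- pmin(max_window, n - umi_end)
    window <- substr(seq, umi_end + 1L, umi_end + w)
    n_t <- nchar(gsub("[^T]", "", window))
    w >= min_window & n_t >= w - slack
}

## Resolve one 9-nt section against a whitelist at Hamming distance <= 1.
## Returns list(idx, d) (1-based whitelist index, distance) or NULL when
## unmatched or ambiguous.
resolve_section <- function(section, wl_entries) {
    d <- hamming_to_table(section, wl_entries)
    cand <- which(d <= 1L)
    if (length(cand) == 1L) list(idx = cand, d = d[cand]) else NULL
}

## Resolve a CLS window of length 8 or 10 (carries the single indel)
## against a whitelist at Levenshtein distance 1 (the one edit being the
## indel itself, so its extra substitution cost is 0).
resolve_section_indel <- function(window, wl_entries) {
    d <- adist(window, wl_entries)
    cand <- which(d == 1L)
    if (length(cand) == 1L) list(idx = cand, d = 0L) else NULL
}

## Substitution cost of the linkers under a frame hypothesis. The linkers
## anchor the label-region frame: a shifted (indel-bearing) read shows
## near-random content at an unshifted linker position (expected Hamming
## ~9 of 12), so a small tolerance separates true frames from chance CLS
## hits. Returns the summed extra substitutions, or NA when either linker
## exceeds `max_mismatch`.
linker_cost <- function(seq, wl, shift = 0L, indel_segment = 0L,
                        max_mismatch = 2L) {
    cost <- 0L
    for (li in 1:2) {
        segment <- c(2L, 4L)[li]
        linker <- c(wl$linker1, wl$linker2)[li]
        width <- nchar(linker)
        s <- SEGMENT_STARTS[segment]
        if (segment == indel_segment) {
            win <- substr(seq, s, s + width - 1L + shift)
            d <- adist(win, linker)[1] - 1L  # the indel itself costs nothing
        } else {
            s <- if (segment > indel_segment) s + shift else s
            win <- substr(seq, s, s + width - 1L)
            d <- hamming_to_table(win, linker)
        }
        if (is.na(d) || d > max_mismatch) return(NA_integer_)
        cost <- cost + d
    }
    cost
}

## Enumerate label-region interpretations of one read. Each interpretation
## is list(idx = c(i1,i2,i3), shift = 0/+1/-1, cost) where cost counts the
## corruption events it assumes (substitutions in sections and linkers,
## plus 1 for a hypothesized indel). shift = 0 is the substitution-only
## reading; the ten indel frames place a single insertion or deletion in
## one of the five segments and shift everything downstream.
enumerate_label_frames <- function(seq, wl) {
    wls <- list(wl$cls1, wl$cls2, wl$cls3)
    hits <- list()
    add_frame <- function(shift, j, base_cost) {
        lc <- linker_cost(seq, wl, shift = shift, indel_segment = j)
        if (is.na(lc)) return()
        idx <- integer(3)
        cost <- base_cost + lc
        for (ci in 1:3) {
            segment <- CLS_SEGMENTS[ci]
            s <- SEGMENT_STARTS[segment]
            r <- if (segment < j || j == 0L) {
                resolve_section(substr(seq, s, s + 8L), wls[[ci]])
            } else if (segment > j) {
                resolve_section(substr(seq, s + shift, s + shift + 8L),
                                wls[[ci]])
            } else {
                resolve_section_indel(substr(seq, s, s + 8L + shift),
                                      wls[[ci]])
            }
            if (is.null(r)) return()
            idx[ci] <- r$idx
            cost <- cost + r$d
        }
        hits[[length(hits) + 1L]] <<- list(idx = idx, shift = shift,
                                           cost = cost)
    }
    add_frame(0L, 0L, 0L)                              # substitution-only
    for (shift in c(-1L, 1L)) for (j in 1:5) add_frame(shift, j, 1L)
    if (length(hits) == 0L) return(list())
    hits <- hits[order(vapply(hits, function(h) as.numeric(h$cost),
                              numeric(1)))]
    keys <- vapply(hits, function(h) paste(c(h$idx, h$shift), collapse = "_"),
                   character(1))
    hits[!duplicated(keys)]  # per (triple, shift): keep its cheapest reading
}

## Vectorized annotation of many R1 sequences. Returns a data.table with
## cls1/cls2/cls3 (1-based whitelist indices or NA), cell_label, umi,
## umi_start (0-based), status, polyt_pass, r1_valid.
annotate_r1_batch <- function(seqs, wl, polyt_slack = 1L) {
    n <- length(seqs)
    len <- nchar(seqs)
    i1 <- match(substr(seqs, 1L, 9L), wl$cls1)
    i2 <- match(substr(seqs, 22L, 30L), wl$cls2)
    i3 <- match(substr(seqs, 44L, 52L), wl$cls3)
    status <- rep("invalid", n)
    shift <- rep(0L, n)
    too_short <- len < 66L
    perfect <- !too_short & !is.na(i1) & !is.na(i2) & !is.na(i3)
    status[perfect] <- "perfect"

    ## Passes 2 and 3: enumerate substitution-only and single-indel
    ## readings of the label region, score each by the corruption events
    ## it assumes, and accept only when all minimum-cost readings agree on
    ## the label triple (and, for indel readings, on the UMI shift).
    ## Disagreement among equally parsimonious readings makes the read
    ## invalid: never guess.
    todo <- which(!perfect & !too_short)
    for (r in todo) {
        frames <- enumerate_label_frames(seqs[r], wl)
        if (length(frames) == 0L) next
        costs <- vapply(frames, function(h) as.numeric(h$cost), numeric(1))
        top <- frames[costs == min(costs)]
        triples <- unique(vapply(top, function(h)
            paste(h$idx, collapse = "_"), character(1)))
        shifts <- unique(vapply(top, `[[`, integer(1), "shift"))
        if (length(triples) != 1L) next           # ambiguous label
        if (any(shifts == 0L)) {
            best <- top[[which(vapply(top, `[[`, integer(1), "shift") == 0L)[1]]]
            status[r] <- "substitution_corrected"
        } else {
            if (length(shifts) != 1L) next        # UMI frame ambiguous
            best <- top[[1]]
            status[r] <- "indel_corrected"
            shift[r] <- best$shift
        }
        i1[r] <- best$idx[1]; i2[r] <- best$idx[2]; i3[r] <- best$idx[3]
    }

    invalid <- status == "invalid"
    i1[invalid] <- NA_integer_; i2[invalid] <- NA_integer_; i3[invalid] <- NA_integer_
    umi_start <- 52L + shift                       # 0-based
    umi <- substr(seqs, umi_start + 1L, umi_start + 8L)
    umi[invalid] <- NA_character_
    polyt <- rep(FALSE, n)
    ok <- which(!invalid)
    if (length(ok)) {
        polyt[ok] <- check_polyt(seqs[ok], umi_start[ok] + 8L,
                                 slack = polyt_slack)
    }
    umi_ok <- !invalid & !is.na(umi) & !grepl("N", umi, fixed = TRUE) &
        nchar(umi) == 8L
    data.table::data.table(
        cls1 = i1, cls2 = i2, cls3 = i3,
        cell_label = ifelse(invalid, NA_character_,
                            paste(i1, i2, i3, sep = "_")),
        umi = umi, umi_start = ifelse(invalid, NA_integer_, umi_start),
        status = status, polyt_pass = polyt,
        r1_valid = umi_ok & polyt)
}

#' Annotate one R1 read
#'
#' Recovers the cell-label section indices, UMI and poly(T) verdict from an
#' R1 sequence (see the package vignette for the three recovery passes).
#'
#' @param seq R1 nucleotide string, length >= 66.
#' @param wl A `whitelists` object.
#' @param polyt_slack Non-T bases tolerated in the poly(T) window
#'   (see [check_polyt()]).
#' @return List with `cls_indices` (integer triple of 1-based whitelist
#'   indices, NA when invalid), `cell_label`, `umi`, `umi_start` (0-based),
#'   `polyt_pass`, `status` (`perfect`, `substitution_corrected`,
#'   `indel_corrected` or `invalid`) and `valid` (label resolved, UMI free
#'   of N, poly(T) present).
#' @examples
#' wl <- generate_whitelists(seed = 7)
#' r1 <- paste0(wl$cls1[6], wl$linker1, wl$cls2[18], wl$linker2, wl$cls3[4],
#'              "ACGTACGT", strrep("T", 10))
#' annotate_r1(r1, wl)$cls_indices
#' @export
annotate_r1 <- function(seq, wl, polyt_slack = 1L) {
    stopifnot(length(seq) == 1L)
    if (nchar(seq) < 66L) stop("R1 shorter than 66 nt")
    a <- annotate_r1_batch(seq, wl, polyt_slack = polyt_slack)
    list(cls_indices = c(a$cls1, a$cls2, a$cls3),
         cell_label = a$cell_label,
         umi = a$umi,
         umi_start = a$umi_start,
         polyt_pass = a$polyt_pass,
         status = a$status,
         valid = a$r1_valid)
}
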