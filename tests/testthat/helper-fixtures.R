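library(data.table)

## Session-cached fixtures: whitelist generation and panel synthesis are
## deterministic but not free, so build them once.
.fixture_cache <- new.env()

fixture_whitelists <- function() {
    if (is.null(.fixture_cache$wl)) {
        .fixture_cache$wl <- generate_whitelists(seed = 7)
    }
    .fixture_cache$wl
}

## 25 mRNA + 5 abtag (30 countable features) + 1 decoy, indexed at k = 18
fixture_panel <- function() {
    if (is.null(.fixture_cache$panel)) {
        .fixture_cache$panel <- build_kmer_index(
            synthesize_panel(n_mrna = 25L, n_abtag = 5L, seed = 3))
    }
    .fixture_cache$panel
}

## Clean R1 for whitelist indices (i1, i2, i3): the standard anatomy with
## a 10-nt poly(T) tail (70 nt total).
make_r1 <- function(wl, i1, i2, i3, umi = "ACGTACGT", tail = strrep("T", 10)) {
    paste0(wl$cls1[i1], wl$linker1, wl$cls2[i2], wl$linker2, wl$cls3[i3],
           umi, tail)
}

## Replace one base at `pos` (1-based) with a different one, deterministically.
flip_base <- function(seq, pos) {
    bases <- c("A", "C", "G", "T")
    old <- substr(seq, pos, pos)
    new <- bases[bases != old][1]
    substr(seq, pos, pos) <- new
    seq
}

## ---- independent oracles --------------------------------------------------

## Brute-force ungapped aligner: every feature, every diagonal, full
## overlap, trim leading/trailing mismatch runs. Pure R character ops,
## no seeding, no shared code with the package aligner.
oracle_align <- function(read, features, max_mm = 0.1, margin = 3,
                         min_ov = 30) {
    rch <- strsplit(read, "")[[1]]
    lr <- length(rch)
    best <- list()
    decoy <- FALSE
    for (fi in seq_len(nrow(features))) {
        fch <- strsplit(features$sequence[fi], "")[[1]]
        lf <- length(fch)
        fb <- NULL
        for (d in (-(lr - 1)):(lf - 1)) {
            i0 <- max(0, -d)
            i1 <- min(lr, lf - d) - 1
            if (i1 < i0) next
            idx <- i0:i1
            mm <- rch[idx + 1] != fch[idx + d + 1]
            a <- which(!mm)[1]
            b <- rev(which(!mm))[1]
            if (is.na(a)) next
            span <- idx[a:b]
            mism <- sum(mm[a:b])
            alen <- length(span)
            if (alen < min_ov || mism > max_mm * alen) next
            sc <- alen - 2 * mism
            if (is.null(fb) || sc > fb$score) {
                fb <- list(score = sc, read_start = span[1], aln_len = alen,
                           mism = mism)
            }
        }
        if (!is.null(fb)) {
            if (features$feature_type[fi] == "decoy") decoy <- TRUE
            else best[[features$name[fi]]] <- fb
        }
    }
    if (!length(best)) {
        return(list(feature = NA_character_, aln_len = 0L, n_candidates = 0L,
                    decoy_hit = decoy))
    }
    scs <- vapply(best, `[[`, numeric(1), "score")
    b <- max(scs)
    ch <- sort(names(best)[scs == b])[1]
    list(feature = ch, aln_len = best[[ch]]$aln_len,
         n_candidates = sum(scs >= b - margin), decoy_hit = decoy)
}

## Exhaustive RSEC merge-order enumeration. The merge rule processes the
## lowest-depth mergeable UMI first (the order is part of the rule: freer
## orders can change the outcome); the only freedom left is among
## equal-depth mergeable children, which the implementation breaks
## lexicographically. The oracle explores every rule-consistent choice at
## each step and returns the set of distinct final states.
oracle_rsec_enum <- function(umis, depths) {
    ham <- function(a, b) sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    final_states <- list()
    recurse <- function(u, d) {
        children <- Filter(function(i) {
            any(vapply(seq_along(u), function(j) {
                j != i && ham(u[i], u[j]) == 1 && d[j] > d[i]
            }, logical(1)))
        }, seq_along(u))
        if (!length(children)) {
            key <- paste(u[order(u)], d[order(u)], collapse = ";")
            final_states[[key]] <<- list(umi = u[order(u)], depth = d[order(u)])
            return()
        }
        dmin <- min(d[children])
        for (ci in children[d[children] == dmin]) {
            nb <- Filter(function(j) {
                j != ci && ham(u[ci], u[j]) == 1 && d[j] > d[ci]
            }, seq_along(u))
            nb <- nb[order(-d[nb], u[nb])]
            parent <- nb[1]
            d2 <- d
            d2[parent] <- d2[parent] + d2[ci]
            recurse(u[-ci], d2[-ci])
        }
    }
    recurse(umis, depths)
    final_states
}

## Independent DBEC threshold search: naive likelihood over all splits,
## written from the model definition (geometric with sample-mean parameter).
oracle_dbec_threshold <- function(depths, min_fold = 4) {
    cand <- sort(unique(depths))
    cand <- cand[-length(cand)]
    if (!length(cand)) return(NULL)
    ll <- function(d) {
        p <- 1 / mean(d)
        sum(log(p) + (d - 1) * log1p(-p + (p == 1)))  # log(p (1-p)^(d-1))
    }
    scores <- vapply(cand, function(t) {
        ll(depths[depths <= t]) + ll(depths[depths > t])
    }, numeric(1))
    t <- cand[which.max(scores)]
    lo <- depths[depths <= t]
    hi <- depths[depths > t]
    list(threshold = t, separated = mean(hi) / mean(lo) >= min_fold)
}

## Fisher's exact test by full hypergeometric enumeration with binomial
## coefficients (two-sided, sum of table probabilities <= observed).
oracle_fisher_enum <- function(k1, n1, k2, n2) {
    K <- k1 + k2
    N <- n1 + n2
    xs <- max(0, K - n2):min(K, n1)
    p_of <- function(x) {
        exp(lchoose(n1, x) + lchoose(n2, K - x) - lchoose(N, K))
    }
    probs <- vapply(xs, p_of, numeric(1))
    sum(probs[probs <= p_of(k1) * (1 + 1e-7)])
}
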