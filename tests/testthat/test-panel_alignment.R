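test_that("an exact substring aligns validly with full span", {
    panel <- fixture_panel()
    feat <- panel$features[feature_type == "mrna"][1]
    read <- substr(feat$sequence, 11, 80)
    a <- align_r2(read, panel)
    expect_equal(a$feature, feat$name)
    expect_equal(a$read_start, 0L)
    expect_equal(a$aln_len, 70L)
    expect_equal(a$n_candidates, 1L)
    expect_true(a$valid)
})

test_that("a 60-column alignment fails the >60 rule", {
    panel <- fixture_panel()
    feat <- panel$features[feature_type == "mrna"][1]
    L <- feat$length
    ## 60-nt suffix of the feature plus 10 bases beyond its end: the
    ## overlap (and so the aligned span) is exactly 60 columns
    read <- paste0(substring(feat$sequence, L - 59), strrep("A", 10))
    a <- align_r2(read, panel)
    expect_equal(a$aln_len, 60L)
    expect_false(a$valid)
    expect_equal(a$reason, "aln_len")
})

test_that("decoy reads are invalid even with a perfect alignment", {
    panel <- fixture_panel()
    dec <- panel$features[feature_type == "decoy"]
    read <- substr(dec$sequence, 101, 170)
    a <- align_r2(read, panel)
    expect_true(a$decoy_hit)
    expect_false(a$valid)
    expect_equal(a$reason, "decoy")
})

test_that("a region duplicated across two features is not unique", {
    set.seed(9)
    pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
    shared <- pad(100)
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">dupA", paste0(pad(50), shared),
                 ">dupB", paste0(shared, pad(80))), fa)
    panel <- build_kmer_index(load_panel(fa), k = 18L)
    read <- substr(shared, 16, 85)
    a <- align_r2(read, panel)
    expect_equal(a$n_candidates, 2L)
    expect_false(a$valid)
    expect_equal(a$reason, "multimapped")
    ## oracle: exhaustive alignment of the read to every feature finds
    ## equal-score hits in both
    o <- oracle_align(read, panel$features)
    expect_equal(o$n_candidates, 2L)
})

test_that("alignment start beyond the first five nucleotides invalidates", {
    panel <- fixture_panel()
    feat <- panel$features[feature_type == "mrna"][2]
    fch <- strsplit(substr(feat$sequence, 1, 5), "")[[1]]
    junk5 <- paste(vapply(fch, function(b) setdiff(c("A", "C", "G", "T"), b)[1],
                          character(1)), collapse = "")
    ## 5 mismatching bases, then the feature from its first base: the
    ## alignment begins at 0-based read offset 5
    read5 <- paste0(junk5, substr(feat$sequence, 1, 65))
    a <- align_r2(read5, panel)
    expect_equal(a$read_start, 5L)
    expect_false(a$valid)
    expect_equal(a$reason, "start")
    ## 4 junk bases: starts at offset 4, still admissible
    read4 <- paste0(substr(junk5, 1, 4), substr(feat$sequence, 1, 66))
    a4 <- align_r2(read4, panel)
    expect_equal(a4$read_start, 4L)
    expect_true(a4$valid)
})

test_that("validity rule order is decoy, unique, start, length", {
    ## a read present verbatim in both the decoy and an mRNA feature
    set.seed(21)
    pad <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")
    shared <- pad(70)
    fa <- withr::local_tempfile(fileext = ".fa")
    writeLines(c(">gene", paste0(shared, pad(40)),
                 ">phix", paste0(pad(30), shared)), fa)
    panel <- build_kmer_index(load_panel(fa, c(phix = "decoy")), k = 18L)
    a <- align_r2(shared, panel)
    expect_true(a$decoy_hit)
    expect_equal(a$reason, "decoy")
})

test_that("seed-and-extend equals the brute-force oracle on random reads", {
    ## k = 8 with stride-1 seeding: every viable alignment of >= 40 columns
    ## is provably seeded, so the two methods must agree exactly
    panel <- build_kmer_index(
        synthesize_panel(n_mrna = 4, n_abtag = 1, mrna_len = 200,
                         abtag_len = 80, decoy_len = 300, seed = 13), k = 8L)
    feats <- panel$features
    set.seed(55)
    reads <- character(300)
    for (i in seq_along(reads)) {
        if (runif(1) < 0.8) {
            fi <- sample(nrow(feats), 1)
            len <- sample(61:90, 1)
            s <- sample(feats$length[fi] - len + 1, 1)
            x <- substring(feats$sequence[fi], s, s + len - 1)
            nm <- rbinom(1, len, 0.03)
            if (nm > 0) {
                p <- sample(len, nm)
                xx <- strsplit(x, "")[[1]]
                xx[p] <- sample(c("A", "C", "G", "T"), nm, TRUE)
                x <- paste(xx, collapse = "")
            }
            reads[i] <- x
        } else {
            reads[i] <- paste(sample(c("A", "C", "G", "T"), 70, TRUE),
                              collapse = "")
        }
    }
    got <- abseqpipe:::align_r2_batch(reads, panel, seed_stride = 1L)
    for (i in seq_along(reads)) {
        o <- oracle_align(reads[i], feats)
        expect_equal(is.na(got$feature[i]), is.na(o$feature))
        if (!is.na(o$feature)) {
            expect_equal(got$feature[i], o$feature)
            expect_equal(got$aln_len[i], o$aln_len)
        }
        expect_equal(got$n_candidates[i], o$n_candidates)
        expect_equal(got$decoy_hit[i], o$decoy_hit)
    }
})

test_that("error-free simulator R2 reads are 100% valid", {
    wl <- fixture_whitelists()
    panel <- fixture_panel()
    cfg <- sim_config(n_cells = 30, n_noise_labels = 0, seed = 8,
                      cell_depth_lognormal = c(log(40), .2))
    run <- simulate_run(cfg, wl, panel, group = "aln")
    pairs <- read_fastq_pairs(run$r1_fastq, run$r2_fastq)
    aln <- validate_alignment(abseqpipe:::align_r2_batch(pairs$r2_seq, panel))
    expect_true(all(aln$valid))
    ## and each read maps to its true feature
    expect_identical(aln$feature, run$truth$ledger$feat)
})

test_that("aligning against an unindexed panel errors", {
    panel <- synthesize_panel(seed = 3)
    expect_error(align_r2(strrep("ACGT", 20), panel), "not indexed")
})
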