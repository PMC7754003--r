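test_that("perfect reads annotate at the fixed positions", {
    wl <- fixture_whitelists()
    r1 <- make_r1(wl, 6, 18, 4, umi = "ACGTACGT")
    a <- annotate_r1(r1, wl)
    expect_equal(a$cls_indices, c(6L, 18L, 4L))
    expect_equal(a$umi, "ACGTACGT")
    expect_equal(a$umi_start, 52L)
    expect_equal(a$status, "perfect")
    expect_true(a$valid)
})

test_that("a single substitution inside a CLS is corrected to the unique entry", {
    wl <- fixture_whitelists()
    r1 <- flip_base(make_r1(wl, 6, 18, 4), 25)  # inside CLS2 (22-30)
    a <- annotate_r1(r1, wl)
    expect_equal(a$status, "substitution_corrected")
    expect_equal(a$cls_indices, c(6L, 18L, 4L))
    ## oracle: exhaustive whitelist scan of the corrupted section
    sec <- substr(r1, 22, 30)
    d <- adist(sec, wl$cls2, costs = list(ins = 9, del = 9, sub = 1))
    expect_equal(which(d <= 1), 18L)
})

test_that("a deletion in L1 is frame-recovered with the UMI shifted left", {
    wl <- fixture_whitelists()
    clean <- make_r1(wl, 6, 18, 4)
    r1 <- paste0(substr(clean, 1, 11), substring(clean, 13))  # drop L1 base
    a <- annotate_r1(r1, wl)
    expect_equal(a$status, "indel_corrected")
    expect_equal(a$cls_indices, c(6L, 18L, 4L))
    expect_equal(a$umi_start, 51L)
    expect_equal(a$umi, "ACGTACGT")
})

test_that("an insertion in L2 is frame-recovered with the UMI shifted right", {
    wl <- fixture_whitelists()
    clean <- make_r1(wl, 6, 18, 4)
    r1 <- paste0(substr(clean, 1, 35), "A", substring(clean, 36))
    a <- annotate_r1(r1, wl)
    expect_equal(a$status, "indel_corrected")
    expect_equal(a$cls_indices, c(6L, 18L, 4L))
    expect_equal(a$umi_start, 53L)
    expect_equal(a$umi, "ACGTACGT")
})

test_that("a deletion inside a CLS section is recovered", {
    wl <- fixture_whitelists()
    clean <- make_r1(wl, 6, 18, 4)
    r1 <- paste0(substr(clean, 1, 25), substring(clean, 27))  # CLS2 base gone
    a <- annotate_r1(r1, wl)
    expect_equal(a$status, "indel_corrected")
    expect_equal(a$cls_indices, c(6L, 18L, 4L))
    expect_equal(a$umi_start, 51L)
})

test_that("heavily corrupted reads are invalid, never guessed", {
    wl <- fixture_whitelists()
    r1 <- make_r1(wl, 6, 18, 4)
    r1 <- flip_base(flip_base(r1, 2), 5)    # 2 subs in CLS1
    r1 <- flip_base(flip_base(r1, 45), 48)  # 2 subs in CLS3
    a <- annotate_r1(r1, wl)
    expect_equal(a$status, "invalid")
    expect_true(is.na(a$cell_label))
    expect_false(a$valid)
})

test_that("reads shorter than 66 nt are rejected", {
    wl <- fixture_whitelists()
    expect_error(annotate_r1(strrep("A", 65), wl), "66")
})

test_that("poly(T) rule: more than 6 of 8 Ts required", {
    wl <- fixture_whitelists()
    base <- substr(make_r1(wl, 1, 1, 1), 1, 60)
    expect_true(check_polyt(paste0(base, "TTTTTTTT"), 60))
    expect_false(check_polyt(paste0(base, "TTTTTTAA"), 60))  # 6 of 8: fails
    expect_true(check_polyt(paste0(base, "TTTTTTTA"), 60))   # 7 of 8: passes
    ## short windows (< 6 bases after the UMI) always fail
    expect_false(check_polyt(paste0(base, "TTTTT"), 60))
    ## a 7-wide window passes with >= 6 Ts
    expect_true(check_polyt(paste0(base, "TTTTTTA"), 60))
    ## an N in the UMI invalidates the R1 even when the label resolves
    r1 <- make_r1(wl, 6, 18, 4, umi = "ACGTNCGT")
    expect_false(annotate_r1(r1, wl)$valid)
})

test_that("substitution recovery on simulated reads is sound", {
    wl <- fixture_whitelists()
    panel <- fixture_panel()
    cfg <- sim_config(n_cells = 80, n_noise_labels = 0, seed = 13,
                      cls_substitution_rate = 0.08,
                      cell_depth_lognormal = c(log(80), .2))
    run <- simulate_run(cfg, wl, panel, group = "sub")
    pairs <- read_fastq_pairs(run$r1_fastq, run$r2_fastq)
    led <- run$truth$ledger
    ann <- abseqpipe:::annotate_r1_batch(pairs$r1_seq, wl)
    ## every corrected read maps to its true origin triple
    corr <- ann$status == "substitution_corrected"
    expect_gt(sum(corr), 0)
    expect_true(all(ann$cell_label[corr] == led$label[corr]))
    ## zero false re-assignment anywhere
    assigned <- !is.na(ann$cell_label)
    expect_true(all(ann$cell_label[assigned] == led$label[assigned]))
    ## monotone pass ordering: clean reads are perfect, never "recovered"
    clean <- !led$err_cls_sub
    expect_true(all(ann$status[clean] == "perfect"))
})
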