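test_that("whitelists satisfy length and distance invariants", {
    wl <- fixture_whitelists()
    for (s in c("cls1", "cls2", "cls3")) {
        entries <- wl[[s]]
        expect_length(entries, 96L)
        expect_true(all(nchar(entries) == 9L))
        expect_equal(anyDuplicated(entries), 0L)
        ## exhaustive 96 x 96 pairwise Hamming check
        chars <- do.call(rbind, strsplit(entries, ""))
        dmin <- 9L
        for (i in 1:95) for (j in (i + 1):96) {
            dmin <- min(dmin, sum(chars[i, ] != chars[j, ]))
        }
        expect_gte(dmin, 3L)
    }
    expect_equal(nchar(wl$linker1), 12L)
    expect_equal(nchar(wl$linker2), 13L)
})

test_that("whitelist generation is deterministic and files round-trip", {
    expect_identical(generate_whitelists(seed = 123),
                     generate_whitelists(seed = 123))
    dir <- withr::local_tempdir()
    wl <- fixture_whitelists()
    write_whitelists(wl, dir)
    expect_identical(read_whitelists(dir), wl)
})

test_that("read counts follow the molecule model exactly", {
    wl <- fixture_whitelists()
    panel <- fixture_panel()
    cfg1 <- sim_config(n_cells = 40, n_noise_labels = 0,
                       reads_per_molecule = 1, seed = 19,
                       cell_depth_lognormal = c(log(40), 0.2))
    run1 <- simulate_run(cfg1, wl, panel, group = "t1")
    expect_equal(nrow(run1$truth$ledger), sum(run1$truth$truth_matrix))

    cfg5 <- sim_config(n_cells = 40, n_noise_labels = 0,
                       reads_per_molecule = 5, seed = 19,
                       cell_depth_lognormal = c(log(100), 0.2))
    run5 <- simulate_run(cfg5, wl, panel, group = "t5")
    expect_equal(nrow(run5$truth$ledger), 5L * sum(run5$truth$truth_matrix))
})

test_that("injected CLS substitution rate matches the configured rate", {
    wl <- fixture_whitelists()
    panel <- fixture_panel()
    cfg <- sim_config(n_cells = 60, n_noise_labels = 0, seed = 77,
                      cls_substitution_rate = 0.05,
                      cell_depth_lognormal = c(log(150), 0.2))
    run <- simulate_run(cfg, wl, panel, group = "errs")
    n <- nrow(run$truth$ledger)
    frac <- mean(run$truth$ledger$err_cls_sub)
    expect_lt(abs(frac - 0.05), 3 * sqrt(0.05 * 0.95 / n))
})

test_that("identical config and seed give byte-identical FASTQ", {
    wl <- fixture_whitelists()
    panel <- fixture_panel()
    cfg <- sim_config(n_cells = 15, n_noise_labels = 20, seed = 4,
                      cell_depth_lognormal = c(log(30), 0.2))
    r1 <- simulate_run(cfg, wl, panel, group = "d", outdir = withr::local_tempdir())
    r2 <- simulate_run(cfg, wl, panel, group = "d", outdir = withr::local_tempdir())
    expect_identical(unname(tools::md5sum(r1$r1_fastq)),
                     unname(tools::md5sum(r2$r1_fastq)))
    expect_identical(unname(tools::md5sum(r1$r2_fastq)),
                     unname(tools::md5sum(r2$r2_fastq)))
})

test_that("cohort subpopulation proportions match the configured shift", {
    wl <- fixture_whitelists()
    panel <- fixture_panel()
    props_case <- c(sp0 = 0.30, sp1 = 0.50, sp2 = 0.20)
    props_ctrl <- c(sp0 = 0.09, sp1 = 0.65, sp2 = 0.26)
    mk <- function(p, seed) sim_config(
        n_cells = 2000, n_noise_labels = 0, reads_per_molecule = 1,
        cell_depth_lognormal = c(log(2), 0.1), subpop_proportions = p,
        seed = seed)
    cohort <- simulate_cohort(mk(props_case, 11), mk(props_ctrl, 12),
                              wl, panel)
    tab <- cluster_proportions(cohort$assignments)
    for (g in c("case", "control")) {
        want <- if (g == "case") props_case else props_ctrl
        for (k in names(want)) {
            got <- tab[group == g & cluster == k, prop]
            se <- sqrt(want[[k]] * (1 - want[[k]]) / 2000)
            expect_lt(abs(got - want[[k]]), 3 * se + 1e-9)
        }
    }
})

test_that("single subpopulation assigns every cell to it", {
    wl <- fixture_whitelists()
    panel <- fixture_panel()
    cfg <- sim_config(n_cells = 25, n_noise_labels = 0, seed = 2,
                      subpop_proportions = c(only = 1),
                      cell_depth_lognormal = c(log(20), 0.2))
    run <- simulate_run(cfg, wl, panel, group = "s")
    expect_true(all(run$truth$cells$subpop == "only"))
})

test_that("sim_config validates rates and proportions", {
    expect_error(sim_config(cls_substitution_rate = 1.5), "rates")
    expect_error(sim_config(subpop_proportions = c(a = .5, b = .2)), "sum to 1")
    expect_error(sim_config(n_cells = 0), "zero cells")
})
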