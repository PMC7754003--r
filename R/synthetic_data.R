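## Synthetic paired-read generator: emits R1/R2 FASTQ with the bead-based
## single-cell read anatomy (three 9-nt cell-label sections separated by two
## linkers, an 8-nt UMI, a poly(T) tail) plus per-read ground truth, so the
## downstream pipeline can be validated against known molecule counts.

R1_SEGMENT_WIDTHS <- c(cls1 = 9L, l1 = 12L, cls2 = 9L, l2 = 13L, cls3 = 9L)
LABEL_REGION_LEN <- 52L  # CLS1+L1+CLS2+L2+CLS3

#' Generate the three 96-entry cell-label whitelists
#'
#' Draws three ordered lists of 96 distinct 9-nt sequences with pairwise
#' Hamming distance >= 3 within each list (so a single substitution is
#' always unambiguously correctable) and, additionally, pairwise Levenshtein
#' distance >= 4. The Levenshtein margin makes single-indel recovery safe:
#' every candidate window inspected during recovery lies within edit
#' distance 2 of its true entry, so with entries >= 4 apart no window can
#' come within the recovery tolerance of a wrong entry.
#' Also draws the two fixed linker sequences (12 and 13 nt) that place the
#' sections at 1-based read positions 1-9, 22-30 and 44-52.
#'
#' @param seed Integer seed; output is deterministic for a fixed seed.
#' @param max_attempts Candidate draws allowed per list before giving up.
#' @return A `whitelists` object: list with `cls1`, `cls2`, `cls3`
#'   (character vectors of 96 9-mers), `linker1` (12 nt), `linker2` (13 nt).
#' @export
generate_whitelists <- function(seed = 1L, max_attempts = 100000L) {
    with_seed(seed, {
        lists <- lapply(1:3, function(i) {
            accepted <- character(0)
            attempts <- 0L
            while (length(accepted) < 96L) {
                attempts <- attempts + 1L
                if (attempts > max_attempts) {
                    stop("failed to reach 96 whitelist sequences at minimum ",
                         "distance 3 after ", max_attempts, " attempts")
                }
                cand <- random_dna(1L, 9L)
                if (length(accepted) == 0L ||
                    (min(hamming_to_table(cand, accepted)) >= 3L &&
                     min(adist(cand, accepted)) >= 4L)) {
                    accepted <- c(accepted, cand)
                }
            }
            accepted
        })
        structure(list(cls1 = lists[[1]], cls2 = lists[[2]], cls3 = lists[[3]],
                       linker1 = random_dna(1L, 12L),
                       linker2 = random_dna(1L, 13L)),
                  class = "whitelists")
    })
}

#' @export
print.whitelists <- function(x, ...) {
    cat("whitelists: 3 x 96 cell-label sections (9 nt), linkers",
        nchar(x$linker1), "/", nchar(x$linker2), "nt\n")
    invisible(x)
}

#' Write/read whitelists as three 96-line text files
#'
#' Files are named `cls1.txt`, `cls2.txt`, `cls3.txt` plus `linkers.txt`
#' (two lines: linker1, linker2).
#'
#' @param wl A `whitelists` object.
#' @param dir Directory to write into (created if needed).
#' @return The directory, invisibly.
#' @export
write_whitelists <- function(wl, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeLines(wl$cls1, file.path(dir, "cls1.txt"))
    writeLines(wl$cls2, file.path(dir, "cls2.txt"))
    writeLines(wl$cls3, file.path(dir, "cls3.txt"))
    writeLines(c(wl$linker1, wl$linker2), file.path(dir, "linkers.txt"))
    invisible(dir)
}

#' @rdname write_whitelists
#' @export
read_whitelists <- function(dir) {
    wl <- list(cls1 = readLines(file.path(dir, "cls1.txt")),
               cls2 = readLines(file.path(dir, "cls2.txt")),
               cls3 = readLines(file.path(dir, "cls3.txt")))
    lk <- readLines(file.path(dir, "linkers.txt"))
    wl$linker1 <- lk[1]
    wl$linker2 <- lk[2]
    for (s in c("cls1", "cls2", "cls3")) {
        if (length(wl[[s]]) != 96L || any(nchar(wl[[s]]) != 9L)) {
            stop("whitelist ", s, " must contain 96 sequences of length 9")
        }
    }
    structure(wl, class = "whitelists")
}

#' Synthesize a random targeted panel
#'
#' Stand-in for the unpublished targeted panel: random mRNA amplicon and
#' antibody-tag sequences plus one synthetic decoy record (the role the
#' phiX174 spike-in plays in the real pipeline; the decoy sequence here is
#' random, not the phiX genome).
#'
#' @param n_mrna,n_abtag Number of mRNA / antibody-tag features.
#' @param mrna_len,abtag_len,decoy_len Sequence lengths (nt); mRNA and
#'   abtag must be >= 61 so reads can satisfy the >60 alignment rule.
#' @param seed Integer seed.
#' @return An unindexed `panel_ref`.
#' @export
synthesize_panel <- function(n_mrna = 30L, n_abtag = 5L, mrna_len = 400L,
                             abtag_len = 80L, decoy_len = 1000L, seed = 1L) {
    stopifnot(mrna_len >= 61L, abtag_len >= 61L)
    with_seed(seed, {
        feats <- data.table::data.table(
            name = c(sprintf("GENE%03d", seq_len(n_mrna)),
                     sprintf("ABTAG%02d", seq_len(n_abtag)),
                     "PHIX_synthetic_decoy"),
            feature_type = c(rep("mrna", n_mrna), rep("abtag", n_abtag), "decoy"),
            sequence = c(random_dna(n_mrna, mrna_len),
                         random_dna(n_abtag, abtag_len),
                         random_dna(1L, decoy_len)))
        feats$length <- nchar(feats$sequence)
        new_panel_ref(feats)
    })
}

#' Simulation configuration
#'
#' Collects the generator's tunables. Defaults describe a small but
#' realistic run: 200 true cells at a log-normal read depth well separated
#' from 500 shallow ambient-noise labels, five reads per molecule, protein
#' tags expressed ~3x deeper than mRNA targets, and no injected errors
#' (error rates are switched on per experiment).
#'
#' @param n_cells Number of true cells.
#' @param n_noise_labels Number of ambient noise cell labels (random valid
#'   whitelist triples distinct from the true cells, sequenced shallowly).
#' @param cell_depth_lognormal,noise_depth_lognormal `c(meanlog, sdlog)` of
#'   the log-normal target read depth per true cell / per noise label.
#' @param reads_per_molecule Mean reads per molecule. With
#'   `reads_per_molecule_exact = TRUE` every molecule gets exactly this many
#'   reads; otherwise depth is `1 + Poisson(mean - 1)` per molecule.
#' @param reads_per_molecule_exact Logical, see above.
#' @param expression_rates Optional named vector of relative expression
#'   weights per countable feature; unnamed features default to 1 (mRNA) or
#'   3 (abtag).
#' @param subpop_proportions Named numeric vector of subpopulation
#'   proportions (must sum to 1); cells are assigned multinomially.
#' @param cls_substitution_rate Probability a read receives one substitution
#'   at a random position of a random CLS section.
#' @param cls_indel_rate Probability a read receives one single-base
#'   insertion or deletion (50/50) at a random position of the 52-nt label
#'   region.
#' @param umi_substitution_rate Probability a read receives one substitution
#'   at a random UMI position.
#' @param r2_substitution_rate Probability a read receives one substitution
#'   at a random R2 position.
#' @param decoy_read_rate Ambient rate of extra decoy-origin reads (fraction
#'   of signal reads), attached to random labels; their R2 comes from the
#'   decoy record.
#' @param quality_model List: `q` constant Phred quality, plus
#'   `bad_read_fraction` of reads written at quality `bad_read_q` (to
#'   exercise the mean-quality filter).
#' @param r2_length R2 read length (>= 64).
#' @param polyt_length Simulated poly(T) tail length (default 10, longer
#'   than the 8 bases the filter inspects, so clean R1 reads are 70 nt).
#' @param umi_length UMI length (8).
#' @param seed Integer seed; all randomness of a run flows from it.
#' @return A validated `sim_config` object (list).
#' @export
sim_config <- function(n_cells = 200L,
                       n_noise_labels = 500L,
                       cell_depth_lognormal = c(meanlog = log(225), sdlog = 0.25),
                       noise_depth_lognormal = c(meanlog = log(8), sdlog = 0.5),
                       reads_per_molecule = 5,
                       reads_per_molecule_exact = TRUE,
                       expression_rates = NULL,
                       subpop_proportions = c(sp1 = 1),
                       cls_substitution_rate = 0,
                       cls_indel_rate = 0,
                       umi_substitution_rate = 0,
                       r2_substitution_rate = 0,
                       decoy_read_rate = 0,
                       quality_model = list(q = 30L, bad_read_fraction = 0,
                                            bad_read_q = 15L),
                       r2_length = 70L,
                       polyt_length = 10L,
                       umi_length = 8L,
                       seed = 1L) {
    cfg <- list(n_cells = as.integer(n_cells),
                n_noise_labels = as.integer(n_noise_labels),
                cell_depth_lognormal = cell_depth_lognormal,
                noise_depth_lognormal = noise_depth_lognormal,
                reads_per_molecule = reads_per_molecule,
                reads_per_molecule_exact = isTRUE(reads_per_molecule_exact),
                expression_rates = expression_rates,
                subpop_proportions = subpop_proportions,
                cls_substitution_rate = cls_substitution_rate,
                cls_indel_rate = cls_indel_rate,
                umi_substitution_rate = umi_substitution_rate,
                r2_substitution_rate = r2_substitution_rate,
                decoy_read_rate = decoy_read_rate,
                quality_model = quality_model,
                r2_length = as.integer(r2_length),
                polyt_length = as.integer(polyt_length),
                umi_length = as.integer(umi_length),
                seed = as.integer(seed))
    rates <- c(cfg$cls_substitution_rate, cfg$cls_indel_rate,
               cfg$umi_substitution_rate, cfg$r2_substitution_rate,
               cfg$decoy_read_rate, cfg$quality_model$bad_read_fraction)
    if (any(rates < 0 | rates > 1)) stop("all rates must be in [0, 1]")
    if (abs(sum(cfg$subpop_proportions) - 1) > 1e-8) {
        stop("subpop_proportions must sum to 1")
    }
    if (is.null(names(cfg$subpop_proportions))) {
        names(cfg$subpop_proportions) <-
            paste0("sp", seq_along(cfg$subpop_proportions))
    }
    if (cfg$n_cells < 1L) stop("zero cells requested")
    if (cfg$reads_per_molecule < 1) stop("reads_per_molecule must be >= 1")
    if (cfg$polyt_length < 8L) stop("polyt_length must be >= 8")
    if (cfg$r2_length < 64L) stop("r2_length must be >= 64")
    structure(cfg, class = "sim_config")
}

## distinct random whitelist index triples, excluding `avoid` (char labels)
sample_label_triples <- function(n, avoid = character(0)) {
    labs <- character(0)
    idx <- NULL
    while (length(labs) < n) {
        m <- max(16L, 2L * (n - length(labs)))
        cand <- data.table::data.table(i1 = sample.int(96L, m, replace = TRUE),
                                       i2 = sample.int(96L, m, replace = TRUE),
                                       i3 = sample.int(96L, m, replace = TRUE))
        cand[, label := paste(i1, i2, i3, sep = "_")]
        cand <- cand[!label %in% c(avoid, labs)]
        cand <- unique(cand, by = "label")
        idx <- rbind(idx, cand)
        labs <- idx$label
    }
    idx[seq_len(n)]
}

feature_weights <- function(panel, expression_rates) {
    feats <- panel$features[panel$features$feature_type != "decoy", ]
    w <- ifelse(feats$feature_type == "abtag", 3, 1)
    names(w) <- feats$name
    if (!is.null(expression_rates)) {
        hit <- match(names(expression_rates), names(w))
        if (anyNA(hit)) stop("expression_rates name not in panel: ",
                             paste(names(expression_rates)[is.na(hit)],
                                   collapse = ", "))
        w[hit] <- expression_rates
    }
    w / sum(w)
}

substitute_base_at <- function(x, pos) {
    bases <- c("A", "C", "G", "T")
    old <- substr(x, pos, pos)
    shift <- sample.int(3L, length(x), replace = TRUE)
    new <- bases[((match(old, bases) - 1L + shift) %% 4L) + 1L]
    substr(x, pos, pos) <- new
    x
}

#' Simulate one sequencing run
#'
#' Builds the per-cell truth matrix, expands it to reads, injects the
#' configured error modes, and writes a gzipped paired FASTQ plus ground
#' truth. Before error injection every R1 is
#' `CLS1+L1+CLS2+L2+CLS3+UMI+poly(T)` and every R2 is a substring of a
#' countable feature (or of the decoy, at `decoy_read_rate`).
#'
#' @param config A [sim_config()].
#' @param wl A `whitelists` object.
#' @param panel A `panel_ref` with at least one countable feature.
#' @param group Group identifier stamped into file names and the truth.
#' @param outdir Output directory (created); default a fresh temp dir.
#' @param write_truth Also serialize truth tables beside the FASTQ.
#' @return List with `r1_fastq`, `r2_fastq` (paths) and `truth`
#'   (a `ground_truth` object: `cells` table, sparse `truth_matrix` of
#'   cells x features molecule counts, `noise_labels`, per-read `ledger`).
#' @export
simulate_run <- function(config, wl, panel, group = "sample",
                         outdir = tempfile("simrun"), write_truth = FALSE) {
    stopifnot(inherits(config, "sim_config"), inherits(wl, "whitelists"),
              inherits(panel, "panel_ref"))
    feats <- panel$features
    countable <- which(feats$feature_type != "decoy")
    if (length(countable) == 0L) stop("panel has no countable feature")
    if (any(feats$length[countable] < config$r2_length)) {
        stop("r2_length exceeds a countable feature length")
    }
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

    with_seed(config$seed, {
        w <- feature_weights(panel, config$expression_rates)
        fnames <- names(w)
        nf <- length(w)

        ## --- true cells, subpopulations, truth matrix -------------------
        cells <- sample_label_triples(config$n_cells)
        cells[, cell_id := paste0(group, ":", label)]
        cells[, subpop := sample(names(config$subpop_proportions),
                                 .N, replace = TRUE,
                                 prob = config$subpop_proportions)]
        depth_c <- rlnorm(config$n_cells,
                          config$cell_depth_lognormal[[1]],
                          config$cell_depth_lognormal[[2]])
        lambda <- outer(depth_c / config$reads_per_molecule, w)
        m <- matrix(rpois(length(lambda), lambda), nrow = config$n_cells)
        truth_matrix <- Matrix::Matrix(m, sparse = TRUE,
                                       dimnames = list(cells$label, fnames))

        ## --- molecules --------------------------------------------------
        nz <- which(m > 0, arr.ind = TRUE)
        mol <- data.table::data.table(
            cell = rep(nz[, 1], m[nz]), feat = rep(nz[, 2], m[nz]))
        mol[, umi := random_dna(.N, config$umi_length)]
        ## distinct UMIs within (cell, feature): a chance duplicate would
        ## silently fuse two true molecules and break truth accounting
        repeat {
            dup <- duplicated(mol, by = c("cell", "feat", "umi"))
            if (!any(dup)) break
            mol[dup, umi := random_dna(sum(dup), config$umi_length)]
        }
        nreads_mol <- if (config$reads_per_molecule_exact) {
            rep(as.integer(round(config$reads_per_molecule)), nrow(mol))
        } else {
            1L + rpois(nrow(mol), config$reads_per_molecule - 1)
        }

        reads <- data.table::data.table(
            origin = "cell",
            cell = rep(mol$cell, nreads_mol),
            feat = rep(fnames[mol$feat], nreads_mol),
            feat_idx = rep(countable[mol$feat], nreads_mol),
            umi = rep(mol$umi, nreads_mol))
        reads[, label := cells$label[cell]]
        reads[, subpop := cells$subpop[cell]]

        ## --- ambient noise labels --------------------------------------
        if (config$n_noise_labels > 0L) {
            noise <- sample_label_triples(config$n_noise_labels,
                                          avoid = cells$label)
            ndepth <- pmax(1L, as.integer(round(rlnorm(
                config$n_noise_labels,
                config$noise_depth_lognormal[[1]],
                config$noise_depth_lognormal[[2]]))))
            fidx <- sample.int(nf, sum(ndepth), replace = TRUE, prob = w)
            nreads <- data.table::data.table(
                origin = "noise",
                cell = NA_integer_,
                feat = fnames[fidx],
                feat_idx = countable[fidx],
                umi = random_dna(sum(ndepth), config$umi_length),
                label = rep(noise$label, ndepth),
                subpop = NA_character_)
            reads <- rbind(reads, nreads)
            noise_labels <- noise$label
        } else {
            noise_labels <- character(0)
        }

        ## --- ambient decoy-origin reads --------------------------------
        decoy_idx <- which(feats$feature_type == "decoy")
        n_decoy <- as.integer(round(config$decoy_read_rate * nrow(reads)))
        if (n_decoy > 0L) {
            if (length(decoy_idx) == 0L) {
                stop("decoy_read_rate > 0 but panel has no decoy feature")
            }
            all_labels <- c(cells$label, noise_labels)
            dreads <- data.table::data.table(
                origin = "decoy",
                cell = NA_integer_,
                feat = feats$name[decoy_idx[1]],
                feat_idx = decoy_idx[1],
                umi = random_dna(n_decoy, config$umi_length),
                label = sample(all_labels, n_decoy, replace = TRUE),
                subpop = NA_character_)
            reads <- rbind(reads, dreads)
        }

        ## --- sequences ---------------------------------------------------
        n <- nrow(reads)
        reads <- reads[sample.int(n)]  # shuffle: no ordering artifacts
        reads[, read_id := sprintf("r%08d", seq_len(n))]
        trip <- data.table::tstrsplit(reads$label, "_", type.convert = TRUE)
        r1 <- paste0(wl$cls1[trip[[1]]], wl$linker1,
                     wl$cls2[trip[[2]]], wl$linker2,
                     wl$cls3[trip[[3]]], reads$umi,
                     strrep("T", config$polyt_length))
        flen <- feats$length[reads$feat_idx]
        start <- 1L + as.integer(floor(runif(n) * (flen - config$r2_length + 1L)))
        r2 <- substring(feats$sequence[reads$feat_idx],
                        start, start + config$r2_length - 1L)

        ## --- error injection --------------------------------------------
        reads[, `:=`(err_cls_sub = runif(n) < config$cls_substitution_rate,
                     err_cls_indel = runif(n) < config$cls_indel_rate,
                     err_umi_sub = runif(n) < config$umi_substitution_rate,
                     err_r2_sub = runif(n) < config$r2_substitution_rate,
                     indel_type = NA_character_,
                     indel_pos = NA_integer_,
                     low_quality =
                         runif(n) < config$quality_model$bad_read_fraction)]
        if (any(reads$err_cls_sub)) {
            i <- which(reads$err_cls_sub)
            sec <- sample.int(3L, length(i), replace = TRUE)
            pos <- c(1L, 22L, 44L)[sec] + sample(0:8, length(i), replace = TRUE)
            r1[i] <- substitute_base_at(r1[i], pos)
        }
        if (any(reads$err_umi_sub)) {
            i <- which(reads$err_umi_sub)
            pos <- 52L + sample.int(config$umi_length, length(i), replace = TRUE)
            r1[i] <- substitute_base_at(r1[i], pos)
        }
        if (any(reads$err_cls_indel)) {
            i <- which(reads$err_cls_indel)
            pos <- sample.int(LABEL_REGION_LEN, length(i), replace = TRUE)
            type <- sample(c("ins", "del"), length(i), replace = TRUE)
            reads[i, `:=`(indel_type = type, indel_pos = pos)]
            del <- i[type == "del"]
            if (length(del)) {
                dp <- pos[type == "del"]
                r1[del] <- paste0(substr(r1[del], 1L, dp - 1L),
                                  substring(r1[del], dp + 1L))
            }
            ins <- i[type == "ins"]
            if (length(ins)) {
                ip <- pos[type == "ins"]
                r1[ins] <- paste0(substr(r1[ins], 1L, ip - 1L),
                                  random_dna(length(ins), 1L),
                                  substring(r1[ins], ip))
            }
        }
        if (any(reads$err_r2_sub)) {
            i <- which(reads$err_r2_sub)
            pos <- sample.int(config$r2_length, length(i), replace = TRUE)
            r2[i] <- substitute_base_at(r2[i], pos)
        }

        q_chr <- rawToChar(as.raw(33L + config$quality_model$q))
        bad_chr <- rawToChar(as.raw(33L + config$quality_model$bad_read_q))
        q1 <- strrep(q_chr, nchar(r1))
        q2 <- strrep(q_chr, nchar(r2))
        if (any(reads$low_quality)) {
            i <- which(reads$low_quality)
            q1[i] <- strrep(bad_chr, nchar(r1[i]))
        }

        r1_path <- file.path(outdir, paste0(group, "_R1.fastq.gz"))
        r2_path <- file.path(outdir, paste0(group, "_R2.fastq.gz"))
        write_fastq(reads$read_id, r1, q1, r1_path)
        write_fastq(reads$read_id, r2, q2, r2_path)

        truth <- structure(list(group = group,
                                cells = cells[],
                                truth_matrix = truth_matrix,
                                noise_labels = noise_labels,
                                ledger = reads[]),
                           class = "ground_truth")
        if (write_truth) write_ground_truth(truth, outdir)
        list(r1_fastq = r1_path, r2_fastq = r2_path, truth = truth)
    })
}

#' @export
print.ground_truth <- function(x, ...) {
    cat("ground_truth [", x$group, "]:", nrow(x$cells), "cells,",
        length(x$noise_labels), "noise labels,",
        sum(x$truth_matrix), "molecules,", nrow(x$ledger), "reads\n")
    invisible(x)
}

#' Serialize ground truth beside a simulated run
#'
#' Writes `<group>_truth_cells.tsv` (cells and subpopulations),
#' `<group>_truth_counts.tsv` (long-form cell x feature molecule counts)
#' and `<group>_ledger.json.gz` (per-read error ledger).
#'
#' @param truth A `ground_truth`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_ground_truth <- function(truth, dir) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    g <- truth$group
    data.table::fwrite(truth$cells,
                       file.path(dir, paste0(g, "_truth_cells.tsv")), sep = "\t")
    tm <- Matrix::summary(methods::as(truth$truth_matrix, "TsparseMatrix"))
    counts <- data.table::data.table(
        cell_label = rownames(truth$truth_matrix)[tm$i],
        feature = colnames(truth$truth_matrix)[tm$j],
        molecules = tm$x)
    data.table::fwrite(counts,
                       file.path(dir, paste0(g, "_truth_counts.tsv")), sep = "\t")
    con <- gzfile(file.path(dir, paste0(g, "_ledger.json.gz")), "w")
    writeLines(jsonlite::toJSON(truth$ledger, dataframe = "rows", na = "null"),
               con)
    close(con)
    invisible(dir)
}

#' Simulate a two-group cohort
#'
#' Runs [simulate_run()] once per group against shared whitelists and panel.
#' The groups typically differ in `subpop_proportions` (a case/control
#' design with shifted subpopulation frequencies) and must use different
#' seeds to be independent.
#'
#' @param config_case,config_control [sim_config()] objects.
#' @param wl,panel Shared whitelists and panel.
#' @param outdir Output directory.
#' @param groups Length-2 character vector of group names.
#' @param ... Passed to [simulate_run()].
#' @return List with `case`, `control` (each a [simulate_run()] result) and
#'   `assignments`: a data.table (`cell_id`, `group`, `cluster`) with the
#'   true subpopulation of every simulated cell, ready for
#'   [cluster_proportions()].
#' @export
simulate_cohort <- function(config_case, config_control, wl, panel,
                            outdir = tempfile("simcohort"),
                            groups = c("case", "control"), ...) {
    stopifnot(length(groups) == 2L)
    runs <- list(simulate_run(config_case, wl, panel, group = groups[1],
                              outdir = outdir, ...),
                 simulate_run(config_control, wl, panel, group = groups[2],
                              outdir = outdir, ...))
    assignments <- data.table::rbindlist(lapply(runs, function(r) {
        data.table::data.table(cell_id = r$truth$cells$cell_id,
                               group = r$truth$group,
                               cluster = r$truth$cells$subpop)
    }))
    list(case = runs[[1]], control = runs[[2]], assignments = assignments)
}

#' Simulate per-label read depths only
#'
#' Depth-only emulation of the two-population (cell vs ambient noise) read
#' distribution, for exercising the knee-point cell caller without
#' generating reads.
#'
#' @param n_cells,n_noise Number of true cells / noise labels.
#' @param cell_lognormal,noise_lognormal `c(meanlog, sdlog)` of each
#'   population's read-depth distribution.
#' @param seed Integer seed.
#' @return Named integer vector of reads per label, with attribute
#'   `true_cells` naming the true-cell labels.
#' @export
simulate_label_depths <- function(n_cells = 500L, n_noise = 5000L,
                                  cell_lognormal = c(9, 0.3),
                                  noise_lognormal = c(3, 0.5),
                                  seed = 1L) {
    with_seed(seed, {
        cells <- pmax(1L, as.integer(round(
            rlnorm(n_cells, cell_lognormal[1], cell_lognormal[2]))))
        noise <- pmax(1L, as.integer(round(
            rlnorm(n_noise, noise_lognormal[1], noise_lognormal[2]))))
        counts <- c(cells, noise)
        names(counts) <- c(sprintf("cell%05d", seq_len(n_cells)),
                           sprintf("noise%05d", seq_len(n_noise)))
        attr(counts, "true_cells") <- names(counts)[seq_len(n_cells)]
        counts
    })
}
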