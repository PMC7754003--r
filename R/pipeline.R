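#' Pipeline run configuration
#'
#' Bundles every stage's inputs and tunables. The resolved configuration is
#' written beside the outputs of every run, and rerunning with an identical
#' configuration reproduces byte-identical outputs (the pipeline itself
#' draws no random numbers).
#'
#' @param r1_fastq,r2_fastq Paired FASTQ paths (optionally gzipped).
#' @param whitelist_dir Directory with `cls1.txt`/`cls2.txt`/`cls3.txt`
#'   (+ `linkers.txt`), see [write_whitelists()].
#' @param panel_fasta Panel FASTA path.
#' @param feature_types Optional name->type map or TSV path (see
#'   [load_panel()]).
#' @param outdir Output directory.
#' @param qc A [qc_thresholds()] (or list of its arguments).
#' @param polyt_slack Non-T bases tolerated in the poly(T) window.
#' @param k Seed length for the panel index.
#' @param max_mismatch,uniq_margin,min_overlap Aligner options, see
#'   [align_r2()].
#' @param max_read_start,min_aln_len R2 validity bounds, see
#'   [validate_alignment()].
#' @param dbec_min_group,dbec_min_fold DBEC options, see [dbec_filter()].
#' @param smooth_window,derivative_mode Cell-calling options, see
#'   [call_cells()].
#' @param seed Run seed (recorded in provenance; the processing pipeline is
#'   deterministic and does not consume it).
#' @return A `run_config` list.
#' @export
run_config <- function(r1_fastq, r2_fastq, whitelist_dir, panel_fasta,
                       feature_types = NULL, outdir = tempfile("abseqrun"),
                       qc = qc_thresholds(), polyt_slack = 1L, k = 18L,
                       max_mismatch = 0.1, uniq_margin = 3L, min_overlap = 30L,
                       max_read_start = 4L, min_aln_len = 60L,
                       dbec_min_group = 20L, dbec_min_fold = 4,
                       smooth_window = 15L,
                       derivative_mode = c("second", "first"), seed = 1L) {
    if (is.list(qc) && !inherits(qc, "qc_thresholds")) {
        qc <- do.call(qc_thresholds, qc)
    }
    structure(list(r1_fastq = r1_fastq, r2_fastq = r2_fastq,
                   whitelist_dir = whitelist_dir, panel_fasta = panel_fasta,
                   feature_types = feature_types, outdir = outdir,
                   qc = qc, polyt_slack = as.integer(polyt_slack),
                   k = as.integer(k), max_mismatch = max_mismatch,
                   uniq_margin = as.integer(uniq_margin),
                   min_overlap = as.integer(min_overlap),
                   max_read_start = as.integer(max_read_start),
                   min_aln_len = as.integer(min_aln_len),
                   dbec_min_group = as.integer(dbec_min_group),
                   dbec_min_fold = dbec_min_fold,
                   smooth_window = as.integer(smooth_window),
                   derivative_mode = match.arg(derivative_mode),
                   seed = as.integer(seed)),
              class = "run_config")
}

#' Read or write a run configuration file (YAML or JSON)
#'
#' @param path Configuration file; format chosen by extension
#'   (`.yaml`/`.yml` or `.json`).
#' @return For `load_run_config`, a `run_config`; for `save_run_config`,
#'   `path` invisibly.
#' @export
load_run_config <- function(path) {
    if (!file.exists(path)) stop("config file not found: ", path)
    vals <- if (grepl("\\.ya?ml$", path)) {
        yaml::read_yaml(path)
    } else {
        jsonlite::read_json(path, simplifyVector = TRUE)
    }
    vals$qc <- vals$qc %||% list()
    do.call(run_config, vals)
}

#' @rdname load_run_config
#' @param config A `run_config`.
#' @export
save_run_config <- function(config, path) {
    vals <- unclass(config)
    vals$qc <- unclass(vals$qc)
    vals$feature_types <- as.list(vals$feature_types)
    if (grepl("\\.ya?ml$", path)) {
        yaml::write_yaml(vals, path)
    } else {
        jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA,
                             null = "null")
    }
    invisible(path)
}

#' Run the full read-processing pipeline
#'
#' Stage order: read QC, R1 cell-label/UMI annotation, R2 panel alignment,
#' pair validity (valid R1 with identified label, N-free UMI and poly(T);
#' valid R2 uniquely aligned per the four rules), molecule collapsing,
#' RSEC, DBEC, knee-point cell calling on reads per label, count-matrix
#' construction. Per-stage read accounting is conserved: input pairs equal
#' the drops at each stage plus the pairs contributing to molecules.
#'
#' @param config A [run_config()].
#' @param write_outputs Write the matrix triplet, metrics JSON, molecule
#'   table, knee diagnostics, called-cell list and resolved configuration
#'   under `config$outdir`.
#' @return List with `matrix` (a `count_matrix`), `knee`, `molecules`
#'   (molecule table with fate column), `metrics` (per-stage counts) and
#'   `outdir`.
#' @export
run_pipeline <- function(config, write_outputs = TRUE) {
    stopifnot(inherits(config, "run_config"))
    for (f in c("r1_fastq", "r2_fastq", "panel_fasta")) {
        if (!file.exists(config[[f]])) {
            stop("input missing (", f, "): ", config[[f]])
        }
    }
    if (!dir.exists(config$whitelist_dir)) {
        stop("input missing (whitelist_dir): ", config$whitelist_dir)
    }
    wl <- read_whitelists(config$whitelist_dir)
    panel <- load_panel(config$panel_fasta, config$feature_types)
    panel <- build_kmer_index(panel, config$k)

    metrics <- list()
    stage <- function(name, expr) {
        tryCatch(expr, error = function(e) {
            stop("pipeline stage '", name, "' failed: ",
                 conditionMessage(e), call. = FALSE)
        })
    }

    ## --- QC -------------------------------------------------------------
    pairs <- stage("read_input",
                   read_fastq_pairs(config$r1_fastq, config$r2_fastq))
    metrics$reads_in <- nrow(pairs)
    pairs <- stage("read_qc", qc_filter(pairs, config$qc))
    metrics$qc_drops <- as.list(table(pairs$drop_reason))
    pairs <- pairs[kept == TRUE]
    metrics$reads_qc_pass <- nrow(pairs)

    ## --- R1 annotation ---------------------------------------------------
    ann <- stage("barcode_annotation",
                 annotate_r1_batch(pairs$r1_seq, wl,
                                   polyt_slack = config$polyt_slack))
    metrics$r1_status <- as.list(table(ann$status))
    metrics$r1_valid <- sum(ann$r1_valid)

    ## --- R2 alignment ----------------------------------------------------
    aln <- stage("panel_alignment",
                 validate_alignment(
                     align_r2_batch(pairs$r2_seq, panel,
                                    max_mismatch = config$max_mismatch,
                                    uniq_margin = config$uniq_margin,
                                    min_overlap = config$min_overlap),
                     max_read_start = config$max_read_start,
                     min_aln_len = config$min_aln_len))
    metrics$r2_invalid_reasons <-
        as.list(table(aln$reason[!is.na(aln$reason)]))
    metrics$r2_valid <- sum(aln$valid)

    ## --- pair validity ----------------------------------------------------
    pair_ok <- ann$r1_valid & aln$valid
    metrics$pairs_valid <- sum(pair_ok)
    metrics$pairs_dropped_r1_only <- sum(!ann$r1_valid & aln$valid)
    metrics$pairs_dropped_r2_only <- sum(ann$r1_valid & !aln$valid)
    metrics$pairs_dropped_both <- sum(!ann$r1_valid & !aln$valid)
    valid <- data.table::data.table(
        read_id = pairs$read_id[pair_ok],
        cell_label = ann$cell_label[pair_ok],
        umi = ann$umi[pair_ok],
        feature = aln$feature[pair_ok])

    ## --- molecules --------------------------------------------------------
    mols <- stage("collapse", collapse_to_molecules(valid))
    metrics$molecules_raw <- nrow(mols)
    rsec <- stage("rsec", rsec_correct(mols))
    metrics$rsec <- rsec$report
    dbec <- stage("dbec", dbec_filter(rsec$molecules,
                                      min_group = config$dbec_min_group,
                                      min_fold = config$dbec_min_fold))
    metrics$dbec <- dbec$report[c("n_in", "n_dbec_removed", "n_out")]
    surviving <- dbec$molecules

    ## molecule fate table for diagnostics
    fate <- data.table::copy(mols)
    fate[, fate := "kept"]
    post_rsec_key <- paste(rsec$molecules$cell_label, rsec$molecules$umi,
                           rsec$molecules$feature)
    surv_key <- paste(surviving$cell_label, surviving$umi, surviving$feature)
    mol_key <- paste(fate$cell_label, fate$umi, fate$feature)
    fate[!mol_key %in% post_rsec_key, fate := "rsec_merged"]
    fate[mol_key %in% setdiff(post_rsec_key, surv_key), fate := "dbec_removed"]

    ## --- cell calling ------------------------------------------------------
    reads_per_label <- valid[, .N, by = cell_label]
    knee <- stage("cell_calling", {
        kc <- build_knee_curve(stats::setNames(reads_per_label$N,
                                               reads_per_label$cell_label))
        call_cells(kc, smooth_window = config$smooth_window,
                   mode = config$derivative_mode)
    })
    metrics$labels_seen <- nrow(reads_per_label)
    metrics$cells_called <- length(knee$called)

    ## --- matrix ------------------------------------------------------------
    provenance <- list(tool = "abseqpipe",
                       version = as.character(packageVersion("abseqpipe")),
                       seed = config$seed,
                       k = config$k,
                       qc = unclass(config$qc))
    mat <- stage("matrix", build_matrix(surviving, knee$called, panel,
                                        provenance = provenance))
    metrics$molecules_in_matrix <- sum(mat$counts)
    metrics$molecules_dropped_uncalled <- mat$n_dropped_uncalled

    if (write_outputs) {
        dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
        write_matrix(mat, file.path(config$outdir, "matrix"))
        jsonlite::write_json(metrics,
                             file.path(config$outdir, "metrics.json"),
                             auto_unbox = TRUE, digits = NA, null = "null")
        data.table::fwrite(fate, file.path(config$outdir, "molecules.tsv"),
                           sep = "\t")
        data.table::fwrite(knee$curve,
                           file.path(config$outdir, "knee_diagnostics.tsv"),
                           sep = "\t")
        writeLines(knee$called, file.path(config$outdir, "called_cells.txt"))
        save_run_config(config, file.path(config$outdir, "run_config.yaml"))
    }
    list(matrix = mat, knee = knee, molecules = fate, metrics = metrics,
         outdir = config$outdir)
}
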