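# abseqpipe

Processing and validation pipeline for bead-barcoded single-cell
multi-omics reads — targeted mRNA panels plus antibody-derived tags
(AbSeq/CITE-seq style) — with case/control cell-proportion statistics.

## Who this is for

Groups running (or reviewing) Rhapsody-style targeted single-cell assays
who need a transparent, testable re-implementation of the vendor's read
processing: every rule is an exported R function, every stage reports its
read accounting, and a paired simulator with per-read ground truth lets
the whole chain be validated end to end.

## What it does

R1 reads carry a cell label split across three 9-nt sections (each one of
96 whitelist sequences, at positions 1–9, 22–30, 44–52, separated by two
fixed linkers), an 8-nt UMI and a poly(T) tail; R2 carries a fragment of a
panel feature. The pipeline:

1. **Read QC** — drop pairs with R1 < 66 nt or R2 < 64 nt, mean Phred
   < 20 on either mate, or single-nucleotide frequency (SNF) ≥ 0.55 (R1) /
   ≥ 0.80 (R2).
2. **Cell-label annotation** — perfect positional match first, then
   recovery of substitutions (Hamming ≤ 1 per section) and single indels
   (±1 frame shifts anchored by the linkers), scored by parsimony;
   ambiguous reads are never guessed. UMI = 8 bases after the identified
   CLS3; then the poly(T) check (more than 6 of 8 bases must be T).
3. **Panel alignment** — built-in seed-and-extend ungapped aligner; a read
   is valid only if it misses the decoy, maps uniquely, starts within the
   first five bases, and spans > 60 match/mismatch columns.
4. **Molecule counting** — collapse by (cell label, UMI, feature);
   **RSEC** merges Hamming-1 UMI children into strictly deeper parents,
   recursively; **DBEC** fits a two-component geometric mixture to
   per-feature molecule depths and removes the shallow error component
   when the means separate ≥ 4-fold.
5. **Cell calling** — knee point of the log10 cumulative read curve
   (minimum second derivative over log rank); labels left of it are cells.
6. **Matrix export** — sparse cells × features MTX triplet with an
   mrna/abtag type column.
7. **Cohort statistics** — per-cluster proportions, case/control fold
   changes and two-proportion z-tests (Fisher's exact optional) on an
   externally supplied cluster assignment.

The companion simulator (`simulate_run`, `simulate_cohort`) generates
paired FASTQ with exactly this anatomy, configurable error injection
(CLS substitutions/indels, UMI and R2 substitutions, low-quality reads,
decoy reads) and a per-read truth ledger.

## Worked example

```r
library(abseqpipe)

wl    <- generate_whitelists(seed = 1)
panel <- build_kmer_index(synthesize_panel(n_mrna = 25, n_abtag = 5, seed = 2))

dir <- tempfile("demo")
cfg <- sim_config(seed = 3, cls_substitution_rate = 0.02,
                  umi_substitution_rate = 0.01)   # 200 cells, ~50k pairs
sim <- simulate_run(cfg, wl, panel, group = "demo", outdir = dir)
write_whitelists(wl, file.path(dir, "wl"))
write_panel_fasta(panel, file.path(dir, "panel.fa"), file.path(dir, "types.tsv"))

rc  <- run_config(sim$r1_fastq, sim$r2_fastq, file.path(dir, "wl"),
                  file.path(dir, "panel.fa"),
                  feature_types = file.path(dir, "types.tsv"),
                  outdir = file.path(dir, "out"))
res <- run_pipeline(rc)
res$matrix
#> count_matrix: 200 cells x 30 features ( abtag=5, mrna=25 ), 9342 molecules
res$knee
#> knee_curve: 700 labels, 51,228 reads
#>   inflection rank: 200 -> 200 called cells
```

All 200 simulated cells are called from among 700 labels; 995 corrupted
R1 reads were recovered to their true label, RSEC merged 476 error UMIs
back into their parents, and DBEC removed the 4,518 shallow ambient
molecules — after which every (cell, feature) entry of the count matrix
equals the simulator's truth matrix.

Cluster proportions between two groups (cluster assignments are an input
column — from any clustering you ran, or the simulator's truth):

```r
compare_clusters(assignments)   # cell_id | group | cluster
#>    cluster n_case n_control pct_case pct_control fold_change      p_value
#> 1:      c0    607       188    30.35         9.4         3.2 6.800952e-62
#> 2:   other   1393      1812    69.65        90.6         0.8 6.800952e-62
```

A cluster at 30.35% of case cells versus 9.4% of control cells is a
3.2-fold enrichment, strongly significant under the two-proportion z-test.

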