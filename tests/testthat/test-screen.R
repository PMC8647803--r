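planted_ids <- function(fx) fx$truth$gene_id[fx$truth$role == "planted"]

test_that("DEG loader normalises log2 fold changes and derives directions", {
  p <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tfold_change\tp_value",
               "G1\t1\t0.001", "G2\t-2\t0.001", "G3\t0.5\t0.5"), p)
  d <- read_deg_table(p, fc_scale = "log2")
  expect_equal(d$fold_change, c(2, -4, 2^0.5))
  expect_equal(d$direction, c("up", "down", "noreg"))
  d2p <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tfold_change\tp_value", "G1\t1.7\t0.01"), d2p)
  expect_equal(read_deg_table(d2p)$fold_change, 1.7)  # signed-linear passes through
  bad <- tempfile(fileext = ".tsv")
  writeLines(c("gene_id\tfc", "G1\t2"), bad)
  expect_error(read_deg_table(bad), "missing column")
})

test_that("stage 1 keeps lncRNA-biotype DEGs in input order and drops unknown ids", {
  fx <- simulate_screen_fixture(n_planted = 3, decoys = c("not_lncRNA"), seed = 21)
  deg <- rbind(fx$deg,
               data.table::data.table(gene_id = "GHOST", gene_name = "GHOST",
                                      fold_change = 2, p_value = 0.01,
                                      direction = "up", bound = 0L))
  expect_warning(ids <- filter_lncrna(deg, fx$ann, fx$cfg), "not found")
  expect_setequal(ids, fx$truth$gene_id[is.na(fx$truth$violation) |
                                          fx$truth$violation != "not_lncRNA"])
  expect_identical(ids, deg$gene_id[deg$gene_id %in% ids])  # order preserved
  expect_length(filter_lncrna(fx$deg[0, ], fx$ann, fx$cfg), 0L)
})

test_that("stage 2 requires an exonic TE of an accepted family, inverted by default", {
  fx <- simulate_screen_fixture(
    n_planted = 1, decoys = c("no_accepted_TE", "TE_intronic", "TE_not_inverted"),
    seed = 22)
  s1 <- filter_lncrna(fx$deg, fx$ann, fx$cfg)
  s2 <- filter_te(s1, fx$ann, fx$repeats, fx$cfg)
  expect_setequal(s2, planted_ids(fx))
  # with the inversion requirement lifted, the same-orientation decoy comes back
  cfg2 <- screen_config(require_inverted = FALSE)
  s2b <- filter_te(s1, fx$ann, fx$repeats, cfg2)
  ni <- fx$truth$gene_id[!is.na(fx$truth$violation) &
                           fx$truth$violation == "TE_not_inverted"]
  expect_setequal(s2b, c(planted_ids(fx), ni))
})

test_that("stage 3 pairs lncRNAs with opposite-strand coding genes at >= 1 nt exonic overlap", {
  fx <- simulate_screen_fixture(n_planted = 2,
                                decoys = c("same_strand_overlap", "no_overlap"),
                                seed = 23)
  pairs <- filter_antisense(fx$truth$gene_id, fx$ann, fx$cfg)
  expect_setequal(pairs$lnc_gene_id, planted_ids(fx))
  expect_true(all(pairs$overlap_nt >= 1))
  truth <- fx$truth[fx$truth$role == "planted", ]
  expect_setequal(paste(pairs$lnc_gene_id, pairs$sense_gene_id),
                  paste(truth$gene_id, truth$sense_gene_id))
})

test_that("stage 4 keeps only pairs whose lnc exons reach the sense start codon", {
  fx <- simulate_screen_fixture(n_planted = 2, decoys = c("no_TIS_overlap"), seed = 24)
  pairs <- filter_antisense(fx$truth$gene_id, fx$ann, fx$cfg)
  kept <- filter_tis_overlap(pairs, fx$ann)
  expect_setequal(kept$lnc_gene_id, planted_ids(fx))
  expect_true(all(kept$tis_overlap_nt >= 1 & kept$tis_overlap_nt <= 3))
})

test_that("a single-nucleotide TIS overlap passes while a start-codon-free overlap does not", {
  # sense + strand: exon 201-800, codon 501-503; antisense exon ends exactly at 501
  sense <- transcript_model("S_T1", "S", "S", "protein_coding", "c", "+",
                            exons = IRanges::IRanges(201, 800),
                            cds = IRanges::IRanges(501, 780),
                            start_codon = IRanges::IRanges(501, 503))
  lnc1 <- transcript_model("L1_T1", "L1", "L1", "lncRNA", "c", "-",
                           exons = IRanges::IRanges(301, 501))
  lnc0 <- transcript_model("L0_T1", "L0", "L0", "lncRNA", "c", "-",
                           exons = IRanges::IRanges(301, 500))
  ann <- annotation_set(list(
    gene_model("S", "S", "protein_coding", "c", "+", list(sense)),
    gene_model("L1", "L1", "lncRNA", "c", "-", list(lnc1)),
    gene_model("L0", "L0", "lncRNA", "c", "-", list(lnc0))))
  pairs <- filter_antisense(c("L1", "L0"), ann, screen_config())
  expect_setequal(pairs$lnc_gene_id, c("L1", "L0"))   # both overlap the mRNA
  kept <- filter_tis_overlap(pairs, ann)
  expect_equal(kept$lnc_gene_id, "L1")                # only one reaches the codon
  expect_equal(kept$tis_overlap_nt, 1L)
})

test_that("the full screen returns no candidates on empty or decoys-only input", {
  fx0 <- simulate_screen_fixture(n_planted = 0, decoys = character(0), seed = 1)
  expect_equal(nrow(run_screen(fx0$deg, fx0$ann, fx0$repeats, fx0$cfg)$candidates), 0L)
  fxd <- simulate_screen_fixture(n_planted = 0, decoys = decoy_classes(), seed = 2)
  res <- run_screen(fxd$deg, fxd$ann, fxd$repeats, fxd$cfg)
  expect_equal(nrow(res$candidates), 0L)
})

test_that("screen output is invariant under permutation of DEG and repeat record order", {
  fx <- simulate_screen_fixture(n_planted = 3, decoys = decoy_classes(), seed = 31)
  ref <- run_screen(fx$deg, fx$ann, fx$repeats, fx$cfg)$candidates
  set.seed(99)
  for (i in 1:3) {
    deg <- fx$deg[sample(nrow(fx$deg)), ]
    reps <- fx$repeats[sample(nrow(fx$repeats)), ]
    expect_equal(run_screen(deg, fx$ann, reps, fx$cfg)$candidates, ref,
                 ignore_attr = TRUE)
  }
})

test_that("screen stages agree with the exhaustive per-base oracle on small fixtures", {
  for (seed in c(101, 202, 303)) {
    fx <- simulate_screen_fixture(n_planted = 3,
                                  decoys = rep(decoy_classes(), 2),  # 19 loci, 38 genes
                                  seed = seed)
    o <- oracle_screen(fx)
    s1 <- filter_lncrna(fx$deg, fx$ann, fx$cfg)
    s2 <- filter_te(s1, fx$ann, fx$repeats, fx$cfg)
    s3p <- filter_antisense(s2, fx$ann, fx$cfg)
    s4 <- filter_tis_overlap(s3p, fx$ann)
    expect_setequal(s1, o$s1)
    expect_setequal(s2, o$s2)
    expect_setequal(unique(s3p$lnc_gene_id), o$s3)
    expect_setequal(unique(s4$lnc_gene_id), o$s4)
  }
})

test_that("per-stage survivor counts are reported and monotonically decreasing", {
  fx <- simulate_screen_fixture(n_planted = 2, decoys = decoy_classes(), seed = 41)
  res <- run_screen(fx$deg, fx$ann, fx$repeats, fx$cfg)
  n <- res$stage_counts$n_genes
  expect_equal(res$stage_counts$stage,
               c("input_deg", "lncrna", "embedded_te", "antisense_pair", "tis_overlap"))
  expect_true(all(diff(n[-1]) <= 0))
  expect_equal(n[5], 2L)
})

test_that("candidate rows carry the lnc DEG statistics and pass-through sense metadata", {
  fx <- benchmark_screen_fixture(seed = 7)
  res <- run_screen(fx$deg, fx$ann, fx$repeats, fx$cfg)
  cand <- res$candidates
  r <- cand[cand$lnc_gene_name == "RAB11B-AS1", ]
  expect_equal(r$lnc_fc, 1.8485)
  expect_equal(r$lnc_p, 0.00519)
  expect_equal(r$lnc_direction, "up")
  expect_equal(r$sense_gene_name, "RAB11B")
  expect_equal(r$sense_fc, 1.46253)
  expect_equal(r$sense_direction, "up")
  expect_equal(r$sense_bound, 1L)    # regulator-binding flag is pass-through input
  s <- cand[cand$lnc_gene_name == "ST7-AS1", ]
  expect_equal(s$lnc_fc, -1.7671)    # signed-linear down-regulation
  expect_equal(s$lnc_direction, "down")
  expect_equal(s$sense_direction, "noreg")
})

test_that("candidate tables write and re-read as TSV", {
  fx <- simulate_screen_fixture(n_planted = 2, decoys = character(0), seed = 51)
  res <- run_screen(fx$deg, fx$ann, fx$repeats, fx$cfg)
  d <- tempfile()
  write_candidate_table(res, d)
  back <- data.table::fread(file.path(d, "candidates.tsv"))
  expect_equal(back$lnc_gene_id, res$candidates$lnc_gene_id)
  expect_equal(nrow(data.table::fread(file.path(d, "stage_counts.tsv"))), 5L)
})
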