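#' Decoy violation classes
#'
#' Each class violates exactly one clause of the four-stage screen while
#' satisfying every clause of the preceding stages, so stage-level tests
#' map one-to-one onto decoy classes.
#'
#' @return Character vector of the eight class names.
#' @export
decoy_classes <- function() c(
  "not_DEG_lnc", "not_lncRNA", "no_accepted_TE", "TE_not_inverted",
  "TE_intronic", "same_strand_overlap", "no_overlap", "no_TIS_overlap")

# Stage at which each decoy class must drop out (0 = never enters the DEG list).
.decoy_stage <- c(
  not_DEG_lnc = 0L, not_lncRNA = 1L, no_accepted_TE = 2L, TE_not_inverted = 2L,
  TE_intronic = 2L, same_strand_overlap = 3L, no_overlap = 3L, no_TIS_overlap = 4L)

.BLOCK <- 3000L

.te_name_for <- function(family) {
  switch(family,
         "SINE/Alu" = sample(c("AluY", "AluSx", "AluJb"), 1L),
         "SINE/MIR" = sample(c("MIRb", "MIR3"), 1L),
         "SINE/B2" = "B2_Mm1a",
         "SINE/B4" = "B4A",
         "Alu_generic")
}

# One locus: a sense coding gene and its antisense lncRNA, in local
# coordinates within a .BLOCK-sized window, plus the repeat record(s).
# `violation` NULL -> planted; otherwise one of decoy_classes().
# `exact` uses the fixed geometry whose BD is 96 nt and whose merged
# FRAM-in-Alu effector cluster is 222 nt (the published human layout).
.build_locus <- function(base, lnc_id, lnc_name, sense_id, sense_name,
                         violation = NULL, exact = FALSE, mirror = FALSE,
                         chrom = "chrS") {
  viol <- violation %||% "none"
  cs <- 2501L                              # start-codon genomic start (local, + strand)
  sense_exon <- c(2201L, 2800L)
  cds <- c(cs, 2780L)
  codon <- c(cs, cs + 2L)

  if (exact) {
    ed_exon <- c(1001L, 1600L)
    bd_exon <- c(2441L, 2536L)
    te <- list(list(s = 1101L, e = 1322L, name = "AluY", class = "SINE", family = "Alu"),
               list(s = 1141L, e = 1280L, name = "FRAM", class = "SINE", family = "Alu"))
  } else {
    ed_len <- sample(400:800, 1L)
    ed_exon <- c(1001L, 1000L + ed_len)
    te_len <- sample(120:300, 1L)
    te_s <- sample((ed_exon[1L] + 50L):(ed_exon[2L] - te_len - 50L), 1L)
    fam <- sample(c("SINE/Alu", "SINE/MIR"), 1L)
    te <- list(list(s = te_s, e = te_s + te_len - 1L, name = .te_name_for(fam),
                    class = sub("/.*", "", fam), family = sub(".*/", "", fam)))
    a <- sample(20:250, 1L)
    b <- sample(0:200, 1L)
    bd_exon <- c(cs - a, cs + 2L + b)
  }

  lnc_strand <- "-"; sense_strand <- "+"
  lnc_biotype <- "lncRNA"
  te_strand <- "+"                          # opposite to lnc -> inverted
  in_deg <- TRUE

  if (viol == "not_lncRNA") lnc_biotype <- "protein_coding"
  if (viol == "not_DEG_lnc") in_deg <- FALSE
  if (viol == "no_accepted_TE")
    te <- list(list(s = te[[1L]]$s, e = te[[1L]]$e, name = "L1MA4",
                    class = "LINE", family = "L1"))
  if (viol == "TE_not_inverted") te_strand <- "-"
  if (viol == "TE_intronic") {
    te_len <- te[[1L]]$e - te[[1L]]$s + 1L
    te[[1L]]$s <- 1850L
    te[[1L]]$e <- 1850L + min(te_len, 300L) - 1L
  }
  if (viol == "same_strand_overlap") { lnc_strand <- "+"; te_strand <- "-" }
  if (viol == "no_overlap") bd_exon <- c(1850L, 1950L)
  if (viol == "no_TIS_overlap") bd_exon <- c(2601L, 2700L)

  flip <- function(iv) c(.BLOCK + 1L - iv[2L], .BLOCK + 1L - iv[1L])
  if (mirror) {
    sense_exon <- flip(sense_exon); cds <- flip(cds); codon <- flip(codon)
    ed_exon <- flip(ed_exon); bd_exon <- flip(bd_exon)
    te <- lapply(te, function(t) { f <- flip(c(t$s, t$e)); t$s <- f[1L]; t$e <- f[2L]; t })
    sw <- function(s) if (s == "+") "-" else "+"
    lnc_strand <- sw(lnc_strand); sense_strand <- sw(sense_strand)
    te_strand <- sw(te_strand)
  }

  g <- function(iv) IRanges::IRanges(base + iv[1L], base + iv[2L])
  sense_tx <- transcript_model(
    paste0(sense_id, "_T1"), sense_id, sense_name, "protein_coding",
    chrom, sense_strand, exons = g(sense_exon), cds = g(cds), start_codon = g(codon))
  lnc_exons <- sort(c(g(ed_exon), g(bd_exon)))
  lnc_tx <- transcript_model(
    paste0(lnc_id, "_T1"), lnc_id, lnc_name, lnc_biotype,
    chrom, lnc_strand, exons = lnc_exons)

  reps <- data.table::rbindlist(lapply(te, function(t) data.table::data.table(
    chrom = chrom, start = base + t$s, end = base + t$e, strand = te_strand,
    repeat_name = t$name, repeat_class = t$class, repeat_family = t$family,
    sw_score = round(stats::runif(1L, 300, 3000)),
    divergence_pct = round(stats::runif(1L, 5, 25), 1L),
    pct_del = round(stats::runif(1L, 0, 10), 1L),
    pct_ins = round(stats::runif(1L, 0, 10), 1L),
    qleft = "(0)", rep_begin = "1", rep_end = as.character(t$e - t$s + 1L),
    rep_left = "(0)", id = "0")))

  list(sense_gene = gene_model(sense_id, sense_name, "protein_coding", chrom,
                               sense_strand, list(sense_tx)),
       lnc_gene = gene_model(lnc_id, lnc_name, lnc_biotype, chrom,
                             lnc_strand, list(lnc_tx)),
       repeats = reps, in_deg = in_deg, violation = violation)
}

.rand_deg_row <- function(gene_id, gene_name, significant = TRUE, bound = NA_integer_) {
  if (significant) {
    fc <- round(stats::runif(1L, 1.5, 3.0), 5L) * sample(c(1, -1), 1L)
    p <- signif(stats::runif(1L, 1e-4, 0.04), 3L)
    dir <- if (fc >= 0) "up" else "down"
  } else {
    fc <- round(stats::runif(1L, 1.0, 1.3), 5L) * sample(c(1, -1), 1L)
    p <- signif(stats::runif(1L, 0.3, 0.9), 3L)
    dir <- "noreg"
  }
  data.table::data.table(gene_id = gene_id, gene_name = gene_name,
                         fold_change = fc, p_value = p, direction = dir,
                         bound = if (is.na(bound)) sample(0:1, 1L) else bound)
}

#' Generate a synthetic screen fixture
#'
#' Lays out one locus (an antisense lncRNA over a coding gene) per planted
#' pair and per decoy along a single contig, each in its own window:
#' planted loci satisfy all four screen predicates; each decoy violates
#' exactly the clause named by its class (see [decoy_classes]) and passes
#' every earlier stage. Locus geometry and orientation are jittered under
#' the seed; repeat records carry realistic score/divergence fields. The
#' generator re-runs the screen predicates on its own output and stops if
#' the construction is ever inconsistent, so the returned `truth` table is
#' a verified contract.
#'
#' @param n_planted Number of planted candidate pairs (ignored when
#'   `planted` is given).
#' @param decoys Character vector of decoy classes, repeats allowed.
#' @param seed Integer seed; fixtures are byte-identical for equal seeds.
#' @param planted Optional `data.frame` describing the planted pairs
#'   (columns `lnc_name`, `lnc_id`, `lnc_fc`, `lnc_p`, `lnc_direction`,
#'   `lnc_bound`, `sense_name`, `sense_id`, `sense_fc`, `sense_p`,
#'   `sense_direction`, `sense_bound`, `exact`); defaults are drawn when
#'   absent.
#' @param cfg [screen_config] used for self-verification.
#' @param genome Also simulate a random genome sequence for the contig
#'   (needed only for sequence extraction / mutant design).
#' @param verify Run the generator/validator closure check (default TRUE).
#' @return List with `ann` ([annotation_set]), `repeats` (hit table),
#'   `deg` (DEG table), `truth` (per-locus role/violation table), `cfg`,
#'   `seed`, and `genome` (a [Biostrings::DNAStringSet] or `NULL`).
#' @export
simulate_screen_fixture <- function(n_planted = 2L, decoys = character(0L),
                                    seed = 1L, planted = NULL,
                                    cfg = screen_config(), genome = FALSE,
                                    verify = TRUE) {
  bad <- setdiff(decoys, decoy_classes())
  if (length(bad)) stopf("unknown decoy class(es): %s", paste(bad, collapse = ", "))
  if (!is.null(planted)) n_planted <- nrow(planted)
  if (n_planted < 0L) stopf("n_planted must be >= 0")
  with_seed(seed, {
    n_loci <- n_planted + length(decoys)
    roles <- c(rep("planted", n_planted), rep("decoy", length(decoys)))
    viols <- c(rep(NA_character_, n_planted), decoys)
    ord <- if (n_loci) sample(n_loci) else integer(0L)  # interleave along the contig
    genes <- list(); reps <- list(); degl <- list(); truth <- list()
    for (k in seq_len(n_loci)) {
      i <- ord[k]
      base <- (k - 1L) * .BLOCK
      isp <- roles[i] == "planted"
      if (isp && !is.null(planted)) {
        p <- planted[i, , drop = FALSE]
        lnc_id <- p$lnc_id; lnc_name <- p$lnc_name
        sense_id <- p$sense_id; sense_name <- p$sense_name
        exact <- isTRUE(p$exact)
      } else {
        tag <- if (isp) sprintf("P%02d", i) else sprintf("D%02d", i - n_planted)
        lnc_id <- paste0("SYNLNC_", tag); lnc_name <- paste0("SYN-AS1-", tag)
        sense_id <- paste0("SYNPC_", tag); sense_name <- paste0("SYN-", tag)
        exact <- FALSE
      }
      mirror <- !exact && stats::runif(1L) < 0.5
      loc <- .build_locus(base, lnc_id, lnc_name, sense_id, sense_name,
                          violation = if (isp) NULL else viols[i],
                          exact = exact, mirror = mirror)
      genes <- c(genes, list(loc$sense_gene, loc$lnc_gene))
      reps[[length(reps) + 1L]] <- loc$repeats
      if (isp && !is.null(planted)) {
        degl[[length(degl) + 1L]] <- data.table::data.table(
          gene_id = c(lnc_id, sense_id), gene_name = c(lnc_name, sense_name),
          fold_change = c(p$lnc_fc, p$sense_fc), p_value = c(p$lnc_p, p$sense_p),
          direction = c(p$lnc_direction, p$sense_direction),
          bound = c(p$lnc_bound, p$sense_bound))
      } else {
        if (loc$in_deg)
          degl[[length(degl) + 1L]] <- .rand_deg_row(lnc_id, lnc_name, significant = TRUE)
        degl[[length(degl) + 1L]] <- .rand_deg_row(sense_id, sense_name, significant = FALSE)
      }
      truth[[length(truth) + 1L]] <- data.table::data.table(
        gene_id = lnc_id, gene_name = lnc_name, role = roles[i],
        violation = viols[i], sense_gene_id = sense_id,
        expected_drop_stage = if (isp) NA_integer_ else .decoy_stage[[viols[i]]])
    }
    deg <- if (length(degl)) data.table::rbindlist(degl) else
      data.table::data.table(gene_id = character(), gene_name = character(),
                             fold_change = numeric(), p_value = numeric(),
                             direction = character(), bound = integer())
    if (nrow(deg)) deg <- deg[sample(nrow(deg)), ]
    fx <- list(
      ann = annotation_set(genes, cfg$lncrna_biotypes),
      repeats = if (length(reps)) data.table::rbindlist(reps) else .empty_repeat_table(),
      deg = deg,
      truth = if (length(truth)) data.table::rbindlist(truth) else
        data.table::data.table(gene_id = character(), gene_name = character(),
                               role = character(), violation = character(),
                               sense_gene_id = character(),
                               expected_drop_stage = integer()),
      cfg = cfg, seed = seed, genome = NULL)
    if (genome) {
      clen <- max(1000L, n_loci * .BLOCK + 200L)
      fx$genome <- Biostrings::DNAStringSet(
        stats::setNames(paste(sample(c("A", "C", "G", "T"), clen, replace = TRUE),
                              collapse = ""), "chrS"))
    }
    if (verify) verify_fixture(fx)
    fx
  })
}

#' Verify the generator/validator closure of a fixture
#'
#' Runs the four screen stages on a fixture and checks that every planted
#' lncRNA survives all of them and that every decoy passes each stage
#' before its declared one and drops exactly there.
#'
#' @param fx Fixture from [simulate_screen_fixture].
#' @return `TRUE` invisibly; stops with a message on any inconsistency.
#' @export
verify_fixture <- function(fx) {
  cfg <- fx$cfg
  s1 <- filter_lncrna(fx$deg, fx$ann, cfg)
  s2 <- filter_te(s1, fx$ann, fx$repeats, cfg)
  s3p <- filter_antisense(s2, fx$ann, cfg)
  s3 <- unique(s3p$lnc_gene_id)
  s4 <- unique(filter_tis_overlap(s3p, fx$ann)$lnc_gene_id)
  stages <- list(fx$deg$gene_id, s1, s2, s3, s4)
  for (i in seq_len(nrow(fx$truth))) {
    t <- fx$truth[i, ]
    if (t$role == "planted") {
      if (!t$gene_id %in% s4)
        stopf("fixture inconsistency: planted %s did not survive the screen", t$gene_id)
    } else {
      ds <- t$expected_drop_stage
      pass_upto <- ds         # must be present in stages[1..ds], absent from stages[ds+1]
      for (k in seq_len(pass_upto))
        if (!t$gene_id %in% stages[[k]])
          stopf("fixture inconsistency: decoy %s (%s) dropped before stage %d",
                t$gene_id, t$violation, ds)
      if (t$gene_id %in% stages[[pass_upto + 1L]])
        stopf("fixture inconsistency: decoy %s (%s) survived its violated stage %d",
              t$gene_id, t$violation, ds)
    }
  }
  invisible(TRUE)
}

#' Write a fixture to disk as standard files
#'
#' Emits `annotation.gtf`, `repeats.out`, `deg.tsv`, `truth.tsv` and, when
#' the fixture carries a genome, `genome.fa`. Byte-identical output for
#' identical fixtures.
#'
#' @param fx Fixture from [simulate_screen_fixture].
#' @param dir Output directory (created if needed).
#' @return Named list of file paths, invisibly.
#' @export
write_screen_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(gtf = file.path(dir, "annotation.gtf"),
                rmsk = file.path(dir, "repeats.out"),
                deg = file.path(dir, "deg.tsv"),
                truth = file.path(dir, "truth.tsv"))
  write_gtf(fx$ann, paths$gtf)
  write_repeatmasker(fx$repeats, paths$rmsk)
  data.table::fwrite(fx$deg, paths$deg, sep = "\t")
  data.table::fwrite(fx$truth, paths$truth, sep = "\t")
  if (!is.null(fx$genome)) {
    paths$genome <- file.path(dir, "genome.fa")
    Biostrings::writeXStringSet(fx$genome, paths$genome)
  }
  invisible(paths)
}

#' The five published candidate pairs as a planted-pair table
#'
#' Gene names, Ensembl ids, signed-linear fold changes, p-values,
#' regulation directions and regulator-binding flags of the five candidate
#' lncRNA / sense mRNA pairs recovered by the original screen. The
#' RAB11B-AS1 pair is flagged `exact`, giving it the fixed synthetic
#' geometry whose binding domain is 96 nt and whose merged FRAM-in-Alu
#' effector cluster is 222 nt.
#'
#' @return `data.frame`, one row per pair.
#' @export
published_candidate_pairs <- function() {
  data.frame(
    lnc_name = c("RP11-400F19.6", "RP11-115C21.2", "RAB11B-AS1", "ST7-AS1",
                 "CTD-2517M22.14"),
    lnc_id = c("ENSG00000266962", "ENSG00000246089", "ENSG00000269386",
               "ENSG00000227199", "ENSG00000255182"),
    lnc_fc = c(2.03495, 1.89649, 1.84850, -1.76710, 2.60614),
    lnc_p = c(0.00009, 0.00336, 0.00519, 0.00991, 0.02712),
    lnc_direction = c("up", "up", "up", "down", "up"),
    lnc_bound = c(0L, 0L, 0L, 0L, 0L),
    sense_name = c("HSD17B1", "MCPH1", "RAB11B", "ST7", "PPP1R16A"),
    sense_id = c("ENSG00000108786", "ENSG00000147316", "ENSG00000185236",
                 "ENSG00000004866", "ENSG00000160972"),
    sense_fc = c(1.29275, 1.12372, 1.46253, 1.06260, 2.17035),
    sense_p = c(0.60422, 0.48333, 0.02023, 0.71902, 0.00004),
    sense_direction = c("noreg", "noreg", "up", "noreg", "up"),
    sense_bound = c(0L, 1L, 1L, 1L, 0L),
    exact = c(FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
}

#' The packaged benchmark fixture: five planted pairs plus thirty decoys
#'
#' Builds the reference fixture used to benchmark screen recovery: the
#' five published candidate pairs ([published_candidate_pairs]) planted among
#' thirty single-violation decoys cycling through all eight decoy classes.
#'
#' @param seed Integer seed (default 7).
#' @param genome Also simulate the contig sequence.
#' @return Fixture list as from [simulate_screen_fixture].
#' @export
benchmark_screen_fixture <- function(seed = 7L, genome = FALSE) {
  dec <- rep(decoy_classes(), length.out = 30L)
  simulate_screen_fixture(planted = published_candidate_pairs(), decoys = dec,
                          seed = seed, genome = genome)
}

#' A single synthetic locus mirroring the published RAB11B-AS1 geometry
#'
#' One planted pair with the fixed geometry: a 96-nt contiguous antisense
#' run over the sense start codon (binding domain) and an inverted FRAM
#' monomer nested in an inverted Alu merging to a 222-nt effector cluster
#' near the transcript 3' end. The sequence is synthetic (random contig);
#' only the interval geometry mirrors the published locus.
#'
#' @param seed Integer seed for the contig sequence and repeat metadata.
#' @return List with `ann`, `repeats`, `genome`, `deg`, plus the
#'   convenience handles `sense_tx`, `lnc_tx` and `tes` (inverted embedded
#'   TE table of the antisense transcript).
#' @export
rab11b_like_locus <- function(seed = 101L) {
  planted <- published_candidate_pairs()[3L, , drop = FALSE]
  fx <- simulate_screen_fixture(planted = planted, decoys = character(0L),
                                seed = seed, genome = TRUE)
  lnc <- fx$ann$genes[[planted$lnc_id]]
  sense <- fx$ann$genes[[planted$sense_id]]
  fx$lnc_tx <- lnc$transcripts[[1L]]
  fx$sense_tx <- sense$transcripts[[1L]]
  tes <- exonic_te_hits(fx$lnc_tx, fx$repeats)
  fx$tes <- tes[tes$inverted, ]
  fx
}

#' Simulate a pair of genes with a target expression correlation
#'
#' Draws two gene rows from a bivariate normal on the log-abundance scale
#' with Pearson correlation `rho` -- the structure of a sense/antisense (or
#' transcript-versus-regulator) co-expression panel.
#'
#' @param n_samples Number of samples (columns), at least 3.
#' @param rho Target Pearson correlation in `[-1, 1]`.
#' @param seed Integer seed.
#' @param gene_names Row names for the two genes.
#' @param means,sds Marginal means and standard deviations (log scale).
#' @return 2 x `n_samples` numeric matrix with `unit = "logCPM"` attribute.
#' @export
simulate_correlated_expression <- function(n_samples, rho, seed = 1L,
                                           gene_names = c("target", "regulator"),
                                           means = c(5, 5), sds = c(1, 1)) {
  if (abs(rho) > 1) stopf("|rho| must be <= 1, got %g", rho)
  if (n_samples < 3L) stopf("n_samples must be >= 3")
  with_seed(seed, {
    sigma <- matrix(c(sds[1L]^2, rho * sds[1L] * sds[2L],
                      rho * sds[1L] * sds[2L], sds[2L]^2), 2L)
    m <- t(MASS::mvrnorm(n_samples, mu = means, Sigma = sigma))
    dimnames(m) <- list(gene_names, sprintf("S%03d", seq_len(n_samples)))
    attr(m, "unit") <- "logCPM"
    m
  })
}

#' Simulate a qPCR Cq table with planted fold changes
#'
#' Builds a calibrator (control) and a treated sample with technical
#' replicates for one or more target genes plus a reference gene. The
#' treated target Cq is shifted by `-log2(FC)` so that the 2^-ddCq method
#' recovers `true_fold_changes` in expectation; Gaussian noise of standard
#' deviation `noise_sd` cycles is added to every individual Cq
#' measurement.
#'
#' @param true_fold_changes Named numeric vector of linear fold changes
#'   (treated versus control), one per target gene.
#' @param n_replicates Technical replicates per (sample, gene).
#' @param noise_sd Cq measurement noise, in cycles.
#' @param seed Integer seed.
#' @param reference_gene,calibrator_sample,treated_sample Labels.
#' @param base_cq_target,base_cq_ref Baseline cycle numbers.
#' @return Long-format `data.table` (`sample`, `gene`, `replicate`, `cq`)
#'   with `reference_gene` and `calibrator_sample` attributes, ready for
#'   [delta_delta_cq].
#' @export
simulate_cq_table <- function(true_fold_changes, n_replicates = 3L,
                              noise_sd = 0.2, seed = 1L,
                              reference_gene = "NONO",
                              calibrator_sample = "control",
                              treated_sample = "kd",
                              base_cq_target = 25, base_cq_ref = 20) {
  if (noise_sd < 0) stopf("noise_sd must be >= 0")
  if (is.null(names(true_fold_changes)))
    stopf("true_fold_changes must be a named vector")
  with_seed(seed, {
    rows <- list()
    add <- function(sample, gene, mu) {
      rows[[length(rows) + 1L]] <<- data.table::data.table(
        sample = sample, gene = gene, replicate = seq_len(n_replicates),
        cq = mu + stats::rnorm(n_replicates, 0, noise_sd))
    }
    for (s in c(calibrator_sample, treated_sample)) add(s, reference_gene, base_cq_ref)
    for (g in names(true_fold_changes)) {
      add(calibrator_sample, g, base_cq_target)
      add(treated_sample, g, base_cq_target - log2(true_fold_changes[[g]]))
    }
    out <- data.table::rbindlist(rows)
    data.table::setattr(out, "reference_gene", reference_gene)
    data.table::setattr(out, "calibrator_sample", calibrator_sample)
    out
  })
}
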