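#' Screen configuration
#'
#' Bundles the tunable parameters of the four-stage SINEUP candidate
#' screen.
#'
#' @param lncrna_biotypes Biotype labels accepted at stage 1.
#' @param te_families Accepted `"class/family"` repeat labels at stage 2.
#' @param require_inverted Require the embedded TE to be inverted relative
#'   to the transcript at stage 2 (default `TRUE`; all published natural
#'   SINEUPs carry inverted elements).
#' @param min_overlap Minimum antisense exonic overlap in nt at stage 3
#'   (default 1, i.e. any exonic overlap qualifies).
#' @param min_exonic_nt Minimum exonic nt of a TE hit for it to count as
#'   embedded (default 1).
#' @param overlap_on `"exons"` (default) or `"spans"`: whether stage 3
#'   intersects exon sets or whole gene spans.
#' @return A `screen_config` list.
#' @export
screen_config <- function(lncrna_biotypes = c("lncRNA", "antisense", "lincRNA"),
                          te_families = sineup_te_families(),
                          require_inverted = TRUE,
                          min_overlap = 1L,
                          min_exonic_nt = 1L,
                          overlap_on = c("exons", "spans")) {
  if (min_overlap < 1L) stopf("min_overlap must be >= 1")
  if (min_exonic_nt < 1L) stopf("min_exonic_nt must be >= 1")
  structure(list(lncrna_biotypes = lncrna_biotypes, te_families = te_families,
                 require_inverted = isTRUE(require_inverted),
                 min_overlap = as.integer(min_overlap),
                 min_exonic_nt = as.integer(min_exonic_nt),
                 overlap_on = match.arg(overlap_on)),
            class = "screen_config")
}

#' Read a differential-expression gene table
#'
#' Expects a TSV with header columns `gene_id`, `fold_change`, `p_value`
#' and optionally `gene_name`, `direction` and `bound` (pass-through
#' regulator-binding metadata). Fold changes may be supplied signed-linear
#' (negative = down-regulated, magnitude = fold) or as log2 ratios; log2
#' input is normalised to the signed-linear convention on load.
#'
#' @param path Path to the TSV.
#' @param fc_scale `"signed_linear"` (default) or `"log2"`.
#' @param noreg_p p-value above which a record without an explicit
#'   `direction` column is labelled `"noreg"` (default 0.05).
#' @return `data.table` of DEG records with signed-linear `fold_change`
#'   and a `direction` factor in `up`/`down`/`noreg`.
#' @export
read_deg_table <- function(path, fc_scale = c("signed_linear", "log2"),
                           noreg_p = 0.05) {
  fc_scale <- match.arg(fc_scale)
  d <- data.table::fread(path)
  need <- c("gene_id", "fold_change", "p_value")
  miss <- setdiff(need, names(d))
  if (length(miss)) stopf("DEG table missing column(s): %s", paste(miss, collapse = ", "))
  if (!"gene_name" %in% names(d)) d$gene_name <- d$gene_id
  if (fc_scale == "log2")
    d$fold_change <- ifelse(d$fold_change >= 0, 2^d$fold_change, -(2^(-d$fold_change)))
  if (!"direction" %in% names(d))
    d$direction <- ifelse(d$p_value > noreg_p, "noreg",
                          ifelse(d$fold_change >= 0, "up", "down"))
  if (any(d$p_value <= 0 | d$p_value > 1))
    stopf("DEG table: p_value out of (0, 1]")
  d
}

#' Stage 1: restrict DEGs to lncRNA-annotated genes
#'
#' @param deg DEG table ([read_deg_table]).
#' @param ann An [annotation_set].
#' @param cfg A [screen_config].
#' @return Character vector of gene ids, in input order. DEG ids absent
#'   from the annotation are dropped with a warning.
#' @export
filter_lncrna <- function(deg, ann, cfg = screen_config()) {
  ids <- deg$gene_id
  known <- ids %in% names(ann$genes)
  if (any(!known))
    warnf("%d DEG gene id(s) not found in annotation; dropped", sum(!known))
  ids <- ids[known]
  bt <- vapply(ids, function(g) ann$genes[[g]]$biotype, "")
  ids[bt %in% cfg$lncrna_biotypes]
}

#' Stage 2: require an embedded (inverted) SINE-family element
#'
#' A gene survives when at least one of its transcripts carries at least
#' one exonic repeat hit of an accepted family (inverted relative to the
#' transcript when `cfg$require_inverted`).
#'
#' @param gene_ids Gene ids surviving stage 1.
#' @param ann An [annotation_set].
#' @param repeats Repeat-hit table ([read_repeatmasker]).
#' @param cfg A [screen_config].
#' @return Character vector of surviving gene ids, order preserved.
#' @export
filter_te <- function(gene_ids, ann, repeats, cfg = screen_config()) {
  keep <- vapply(gene_ids, function(gid) {
    g <- ann$genes[[gid]]
    any(vapply(g$transcripts, function(tx) {
      te <- exonic_te_hits(tx, repeats, cfg$te_families, cfg$min_exonic_nt)
      if (cfg$require_inverted) te <- te[te$inverted, ]
      nrow(te) > 0L
    }, logical(1L)))
  }, logical(1L))
  gene_ids[keep]
}

.pair_overlap_nt <- function(lnc, pc, cfg) {
  if (cfg$overlap_on == "spans") {
    if (lnc$chrom != pc$chrom) return(list(nt = 0L))
    iv <- IRanges::intersect(lnc$span, pc$span)
    return(list(nt = sum(IRanges::width(iv)),
                lnc_tx = names(lnc$transcripts)[1L], sense_tx = names(pc$transcripts)[1L]))
  }
  best <- list(nt = 0L, lnc_tx = NA_character_, sense_tx = NA_character_)
  for (lt in lnc$transcripts) for (st in pc$transcripts) {
    nt <- exonic_intersection(lt, st)$total_nt
    if (nt > best$nt ||
        (nt == best$nt && nt > 0L &&
         paste(lt$transcript_id, st$transcript_id) <
         paste(best$lnc_tx, best$sense_tx)))
      best <- list(nt = nt, lnc_tx = lt$transcript_id, sense_tx = st$transcript_id)
  }
  best
}

#' Stage 3: antisense exonic overlap with a protein-coding gene
#'
#' Pairs each surviving lncRNA gene with every protein-coding gene on the
#' opposite strand whose exons overlap by at least `cfg$min_overlap` nt for
#' at least one isoform pair; the reported overlap is the maximum over
#' isoform pairs.
#'
#' @param gene_ids Gene ids surviving stage 2.
#' @param ann An [annotation_set].
#' @param cfg A [screen_config].
#' @return `data.table` with one row per (lnc gene, sense gene) pair:
#'   `lnc_gene_id`, `sense_gene_id`, `overlap_nt`, `lnc_tx`, `sense_tx`.
#' @export
filter_antisense <- function(gene_ids, ann, cfg = screen_config()) {
  coding <- Filter(function(g) g$biotype == "protein_coding", ann$genes)
  rows <- list()
  for (gid in gene_ids) {
    lnc <- ann$genes[[gid]]
    for (pc in coding) {
      if (pc$chrom != lnc$chrom || pc$strand == lnc$strand) next
      if (!IRanges::overlapsAny(lnc$span, pc$span)) next
      best <- .pair_overlap_nt(lnc, pc, cfg)
      if (best$nt >= cfg$min_overlap)
        rows[[length(rows) + 1L]] <- data.table::data.table(
          lnc_gene_id = gid, sense_gene_id = pc$gene_id,
          overlap_nt = best$nt, lnc_tx = best$lnc_tx, sense_tx = best$sense_tx)
    }
  }
  if (!length(rows))
    return(data.table::data.table(lnc_gene_id = character(), sense_gene_id = character(),
                                  overlap_nt = integer(), lnc_tx = character(),
                                  sense_tx = character()))
  data.table::rbindlist(rows)
}

#' Stage 4: overlap of the sense start codon (first ATG)
#'
#' A pair survives when some lncRNA isoform's exons cover at least 1 nt of
#' some sense coding isoform's start-codon interval(s); the supporting
#' isoform pair with the largest codon overlap (ties broken
#' lexicographically) is recorded.
#'
#' @param pairs Pair table from [filter_antisense].
#' @param ann An [annotation_set].
#' @return `pairs` subset with added columns `tis_overlap_nt` (1-3),
#'   `tis_lnc_tx`, `tis_sense_tx`. Sense genes with no coding isoform are
#'   dropped with a warning.
#' @export
filter_tis_overlap <- function(pairs, ann) {
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    p <- pairs[i, ]
    lnc <- ann$genes[[p$lnc_gene_id]]
    sg <- ann$genes[[p$sense_gene_id]]
    coding_tx <- Filter(function(tx) length(tx$cds) || length(tx$start_codon), sg$transcripts)
    if (!length(coding_tx)) {
      warnf("pair %s/%s: sense gene has no coding isoform; dropped",
            p$lnc_gene_id, p$sense_gene_id)
      next
    }
    best <- list(nt = 0L, lnc_tx = NA_character_, sense_tx = NA_character_)
    for (st in coding_tx) {
      codon <- start_codon_intervals(st)
      for (lt in lnc$transcripts) {
        if (lt$chrom != st$chrom) next
        nt <- sum(IRanges::width(IRanges::intersect(IRanges::reduce(lt$exons), codon)))
        if (nt > best$nt ||
            (nt == best$nt && nt > 0L &&
             paste(lt$transcript_id, st$transcript_id) <
             paste(best$lnc_tx, best$sense_tx)))
          best <- list(nt = nt, lnc_tx = lt$transcript_id, sense_tx = st$transcript_id)
      }
    }
    if (best$nt >= 1L) {
      p$tis_overlap_nt <- best$nt
      p$tis_lnc_tx <- best$lnc_tx
      p$tis_sense_tx <- best$sense_tx
      out[[length(out) + 1L]] <- p
    }
  }
  if (!length(out))
    return(cbind(pairs[0L, ], data.table::data.table(
      tis_overlap_nt = integer(), tis_lnc_tx = character(), tis_sense_tx = character())))
  data.table::rbindlist(out)
}

.deg_lookup <- function(deg, gid) {
  j <- which(deg$gene_id == gid)
  if (!length(j)) return(list(gene_name = NA_character_, fold_change = NA_real_,
                              p_value = NA_real_, direction = "noreg", bound = NA))
  r <- deg[j[1L], ]
  list(gene_name = r$gene_name, fold_change = r$fold_change, p_value = r$p_value,
       direction = as.character(r$direction),
       bound = if ("bound" %in% names(deg)) r$bound else NA)
}

#' Run the full four-stage SINEUP candidate screen
#'
#' Composes the four filters in their canonical order -- lncRNA biotype,
#' embedded inverted SINE-family element, antisense exonic overlap with a
#' protein-coding gene, overlap of the sense translation-initiation site --
#' and reports the surviving (lncRNA, sense mRNA) pairs together with
#' per-stage survivor counts. The differential-expression requirement
#' applies to the lncRNA only; the sense gene's statistics are reported as
#' found (possibly `noreg`), as is any `bound` regulator-binding metadata
#' carried by the DEG table.
#'
#' @param deg DEG table ([read_deg_table]).
#' @param ann An [annotation_set].
#' @param repeats Repeat-hit table ([read_repeatmasker]).
#' @param cfg A [screen_config].
#' @return A `candidate_table`: list with `candidates` (one row per pair,
#'   ordered by lnc then sense gene id), `stage_counts`, and `config`.
#' @export
run_screen <- function(deg, ann, repeats, cfg = screen_config()) {
  s1 <- filter_lncrna(deg, ann, cfg)
  s2 <- filter_te(s1, ann, repeats, cfg)
  s3 <- filter_antisense(s2, ann, cfg)
  s4 <- filter_tis_overlap(s3, ann)

  rows <- list()
  for (i in seq_len(nrow(s4))) {
    p <- s4[i, ]
    ldeg <- .deg_lookup(deg, p$lnc_gene_id)
    sdeg <- .deg_lookup(deg, p$sense_gene_id)
    lnc <- ann$genes[[p$lnc_gene_id]]
    tes <- exonic_te_hits(lnc$transcripts[[p$lnc_tx]], repeats,
                          cfg$te_families, cfg$min_exonic_nt)
    if (cfg$require_inverted) tes <- tes[tes$inverted, ]
    rows[[length(rows) + 1L]] <- data.table::data.table(
      lnc_gene_name = if (is.na(ldeg$gene_name)) lnc$gene_name else ldeg$gene_name,
      lnc_gene_id = p$lnc_gene_id,
      lnc_fc = ldeg$fold_change, lnc_p = ldeg$p_value,
      lnc_direction = ldeg$direction, lnc_bound = ldeg$bound,
      sense_gene_name = if (is.na(sdeg$gene_name))
        ann$genes[[p$sense_gene_id]]$gene_name else sdeg$gene_name,
      sense_gene_id = p$sense_gene_id,
      sense_fc = sdeg$fold_change, sense_p = sdeg$p_value,
      sense_direction = sdeg$direction, sense_bound = sdeg$bound,
      antisense_overlap_nt = p$overlap_nt,
      tis_overlap_nt = p$tis_overlap_nt,
      n_embedded_te = nrow(tes),
      te_names = paste(tes$repeat_name, collapse = ","),
      lnc_tx = p$lnc_tx, sense_tx = p$sense_tx)
  }
  cand <- if (length(rows)) data.table::rbindlist(rows) else
    data.table::data.table(lnc_gene_name = character(), lnc_gene_id = character(),
                           lnc_fc = numeric(), lnc_p = numeric(),
                           lnc_direction = character(), lnc_bound = logical(),
                           sense_gene_name = character(), sense_gene_id = character(),
                           sense_fc = numeric(), sense_p = numeric(),
                           sense_direction = character(), sense_bound = logical(),
                           antisense_overlap_nt = integer(), tis_overlap_nt = integer(),
                           n_embedded_te = integer(), te_names = character(),
                           lnc_tx = character(), sense_tx = character())
  cand <- cand[order(cand$lnc_gene_id, cand$sense_gene_id), ]

  stage_counts <- data.table::data.table(
    stage = c("input_deg", "lncrna", "embedded_te", "antisense_pair", "tis_overlap"),
    n_genes = c(length(unique(deg$gene_id)), length(s1), length(s2),
                length(unique(s3$lnc_gene_id)), length(unique(cand$lnc_gene_id))))

  res <- structure(list(candidates = cand, stage_counts = stage_counts, config = cfg),
                   class = "candidate_table")
  .validate_candidates(res, ann)
  res
}

# Self-check: every emitted pair satisfies the candidate invariants.
.validate_candidates <- function(ct, ann) {
  cand <- ct$candidates
  for (i in seq_len(nrow(cand))) {
    r <- cand[i, ]
    lnc <- ann$genes[[r$lnc_gene_id]]
    sg <- ann$genes[[r$sense_gene_id]]
    ok <- r$antisense_overlap_nt >= 1L && r$tis_overlap_nt >= 1L &&
      r$tis_overlap_nt <= 3L && lnc$strand != sg$strand &&
      (!ct$config$require_inverted || r$n_embedded_te >= 1L)
    if (!ok) stopf("internal error: candidate %s/%s violates pair invariants",
                   r$lnc_gene_id, r$sense_gene_id)
  }
  invisible(TRUE)
}

#' @export
print.candidate_table <- function(x, ...) {
  cat(sprintf("<candidate_table> %d candidate pair(s)\n", nrow(x$candidates)))
  print(x$stage_counts)
  if (nrow(x$candidates))
    print(x$candidates[, c("lnc_gene_name", "lnc_fc", "lnc_p", "lnc_direction",
                           "sense_gene_name", "sense_fc", "sense_p",
                           "antisense_overlap_nt", "tis_overlap_nt")])
  invisible(x)
}

#' Write a candidate table to disk
#'
#' @param ct A `candidate_table` from [run_screen].
#' @param dir Output directory (created if needed); writes
#'   `candidates.tsv` and `stage_counts.tsv`.
#' @return `dir`, invisibly.
#' @export
write_candidate_table <- function(ct, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(ct$candidates, file.path(dir, "candidates.tsv"), sep = "\t")
  data.table::fwrite(ct$stage_counts, file.path(dir, "stage_counts.tsv"), sep = "\t")
  invisible(dir)
}
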