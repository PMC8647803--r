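.tx_exons_5to3 <- function(tx) {
  ex <- sort(tx$exons)
  if (tx$strand == "-") ex[rev(seq_along(ex))] else ex
}

#' Map a genomic interval onto transcript (spliced) coordinates
#'
#' Transcript coordinates are 1-based closed, counted 5' to 3' along the
#' mature RNA; on the minus strand position 1 is the exon base with the
#' highest genomic coordinate. The interval is clipped to the exons; an
#' interval touching consecutive exons maps to one contiguous transcript
#' interval whose length equals the exonic overlap.
#'
#' @param tx A `transcript_model`.
#' @param gstart,gend Genomic interval (1-based closed).
#' @return Named integer vector `c(start, end)` in transcript coordinates.
#' @export
genomic_to_transcript_coords <- function(tx, gstart, gend) {
  if (gend < gstart) stopf("empty genomic interval")
  g <- IRanges::IRanges(gstart, gend)
  exs <- .tx_exons_5to3(tx)
  pos <- integer(0L)
  off <- 0L
  for (i in seq_along(exs)) {
    ov <- IRanges::intersect(IRanges::IRanges(IRanges::start(exs)[i], IRanges::end(exs)[i]), g)
    if (length(ov)) {
      s <- IRanges::start(ov)
      e <- IRanges::end(ov)
      if (tx$strand == "+") {
        tpos <- c(off + (s - IRanges::start(exs)[i]) + 1L,
                  off + (e - IRanges::start(exs)[i]) + 1L)
      } else {
        tpos <- c(off + (IRanges::end(exs)[i] - e) + 1L,
                  off + (IRanges::end(exs)[i] - s) + 1L)
      }
      pos <- c(pos, tpos)
    }
    off <- off + IRanges::width(exs)[i]
  }
  if (!length(pos))
    stopf("interval %d-%d is fully intronic or outside transcript %s",
          gstart, gend, tx$transcript_id)
  c(start = min(pos), end = max(pos))
}

#' Map a transcript interval back to genomic intervals
#'
#' Inverse of [genomic_to_transcript_coords] on exonic positions; a
#' transcript interval spanning a splice junction yields one genomic
#' interval per touched exon.
#'
#' @param tx A `transcript_model`.
#' @param tstart,tend Transcript interval (1-based closed, 5' to 3').
#' @return [IRanges::IRanges] of genomic intervals (sorted by start).
#' @export
transcript_to_genomic_coords <- function(tx, tstart, tend) {
  tlen <- transcript_length(tx)
  if (tstart < 1L || tend > tlen || tstart > tend)
    stopf("transcript interval %d-%d outside [1, %d]", tstart, tend, tlen)
  exs <- .tx_exons_5to3(tx)
  out <- list()
  off <- 0L
  for (i in seq_along(exs)) {
    w <- IRanges::width(exs)[i]
    lo <- max(tstart, off + 1L)
    hi <- min(tend, off + w)
    if (lo <= hi) {
      if (tx$strand == "+") {
        gs <- IRanges::start(exs)[i] + (lo - off - 1L)
        ge <- IRanges::start(exs)[i] + (hi - off - 1L)
      } else {
        gs <- IRanges::end(exs)[i] - (hi - off - 1L)
        ge <- IRanges::end(exs)[i] - (lo - off - 1L)
      }
      out[[length(out) + 1L]] <- IRanges::IRanges(gs, ge)
    }
    off <- off + w
  }
  sort(do.call(c, out))
}

#' Binding domain of a candidate SINEUP pair
#'
#' The binding domain (BD) is the maximal contiguous run of the per-base
#' exonic intersection of the antisense and sense transcripts that contains
#' at least one base of the sense start codon -- the head-to-head antisense
#' region around the translation-initiation site that gives a SINEUP its
#' target specificity.
#'
#' @param sense_tx Coding `transcript_model` (sense mRNA).
#' @param lnc_tx Antisense `transcript_model`.
#' @return List with `bd_genomic` ([IRanges::IRanges], single run),
#'   `bd_len_nt`, and `chrom`.
#' @export
compute_binding_domain <- function(sense_tx, lnc_tx) {
  runs <- exonic_intersection(sense_tx, lnc_tx)$intervals
  codon <- start_codon_intervals(sense_tx)
  hit <- which(vapply(seq_along(runs), function(i)
    sum(IRanges::width(IRanges::intersect(runs[i], codon))) > 0L, logical(1L)))
  if (!length(hit))
    stopf("not a TIS-overlapping pair: no intersection run contains the start codon")
  if (length(hit) > 1L) {
    covs <- vapply(hit, function(i)
      sum(IRanges::width(IRanges::intersect(runs[i], codon))), integer(1L))
    hit <- hit[order(-covs, IRanges::start(runs)[hit])][1L]
  }
  bd <- runs[hit]
  list(bd_genomic = bd, bd_len_nt = IRanges::width(bd), chrom = sense_tx$chrom)
}

#' Effector domain of a candidate SINEUP transcript
#'
#' Genomically overlapping or adjacent embedded-TE hits are merged into a
#' single union interval (the published human case is a FRAM monomer nested
#' inside a SINE/Alu hit, jointly treated as one effector domain). When
#' several disjoint clusters exist, the one nearest the transcript 3' end
#' is reported as the effector domain (ED) and the rest as secondary
#' clusters. `ed_len_nt` is the raw union length; `ed_exonic_len_nt` clips
#' the union to exonic positions (identical for fully exonic elements).
#'
#' @param lnc_tx Antisense `transcript_model`.
#' @param tes Embedded-TE table from [exonic_te_hits]; must be non-empty
#'   (typically the inverted, accepted-family hits).
#' @return List with `ed_genomic`, `ed_len_nt`, `ed_exonic_len_nt`,
#'   `ed_tx_coords`, `ed_dist_to_3prime_nt`, `ed_members` (TE table rows of
#'   the chosen cluster), and `secondary_clusters`.
#' @export
compute_effector_domain <- function(lnc_tx, tes) {
  if (!nrow(tes)) stopf("no embedded TE hits supplied")
  hitR <- IRanges::IRanges(tes$start, tes$end)
  clusters <- IRanges::reduce(hitR)
  ex <- IRanges::reduce(lnc_tx$exons)
  exonic_nt <- vapply(seq_along(clusters), function(i)
    sum(IRanges::width(IRanges::intersect(clusters[i], ex))), integer(1L))
  keep <- which(exonic_nt > 0L)
  if (!length(keep)) stopf("no TE cluster overlaps the exons of %s", lnc_tx$transcript_id)
  clusters <- clusters[keep]
  exonic_nt <- exonic_nt[keep]
  tlen <- transcript_length(lnc_tx)
  txc <- lapply(seq_along(clusters), function(i)
    genomic_to_transcript_coords(lnc_tx, IRanges::start(clusters)[i], IRanges::end(clusters)[i]))
  dist3 <- vapply(txc, function(tc) tlen - tc[["end"]], numeric(1L))
  pick <- order(dist3, vapply(txc, `[[`, 0, "start"))[1L]
  members <- tes[IRanges::overlapsAny(hitR, clusters[pick]), ]
  list(ed_genomic = clusters[pick],
       ed_len_nt = IRanges::width(clusters[pick]),
       ed_exonic_len_nt = exonic_nt[pick],
       ed_tx_coords = txc[[pick]],
       ed_dist_to_3prime_nt = as.integer(dist3[pick]),
       ed_members = members,
       secondary_clusters = clusters[-pick])
}

#' Annotate both SINEUP domains on a candidate pair
#'
#' Convenience wrapper combining [compute_binding_domain] and
#' [compute_effector_domain], with both domains also placed in antisense
#' transcript coordinates.
#'
#' @param sense_tx Coding sense `transcript_model`.
#' @param lnc_tx Antisense `transcript_model`.
#' @param tes Embedded-TE table for `lnc_tx` (see [exonic_te_hits]).
#' @return A `sineup_domains` list.
#' @export
annotate_sineup_domains <- function(sense_tx, lnc_tx, tes) {
  bd <- compute_binding_domain(sense_tx, lnc_tx)
  ed <- compute_effector_domain(lnc_tx, tes)
  bd_tx <- genomic_to_transcript_coords(lnc_tx, IRanges::start(bd$bd_genomic),
                                        IRanges::end(bd$bd_genomic))
  structure(c(bd, list(bd_tx_coords = bd_tx), ed,
              list(lnc_tx_id = lnc_tx$transcript_id,
                   sense_tx_id = sense_tx$transcript_id,
                   lnc_tx_len = transcript_length(lnc_tx))),
            class = "sineup_domains")
}

#' @export
print.sineup_domains <- function(x, ...) {
  cat(sprintf("<sineup_domains> %s vs %s\n", x$lnc_tx_id, x$sense_tx_id))
  cat(sprintf("  BD %s:%d-%d (%d nt), tx %d-%d\n", x$chrom,
              IRanges::start(x$bd_genomic), IRanges::end(x$bd_genomic),
              x$bd_len_nt, x$bd_tx_coords[["start"]], x$bd_tx_coords[["end"]]))
  cat(sprintf("  ED %s:%d-%d (%d nt union, %d nt exonic), tx %d-%d, %d nt from 3' end, %d member hit(s)\n",
              x$chrom, IRanges::start(x$ed_genomic), IRanges::end(x$ed_genomic),
              x$ed_len_nt, x$ed_exonic_len_nt,
              x$ed_tx_coords[["start"]], x$ed_tx_coords[["end"]],
              x$ed_dist_to_3prime_nt, nrow(x$ed_members)))
  invisible(x)
}

#' Domain-deletion mutant of a spliced sequence
#'
#' Removes a transcript-coordinate interval (1-based closed, on the mature
#' RNA) from the wild-type sequence -- the in-silico counterpart of
#' site-directed deletion mutagenesis of a cloned construct.
#'
#' @param wt_sequence Wild-type nucleotide string.
#' @param del_start,del_end Interval to excise, 1-based closed.
#' @param name Construct name (e.g. `"dBD"`, `"dED"`).
#' @return A `mutant_construct` list: `name`, `sequence`,
#'   `deleted_tx_interval`.
#' @export
make_deletion_mutant <- function(wt_sequence, del_start, del_end, name = "mutant") {
  n <- nchar(wt_sequence)
  if (del_start < 1L || del_end > n || del_start > del_end)
    stopf("deletion interval %d-%d out of range for a %d-nt sequence",
          del_start, del_end, n)
  structure(list(
    name = name,
    sequence = paste0(substr(wt_sequence, 1L, del_start - 1L),
                      substr(wt_sequence, del_end + 1L, n)),
    deleted_tx_interval = c(start = del_start, end = del_end)
  ), class = "mutant_construct")
}

#' Design WT / dBD / dED constructs for a candidate transcript
#'
#' Extracts the wild-type spliced sequence and derives the two
#' domain-deletion constructs in transcript coordinates (the cloned
#' construct is the mature RNA, so deletions are designed on the spliced
#' sequence).
#'
#' @param lnc_tx Antisense `transcript_model`.
#' @param genome Genome FASTA path or [Biostrings::DNAStringSet].
#' @param domains A `sineup_domains` object ([annotate_sineup_domains]).
#' @return Named list of `mutant_construct`s: `WT`, `dBD`, `dED`.
#' @export
design_deletion_mutants <- function(lnc_tx, genome, domains) {
  wt <- spliced_sequence(lnc_tx, genome)
  list(
    WT = structure(list(name = "WT", sequence = wt, deleted_tx_interval = NULL),
                   class = "mutant_construct"),
    dBD = make_deletion_mutant(wt, domains$bd_tx_coords[["start"]],
                               domains$bd_tx_coords[["end"]], "dBD"),
    dED = make_deletion_mutant(wt, domains$ed_tx_coords[["start"]],
                               domains$ed_tx_coords[["end"]], "dED"))
}

#' Write mutant constructs as FASTA
#' @param constructs List of `mutant_construct`s ([design_deletion_mutants]).
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_constructs_fasta <- function(constructs, path) {
  seqs <- Biostrings::DNAStringSet(vapply(constructs, `[[`, "", "sequence"))
  names(seqs) <- vapply(constructs, `[[`, "", "name")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Export BD/ED intervals as BED
#'
#' BED uses 0-based half-open coordinates; conversion from the internal
#' 1-based closed convention happens here.
#'
#' @param domains A `sineup_domains` object.
#' @param path Output BED path.
#' @param lnc_strand Strand written for both features.
#' @return `path`, invisibly.
#' @export
domains_to_bed <- function(domains, path, lnc_strand = "-") {
  bed <- c(
    sprintf("%s\t%d\t%d\tBD\t0\t%s", domains$chrom,
            IRanges::start(domains$bd_genomic) - 1L, IRanges::end(domains$bd_genomic),
            lnc_strand),
    sprintf("%s\t%d\t%d\tED\t0\t%s", domains$chrom,
            IRanges::start(domains$ed_genomic) - 1L, IRanges::end(domains$ed_genomic),
            lnc_strand))
  writeLines(bed, path)
  invisible(path)
}
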