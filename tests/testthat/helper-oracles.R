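# Brute-force per-base oracles, independent of the IRanges-backed
# implementation: intervals are expanded into integer position sets and all
# predicates are evaluated with base set operations and explicit loops.

ir_bases <- function(ir) {
  if (!length(ir)) return(integer(0))
  unlist(Map(seq.int, IRanges::start(ir), IRanges::end(ir)))
}

tx_exon_bases <- function(tx) ir_bases(tx$exons)

# Per-base intersection length of two transcripts' exon sets.
oracle_exonic_overlap <- function(txA, txB) {
  if (txA$chrom != txB$chrom) return(0L)
  length(intersect(tx_exon_bases(txA), tx_exon_bases(txB)))
}

# Stage-wise survivor sets, evaluated by exhaustive per-base enumeration
# over all (lnc isoform x sense isoform x repeat hit) combinations.
oracle_screen <- function(fx, cfg = fx$cfg) {
  ann <- fx$ann
  hits <- fx$repeats
  deg_ids <- fx$deg$gene_id
  deg_ids <- deg_ids[deg_ids %in% names(ann$genes)]

  s1 <- deg_ids[vapply(deg_ids, function(g)
    ann$genes[[g]]$biotype %in% cfg$lncrna_biotypes, logical(1))]

  has_te <- function(gid) {
    for (tx in ann$genes[[gid]]$transcripts) {
      exb <- tx_exon_bases(tx)
      for (j in seq_len(nrow(hits))) {
        h <- hits[j, ]
        if (h$chrom != tx$chrom) next
        if (!paste0(h$repeat_class, "/", h$repeat_family) %in% cfg$te_families) next
        if (cfg$require_inverted && h$strand == tx$strand) next
        if (length(intersect(seq.int(h$start, h$end), exb)) >= cfg$min_exonic_nt)
          return(TRUE)
      }
    }
    FALSE
  }
  s2 <- s1[vapply(s1, has_te, logical(1))]

  pcs <- Filter(function(g) g$biotype == "protein_coding", ann$genes)
  antisense_partners <- function(gid) {
    lnc <- ann$genes[[gid]]
    out <- character(0)
    for (pc in pcs) {
      if (pc$chrom != lnc$chrom || pc$strand == lnc$strand) next
      found <- FALSE
      for (lt in lnc$transcripts) for (st in pc$transcripts)
        if (length(intersect(tx_exon_bases(lt), tx_exon_bases(st))) >= cfg$min_overlap)
          found <- TRUE
      if (found) out <- c(out, pc$gene_id)
    }
    out
  }
  partners <- lapply(s2, antisense_partners)
  names(partners) <- s2
  s3 <- s2[lengths(partners) > 0]

  tis_ok <- function(gid) {
    lnc <- ann$genes[[gid]]
    for (pcid in partners[[gid]]) {
      for (st in ann$genes[[pcid]]$transcripts) {
        if (!length(st$start_codon) && !length(st$cds)) next
        codon_b <- if (length(st$start_codon)) ir_bases(st$start_codon) else
          ir_bases(sineupscreen::start_codon_intervals(st))
        for (lt in lnc$transcripts)
          if (lt$chrom == st$chrom &&
              length(intersect(tx_exon_bases(lt), codon_b)) >= 1)
            return(TRUE)
      }
    }
    FALSE
  }
  s4 <- s3[vapply(s3, tis_ok, logical(1))]

  list(s1 = unname(s1), s2 = unname(s2), s3 = unname(s3), s4 = unname(s4))
}

# Closed-form simple OLS with the t-statistic slope test.
oracle_ols <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  res <- y - intercept - slope * x
  se <- sqrt(sum(res^2) / (n - 2) / sxx)
  tstat <- slope / se
  list(slope = slope, intercept = intercept,
       r = sxy / sqrt(sxx * sum((y - mean(y))^2)),
       p = 2 * stats::pt(-abs(tstat), df = n - 2))
}

# Random transcript over a small contig, for coordinate property tests.
random_transcript <- function(strand = sample(c("+", "-"), 1), n_exons = sample(1:4, 1),
                              chrom = "chrT") {
  starts <- sort(sample(seq(1, 900, by = 25), n_exons))
  ex <- IRanges::IRanges(starts, width = sample(10:20, n_exons, replace = TRUE))
  while (length(IRanges::reduce(ex)) < n_exons) {
    starts <- sort(sample(seq(1, 900, by = 25), n_exons))
    ex <- IRanges::IRanges(starts, width = sample(10:20, n_exons, replace = TRUE))
  }
  transcript_model(paste0("TX", sample(1e6, 1)), "G1", "G1", "lncRNA",
                   chrom, strand, exons = ex)
}
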