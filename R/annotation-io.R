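#' Transcript model
#'
#' Container for the stranded exon/CDS/start-codon structure of a single
#' isoform. All coordinates are 1-based closed genomic intervals
#' ([IRanges::IRanges]), the native convention of the R genomics stack;
#' conversion from/to other conventions (GTF is already 1-based closed,
#' BED is 0-based half-open) happens at the I/O boundary.
#'
#' @param transcript_id,gene_id,gene_name Identifier strings.
#' @param biotype Gene biotype label (e.g. `"lncRNA"`, `"protein_coding"`).
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`.
#' @param exons [IRanges::IRanges] of exons; must be disjoint. Stored sorted
#'   by genomic start.
#' @param cds Optional [IRanges::IRanges] of coding intervals; must fall
#'   within the exons.
#' @param start_codon Optional [IRanges::IRanges] of start-codon parts
#'   (split codons allowed); total width must be 3 when present.
#' @return An object of class `transcript_model`.
#' @export
transcript_model <- function(transcript_id, gene_id, gene_name = gene_id,
                             biotype = "protein_coding", chrom, strand,
                             exons, cds = NULL, start_codon = NULL) {
  if (!strand %in% c("+", "-")) stopf("strand must be '+' or '-', got '%s'", strand)
  exons <- sort(exons)
  if (length(exons) > 1L && any(IRanges::start(exons)[-1L] <= IRanges::end(exons)[-length(exons)]))
    stopf("transcript %s: exons overlap", transcript_id)
  cds <- cds %||% IRanges::IRanges()
  start_codon <- start_codon %||% IRanges::IRanges()
  if (length(cds) && sum(IRanges::width(IRanges::intersect(cds, exons))) != sum(IRanges::width(IRanges::reduce(cds))))
    stopf("transcript %s: CDS not contained in exons", transcript_id)
  if (length(start_codon) && sum(IRanges::width(start_codon)) != 3L)
    stopf("transcript %s: start_codon total length must be 3", transcript_id)
  structure(list(
    transcript_id = transcript_id, gene_id = gene_id, gene_name = gene_name,
    biotype = biotype, chrom = chrom, strand = strand,
    exons = exons, cds = sort(cds), start_codon = sort(start_codon)
  ), class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s, %s) %s:%s %d exon(s), %d nt%s\n",
              x$transcript_id, x$gene_name, x$biotype, x$chrom, x$strand,
              length(x$exons), sum(IRanges::width(x$exons)),
              if (length(x$cds)) ", coding" else ""))
  invisible(x)
}

#' Total spliced length of a transcript
#' @param tx A `transcript_model`.
#' @return Integer number of exonic nucleotides.
#' @export
transcript_length <- function(tx) sum(IRanges::width(tx$exons))

#' Gene model
#'
#' Groups one or more [transcript_model]s of the same gene; the gene span
#' is the min-start/max-end envelope over all transcript exons and is used
#' only for coarse candidate-pair pruning, never for overlap counting.
#'
#' @param gene_id,gene_name Identifier strings.
#' @param biotype Gene biotype label.
#' @param chrom Chromosome / contig name.
#' @param strand `"+"` or `"-"`; all transcripts must agree.
#' @param transcripts List of [transcript_model]s.
#' @return An object of class `gene_model`.
#' @export
gene_model <- function(gene_id, gene_name, biotype, chrom, strand, transcripts) {
  stopifnot(length(transcripts) >= 1L)
  st <- vapply(transcripts, `[[`, "", "strand")
  if (length(unique(st)) != 1L) stopf("gene %s: transcripts on mixed strands", gene_id)
  sp <- range(unlist(lapply(transcripts, function(t)
    c(IRanges::start(t$exons), IRanges::end(t$exons)))))
  structure(list(
    gene_id = gene_id, gene_name = gene_name, biotype = biotype,
    chrom = chrom, strand = strand,
    transcripts = stats::setNames(transcripts, vapply(transcripts, `[[`, "", "transcript_id")),
    span = IRanges::IRanges(sp[1L], sp[2L])
  ), class = "gene_model")
}

#' Assemble an annotation set from gene models
#'
#' @param genes List of `gene_model` objects.
#' @param lncrna_biotypes Character vector of biotype labels flagged as lncRNA.
#' @return An `annotation_set`: genes indexed by `gene_id`, a
#'   transcript-to-gene map, and the lncRNA biotype configuration.
#' @export
annotation_set <- function(genes, lncrna_biotypes = c("lncRNA", "antisense", "lincRNA")) {
  genes <- stats::setNames(genes, vapply(genes, `[[`, "", "gene_id"))
  tx2gene <- unlist(lapply(genes, function(g)
    stats::setNames(rep(g$gene_id, length(g$transcripts)), names(g$transcripts))))
  structure(list(genes = genes, tx2gene = tx2gene,
                 lncrna_biotypes = lncrna_biotypes),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  bt <- vapply(x$genes, `[[`, "", "biotype")
  cat(sprintf("<annotation_set> %d gene(s) (%d lncRNA-flagged), %d transcript(s)\n",
              length(x$genes), sum(bt %in% x$lncrna_biotypes), length(x$tx2gene)))
  invisible(x)
}

#' Is a gene flagged as lncRNA?
#' @param ann An `annotation_set`.
#' @param gene_id Gene identifier(s).
#' @return Logical vector.
#' @export
is_lncrna <- function(ann, gene_id) {
  vapply(gene_id, function(g) {
    gm <- ann$genes[[g]]
    !is.null(gm) && gm$biotype %in% ann$lncrna_biotypes
  }, logical(1L))
}

gtf_attr <- function(attrs, key) {
  m <- regmatches(attrs, regexec(paste0(key, '\\s+"([^"]*)"'), attrs))
  vapply(m, function(x) if (length(x) == 2L) x[[2L]] else NA_character_, "")
}

#' Read a GENCODE-dialect GTF into an annotation set
#'
#' Parses `gene`/`transcript`/`exon`/`CDS`/`start_codon` records into
#' [transcript_model]s grouped by gene. GTF coordinates are 1-based closed
#' and are kept as such internally. The biotype is looked up under
#' `gene_type` then `gene_biotype` (configurable); gene records lacking a
#' biotype attribute are skipped with a warning.
#'
#' @param path Path to a GTF file.
#' @param lncrna_biotypes Biotype labels to flag as lncRNA. The default
#'   spans GENCODE versions, where older releases used `antisense` /
#'   `lincRNA` before these were folded into `lncRNA`.
#' @param biotype_keys Attribute keys probed, in order, for the biotype.
#' @return An [annotation_set].
#' @export
read_gtf <- function(path, lncrna_biotypes = c("lncRNA", "antisense", "lincRNA"),
                     biotype_keys = c("gene_type", "gene_biotype")) {
  lines <- readLines(path)
  keepln <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (!length(keepln))
    return(annotation_set(list(), lncrna_biotypes))
  fields <- strsplit(lines[keepln], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 9L))
    stopf("malformed GTF line %d: expected 9 tab-separated fields, found %d",
          keepln[which(nf != 9L)[1L]], nf[nf != 9L][1L])
  tab <- data.table::data.table(
    line = keepln,
    chrom = vapply(fields, `[[`, "", 1L),
    feature = vapply(fields, `[[`, "", 3L),
    start = suppressWarnings(as.integer(vapply(fields, `[[`, "", 4L))),
    end = suppressWarnings(as.integer(vapply(fields, `[[`, "", 5L))),
    strand = vapply(fields, `[[`, "", 7L),
    attrs = vapply(fields, `[[`, "", 9L)
  )
  bad <- which(is.na(tab$start) | is.na(tab$end) | tab$start > tab$end)
  if (length(bad))
    stopf("malformed GTF line %d: invalid start/end", tab$line[bad[1L]])
  tab <- tab[tab$feature %in% c("gene", "transcript", "exon", "CDS", "start_codon"), ]
  tab$gene_id <- gtf_attr(tab$attrs, "gene_id")
  tab$transcript_id <- gtf_attr(tab$attrs, "transcript_id")
  tab$gene_name <- gtf_attr(tab$attrs, "gene_name")
  tab$biotype <- NA_character_
  for (k in biotype_keys) {
    v <- gtf_attr(tab$attrs, k)
    tab$biotype <- ifelse(is.na(tab$biotype), v, tab$biotype)
  }
  bad <- which(is.na(tab$gene_id))
  if (length(bad))
    stopf("malformed GTF line %d: missing gene_id attribute", tab$line[bad[1L]])

  nob <- tab$feature == "gene" & is.na(tab$biotype)
  if (any(nob)) {
    warnf("skipped %d gene record(s) with no %s attribute (first at line %d)",
          sum(nob), paste(biotype_keys, collapse = "/"), tab$line[which(nob)[1L]])
    drop_genes <- tab$gene_id[nob]
    tab <- tab[!tab$gene_id %in% drop_genes, ]
  }

  genes <- list()
  for (gid in unique(tab$gene_id)) {
    gt <- tab[tab$gene_id == gid, ]
    grec <- gt[gt$feature == "gene", ]
    gname <- if (nrow(grec) && !is.na(grec$gene_name[1L])) grec$gene_name[1L] else
      (gt$gene_name[!is.na(gt$gene_name)][1L] %||% gid)
    if (is.na(gname)) gname <- gid
    gbio <- if (nrow(grec)) grec$biotype[1L] else gt$biotype[!is.na(gt$biotype)][1L]
    if (is.na(gbio)) {
      warnf("gene %s: no biotype attribute on any record; gene skipped", gid)
      next
    }
    txs <- list()
    for (tid in unique(gt$transcript_id[!is.na(gt$transcript_id)])) {
      tt <- gt[!is.na(gt$transcript_id) & gt$transcript_id == tid, ]
      ex <- tt[tt$feature == "exon", ]
      if (!nrow(ex)) next
      mkir <- function(d) if (nrow(d)) IRanges::IRanges(d$start, d$end) else NULL
      txs[[tid]] <- transcript_model(
        transcript_id = tid, gene_id = gid, gene_name = gname, biotype = gbio,
        chrom = ex$chrom[1L], strand = ex$strand[1L],
        exons = IRanges::IRanges(ex$start, ex$end),
        cds = mkir(tt[tt$feature == "CDS", ]),
        start_codon = mkir(tt[tt$feature == "start_codon", ])
      )
    }
    if (!length(txs)) next
    genes[[gid]] <- gene_model(gid, gname, gbio, txs[[1L]]$chrom, txs[[1L]]$strand, txs)
  }
  annotation_set(unname(genes), lncrna_biotypes)
}

#' Write an annotation set back to GTF
#'
#' Emits `gene`/`transcript`/`exon`/`CDS`/`start_codon` records with 1-based
#' closed coordinates, so a parse/emit cycle preserves all coordinates
#' exactly.
#'
#' @param ann An [annotation_set].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  out <- character(0L)
  line <- function(chrom, feat, s, e, strand, attrs)
    sprintf("%s\tsineupscreen\t%s\t%d\t%d\t.\t%s\t.\t%s", chrom, feat, s, e, strand, attrs)
  for (g in ann$genes) {
    gattr <- sprintf('gene_id "%s"; gene_name "%s"; gene_type "%s";',
                     g$gene_id, g$gene_name, g$biotype)
    out <- c(out, line(g$chrom, "gene", IRanges::start(g$span), IRanges::end(g$span),
                       g$strand, gattr))
    for (tx in g$transcripts) {
      tattr <- sprintf('%s transcript_id "%s";', gattr, tx$transcript_id)
      out <- c(out, line(tx$chrom, "transcript", min(IRanges::start(tx$exons)),
                         max(IRanges::end(tx$exons)), tx$strand, tattr))
      emit <- function(feat, ir) vapply(seq_along(ir), function(i)
        line(tx$chrom, feat, IRanges::start(ir)[i], IRanges::end(ir)[i], tx$strand, tattr), "")
      out <- c(out, emit("exon", tx$exons), emit("CDS", tx$cds),
               emit("start_codon", tx$start_codon))
    }
  }
  writeLines(out, path)
  invisible(path)
}

#' Start-codon interval(s) of a coding transcript
#'
#' Returns the annotated start codon when present; otherwise derives it as
#' the three 5'-most CDS bases in transcript orientation (on the minus
#' strand the codon sits at the maximum-end side of the CDS). Split codons
#' across introns are handled.
#'
#' @param tx A `transcript_model`.
#' @return [IRanges::IRanges] totalling exactly 3 nt.
#' @export
start_codon_intervals <- function(tx) {
  if (length(tx$start_codon)) return(tx$start_codon)
  if (!length(tx$cds)) stopf("non-coding transcript %s: no start_codon and no CDS", tx$transcript_id)
  cds <- sort(tx$cds)
  need <- 3L
  parts <- list()
  if (tx$strand == "+") {
    for (i in seq_along(cds)) {
      k <- min(need, IRanges::width(cds)[i])
      parts[[length(parts) + 1L]] <-
        IRanges::IRanges(IRanges::start(cds)[i], IRanges::start(cds)[i] + k - 1L)
      need <- need - k
      if (need == 0L) break
    }
  } else {
    for (i in rev(seq_along(cds))) {
      k <- min(need, IRanges::width(cds)[i])
      parts[[length(parts) + 1L]] <-
        IRanges::IRanges(IRanges::end(cds)[i] - k + 1L, IRanges::end(cds)[i])
      need <- need - k
      if (need == 0L) break
    }
  }
  if (need > 0L) stopf("transcript %s: CDS shorter than 3 nt", tx$transcript_id)
  sort(do.call(c, parts))
}

#' Per-base exonic intersection of two transcripts
#'
#' @param txA,txB `transcript_model` objects. If they sit on different
#'   chromosomes the intersection is empty.
#' @return List with `intervals` (merged maximal runs, [IRanges::IRanges])
#'   and `total_nt` (integer). Symmetric in its arguments.
#' @export
exonic_intersection <- function(txA, txB) {
  if (txA$chrom != txB$chrom)
    return(list(intervals = IRanges::IRanges(), total_nt = 0L))
  iv <- IRanges::intersect(IRanges::reduce(txA$exons), IRanges::reduce(txB$exons))
  list(intervals = iv, total_nt = sum(IRanges::width(iv)))
}

#' Spliced (mature) transcript sequence
#'
#' Concatenates exon sequences 5' to 3' in transcript orientation; minus
#' strand output is reverse-complemented.
#'
#' @param tx A `transcript_model`.
#' @param genome A [Biostrings::DNAStringSet] (names = contig names) or a
#'   path to a FASTA file.
#' @return Character scalar of length `transcript_length(tx)`.
#' @export
spliced_sequence <- function(tx, genome) {
  if (is.character(genome) && length(genome) == 1L)
    genome <- Biostrings::readDNAStringSet(genome)
  names(genome) <- sub("\\s.*$", "", names(genome))
  if (!tx$chrom %in% names(genome))
    stopf("contig '%s' not found in genome", tx$chrom)
  contig <- genome[[tx$chrom]]
  if (max(IRanges::end(tx$exons)) > length(contig))
    stopf("transcript %s: exon beyond end of contig '%s'", tx$transcript_id, tx$chrom)
  pieces <- Biostrings::extractAt(contig, tx$exons)
  s <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (tx$strand == "-") s <- Biostrings::reverseComplement(s)
  as.character(s)
}
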