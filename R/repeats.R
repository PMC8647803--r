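#' Accepted SINEUP effector-domain repeat families
#'
#' Default `"class/family"` labels accepted as effector-domain candidates:
#' SINE/Alu (which includes the FLAM/FRAM monomer names), SINE/MIR, and the
#' murine SINE/B2 and SINE/B4 families, covering both the human candidates
#' and the mouse SINEB2-bearing analog.
#'
#' @return Character vector of `"class/family"` labels.
#' @export
sineup_te_families <- function() c("SINE/Alu", "SINE/MIR", "SINE/B2", "SINE/B4")

.rm_header <- c(
  "   SW   perc perc perc  query      position in query              matching       repeat              position in repeat",
  "score   div. del. ins.  sequence   begin end          (left)   repeat         class/family      begin  end    (left)     ID",
  "")

#' Read a RepeatMasker .out annotation
#'
#' Standard 15-column layout: three header lines followed by
#' whitespace-delimited records. The strand column uses `+` or `C`
#' (complement); `C` is mapped to `-`. `class/family` is split on `/`;
#' single-token classes get `repeat_family == repeat_class`.
#'
#' @param path Path to a RepeatMasker `.out` file (or a UCSC rmsk-style TSV
#'   when `dialect = "rmsk"`, whose `genoStart` is 0-based and is converted).
#' @param dialect `"out"` (default) or `"rmsk"`.
#' @return A `data.table` of repeat hits with columns `chrom`, `start`,
#'   `end` (1-based closed), `strand`, `repeat_name`, `repeat_class`,
#'   `repeat_family`, `sw_score`, `divergence_pct` plus the remaining .out
#'   fields for lossless re-emission.
#' @export
read_repeatmasker <- function(path, dialect = c("out", "rmsk")) {
  dialect <- match.arg(dialect)
  if (dialect == "rmsk") {
    d <- data.table::fread(path)
    return(data.table::data.table(
      chrom = d$genoName, start = d$genoStart + 1L, end = d$genoEnd,
      strand = ifelse(d$strand == "C", "-", d$strand),
      repeat_name = d$repName, repeat_class = d$repClass,
      repeat_family = ifelse(is.na(d$repFamily) | d$repFamily == "",
                             d$repClass, d$repFamily),
      sw_score = as.numeric(d$swScore), divergence_pct = d$milliDiv / 10,
      pct_del = 0, pct_ins = 0, qleft = "(0)",
      rep_begin = "1", rep_end = "1", rep_left = "(0)",
      id = as.character(seq_len(nrow(d)))))
  }
  lines <- readLines(path)
  if (length(lines) < 3L) stopf("RepeatMasker file '%s' is missing its 3 header lines", path)
  body <- lines[-(1:3)]
  keep <- which(nzchar(trimws(body)))
  if (!length(keep)) return(.empty_repeat_table())
  fields <- strsplit(trimws(body[keep]), "\\s+")
  nf <- lengths(fields)
  if (any(nf < 14L))
    stopf("truncated RepeatMasker record at line %d: %d field(s)",
          keep[which(nf < 14L)[1L]] + 3L, nf[nf < 14L][1L])
  f <- function(i) vapply(fields, function(x) if (i <= length(x)) x[[i]] else "", "")
  cf <- f(11L)
  parts <- strsplit(cf, "/", fixed = TRUE)
  strand_raw <- f(9L)
  if (!all(strand_raw %in% c("+", "C")))
    stopf("unexpected strand symbol '%s' (expected '+' or 'C')",
          setdiff(strand_raw, c("+", "C"))[1L])
  data.table::data.table(
    chrom = f(5L),
    start = as.integer(f(6L)),
    end = as.integer(f(7L)),
    strand = ifelse(strand_raw == "C", "-", "+"),
    repeat_name = f(10L),
    repeat_class = vapply(parts, `[[`, "", 1L),
    repeat_family = vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else p[[1L]], ""),
    sw_score = as.numeric(f(1L)),
    divergence_pct = as.numeric(f(2L)),
    pct_del = as.numeric(f(3L)),
    pct_ins = as.numeric(f(4L)),
    qleft = f(8L),
    rep_begin = f(12L),
    rep_end = f(13L),
    rep_left = f(14L),
    id = f(15L)
  )
}

.empty_repeat_table <- function() {
  data.table::data.table(
    chrom = character(), start = integer(), end = integer(), strand = character(),
    repeat_name = character(), repeat_class = character(), repeat_family = character(),
    sw_score = numeric(), divergence_pct = numeric(), pct_del = numeric(),
    pct_ins = numeric(), qleft = character(), rep_begin = character(),
    rep_end = character(), rep_left = character(), id = character())
}

#' Write repeat hits as a RepeatMasker .out file
#'
#' Emits the 3-line header and 15-column records; [read_repeatmasker] on the
#' result reproduces the input table.
#'
#' @param hits A repeat-hit `data.table` as returned by [read_repeatmasker].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_repeatmasker <- function(hits, path) {
  recs <- vapply(seq_len(nrow(hits)), function(i) {
    h <- hits[i, ]
    cf <- if (h$repeat_class == h$repeat_family) h$repeat_class else
      paste0(h$repeat_class, "/", h$repeat_family)
    sprintf("%6.0f %5.1f %4.1f %4.1f  %s %d %d %s %s %s %s %s %s %s %s",
            h$sw_score, h$divergence_pct, h$pct_del, h$pct_ins,
            h$chrom, h$start, h$end, h$qleft,
            if (h$strand == "-") "C" else "+",
            h$repeat_name, cf, h$rep_begin, h$rep_end, h$rep_left, h$id)
  }, "")
  writeLines(c(.rm_header, recs), path)
  invisible(path)
}

#' Embedded transposable elements in a transcript's mature RNA
#'
#' Retains repeat hits of accepted families whose overlap with the
#' transcript's exons is at least `min_exonic_nt`, and annotates each with
#' its exonic overlap, exonic fraction and inversion status. A hit is
#' *inverted* when its consensus strand differs from the transcript strand
#' (the SINEUP-literature convention for an "inverted SINEB2"); purely
#' intronic hits are excluded because the effector domain acts in the
#' mature RNA.
#'
#' @param tx A `transcript_model`.
#' @param hits Repeat-hit table from [read_repeatmasker].
#' @param families Accepted `"class/family"` labels (see
#'   [sineup_te_families]).
#' @param min_exonic_nt Minimum exonic overlap in nt (default 1).
#' @return `data.table` of embedded TEs sorted by genomic start, with
#'   added columns `transcript_id`, `exonic_overlap_nt`, `exonic_fraction`,
#'   `inverted`.
#' @export
exonic_te_hits <- function(tx, hits, families = sineup_te_families(),
                           min_exonic_nt = 1L) {
  h <- hits[hits$chrom == tx$chrom &
              paste0(hits$repeat_class, "/", hits$repeat_family) %in% families, ]
  if (!nrow(h)) return(cbind(h, data.table::data.table(
    transcript_id = character(), exonic_overlap_nt = integer(),
    exonic_fraction = numeric(), inverted = logical())))
  ex <- IRanges::reduce(tx$exons)
  ov <- vapply(seq_len(nrow(h)), function(i)
    sum(IRanges::width(IRanges::intersect(IRanges::IRanges(h$start[i], h$end[i]), ex))),
    integer(1L))
  h$transcript_id <- tx$transcript_id
  h$exonic_overlap_nt <- ov
  h$exonic_fraction <- ov / (h$end - h$start + 1L)
  h$inverted <- h$strand != tx$strand
  h <- h[h$exonic_overlap_nt >= min_exonic_nt, ]
  h[order(h$start, h$end, h$repeat_name), ]
}
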