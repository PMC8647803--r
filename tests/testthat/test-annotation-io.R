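make_gtf <- function(lines) {
  path <- tempfile(fileext = ".gtf")
  writeLines(lines, path)
  path
}

two_gene_gtf <- function() make_gtf(c(
  "#!genome-build test",
  paste0("chr1\tx\tgene\t101\t200\t.\t+\t.\t",
         'gene_id "G1"; gene_name "LNC1"; gene_type "lncRNA";'),
  paste0("chr1\tx\texon\t101\t200\t.\t+\t.\t",
         'gene_id "G1"; transcript_id "G1_T1"; gene_type "lncRNA";'),
  paste0("chr1\tx\tgene\t301\t500\t.\t-\t.\t",
         'gene_id "G2"; gene_name "PC1"; gene_type "protein_coding";'),
  paste0("chr1\tx\texon\t301\t500\t.\t-\t.\t",
         'gene_id "G2"; transcript_id "G2_T1"; gene_type "protein_coding";'),
  paste0("chr1\tx\tCDS\t351\t450\t.\t-\t.\t",
         'gene_id "G2"; transcript_id "G2_T1"; gene_type "protein_coding";')))

test_that("GTF records parse to 1-based closed intervals with correct lengths and biotype flags", {
  ann <- read_gtf(two_gene_gtf())
  expect_length(ann$genes, 2L)
  tx <- ann$genes[["G1"]]$transcripts[["G1_T1"]]
  expect_equal(IRanges::start(tx$exons), 101L)
  expect_equal(IRanges::end(tx$exons), 200L)
  expect_equal(transcript_length(tx), 100L)   # GTF start=101,end=200 spans 100 nt
  expect_equal(unname(is_lncrna(ann, c("G1", "G2"))), c(TRUE, FALSE))
})

test_that("header-only GTF yields an empty annotation set", {
  ann <- read_gtf(make_gtf(c("# only", "#! comments")))
  expect_length(ann$genes, 0L)
})

test_that("malformed GTF lines are rejected with their line number", {
  p <- make_gtf(c("# header", "chr1\tx\texon\t1\t10"))
  expect_error(read_gtf(p), "line 2")
  p2 <- make_gtf(c(paste0("chr1\tx\texon\tzzz\t10\t.\t+\t.\t",
                          'gene_id "G"; gene_type "lncRNA"; transcript_id "T";')))
  expect_error(read_gtf(p2), "line 1")
})

test_that("gene records without a biotype attribute are skipped with a warning", {
  p <- make_gtf(c(
    'chr1\tx\tgene\t1\t50\t.\t+\t.\tgene_id "G0";',
    'chr1\tx\texon\t1\t50\t.\t+\t.\tgene_id "G0"; transcript_id "G0_T1";',
    paste0("chr1\tx\texon\t101\t200\t.\t+\t.\t",
           'gene_id "G1"; transcript_id "G1_T1"; gene_biotype "lncRNA";')))
  expect_warning(ann <- read_gtf(p), "biotype")
  expect_named(ann$genes, "G1")
  expect_equal(ann$genes[["G1"]]$biotype, "lncRNA")  # gene_biotype key accepted
})

test_that("parse/emit round trip preserves all coordinates exactly", {
  fx <- simulate_screen_fixture(n_planted = 2, decoys = c("no_TIS_overlap", "TE_intronic"),
                                seed = 11)
  p1 <- tempfile(fileext = ".gtf")
  write_gtf(fx$ann, p1)
  ann2 <- read_gtf(p1)
  expect_setequal(names(ann2$genes), names(fx$ann$genes))
  for (gid in names(fx$ann$genes)) {
    g1 <- fx$ann$genes[[gid]]; g2 <- ann2$genes[[gid]]
    for (tid in names(g1$transcripts)) {
      t1 <- g1$transcripts[[tid]]; t2 <- g2$transcripts[[tid]]
      for (slot in c("exons", "cds", "start_codon")) {
        expect_identical(IRanges::start(t1[[slot]]), IRanges::start(t2[[slot]]))
        expect_identical(IRanges::end(t1[[slot]]), IRanges::end(t2[[slot]]))
      }
      expect_identical(t1$strand, t2$strand)
    }
  }
})

test_that("start codon is the annotated codon or the 5'-most three CDS bases, on either strand", {
  mk <- function(strand, cds) transcript_model("T", "G", "G", "protein_coding",
                                               "chr1", strand,
                                               exons = IRanges::IRanges(1, 1000), cds = cds)
  sc <- start_codon_intervals(mk("+", IRanges::IRanges(101, 200)))
  expect_equal(c(IRanges::start(sc), IRanges::end(sc)), c(101L, 103L))
  sc <- start_codon_intervals(mk("-", IRanges::IRanges(101, 200)))
  expect_equal(c(IRanges::start(sc), IRanges::end(sc)), c(198L, 200L))
  # codon split across a splice junction: 2 bases in the first piece, 1 in the next
  sc <- start_codon_intervals(mk("+", IRanges::IRanges(c(101, 201), c(102, 300))))
  expect_equal(IRanges::start(sc), c(101L, 201L))
  expect_equal(IRanges::end(sc), c(102L, 201L))
  expect_equal(sum(IRanges::width(sc)), 3L)
})

test_that("derived start codons always total 3 nt over random CDS structures", {
  set.seed(42)
  for (i in 1:50) {
    strand <- sample(c("+", "-"), 1)
    n <- sample(1:3, 1)
    starts <- sort(sample(seq(1, 500, by = 30), n))
    cds <- IRanges::IRanges(starts, width = sample(2:25, n, replace = TRUE))
    tx <- transcript_model("T", "G", "G", "protein_coding", "chr1", strand,
                           exons = IRanges::IRanges(1, 1000), cds = cds)
    if (sum(IRanges::width(cds)) < 3) {
      expect_error(start_codon_intervals(tx), "shorter")
    } else {
      sc <- start_codon_intervals(tx)
      expect_equal(sum(IRanges::width(sc)), 3L)
      expect_true(all(ir_bases(sc) %in% ir_bases(cds)))
      # codon sits at the 5' extremity in transcript orientation
      if (strand == "+") expect_equal(min(ir_bases(sc)), min(ir_bases(cds)))
      else expect_equal(max(ir_bases(sc)), max(ir_bases(cds)))
    }
  }
})

test_that("start_codon_intervals rejects non-coding transcripts", {
  tx <- transcript_model("T", "G", "G", "lncRNA", "chr1", "+",
                         exons = IRanges::IRanges(1, 100))
  expect_error(start_codon_intervals(tx), "non-coding")
})

test_that("exonic intersection matches the per-base oracle and is symmetric", {
  mk <- function(strand, starts, ends, chrom = "chr1")
    transcript_model(paste0("T", sample(1e6, 1)), "G", "G", "lncRNA", chrom, strand,
                     exons = IRanges::IRanges(starts, ends))
  a <- mk("+", 1, 100); b <- mk("-", 51, 150)
  r <- exonic_intersection(a, b)
  expect_equal(r$total_nt, 50L)
  expect_equal(c(IRanges::start(r$intervals), IRanges::end(r$intervals)), c(51L, 100L))
  expect_equal(exonic_intersection(mk("+", 1, 100), mk("-", 201, 300))$total_nt, 0L)
  r <- exonic_intersection(mk("+", c(1, 81), c(60, 120)), mk("-", 51, 100))
  expect_equal(r$total_nt, 30L)
  expect_equal(IRanges::start(r$intervals), c(51L, 81L))
  expect_equal(IRanges::end(r$intervals), c(60L, 100L))
  expect_equal(exonic_intersection(a, mk("+", 1, 10, chrom = "chr2"))$total_nt, 0L)
  set.seed(7)
  for (i in 1:25) {
    a <- random_transcript(); b <- random_transcript()
    ab <- exonic_intersection(a, b); ba <- exonic_intersection(b, a)
    expect_identical(ab$total_nt, ba$total_nt)
    expect_identical(ab$total_nt, oracle_exonic_overlap(a, b))
  }
})

test_that("spliced sequence concatenates exons 5' to 3' and reverse-complements the minus strand", {
  genome <- Biostrings::DNAStringSet(c(chrT = "AACCGGTT"))
  mk <- function(strand, starts, ends)
    transcript_model("T", "G", "G", "lncRNA", "chrT", strand,
                     exons = IRanges::IRanges(starts, ends))
  expect_equal(spliced_sequence(mk("+", 1, 4), genome), "AACC")
  expect_equal(spliced_sequence(mk("-", 1, 4), genome), "GGTT")
  # 2-exon minus-strand: exon slices AC (2-3) + GT (6-7) -> "ACGT" -> revcomp "ACGT"
  expect_equal(spliced_sequence(mk("-", c(2, 6), c(3, 7)), genome), "ACGT")
  # and a non-palindromic case worked by hand: AAC (1-3) + TT (7-8) -> "AACTT" -> "AAGTT"
  expect_equal(spliced_sequence(mk("-", c(1, 7), c(3, 8)), genome), "AAGTT")
  expect_error(spliced_sequence(
    transcript_model("T", "G", "G", "lncRNA", "chrX", "+",
                     exons = IRanges::IRanges(1, 4)), genome), "chrX")
  expect_error(spliced_sequence(mk("+", 1, 99), genome), "beyond")
})

test_that("spliced sequence length equals the exonic total for random transcripts", {
  set.seed(3)
  genome <- Biostrings::DNAStringSet(stats::setNames(
    paste(sample(c("A", "C", "G", "T"), 1000, replace = TRUE), collapse = ""), "chrT"))
  for (i in 1:10) {
    tx <- random_transcript()
    expect_equal(nchar(spliced_sequence(tx, genome)), transcript_length(tx))
  }
})
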