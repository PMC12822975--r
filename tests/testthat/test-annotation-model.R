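gtf_line <- function(chrom, feat, start, end, strand, frame, attrs) {
  paste(chrom, "src", feat, start, end, ".", strand, frame, attrs,
        sep = "\t")
}

test_that("a minimal one-CDS GTF document parses into a single transcript", {
  txs <- parse_gtf(gtf_line("chr1", "CDS", 101, 160, "+", 0,
                            'gene_id "g1"; transcript_id "t1";'), "gtf")
  expect_length(txs, 1L)
  t1 <- txs[["t1"]]
  expect_equal(t1$cds_blocks, data.frame(start = 101L, end = 160L))
  expect_equal(t1$phases, 0L)
  expect_equal(t1$gene_id, "g1")
  expect_true(is.na(t1$stop_included))
})

test_that("minus-strand CDS features are stored in translation order", {
  lines <- c(
    gtf_line("chr1", "CDS", 300, 380, "-", 0,
             'gene_id "g"; transcript_id "t";'),
    gtf_line("chr1", "CDS", 500, 560, "-", 0,
             'gene_id "g"; transcript_id "t";'))
  t1 <- parse_gtf(lines, "gtf")[["t"]]
  ## translation order on '-' is descending genomic coordinate
  expect_equal(t1$cds_blocks$start, c(500L, 300L))
  expect_equal(t1$cds_blocks$end, c(560L, 380L))
})

test_that("malformed documents raise parse errors naming the line", {
  expect_error(parse_gtf("chr1\tsrc\tCDS\t1\t60\t.\t+", "gtf"),
               "line 1.*columns")
  lines <- c(gtf_line("chr1", "CDS", 101, 160, "+", 0,
                      'gene_id "g"; transcript_id "t";'),
             gtf_line("chr1", "CDS", "ten", 160, "+", 0,
                      'gene_id "g"; transcript_id "t";'))
  expect_error(parse_gtf(lines, "gtf"), "line 2.*non-numeric")
  expect_error(parse_gtf(gtf_line("chr1", "CDS", 200, 100, "+", 0,
                                  'gene_id "g"; transcript_id "t";'), "gtf"),
               "end < start")
  expect_error(parse_gtf(gtf_line("chr1", "CDS", 1, 60, "+", 0,
                                  'gene_id "g";'), "gtf"),
               "transcript_id")
  expect_error(parse_gtf("chr1\tsrc\tCDS\t1\t60\t.\t+\t0\tID=x", "gff3"),
               "Parent")
})

test_that("write/parse round-trips transcripts in both dialects and both stop dialects", {
  for (dialect in c("gtf", "gff3")) {
    for (stop_inc in list(TRUE, FALSE, NA)) {
      for (strand in c("+", "-")) {
        tx <- annotated_transcript(
          "t1", "g1", "chr3", strand,
          data.frame(start = c(1000L, 2000L, 3000L),
                     end = c(1090L, 2063L, 3100L)),
          stop_included = stop_inc)
        back <- parse_gtf(write_gtf(tx, dialect), dialect)[["t1"]]
        expect_equal(back, tx)
      }
    }
  }
})

test_that("write/parse round-trips predictions including the sec_codon attribute", {
  for (dialect in c("gtf", "gff3")) {
    for (seed in 1:10) {
      p <- random_sec_prediction(seed)
      p$protein_seq <- NA_character_  # the FASTA is a separate channel
      back <- parse_gtf(write_gtf(p, dialect), dialect)[[p$prediction_id]]
      expect_s3_class(back, "sec_prediction")
      expect_equal(back$cds_blocks, p$cds_blocks)
      expect_equal(back$sec_codon, p$sec_codon)
      expect_equal(back$sec_protein_index, p$sec_protein_index)
      expect_equal(back$family, p$family)
      ## features come out in ascending genomic order regardless of strand
      starts <- as.integer(vapply(strsplit(write_gtf(p, dialect), "\t"),
                                  `[`, "", 4L))
      expect_equal(starts, sort(starts))
    }
  }
})

test_that("an empty collection writes an empty document", {
  expect_length(write_gtf(list(), "gtf"), 0L)
  expect_length(parse_gtf(character(0), "gtf"), 0L)
})

test_that("frame_at matches simple arithmetic on a single-exon transcript", {
  t1 <- annotated_transcript("t", "g", "chr1", "+",
                             data.frame(start = 101L, end = 160L))
  expect_equal(frame_at(t1, 101), 0L)
  expect_equal(frame_at(t1, 105), 1L)
  expect_error(frame_at(t1, 99), "not coding")
})

test_that("frame_at honours a non-zero first-block phase", {
  t1 <- annotated_transcript("t", "g", "chr1", "+",
                             data.frame(start = 101L, end = 160L),
                             phases = 2L)
  expect_equal(frame_at(t1, 103), 0L)
  expect_equal(frame_at(t1, 101), (0L - 2L) %% 3L)
})

test_that("frame_at equals the spliced-concatenation oracle on random transcripts", {
  set.seed(42)
  for (seed in 1:200) {
    p <- random_sec_prediction(seed)
    pos <- sample(cds_positions(p), 5L)
    expect_equal(frame_at(p, pos), frame_oracle(p, pos))
  }
})

test_that("sec_codon_span does plain arithmetic on a single plus-strand exon", {
  p <- sec_prediction("p", "GPX", "chr1", "+",
                      data.frame(start = 101L, end = 160L),
                      sec_protein_index = 2L)
  expect_equal(p$sec_codon, c(104L, 105L, 106L))
  expect_equal(sec_codon_span(p), c(104L, 105L, 106L))
})

test_that("sec_codon_span reverses on the minus strand", {
  p <- sec_prediction("p", "GPX", "chr1", "-",
                      data.frame(start = 300L, end = 380L),
                      sec_protein_index = 1L)
  expect_equal(p$sec_codon, c(380L, 379L, 378L))
})

test_that("a codon split 2|1 across blocks ends in the second block", {
  p <- sec_prediction("p", "GPX", "chr1", "+",
                      data.frame(start = c(101L, 201L),
                                 end = c(110L, 210L)),
                      sec_protein_index = 4L)
  ## transcript positions 10,11,12 -> genomic 110 | 201,202
  expect_equal(p$sec_codon, c(110L, 201L, 202L))
  expect_equal(p$sec_codon, cds_positions(p)[10:12])
})

test_that("sec_codon_span rejects out-of-range codon indices", {
  p <- sec_prediction("p", "GPX", "chr1", "+",
                      data.frame(start = 101L, end = 160L),
                      sec_protein_index = 2L)
  expect_error(sec_codon_span(p, 21L), "beyond coding length")
})

test_that("sec_codon_span is 3-long and strictly monotone in transcript coordinates", {
  for (seed in 1:100) {
    p <- random_sec_prediction(seed)
    span <- sec_codon_span(p)
    expect_length(span, 3L)
    tp <- match(span, cds_positions(p))
    expect_equal(diff(tp), c(1L, 1L))
  }
})
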