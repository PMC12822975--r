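mkpred <- function(blocks, strand = "+", chrom = "chr1", sec = 2L,
                   id = "p1", family = "GPX") {
  sec_prediction(id, family, chrom, strand, blocks, sec_protein_index = sec)
}
mktx <- function(blocks, strand = "+", chrom = "chr1", id = "t1",
                 stop_included = NA, phases = NULL) {
  annotated_transcript(id, "g1", chrom, strand, blocks,
                       phases = phases, stop_included = stop_included)
}

test_that("overlapping same-strand pairs match; opposite strands never do", {
  p <- mkpred(data.frame(start = 101L, end = 160L))
  t_same <- mktx(data.frame(start = 150L, end = 220L), "+")
  t_opp <- mktx(data.frame(start = 150L, end = 220L), "-")
  expect_equal(nrow(match_overlaps(list(p), list(t_same))), 1L)
  expect_equal(nrow(match_overlaps(list(p), list(t_opp))), 0L)
})

test_that("match_overlaps equals the brute-force quadratic oracle on random fixtures", {
  set.seed(7)
  cases <- lapply(1:100, function(s)
    make_assessment_case(sample(c(transcript_status_levels(), "ABSENT"), 1),
                         s))
  preds <- lapply(cases, `[[`, "prediction")
  txs <- lapply(cases, function(cc) cc$annotation[[1]])
  ## spread over a few chromosomes so cross-case overlaps are possible
  for (i in seq_along(preds)) {
    chrom <- paste0("chr", 1 + i %% 4)
    preds[[i]]$chrom <- chrom
    if (txs[[i]]$chrom == "chr1") txs[[i]]$chrom <- chrom
  }
  got <- match_overlaps(preds, txs)
  want <- overlap_oracle(preds, txs)
  want <- want[order(want$pred_idx, want$tx_idx), ]
  rownames(want) <- NULL
  expect_equal(got, want)
})

test_that("an annotation identical to the prediction is well annotated", {
  p <- mkpred(data.frame(start = c(101L, 300L), end = c(160L, 402L)))
  t1 <- mktx(p$cds_blocks)
  expect_equal(classify_pair(p, t1), "WELL_ANNOTATED")
})

test_that("a CDS ending one base before the Sec UGA is a stop-codon misannotation", {
  ## stop-excluded dialect: Sec codon at protein position 5 = bases 13-15
  p <- mkpred(data.frame(start = 101L, end = 160L), sec = 5L)
  expect_equal(p$sec_codon, c(113L, 114L, 115L))
  t1 <- mktx(data.frame(start = 101L, end = 112L), stop_included = FALSE)
  expect_equal(classify_pair(p, t1), "STOP_CODON")
  ## stop-included dialect: the final CDS codon occupies the Sec positions
  t2 <- mktx(data.frame(start = 101L, end = 115L), stop_included = TRUE)
  expect_equal(classify_pair(p, t2), "STOP_CODON")
})

test_that("keeping flanking exons but dropping the Sec exon is skipped", {
  p <- mkpred(data.frame(start = c(101L, 300L, 500L),
                         end = c(160L, 362L, 601L)), sec = 25L)
  ## Sec codon bases are transcript 73-75, inside the middle exon
  expect_true(all(p$sec_codon >= 300 & p$sec_codon <= 362))
  t1 <- mktx(data.frame(start = c(101L, 500L), end = c(160L, 601L)),
             phases = c(0L, 0L))
  expect_equal(classify_pair(p, t1), "SKIPPED")
})

test_that("a +1-shifted annotation with no in-frame overlap is out of frame", {
  p <- mkpred(data.frame(start = c(101L, 300L), end = c(160L, 402L)),
              sec = 10L)
  b <- p$cds_blocks
  b$start <- b$start + 1L
  b$end <- b$end + 1L
  expect_equal(classify_pair(p, mktx(b)), "OUT_OF_FRAME")
})

test_that("annotation only 5' or only 3' of the Sec codon is upstream/downstream", {
  p <- mkpred(data.frame(start = 101L, end = 160L), sec = 10L)
  expect_equal(classify_pair(p, mktx(data.frame(start = 101L, end = 121L))),
               "UPSTREAM")
  dn <- mktx(data.frame(start = 131L, end = 160L))
  expect_equal(classify_pair(p, dn), "DOWNSTREAM")
})

test_that("a splice site inside the Sec codon takes precedence over positional classes", {
  p <- mkpred(data.frame(start = 101L, end = 190L), sec = 10L)
  ## Sec codon = 128,129,130; intron opens right after base 128
  t1 <- mktx(data.frame(start = c(101L, 161L), end = c(128L, 190L)),
             phases = c(0L, 0L))
  expect_equal(classify_pair(p, t1), "SPLICED")
})

test_that("non-overlapping pairs are a contract violation", {
  p <- mkpred(data.frame(start = 101L, end = 160L))
  expect_error(classify_pair(p, mktx(data.frame(start = 500L, end = 600L))),
               "does not overlap")
})

test_that("gene status aggregates pairs with well-annotated dominance", {
  expect_equal(aggregate_gene_status(character(0)), "ABSENT")
  expect_equal(aggregate_gene_status(c("STOP_CODON", "WELL_ANNOTATED")),
               "WELL_ANNOTATED")
  expect_equal(aggregate_gene_status(c("UPSTREAM", "SKIPPED")),
               "MISANNOTATION")
})

test_that("summaries conserve counts and match the generator's label tally", {
  set.seed(11)
  labels <- sample(c(transcript_status_levels(), "ABSENT"), 200,
                   replace = TRUE)
  preds <- list(); txs <- list()
  for (i in seq_along(labels)) {
    case <- make_assessment_case(labels[i], 5000L + i)
    p <- case$prediction; t1 <- case$annotation[[1]]
    p$prediction_id <- sprintf("p%03d", i)
    t1$transcript_id <- sprintf("t%03d", i)
    p$chrom <- sprintf("chr%d", i)
    t1$chrom <- if (labels[i] == "ABSENT") sprintf("chr%d_alt", i)
                else sprintf("chr%d", i)
    preds[[i]] <- p; txs[[i]] <- t1
  }
  records <- assess(preds, txs)
  tab <- summarize_assessment(records, "transcript")
  expect_equal(sum(tab$count), length(labels))
  tally <- table(labels)
  for (st in names(tally))
    expect_equal(sum(tab$count[tab$status == st]), unname(tally[[st]]),
                 label = st)
  ## per-family percentages sum to 100
  for (f in unique(tab$family))
    expect_equal(sum(tab$percent[tab$family == f]), 100)
  gene <- summarize_assessment(records, "gene")
  expect_equal(sum(gene$count), length(labels))
  expect_equal(sum(gene$count[gene$status == "ABSENT"]),
               unname(tally[["ABSENT"]]))
})

test_that("assessment records are complete and order-independent", {
  set.seed(3)
  cases <- lapply(1:30, function(s)
    make_assessment_case(sample(c(transcript_status_levels(), "ABSENT"), 1),
                         300L + s))
  preds <- lapply(seq_along(cases), function(i) {
    p <- cases[[i]]$prediction
    p$prediction_id <- sprintf("p%02d", i); p$chrom <- sprintf("chr%d", i); p
  })
  txs <- lapply(seq_along(cases), function(i) {
    t1 <- cases[[i]]$annotation[[1]]
    t1$transcript_id <- sprintf("t%02d", i)
    if (t1$chrom == "chr1") t1$chrom <- sprintf("chr%d", i)
    else t1$chrom <- sprintf("chr%d_alt", i)
    t1
  })
  rec <- assess(preds, txs)
  expect_equal(sort(unique(rec$prediction_id)),
               sort(vapply(preds, `[[`, "", "prediction_id")))
  expect_true(all(table(rec$prediction_id[!duplicated(
    paste(rec$prediction_id, rec$gene_status))]) == 1L))
  perm <- sample(length(preds))
  rec2 <- assess(preds[perm], txs[rev(seq_along(txs))])
  key <- function(r) r[order(r$prediction_id, r$transcript_id), ]
  expect_equal(key(rec2)$transcript_status, key(rec)$transcript_status)
  expect_equal(key(rec2)$gene_status, key(rec)$gene_status)
})

test_that("reversing all transcript strands turns every pair into absent", {
  for (seed in 1:20) {
    case <- make_assessment_case("WELL_ANNOTATED", 800L + seed)
    t1 <- case$annotation[[1]]
    t1$strand <- if (t1$strand == "+") "-" else "+"
    t1$cds_blocks <- t1$cds_blocks[rev(seq_len(nrow(t1$cds_blocks))), ]
    rec <- assess(list(case$prediction), list(t1))
    expect_equal(rec$gene_status, "ABSENT")
  }
})
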