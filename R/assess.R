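## Annotation assessment: match Sec predictions to database transcripts by
## genomic CDS overlap (same chromosome AND same strand), classify each
## overlapping pair into the transcript-level status taxonomy, then
## aggregate to gene level.

#' Transcript- and gene-level status labels
#'
#' `transcript_status_levels()` returns the seven mutually exclusive
#' transcript-level classes; `gene_status_levels()` the three gene-level
#' classes.
#'
#' @return Character vector of labels.
#' @export
transcript_status_levels <- function() {
  c("WELL_ANNOTATED", "STOP_CODON", "UPSTREAM", "DOWNSTREAM",
    "SKIPPED", "OUT_OF_FRAME", "SPLICED")
}

#' @rdname transcript_status_levels
#' @export
gene_status_levels <- function() {
  c("WELL_ANNOTATED", "MISANNOTATION", "ABSENT")
}

.blocks_granges <- function(objs) {
  n <- vapply(objs, function(o) nrow(o$cds_blocks), 1L)
  GenomicRanges::GRanges(
    seqnames = rep(vapply(objs, `[[`, "", "chrom"), n),
    ranges = IRanges::IRanges(
      start = unlist(lapply(objs, function(o) pmin(o$cds_blocks$start,
                                                   o$cds_blocks$end))),
      end = unlist(lapply(objs, function(o) pmax(o$cds_blocks$start,
                                                 o$cds_blocks$end)))),
    strand = rep(vapply(objs, `[[`, "", "strand"), n),
    idx = rep(seq_along(objs), n))
}

#' Match predictions to database transcripts by CDS overlap
#'
#' Returns every (prediction, transcript) pair whose CDS blocks share at
#' least one base on the same chromosome and the same strand. Pairs on
#' opposite strands are never returned.
#'
#' @param predictions List of [sec_prediction()] objects.
#' @param transcripts List of [annotated_transcript()] objects.
#' @return Data frame with columns `pred_idx`, `tx_idx` (indices into the
#'   two input lists), one row per overlapping pair.
#' @export
match_overlaps <- function(predictions, transcripts) {
  if (length(predictions) == 0L || length(transcripts) == 0L)
    return(data.frame(pred_idx = integer(0), tx_idx = integer(0)))
  pg <- .blocks_granges(predictions)
  tg <- .blocks_granges(transcripts)
  ## disjoint seqlevels (a prediction on a chromosome with no annotation)
  ## are a legitimate input, not a worry
  hits <- suppressWarnings(
    GenomicRanges::findOverlaps(pg, tg, ignore.strand = FALSE))
  pairs <- unique(data.frame(
    pred_idx = pg$idx[S4Vectors::queryHits(hits)],
    tx_idx = tg$idx[S4Vectors::subjectHits(hits)]))
  pairs <- pairs[order(pairs$pred_idx, pairs$tx_idx), , drop = FALSE]
  rownames(pairs) <- NULL
  pairs
}

## Genomic positions coding in both structures (any frame).
.shared_coding <- function(pred, tx) {
  intersect(cds_positions(pred), cds_positions(tx))
}

## TRUE if tx has an intron boundary between genomic positions q and q+1,
## i.e. an exon ending at q with a later exon, or an exon starting at q+1
## with an earlier exon (sorted genomically).
.splices_between <- function(tx, q) {
  b <- tx$cds_blocks[order(tx$cds_blocks$start), , drop = FALSE]
  n <- nrow(b)
  if (n < 2L) return(FALSE)
  any(b$end[-n] == q) || any(b$start[-1L] == q + 1L)
}

#' Classify one overlapping (prediction, transcript) pair
#'
#' Assigns exactly one transcript-level status using a fixed precedence:
#' structural incompatibilities first (`OUT_OF_FRAME`, then `SPLICED`),
#' then `WELL_ANNOTATED`, then the positional misannotation classes
#' (`STOP_CODON`, `SKIPPED`, `UPSTREAM`/`DOWNSTREAM`).
#'
#' * `OUT_OF_FRAME` — no position of the CDS intersection is coding in the
#'   same frame in both structures.
#' * `SPLICED` — the transcript has an intron boundary strictly inside the
#'   Sec codon at a point where the prediction is contiguous.
#' * `WELL_ANNOTATED` — all 3 Sec codon positions are coding in the
#'   transcript, in matching frame, and the codon is not the transcript's
#'   terminal codon.
#' * `STOP_CODON` — the transcript's translation terminates at the Sec
#'   codon: its final codon occupies exactly the Sec positions
#'   (stop-included dialect), or its CDS ends at the base immediately 5' of
#'   the Sec codon so that the next in-frame codon is the Sec UGA
#'   (stop-excluded dialect).
#' * `SKIPPED` — in-frame coding positions exist both 5' and 3' of the Sec
#'   codon but the codon itself is not fully coding.
#' * `UPSTREAM` / `DOWNSTREAM` — the in-frame coding overlap lies only 5' /
#'   only 3' of the Sec codon.
#'
#' @param pred A [sec_prediction()].
#' @param tx An [annotated_transcript()] overlapping `pred` on the same
#'   strand.
#' @return A single status string (see [transcript_status_levels()]).
#' @export
classify_pair <- function(pred, tx) {
  shared <- .shared_coding(pred, tx)
  if (length(shared) == 0L)
    stop("classify_pair: pair does not overlap; use match_overlaps first")
  in_frame <- shared[frame_at(pred, shared) == frame_at(tx, shared)]
  if (length(in_frame) == 0L) return("OUT_OF_FRAME")

  span <- pred$sec_codon
  ## (2) spliced inside the Sec codon where the prediction is contiguous
  for (k in 1:2) {
    a <- span[k]; b <- span[k + 1L]
    if (abs(b - a) == 1L && .splices_between(tx, min(a, b)))
      return("SPLICED")
  }

  tx_pos <- cds_positions(tx)
  codon_coding <- all(span %in% tx_pos)
  codon_in_frame <- codon_coding &&
    all(frame_at(pred, span) == frame_at(tx, span))
  last3 <- if (length(tx_pos) >= 3L)
    tx_pos[(length(tx_pos) - 2L):length(tx_pos)] else integer(0)
  codon_is_terminal <- identical(sort(last3), sort(span))

  ## (3) well annotated
  if (codon_in_frame && !codon_is_terminal) return("WELL_ANNOTATED")

  ## (4) stop codon, either dialect
  if (codon_in_frame && codon_is_terminal) return("STOP_CODON")
  tx_end <- tx_pos[length(tx_pos)]
  ends_before <- if (pred$strand == "+") tx_end == span[1L] - 1L
                 else tx_end == span[1L] + 1L
  if (ends_before && !is.na(transcript_position(pred, tx_end)) &&
      frame_at(pred, tx_end) == frame_at(tx, tx_end) &&
      frame_at(pred, tx_end) == 2L)
    return("STOP_CODON")

  ## (5)/(6): position of in-frame overlap relative to the Sec codon,
  ## measured in the prediction's transcript coordinates
  tp <- transcript_position(pred, in_frame)
  codon_tp <- range(transcript_position(pred, span))
  has5 <- any(tp < codon_tp[1L], na.rm = TRUE)
  has3 <- any(tp > codon_tp[2L], na.rm = TRUE)
  if (has5 && has3 && !codon_coding) return("SKIPPED")
  if (has5 && has3) return("SKIPPED")  # codon coding but frame-shifted
  if (has5) return("UPSTREAM")
  if (has3) return("DOWNSTREAM")
  ## overlap confined to a partial codon: decide by where tx's CDS ends
  if (!is.na(transcript_position(pred, tx_end)) &&
      transcript_position(pred, tx_end) <= codon_tp[2L]) "UPSTREAM"
  else "DOWNSTREAM"
}

#' Aggregate transcript-level statuses to a gene-level status
#'
#' A prediction with no overlapping transcript is `ABSENT`; one with at
#' least one `WELL_ANNOTATED` pair is `WELL_ANNOTATED`; anything else is a
#' `MISANNOTATION`.
#'
#' @param statuses Character vector of transcript statuses for one
#'   prediction (possibly empty).
#' @return A single gene-level status string.
#' @export
aggregate_gene_status <- function(statuses) {
  if (length(statuses) == 0L) return("ABSENT")
  if (any(statuses == "WELL_ANNOTATED")) return("WELL_ANNOTATED")
  "MISANNOTATION"
}

#' Assess a prediction set against a database annotation
#'
#' Runs [match_overlaps()], [classify_pair()] and
#' [aggregate_gene_status()] over whole collections.
#'
#' @param predictions List of [sec_prediction()] objects.
#' @param transcripts List of [annotated_transcript()] objects.
#' @return Data frame with one row per (prediction, overlapping
#'   transcript) pair plus one row per prediction without overlaps;
#'   columns `prediction_id`, `family`, `chrom`, `strand`, `sec_codon`,
#'   `transcript_id`, `transcript_status`, `gene_status`.
#' @export
assess <- function(predictions, transcripts) {
  pairs <- match_overlaps(predictions, transcripts)
  rows <- list()
  for (i in seq_along(predictions)) {
    pred <- predictions[[i]]
    tx_idx <- pairs$tx_idx[pairs$pred_idx == i]
    statuses <- vapply(tx_idx,
                       function(j) classify_pair(pred, transcripts[[j]]), "")
    gene <- aggregate_gene_status(statuses)
    base <- data.frame(
      prediction_id = pred$prediction_id, family = pred$family,
      chrom = pred$chrom, strand = pred$strand,
      sec_codon = paste(pred$sec_codon, collapse = ","),
      stringsAsFactors = FALSE)
    if (length(tx_idx) == 0L) {
      rows[[length(rows) + 1L]] <- cbind(
        base, transcript_id = NA_character_,
        transcript_status = NA_character_, gene_status = gene)
    } else {
      rows[[length(rows) + 1L]] <- cbind(
        base[rep(1L, length(tx_idx)), , drop = FALSE],
        transcript_id = vapply(transcripts[tx_idx], `[[`, "",
                               "transcript_id"),
        transcript_status = statuses, gene_status = gene)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Summarize assessment records per family and status
#'
#' At gene level each prediction counts once with its gene status; at
#' transcript level each overlapping pair counts once and predictions with
#' no overlap count once as `ABSENT`.
#'
#' @param records Data frame from [assess()].
#' @param level `"gene"` or `"transcript"`.
#' @return Data frame with columns `family`, `status`, `count`, `percent`
#'   (percentages per family sum to 100 up to rounding).
#' @export
summarize_assessment <- function(records, level = c("gene", "transcript")) {
  level <- match.arg(level)
  if (level == "gene") {
    u <- unique(records[, c("prediction_id", "family", "gene_status")])
    tab <- stats::aggregate(list(count = u$prediction_id),
                            by = list(family = u$family,
                                      status = u$gene_status), FUN = length)
  } else {
    st <- ifelse(is.na(records$transcript_status), "ABSENT",
                 records$transcript_status)
    tab <- stats::aggregate(list(count = records$prediction_id),
                            by = list(family = records$family, status = st),
                            FUN = length)
  }
  fam_tot <- stats::aggregate(list(total = tab$count),
                              by = list(family = tab$family), FUN = sum)
  tab <- merge(tab, fam_tot, by = "family")
  tab$percent <- 100 * tab$count / tab$total
  tab$total <- NULL
  tab <- tab[order(tab$family, tab$status), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
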