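## Data model for gene structures.
##
## Coordinates are 1-based inclusive (GTF convention) throughout; GFF3 input
## uses the same convention so no conversion is needed. CDS blocks are stored
## in TRANSLATION order: ascending genomic coordinate on '+', descending on
## '-'. All 5'/3' language in this package is relative to the mRNA, not the
## genome.

#' Construct an annotated transcript
#'
#' An `annotated_transcript` is a database gene model restricted to its
#' coding part: an ordered set of CDS blocks with per-block phases.
#'
#' @param transcript_id,gene_id Character identifiers.
#' @param chrom Sequence (chromosome/scaffold) name.
#' @param strand `"+"` or `"-"`.
#' @param cds_blocks Data frame with integer columns `start`, `end`
#'   (1-based inclusive), given in translation order (descending genomic
#'   coordinate on the minus strand). Ascending genomic order is also
#'   accepted and reordered.
#' @param phases Integer vector of per-block phases in `{0,1,2}` (number of
#'   bases at the block 5' end that complete the previous codon). Defaults
#'   to phase 0 for the first block with the rest derived from block
#'   lengths.
#' @param stop_included `TRUE` if the terminal stop codon lies inside
#'   `cds_blocks` (GenBank-style dialect), `FALSE` if it is excluded
#'   (Ensembl-style), `NA` when unknown.
#' @return An object of class `annotated_transcript`.
#' @export
annotated_transcript <- function(transcript_id, gene_id, chrom, strand,
                                 cds_blocks, phases = NULL,
                                 stop_included = NA) {
  cds_blocks <- .normalize_blocks(cds_blocks, strand)
  if (is.null(phases)) phases <- derive_phases(cds_blocks, 0L)
  stopifnot(length(phases) == nrow(cds_blocks), all(phases %in% 0:2))
  x <- structure(
    list(transcript_id = as.character(transcript_id),
         gene_id = as.character(gene_id),
         chrom = as.character(chrom), strand = strand,
         cds_blocks = cds_blocks, phases = as.integer(phases),
         stop_included = stop_included),
    class = "annotated_transcript")
  .validate_gene_structure(x)
  if (coding_length(x) < 3L)
    stop("annotated_transcript: total coding length must be >= 3")
  x
}

#' Construct a Sec-containing gene prediction
#'
#' A `sec_prediction` is a predicted selenoprotein gene model whose (first)
#' selenocysteine codon position is known. Multi-Sec proteins (SELENOP,
#' SELENOL) are represented by their first Sec residue only.
#'
#' @inheritParams annotated_transcript
#' @param prediction_id Character identifier.
#' @param family Profile/family name (e.g. `"GPX"`, `"TXNRD"`).
#' @param sec_protein_index 1-based residue index of the (first) Sec.
#' @param protein_seq Optional amino-acid string with `"U"` at
#'   `sec_protein_index`.
#' @param sec_codon Optional integer vector of the 3 genomic positions of
#'   the Sec codon in translation order; recomputed from
#'   `sec_protein_index` when missing.
#' @param subfamily Optional subfamily (orthologous group) label.
#' @return An object of class `sec_prediction`.
#' @export
sec_prediction <- function(prediction_id, family, chrom, strand, cds_blocks,
                           sec_protein_index, protein_seq = NA_character_,
                           sec_codon = NULL, subfamily = NA_character_) {
  cds_blocks <- .normalize_blocks(cds_blocks, strand)
  x <- structure(
    list(prediction_id = as.character(prediction_id),
         family = as.character(family),
         subfamily = as.character(subfamily),
         chrom = as.character(chrom), strand = strand,
         cds_blocks = cds_blocks,
         phases = derive_phases(cds_blocks, 0L),
         sec_protein_index = as.integer(sec_protein_index),
         protein_seq = protein_seq,
         sec_codon = NULL, stop_included = FALSE),
    class = c("sec_prediction", "annotated_transcript"))
  .validate_gene_structure(x)
  span <- sec_codon_span(x)
  if (!is.null(sec_codon)) {
    sec_codon <- as.integer(sec_codon)
    if (!identical(sec_codon, span))
      stop("sec_prediction: supplied sec_codon does not match ",
           "sec_protein_index (", paste(sec_codon, collapse = ","),
           " vs ", paste(span, collapse = ","), ")")
  }
  x$sec_codon <- span
  if (!is.na(protein_seq)) {
    if (nchar(protein_seq) * 3L > coding_length(x) ||
        substr(protein_seq, x$sec_protein_index, x$sec_protein_index) != "U")
      stop("sec_prediction: protein_seq must carry 'U' at sec_protein_index",
           " and fit the coding length")
  }
  x
}

.normalize_blocks <- function(blocks, strand) {
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  blocks <- as.data.frame(blocks)[, c("start", "end")]
  blocks$start <- as.integer(blocks$start)
  blocks$end <- as.integer(blocks$end)
  if (nrow(blocks) == 0L) stop("at least one CDS block is required")
  if (any(blocks$start < 1L) || any(blocks$end < blocks$start))
    stop("invalid CDS block coordinates (need 1 <= start <= end)")
  ord <- order(blocks$start, decreasing = (strand == "-"))
  blocks <- blocks[ord, , drop = FALSE]
  rownames(blocks) <- NULL
  blocks
}

.validate_gene_structure <- function(x) {
  b <- x$cds_blocks
  if (nrow(b) > 1L) {
    g <- b[order(b$start), , drop = FALSE]
    if (any(g$start[-1L] <= g$end[-nrow(g)]))
      stop("CDS blocks overlap")
  }
  invisible(x)
}

#' Derive per-block phases from block lengths
#'
#' Uses the standard recurrence `phase[i+1] = (3 - (len[i] - phase[i]) %% 3) %% 3`.
#'
#' @param cds_blocks Block data frame in translation order.
#' @param first Phase of the first block.
#' @return Integer vector of phases.
#' @export
derive_phases <- function(cds_blocks, first = 0L) {
  len <- cds_blocks$end - cds_blocks$start + 1L
  n <- length(len)
  ph <- integer(n)
  ph[1L] <- as.integer(first)
  if (n > 1L) for (i in seq_len(n - 1L))
    ph[i + 1L] <- (3L - (len[i] - ph[i]) %% 3L) %% 3L
  ph
}

#' Total coding length of a gene structure
#' @param x An `annotated_transcript` or `sec_prediction`.
#' @return Integer number of coding bases.
#' @export
coding_length <- function(x) {
  sum(x$cds_blocks$end - x$cds_blocks$start + 1L)
}

#' Genomic positions of the coding sequence in translation order
#' @inheritParams coding_length
#' @return Integer vector, one genomic position per coding base, 5' to 3'.
#' @export
cds_positions <- function(x) {
  b <- x$cds_blocks
  if (x$strand == "+") {
    unlist(lapply(seq_len(nrow(b)), function(i) b$start[i]:b$end[i]),
           use.names = FALSE)
  } else {
    unlist(lapply(seq_len(nrow(b)), function(i) b$end[i]:b$start[i]),
           use.names = FALSE)
  }
}

## 1-based transcript (spliced CDS) coordinate of genomic position p,
## NA if p is not coding. Vectorised over p.
transcript_position <- function(x, p) {
  b <- x$cds_blocks
  len <- b$end - b$start + 1L
  before <- c(0L, cumsum(len))[seq_len(nrow(b))]
  vapply(as.integer(p), function(pp) {
    hit <- which(pp >= b$start & pp <= b$end)
    if (length(hit) == 0L) return(NA_integer_)
    hit <- hit[1L]
    off <- if (x$strand == "+") pp - b$start[hit] else b$end[hit] - pp
    before[hit] + off + 1L
  }, integer(1L))
}

## Genomic position of 1-based transcript coordinate i. Vectorised.
genomic_position <- function(x, i) {
  pos <- cds_positions(x)
  i <- as.integer(i)
  if (any(i < 1L | i > length(pos)))
    stop("transcript coordinate out of coding range")
  pos[i]
}

#' Reading frame at a genomic position
#'
#' Returns the frame (0, 1 or 2) of a coding genomic position: the number of
#' coding bases 5' of it within its codon. The first base of each codon has
#' frame 0; the phase of the block containing the position is honoured, so
#' the first coding base after the first block's phase offset has frame 0.
#'
#' @param x An `annotated_transcript` or `sec_prediction`.
#' @param p Genomic position (may be a vector).
#' @return Integer frame(s) in `{0,1,2}`.
#' @export
frame_at <- function(x, p) {
  b <- x$cds_blocks
  vapply(as.integer(p), function(pp) {
    hit <- which(pp >= b$start & pp <= b$end)
    if (length(hit) == 0L)
      stop("frame_at: position ", pp, " is not coding in ",
           x$transcript_id %||% x$prediction_id)
    hit <- hit[1L]
    off <- if (x$strand == "+") pp - b$start[hit] else b$end[hit] - pp
    (off - x$phases[hit]) %% 3L
  }, integer(1L))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Genomic span of the Sec codon
#'
#' The three genomic positions, in translation order, of codon number
#' `sec_protein_index`. When the codon crosses an intron the positions are
#' not contiguous in genomic space.
#'
#' @param pred A `sec_prediction` (any gene structure works if an index is
#'   supplied).
#' @param index Codon number; defaults to `pred$sec_protein_index`.
#' @return Integer vector of 3 genomic positions.
#' @export
sec_codon_span <- function(pred, index = pred$sec_protein_index) {
  index <- as.integer(index)
  if (is.na(index) || index < 1L)
    stop("sec_codon_span: invalid codon index")
  tpos <- (3L * (index - 1L) + 1L):(3L * index)
  if (3L * index > coding_length(pred))
    stop("sec_codon_span: codon ", index, " beyond coding length")
  genomic_position(pred, tpos)
}

#' @export
print.annotated_transcript <- function(x, ...) {
  id <- x$transcript_id %||% x$prediction_id
  cat(sprintf("<%s> %s  %s:%s  %d CDS block(s), %d coding bases\n",
              class(x)[1L], id, x$chrom, x$strand,
              nrow(x$cds_blocks), coding_length(x)))
  invisible(x)
}

#' @export
print.sec_prediction <- function(x, ...) {
  cat(sprintf(
    "<sec_prediction> %s  family=%s  %s:%s  %d block(s), Sec codon %s\n",
    x$prediction_id, x$family, x$chrom, x$strand, nrow(x$cds_blocks),
    paste(x$sec_codon, collapse = ",")))
  invisible(x)
}
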