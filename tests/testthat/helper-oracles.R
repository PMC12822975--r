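## Independent oracles used across test files. Each one recomputes a
## quantity by the most naive route available so that it shares no code
## path with the implementation it checks.

## Frame by concatenating the spliced CDS and indexing into it.
frame_oracle <- function(x, p) {
  spliced <- cds_positions(x)
  idx <- match(p, spliced)
  stopifnot(!anyNA(idx))
  (idx - 1L - x$phases[1L]) %% 3L
}

## AWSI by an explicit per-column loop.
awsi_oracle <- function(x, y, w) {
  cx <- strsplit(x, "")[[1]]
  cy <- strsplit(y, "")[[1]]
  num <- 0; den <- 0
  for (c in seq_along(cx)) {
    if (cx[c] == "-" || cy[c] == "-") next
    den <- den + w[c]
    if (cx[c] == cy[c]) num <- num + w[c]
  }
  if (den == 0) NA_real_ else num / den
}

## All-vs-all quadratic interval intersection over CDS blocks.
overlap_oracle <- function(predictions, transcripts) {
  out <- list()
  for (i in seq_along(predictions)) for (j in seq_along(transcripts)) {
    p <- predictions[[i]]; t <- transcripts[[j]]
    if (p$chrom != t$chrom || p$strand != t$strand) next
    hit <- FALSE
    for (a in seq_len(nrow(p$cds_blocks))) for (b in seq_len(nrow(t$cds_blocks))) {
      if (max(p$cds_blocks$start[a], t$cds_blocks$start[b]) <=
          min(p$cds_blocks$end[a], t$cds_blocks$end[b])) hit <- TRUE
    }
    if (hit) out[[length(out) + 1L]] <- c(i, j)
  }
  if (length(out) == 0L)
    return(data.frame(pred_idx = integer(0), tx_idx = integer(0)))
  m <- do.call(rbind, out)
  data.frame(pred_idx = m[, 1L], tx_idx = m[, 2L])
}

## Random aligned pair over a random small anchor, for AWSI checks.
random_awsi_case <- function(len = NULL) {
  aa <- c(LETTERS[1:20])
  if (is.null(len)) len <- sample(10:200, 1)
  gap_frac <- runif(1, 0, 0.3)
  mkrow <- function() {
    s <- sample(aa, len, replace = TRUE)
    s[runif(len) < gap_frac] <- "-"
    paste(s, collapse = "")
  }
  rows <- replicate(4, mkrow())
  ## anchors reject all-gap rows; regenerate any
  while (any(gsub("-", "", rows) == "")) rows <- replicate(4, mkrow())
  anchor <- anchor_alignment(paste0("r", 1:4), rep(c("A", "B"), 2), rows)
  list(x = mkrow(), y = mkrow(), w = column_weights(anchor))
}
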