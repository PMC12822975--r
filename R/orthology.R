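## Subfamily (orthologous group) assignment via anchor alignments and
## average weighted sequence identity (AWSI).
##
## An anchor is a fixed-column reference alignment whose rows carry
## subfamily (and lineage) labels. Candidates are placed into the anchor's
## column space, scored by AWSI against each subfamily's representatives,
## and assigned to the best-scoring subfamily.

.AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
                  "F","P","S","T","W","Y","V","B","Z","X","U")

#' Construct an anchor alignment
#'
#' @param ids Character vector of sequence identifiers.
#' @param subfamily Character vector of subfamily labels (one per row).
#' @param seqs Character vector of aligned amino-acid strings, all the
#'   same length, with `-` for gaps.
#' @param lineage Optional character vector of lineage labels.
#' @return An object of class `anchor_alignment` with elements `ids`,
#'   `subfamily`, `lineage`, `seqs` and `columns`.
#' @export
anchor_alignment <- function(ids, subfamily, seqs, lineage = NULL) {
  ids <- as.character(ids); subfamily <- as.character(subfamily)
  seqs <- toupper(as.character(seqs))
  if (is.null(lineage)) lineage <- rep(NA_character_, length(ids))
  n <- length(ids)
  stopifnot(n >= 1L, length(subfamily) == n, length(seqs) == n,
            length(lineage) == n)
  if (anyNA(subfamily) || any(!nzchar(subfamily)))
    stop("anchor_alignment: every row needs a subfamily label")
  w <- unique(nchar(seqs))
  if (length(w) != 1L)
    stop("anchor_alignment: rows have unequal lengths")
  if (any(gsub("-", "", seqs, fixed = TRUE) == ""))
    stop("anchor_alignment: all-gap rows are not allowed")
  structure(list(ids = ids, subfamily = subfamily,
                 lineage = as.character(lineage), seqs = seqs,
                 columns = w),
            class = "anchor_alignment")
}

#' @export
print.anchor_alignment <- function(x, ...) {
  cat(sprintf("<anchor_alignment> %d rows x %d columns, %d subfamilies\n",
              length(x$ids), x$columns, length(unique(x$subfamily))))
  invisible(x)
}

.anchor_matrix <- function(anchor) {
  do.call(rbind, strsplit(anchor$seqs, "", fixed = TRUE))
}

#' Per-column conservation weights of an anchor alignment
#'
#' The weight of a column is the count of its most frequent non-gap
#' character divided by the total number of rows, so fully conserved
#' gap-free columns weigh 1 and all-gap columns weigh 0.
#'
#' @param anchor An [anchor_alignment()].
#' @return Numeric vector of weights in `[0, 1]`, one per column.
#' @export
column_weights <- function(anchor) {
  m <- .anchor_matrix(anchor)
  nrows <- nrow(m)
  apply(m, 2L, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0L) return(0)
    max(tabulate(factor(col, levels = unique(col)))) / nrows
  })
}

#' Average weighted sequence identity between two aligned strings
#'
#' Computed over columns where neither sequence has a gap:
#' `sum(w * identical) / sum(w)`. Returns `NA` when no gap-free column
#' with positive weight exists.
#'
#' @param x,y Aligned strings of equal length.
#' @param w Numeric column weights of the same length.
#' @return AWSI score in `[0, 1]`, or `NA_real_`.
#' @export
awsi <- function(x, y, w) {
  cx <- strsplit(toupper(x), "", fixed = TRUE)[[1L]]
  cy <- strsplit(toupper(y), "", fixed = TRUE)[[1L]]
  if (length(cx) != length(cy) || length(cx) != length(w))
    stop("awsi: x, y and w must have equal lengths")
  keep <- cx != "-" & cy != "-"
  if (!any(keep)) return(NA_real_)
  wt <- w[keep]
  tot <- sum(wt)
  if (tot == 0) return(NA_real_)
  sum(wt * (cx[keep] == cy[keep])) / tot
}

## Column x residue score matrix for the profile aligner: occupancy-scaled
## average BLOSUM62 score of each alphabet residue against the column's
## residue frequencies. Sec (U) is scored through the Cys column.
.profile_scores <- function(anchor) {
  b62 <- get(utils::data("BLOSUM62", package = "Biostrings",
                         envir = environment()), envir = environment())
  lookup <- .AA_ALPHABET
  lookup[lookup == "U"] <- "C"
  sub <- b62[lookup, lookup]
  m <- .anchor_matrix(anchor)
  nres <- length(.AA_ALPHABET)
  smat <- matrix(0, nrow = ncol(m), ncol = nres)
  for (j in seq_len(ncol(m))) {
    col <- m[, j]
    col <- col[col != "-"]
    if (length(col) == 0L) next
    idx <- match(col, .AA_ALPHABET)
    idx[is.na(idx)] <- match("X", .AA_ALPHABET)
    f <- tabulate(idx, nbins = nres) / length(idx)
    occ <- length(col) / nrow(m)
    smat[j, ] <- occ * as.numeric(f %*% sub)
  }
  smat
}

.anchor_occupancy <- function(anchor) {
  m <- .anchor_matrix(anchor)
  colMeans(m != "-")
}

#' Place a candidate protein into an anchor's column space
#'
#' Global profile-to-sequence alignment with position-specific residue
#' frequencies (BLOSUM62-scored), affine gaps, and occupancy-scaled
#' deletion costs; terminal deletions are free so fragments align to the
#' anchor span they cover. Candidate residues that would require new
#' columns (insertions relative to the anchor) are dropped. Deterministic
#' for fixed inputs.
#'
#' @param candidate Unaligned amino-acid string.
#' @param anchor An [anchor_alignment()].
#' @param gap_open,gap_ext Affine gap penalties (positive numbers).
#' @return Aligned string of length `anchor$columns`.
#' @export
align_to_anchor <- function(candidate, anchor, gap_open = 11, gap_ext = 1) {
  candidate <- toupper(gsub("[-*. ]", "", candidate))
  if (!nzchar(candidate)) stop("align_to_anchor: empty candidate")
  chars <- strsplit(candidate, "", fixed = TRUE)[[1L]]
  idx <- match(chars, .AA_ALPHABET)
  idx[is.na(idx)] <- match("X", .AA_ALPHABET)
  smat <- .profile_scores(anchor)
  occ <- .anchor_occupancy(anchor)
  placement <- profile_align_cpp(idx - 1L, smat, occ, gap_open, gap_ext)
  out <- rep("-", anchor$columns)
  hit <- placement > 0L
  out[hit] <- chars[placement[hit]]
  paste(out, collapse = "")
}

#' Score a candidate against every subfamily of an anchor
#'
#' The candidate is placed into the anchor's columns once, then scored by
#' [awsi()] against each anchor row; the per-subfamily score is the mean
#' over that subfamily's representatives. The best subfamily is assigned,
#' with ties broken lexicographically; `margin` is best minus second-best
#' (`NA` with a single subfamily). A candidate whose AWSI is undefined
#' against every row yields `assigned = NA` (unassignable), not an error.
#'
#' @param candidate Unaligned amino-acid string (or an already aligned
#'   string of length `anchor$columns` when `aligned = TRUE`).
#' @param anchor An [anchor_alignment()].
#' @param aligned Set to `TRUE` when `candidate` is already in anchor
#'   column space.
#' @return A list of class `subfamily_scores`: `candidate_aligned`,
#'   `scores` (named per subfamily), `assigned`, `margin`.
#' @export
score_subfamilies <- function(candidate, anchor, aligned = FALSE) {
  al <- if (aligned) toupper(candidate) else align_to_anchor(candidate, anchor)
  w <- column_weights(anchor)
  row_scores <- vapply(anchor$seqs, function(s) awsi(al, s, w), 0,
                       USE.NAMES = FALSE)
  subs <- sort(unique(anchor$subfamily))
  scores <- vapply(subs, function(sf) {
    v <- row_scores[anchor$subfamily == sf]
    if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }, 0)
  if (all(is.na(scores))) {
    res <- list(candidate_aligned = al, scores = scores,
                assigned = NA_character_, margin = NA_real_)
  } else {
    best <- which(scores == max(scores, na.rm = TRUE))[1L]  # subs sorted
    second <- if (length(scores) > 1L)
      max(scores[-best], na.rm = TRUE) else NA_real_
    if (is.infinite(second)) second <- NA_real_
    res <- list(candidate_aligned = al, scores = scores,
                assigned = subs[best],
                margin = if (is.na(second)) NA_real_
                         else unname(scores[best] - second))
  }
  class(res) <- "subfamily_scores"
  res
}

## Pairwise identity between two anchor rows: fraction of identical
## residues over mutually non-gap columns (unweighted).
.pairwise_identity <- function(x, y) {
  cx <- strsplit(x, "", fixed = TRUE)[[1L]]
  cy <- strsplit(y, "", fixed = TRUE)[[1L]]
  keep <- cx != "-" & cy != "-"
  if (!any(keep)) return(0)
  mean(cx[keep] == cy[keep])
}

#' Reduce a labelled alignment to representative anchor rows
#'
#' Per (subfamily, lineage) group, keeps at most `k` rows chosen by greedy
#' maximal-diversity selection: first the two most dissimilar rows, then
#' iteratively the row whose maximum identity to the already chosen set is
#' smallest. Groups of size `<= k` are kept whole.
#'
#' @param anchor An [anchor_alignment()] with subfamily (and optionally
#'   lineage) labels on every row.
#' @param k Maximum representatives per (subfamily, lineage) group;
#'   default 12.
#' @return A reduced [anchor_alignment()] preserving original row order.
#' @export
build_anchor <- function(anchor, k = 12L) {
  k <- as.integer(k)
  stopifnot(k >= 1L)
  grp <- paste(anchor$subfamily, anchor$lineage, sep = "\r")
  keep <- logical(length(anchor$ids))
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) <= k) { keep[idx] <- TRUE; next }
    seqs <- anchor$seqs[idx]
    ng <- length(idx)
    id <- matrix(1, ng, ng)
    for (a in seq_len(ng - 1L)) for (b in (a + 1L):ng)
      id[a, b] <- id[b, a] <- .pairwise_identity(seqs[a], seqs[b])
    ## seed: the most dissimilar pair (first such pair in index order)
    pair <- which(id == min(id[upper.tri(id)]), arr.ind = TRUE)
    pair <- pair[pair[, 1L] < pair[, 2L], , drop = FALSE][1L, ]
    chosen <- sort(unname(pair))
    if (k == 1L) chosen <- chosen[1L]
    while (length(chosen) < k) {
      rest <- setdiff(seq_len(ng), chosen)
      worst <- vapply(rest, function(r) max(id[r, chosen]), 0)
      chosen <- c(chosen, rest[which.min(worst)])
    }
    keep[idx[chosen]] <- TRUE
  }
  anchor_alignment(anchor$ids[keep], anchor$subfamily[keep],
                   anchor$seqs[keep], anchor$lineage[keep])
}

#' Read an anchor alignment from aligned FASTA
#'
#' Headers follow the convention
#' `>id subfamily=<name> lineage=<name>` (lineage optional).
#'
#' @param path FASTA file path.
#' @return An [anchor_alignment()].
#' @export
read_anchor_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  grab <- function(key) {
    m <- regmatches(headers,
                    regexec(paste0(key, "=(\\S+)"), headers))
    vapply(m, function(z) if (length(z) == 2L) z[2L] else NA_character_, "")
  }
  anchor_alignment(ids, grab("subfamily"), as.character(aa),
                   lineage = grab("lineage"))
}

#' Write an anchor alignment as aligned FASTA
#'
#' @param anchor An [anchor_alignment()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_anchor_fasta <- function(anchor, path) {
  lin <- ifelse(is.na(anchor$lineage), "",
                paste0(" lineage=", anchor$lineage))
  writeLines(paste0(">", anchor$ids, " subfamily=", anchor$subfamily, lin,
                    "\n", anchor$seqs), path)
  invisible(path)
}

#' Assign a set of candidate proteins to subfamilies
#'
#' @param candidates Named character vector of protein sequences.
#' @param anchor An [anchor_alignment()].
#' @return Data frame with columns `candidate_id`, `assigned_subfamily`,
#'   `score`, `margin`, and `subfamily_scores` (semicolon-separated
#'   `name:score` list).
#' @export
assign_subfamilies <- function(candidates, anchor) {
  stopifnot(!is.null(names(candidates)))
  rows <- lapply(names(candidates), function(id) {
    ss <- score_subfamilies(candidates[[id]], anchor)
    data.frame(
      candidate_id = id,
      assigned_subfamily = ss$assigned,
      score = if (is.na(ss$assigned)) NA_real_
              else unname(ss$scores[ss$assigned]),
      margin = ss$margin,
      subfamily_scores = paste(names(ss$scores),
                               sprintf("%.6f", ss$scores),
                               sep = ":", collapse = ";"),
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
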