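## Lineage-expectation filtering: compare assigned predictions with the
## expected selenoproteome of the species' lineage, keep the N top-scoring
## predictions per subfamily (N = expected count), and report the rest as
## filtered out, together with any expected-but-undetected subfamilies
## (missing).

#' Load an expectation table from CSV
#'
#' The CSV must have columns `lineage`, `subfamily`, `expected_count`
#' (non-negative integers). Duplicate (lineage, subfamily) keys are an
#' error.
#'
#' @param path CSV file path (or a data frame with the same columns).
#' @return Data frame of class `expectation_table`.
#' @export
load_expectation_table <- function(path) {
  tab <- if (is.data.frame(path)) path
         else utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("lineage", "subfamily", "expected_count")
  if (!all(need %in% names(tab)))
    stop("expectation table: missing column(s) ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab <- tab[, need]
  cnt <- suppressWarnings(as.numeric(tab$expected_count))
  if (anyNA(cnt) || any(cnt < 0) || any(cnt != floor(cnt)))
    stop("expectation table: expected_count must be non-negative integers")
  tab$expected_count <- as.integer(cnt)
  key <- paste(tab$lineage, tab$subfamily, sep = "\r")
  if (anyDuplicated(key))
    stop("expectation table: duplicate (lineage, subfamily) rows")
  class(tab) <- c("expectation_table", "data.frame")
  tab
}

#' Resolve the lineage of a species
#'
#' An explicit override wins; otherwise the species is looked up in the
#' mapping table. An unknown species without an override is an error
#' telling the caller to pass the lineage explicitly.
#'
#' @param species Species name (e.g. `"Mus musculus"`).
#' @param mapping Data frame with columns `species`, `lineage` (or a TSV
#'   file path). Defaults to the small table shipped with the package.
#' @param override Optional lineage label that bypasses the mapping.
#' @return A lineage label.
#' @export
resolve_lineage <- function(species, mapping = NULL, override = NULL) {
  if (!is.null(override) && nzchar(override)) return(override)
  if (is.null(mapping))
    mapping <- utils::read.delim(
      system.file("extdata", "species_lineage.tsv", package = "selannot"),
      stringsAsFactors = FALSE)
  if (!is.data.frame(mapping))
    mapping <- utils::read.delim(mapping, stringsAsFactors = FALSE)
  hit <- mapping$lineage[mapping$species == species]
  if (length(hit) == 0L)
    stop("resolve_lineage: species '", species, "' not in the mapping; ",
         "pass an explicit lineage (--lineage)")
  hit[1L]
}

#' Filter assigned predictions against lineage expectations
#'
#' For each subfamily with expected count `N`, predictions are ranked by
#' score (descending; ties broken by `prediction_id`) and the top
#' `min(N, predicted)` are kept; the rest are filtered out. Subfamilies
#' with fewer predictions than expected are reported as missing with
#' their deficit. Subfamilies predicted but not listed for the lineage are
#' kept and flagged `"unexpected"` rather than dropped.
#'
#' @param assigned Data frame with columns `prediction_id`, `subfamily`,
#'   `score` (e.g. from [assign_subfamilies()], renaming `candidate_id`
#'   and `assigned_subfamily`).
#' @param lineage Lineage label, present in `table`.
#' @param table An [load_expectation_table()] result.
#' @return A list of class `lineage_report`: `decisions` (data frame
#'   `prediction_id`, `subfamily`, `score`, `decision`, `tie`), `kept`,
#'   `filtered_out`, `unexpected` (prediction id vectors) and `missing`
#'   (named integer deficit per subfamily).
#' @export
apply_lineage_filter <- function(assigned, lineage, table) {
  stopifnot(all(c("prediction_id", "subfamily", "score") %in%
                names(assigned)))
  if (!lineage %in% table$lineage)
    stop("apply_lineage_filter: lineage '", lineage,
         "' absent from the expectation table")
  exp_tab <- table[table$lineage == lineage, ]
  expected <- stats::setNames(exp_tab$expected_count, exp_tab$subfamily)
  decisions <- assigned[0, c("prediction_id", "subfamily", "score")]
  decisions$decision <- character(0)
  decisions$tie <- logical(0)
  missing <- stats::setNames(integer(0), character(0))
  subs <- sort(unique(c(assigned$subfamily, names(expected))))
  for (sf in subs) {
    rows <- assigned[assigned$subfamily == sf, , drop = FALSE]
    if (!sf %in% names(expected)) {
      if (nrow(rows) > 0L)
        decisions <- rbind(decisions, data.frame(
          prediction_id = rows$prediction_id, subfamily = sf,
          score = rows$score, decision = "unexpected", tie = FALSE))
      next
    }
    n_exp <- expected[[sf]]
    if (nrow(rows) < n_exp)
      missing[sf] <- n_exp - nrow(rows)
    if (nrow(rows) == 0L) next
    ord <- order(-rows$score, rows$prediction_id)
    rows <- rows[ord, , drop = FALSE]
    n_keep <- min(n_exp, nrow(rows))
    dec <- rep("filtered_out", nrow(rows))
    if (n_keep > 0L) dec[seq_len(n_keep)] <- "kept"
    ## flag score ties straddling the keep/cut boundary
    tie <- rep(FALSE, nrow(rows))
    if (n_keep > 0L && n_keep < nrow(rows) &&
        isTRUE(rows$score[n_keep] == rows$score[n_keep + 1L])) {
      tie[rows$score == rows$score[n_keep]] <- TRUE
    }
    decisions <- rbind(decisions, data.frame(
      prediction_id = rows$prediction_id, subfamily = sf,
      score = rows$score, decision = dec, tie = tie))
  }
  rownames(decisions) <- NULL
  ## unexpected predictions are kept (flagged, not dropped), so kept and
  ## filtered_out always partition the input
  res <- list(
    decisions = decisions,
    kept = decisions$prediction_id[decisions$decision %in%
                                     c("kept", "unexpected")],
    filtered_out = decisions$prediction_id[decisions$decision ==
                                             "filtered_out"],
    unexpected = decisions$prediction_id[decisions$decision ==
                                           "unexpected"],
    missing = missing)
  class(res) <- "lineage_report"
  res
}

#' @export
print.lineage_report <- function(x, ...) {
  cat(sprintf(
    "<lineage_report> kept %d, filtered out %d, unexpected %d, missing %d\n",
    length(x$kept), length(x$filtered_out), length(x$unexpected),
    sum(x$missing)))
  invisible(x)
}
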