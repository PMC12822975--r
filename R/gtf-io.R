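## GTF / GFF3 reading and writing.
##
## Both dialects are 9 tab-separated columns with 1-based inclusive
## coordinates; they differ only in the attribute syntax (GTF:
## `key "value"; ...`, GFF3: `key=value;...`) and in how features are
## grouped (GTF: transcript_id attribute; GFF3: Parent). Only CDS and
## stop_codon features are consumed; everything else is ignored.
##
## Prediction files additionally carry a `sec_codon` attribute on their CDS
## lines (comma-separated genomic positions of the Sec codon), a `family`
## attribute, and optionally `sec_protein_index`. This is this package's
## interchange convention for making Sec positions explicit.

.parse_attributes <- function(attr, dialect, lineno) {
  attr <- sub("\\s*;?\\s*$", "", attr)
  if (dialect == "gtf") {
    parts <- strsplit(attr, ";")[[1L]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    m <- regmatches(parts, regexec('^(\\S+)\\s+"([^"]*)"$', parts))
    bad <- vapply(m, length, 1L) != 3L
    if (any(bad))
      stop("parse error at line ", lineno, ": malformed GTF attribute '",
           parts[bad][1L], "'")
    as.list(stats::setNames(vapply(m, `[`, "", 3L),
                             vapply(m, `[`, "", 2L)))
  } else {
    parts <- strsplit(attr, ";")[[1L]]
    parts <- trimws(parts)
    parts <- parts[nzchar(parts)]
    kv <- strsplit(parts, "=", fixed = TRUE)
    bad <- vapply(kv, length, 1L) < 2L
    if (any(bad))
      stop("parse error at line ", lineno, ": malformed GFF3 attribute '",
           parts[bad][1L], "'")
    as.list(stats::setNames(
      vapply(kv, function(z) paste(z[-1L], collapse = "="), ""),
      vapply(kv, `[`, "", 1L)))
  }
}

.split_gxf_lines <- function(lines, dialect, lineno_offset = 0L) {
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  rows <- vector("list", length(idx))
  for (k in seq_along(idx)) {
    i <- idx[k]
    f <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(f) != 9L)
      stop("parse error at line ", i + lineno_offset, ": expected 9 ",
           "tab-separated columns, found ", length(f))
    start <- suppressWarnings(as.integer(f[4L]))
    end <- suppressWarnings(as.integer(f[5L]))
    if (is.na(start) || is.na(end))
      stop("parse error at line ", i + lineno_offset,
           ": non-numeric coordinates")
    if (end < start)
      stop("parse error at line ", i + lineno_offset, ": end < start")
    if (!f[7L] %in% c("+", "-"))
      stop("parse error at line ", i + lineno_offset,
           ": strand must be '+' or '-'")
    rows[[k]] <- list(chrom = f[1L], source = f[2L], feature = f[3L],
                      start = start, end = end, score = f[6L],
                      strand = f[7L], frame = f[8L],
                      attrs = .parse_attributes(f[9L], dialect, i),
                      lineno = i + lineno_offset)
  }
  rows
}

.group_id <- function(row, dialect) {
  key <- if (dialect == "gtf") "transcript_id" else "Parent"
  id <- row$attrs[[key]]
  if (is.null(id) || !nzchar(id))
    stop("parse error at line ", row$lineno, ": ", row$feature,
         " feature lacks a ", key, " attribute")
  id
}

#' Parse GTF/GFF3 text into annotated transcripts
#'
#' Reads CDS (and stop_codon) features and assembles one
#' [annotated_transcript()] per transcript identifier. Whether the terminal
#' stop codon is part of the CDS (`stop_included`) is derived from
#' stop_codon features when present (inside the CDS blocks: included;
#' outside: excluded) and is `NA` otherwise.
#'
#' @param lines Character vector of GTF/GFF3 lines (or a file path of
#'   length 1 pointing to an existing file).
#' @param dialect `"gtf"` or `"gff3"`.
#' @return A named list of `annotated_transcript` objects, in order of
#'   first appearance.
#' @export
parse_gtf <- function(lines, dialect = c("gtf", "gff3")) {
  dialect <- match.arg(dialect)
  if (length(lines) == 1L && !grepl("\t", lines) && file.exists(lines))
    lines <- readLines(lines)
  rows <- .split_gxf_lines(lines, dialect)
  feats <- vapply(rows, `[[`, "", "feature")
  cds <- rows[feats == "CDS"]
  stops <- rows[feats == "stop_codon"]
  if (length(cds) == 0L) return(list())
  ids <- vapply(cds, .group_id, "", dialect = dialect)
  stop_ids <- vapply(stops, .group_id, "", dialect = dialect)
  out <- list()
  for (tid in unique(ids)) {
    rr <- cds[ids == tid]
    chrom <- rr[[1L]]$chrom
    strand <- rr[[1L]]$strand
    if (any(vapply(rr, `[[`, "", "chrom") != chrom) ||
        any(vapply(rr, `[[`, "", "strand") != strand))
      stop("transcript ", tid, ": CDS features disagree on chrom/strand")
    blocks <- data.frame(start = vapply(rr, `[[`, 1L, "start"),
                         end = vapply(rr, `[[`, 1L, "end"))
    ord <- order(blocks$start, decreasing = (strand == "-"))
    blocks <- blocks[ord, , drop = FALSE]
    frames <- vapply(rr, `[[`, "", "frame")[ord]
    phases <- suppressWarnings(as.integer(frames))
    if (anyNA(phases)) phases <- derive_phases(blocks, 0L)
    gid <- rr[[1L]]$attrs[["gene_id"]] %||% tid
    st <- stops[stop_ids == tid]
    stop_included <- NA
    if (length(st) > 0L) {
      s1 <- st[[1L]]
      inside <- any(s1$start >= blocks$start & s1$end <= blocks$end)
      stop_included <- inside
    }
    attrs <- rr[[1L]]$attrs
    if (!is.null(attrs[["sec_codon"]])) {
      span <- as.integer(strsplit(attrs[["sec_codon"]], ",")[[1L]])
      fam <- attrs[["family"]] %||% gid
      tmp <- annotated_transcript(tid, gid, chrom, strand, blocks,
                                  phases, stop_included %||% FALSE)
      idx <- attrs[["sec_protein_index"]]
      idx <- if (!is.null(idx)) as.integer(idx) else
        (transcript_position(tmp, span[1L]) + 2L) %/% 3L
      out[[tid]] <- sec_prediction(
        prediction_id = tid, family = fam, chrom = chrom, strand = strand,
        cds_blocks = blocks, sec_protein_index = idx, sec_codon = span)
    } else {
      out[[tid]] <- annotated_transcript(tid, gid, chrom, strand, blocks,
                                         phases, stop_included)
    }
  }
  out
}

.format_attributes <- function(attrs, dialect) {
  if (dialect == "gtf") {
    paste0(paste0(names(attrs), ' "', unname(attrs), '";'), collapse = " ")
  } else {
    paste0(names(attrs), "=", unname(attrs), collapse = ";")
  }
}

#' Write annotated transcripts or predictions as GTF/GFF3 text
#'
#' Features are emitted in ascending genomic order per transcript (the GTF
#' convention); translation order is recoverable from the strand.
#' `parse_gtf(write_gtf(x), dialect)` reconstructs `x` exactly.
#'
#' @param x A single `annotated_transcript`/`sec_prediction` or a list of
#'   them.
#' @param dialect `"gtf"` or `"gff3"`.
#' @param file Optional path; when given, lines are also written there.
#' @return Character vector of GTF/GFF3 lines, invisibly when `file` is
#'   given.
#' @export
write_gtf <- function(x, dialect = c("gtf", "gff3"), file = NULL) {
  dialect <- match.arg(dialect)
  if (inherits(x, "annotated_transcript")) x <- list(x)
  lines <- character(0)
  for (tx in x) {
    is_pred <- inherits(tx, "sec_prediction")
    tid <- if (is_pred) tx$prediction_id else tx$transcript_id
    gid <- if (is_pred) tx$family else tx$gene_id
    b <- tx$cds_blocks
    ord <- order(b$start)
    src <- if (is_pred) "selannot_prediction" else "selannot"
    for (j in seq_along(ord)) {
      i <- ord[j]
      if (dialect == "gtf") {
        attrs <- c(gene_id = gid, transcript_id = tid)
      } else {
        attrs <- c(ID = paste0(tid, ".cds", j), Parent = tid, gene_id = gid)
      }
      if (is_pred) {
        attrs <- c(attrs, family = tx$family,
                   sec_codon = paste(tx$sec_codon, collapse = ","),
                   sec_protein_index = as.character(tx$sec_protein_index))
      }
      lines <- c(lines, paste(
        tx$chrom, src, "CDS", b$start[i], b$end[i], ".", tx$strand,
        tx$phases[i], .format_attributes(attrs, dialect), sep = "\t"))
    }
    if (!is_pred && isTRUE(!is.na(tx$stop_included))) {
      pos <- cds_positions(tx)
      if (isTRUE(tx$stop_included)) {
        sc <- sort(pos[(length(pos) - 2L):length(pos)])
      } else {
        last <- pos[length(pos)]
        sc <- if (tx$strand == "+") c(last + 1L, last + 3L)
              else c(last - 3L, last - 1L)
        sc <- sc[1L]:sc[length(sc)]
      }
      attrs <- if (dialect == "gtf") {
        c(gene_id = gid, transcript_id = tid)
      } else {
        c(ID = paste0(tid, ".stop"), Parent = tid, gene_id = gid)
      }
      lines <- c(lines, paste(
        tx$chrom, src, "stop_codon", min(sc), max(sc), ".", tx$strand, "0",
        .format_attributes(attrs, dialect), sep = "\t"))
    }
  }
  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}

#' Read a protein FASTA into a named character vector
#'
#' Thin wrapper over [Biostrings::readAAStringSet()]; FASTA headers are
#' truncated at the first whitespace to form names.
#'
#' @param path FASTA file path.
#' @return Named character vector of amino-acid sequences.
#' @export
read_protein_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  seqs <- as.character(aa)
  names(seqs) <- sub("\\s.*$", "", names(aa))
  seqs
}
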