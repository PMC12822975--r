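## Seeded synthetic-fixture generator. Every input the other modules
## consume can be generated here with known ground truth: assessment cases
## are built by perturbing a prediction so that the perturbation satisfies
## the defining condition of one target status; family datasets evolve
## proteins by substitution only, so the true alignment is the identity
## mapping; lineage scenarios carry their own sort-and-slice partition.

.AA20 <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M",
           "F","P","S","T","W","Y","V")

## Run code under a fixed seed without disturbing the caller's RNG state.
.with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(),
                     inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

.random_protein <- function(n, sec_index = NULL) {
  aa <- sample(.AA20, n, replace = TRUE)
  if (!is.null(sec_index)) aa[sec_index] <- "U"
  paste(aa, collapse = "")
}

## Random multi-exon Sec prediction: 1-5 exons of 30-300 bp, introns
## 50-500 bp, total coding length a multiple of 3, Sec at an internal
## codon lying fully inside one exon with >= 3 bases of intra-exon padding
## on both sides (so every perturbation below is well defined).
.random_sec_prediction_geometry <- function(min_sec_index = 2L) {
  repeat {
    n_ex <- sample(1:5, 1L)
    lens <- sample(30:300, n_ex, replace = TRUE)
    lens[n_ex] <- lens[n_ex] + (3L - sum(lens) %% 3L) %% 3L
    total <- sum(lens)
    ncod <- total %/% 3L
    ## exon index and within-exon offset of each transcript position
    ex_of <- rep(seq_len(n_ex), lens)
    off_of <- unlist(lapply(lens, seq_len))  # 1-based offset inside exon
    valid <- integer(0)
    for (i in min_sec_index:(ncod - 1L)) {
      tp <- (3L * (i - 1L) + 1L):(3L * i)
      if (length(unique(ex_of[tp])) == 1L &&
          off_of[tp[1L]] > 3L && off_of[tp[3L]] <= lens[ex_of[tp[1L]]] - 3L)
        valid <- c(valid, i)
    }
    if (length(valid) > 0L)
      return(list(lens = lens, sec_idx = valid[sample.int(length(valid), 1L)]))
  }
}

#' Generate a random Sec-containing gene prediction
#'
#' Geometry: 1-5 exons of 30-300 bp, introns of 50-500 bp, random strand,
#' Sec at a random internal codon fully inside one exon. Deterministic per
#' seed.
#'
#' @param seed Integer seed.
#' @param prediction_id,family Identifiers for the generated prediction.
#' @param chrom Chromosome name.
#' @param min_sec_index Smallest allowed Sec codon index (some
#'   perturbations need extra room upstream of the codon).
#' @return A [sec_prediction()] with a random protein sequence.
#' @export
random_sec_prediction <- function(seed, prediction_id = "pred1",
                                  family = "GPX", chrom = "chr1",
                                  min_sec_index = 2L) {
  .with_seed(seed, {
    geo <- .random_sec_prediction_geometry(min_sec_index)
    lens <- geo$lens
    n_ex <- length(lens)
    strand <- sample(c("+", "-"), 1L)
    introns <- if (n_ex > 1L) sample(50:500, n_ex - 1L, replace = TRUE)
               else integer(0)
    origin <- sample(1000:100000, 1L)
    ## genomic blocks in ascending order, then translation order by strand
    starts <- origin + c(0L, cumsum(lens[-n_ex] + introns))
    blocks <- data.frame(start = starts, end = starts + lens - 1L)
    if (strand == "-") {
      ## translation order is descending: the first exon (5') is the
      ## genomically last; reverse the length layout
      lens_g <- rev(lens)
      starts <- origin + c(0L, cumsum(lens_g[-n_ex] + rev(introns)))
      blocks <- data.frame(start = starts, end = starts + lens_g - 1L)
    }
    ncod <- sum(lens) %/% 3L
    sec_prediction(prediction_id, family, chrom, strand, blocks,
                   sec_protein_index = geo$sec_idx,
                   protein_seq = .random_protein(ncod, geo$sec_idx))
  })
}

## Blocks covering transcript positions from..to of a gene structure,
## returned in translation order.
.subset_blocks <- function(x, from, to) {
  pos <- cds_positions(x)[from:to]
  brk <- c(TRUE, abs(diff(pos)) != 1L)
  grp <- cumsum(brk)
  blocks <- do.call(rbind, lapply(split(pos, grp), function(p)
    data.frame(start = min(p), end = max(p))))
  rownames(blocks) <- NULL
  blocks
}

#' Generate one assessment case with a known target status
#'
#' Builds a random prediction ([random_sec_prediction()]) and a database
#' transcript perturbed so that, by construction, the pair's transcript
#' status (or the prediction's gene status for `"ABSENT"`) equals
#' `target`:
#' * `WELL_ANNOTATED` — identical structure with a 3' extension.
#' * `STOP_CODON` — CDS truncated at the Sec codon (stop-included
#'   dialect) or one base before it (stop-excluded), chosen by seed.
#' * `UPSTREAM` / `DOWNSTREAM` — CDS truncated to strictly before / after
#'   the Sec codon.
#' * `SKIPPED` — the Sec codon excised, flanking CDS kept as two exons.
#' * `OUT_OF_FRAME` — entire structure shifted by +1 base.
#' * `SPLICED` — the Sec exon split by a new intron directly after the
#'   first Sec codon base.
#' * `ABSENT` — same structure on another chromosome.
#'
#' @param target One of the seven transcript statuses or `"ABSENT"`.
#' @param seed Integer seed.
#' @return A list of class `assessment_case`: `intended_status`,
#'   `prediction`, `annotation` (list of transcripts), `seed`.
#' @export
make_assessment_case <- function(target, seed) {
  statuses <- c(transcript_status_levels(), "ABSENT")
  if (!target %in% statuses)
    stop("make_assessment_case: unknown target label '", target, "'")
  pred <- random_sec_prediction(
    seed, min_sec_index = if (target == "UPSTREAM") 3L else 2L)
  tx <- .with_seed(seed + 10000L, .perturb_for_target(pred, target, seed))
  structure(list(intended_status = target, prediction = pred,
                 annotation = list(tx), seed = seed),
            class = "assessment_case")
}

.perturb_for_target <- function(pred, target, seed) {
  total <- coding_length(pred)
  sec_idx <- pred$sec_protein_index
  span <- pred$sec_codon
  mk <- function(blocks, chrom = pred$chrom, stop_included = NA,
                 phases = NULL)
    annotated_transcript("t1", "g1", chrom, pred$strand, blocks,
                         phases = phases, stop_included = stop_included)
  switch(target,
    WELL_ANNOTATED = {
      b <- pred$cds_blocks
      last <- nrow(b)
      ext <- 3L * sample(5:15, 1L)
      if (pred$strand == "+") b$end[last] <- b$end[last] + ext
      else b$start[last] <- b$start[last] - ext
      mk(b, stop_included = FALSE)
    },
    STOP_CODON = {
      included <- seed %% 2L == 0L
      end_tpos <- if (included) 3L * sec_idx else 3L * (sec_idx - 1L)
      mk(.subset_blocks(pred, 1L, end_tpos), stop_included = included)
    },
    UPSTREAM = {
      ## end >= 1 full codon before the Sec codon, so the stop-excluded
      ## "ends precisely at the Sec UGA" rule can never fire
      end_tpos <- 3L * (sec_idx - 1L - sample.int(sec_idx - 2L, 1L))
      mk(.subset_blocks(pred, 1L, end_tpos))
    },
    DOWNSTREAM = {
      start_tpos <- 3L * sec_idx + 1L
      blocks <- .subset_blocks(pred, start_tpos, total)
      mk(blocks, phases = derive_phases(blocks, 0L))
    },
    SKIPPED = {
      pre <- .subset_blocks(pred, 1L, 3L * (sec_idx - 1L))
      post <- .subset_blocks(pred, 3L * sec_idx + 1L, total)
      mk(rbind(pre, post))
    },
    OUT_OF_FRAME = {
      b <- pred$cds_blocks
      b$start <- b$start + 1L
      b$end <- b$end + 1L
      mk(b)
    },
    SPLICED = {
      s1_tpos <- 3L * (sec_idx - 1L) + 1L
      pre <- .subset_blocks(pred, 1L, s1_tpos)
      post <- .subset_blocks(pred, s1_tpos + 4L, total)  # drop 3 bases
      mk(rbind(pre, post))
    },
    ABSENT = mk(pred$cds_blocks, chrom = paste0(pred$chrom, "_alt"))
  )
}

#' Generate a synthetic family dataset for orthology benchmarking
#'
#' Evolves a random ancestor protein into `n_subfamilies` founders
#' (per-site substitution probability `p_between`), then derives anchor
#' representatives and candidates from each founder (per-site probability
#' `p_within`). Substitution-only evolution means the true alignment is
#' column-identical, so the generator's labels are an exact oracle.
#'
#' @param n_subfamilies Number of subfamilies.
#' @param n_candidates Total number of labelled candidates.
#' @param p_within Per-site substitution probability founder -> member.
#' @param p_between Per-site substitution probability ancestor -> founder;
#'   must exceed `p_within`.
#' @param length Protein length (alignment columns).
#' @param seed Integer seed.
#' @param n_representatives Anchor rows per subfamily.
#' @return A list of class `family_dataset`: `anchor`
#'   ([anchor_alignment()]), `candidates` (named character vector),
#'   `truth` (named subfamily labels), and `params`.
#' @export
make_family_dataset <- function(n_subfamilies = 4L, n_candidates = 200L,
                                p_within = 0.10, p_between = 0.35,
                                length = 120L, seed = 1L,
                                n_representatives = 3L) {
  if (!(p_within >= 0 && p_within < p_between && p_between <= 1))
    stop("make_family_dataset: need 0 <= p_within < p_between <= 1")
  .with_seed(seed, {
    mutate <- function(aa, p) {
      hit <- stats::runif(base::length(aa)) < p
      if (any(hit))
        aa[hit] <- vapply(aa[hit], function(a)
          sample(setdiff(.AA20, a), 1L), "")
      aa
    }
    anc <- sample(.AA20, length, replace = TRUE)
    subs <- sprintf("sub%02d", seq_len(n_subfamilies))
    founders <- lapply(subs, function(s) mutate(anc, p_between))
    names(founders) <- subs
    rep_ids <- character(0); rep_sub <- character(0); rep_seq <- character(0)
    for (s in subs) for (r in seq_len(n_representatives)) {
      rep_ids <- c(rep_ids, sprintf("%s_rep%d", s, r))
      rep_sub <- c(rep_sub, s)
      rep_seq <- c(rep_seq, paste(mutate(founders[[s]], p_within),
                                  collapse = ""))
    }
    anchor <- anchor_alignment(rep_ids, rep_sub, rep_seq,
                               lineage = rep("vertebrates",
                                             base::length(rep_ids)))
    truth <- subs[1L + (seq_len(n_candidates) - 1L) %% n_subfamilies]
    cand <- vapply(seq_len(n_candidates), function(i)
      paste(mutate(founders[[truth[i]]], p_within), collapse = ""), "")
    ids <- sprintf("cand%03d", seq_len(n_candidates))
    names(cand) <- ids
    names(truth) <- ids
    structure(list(anchor = anchor, candidates = cand, truth = truth,
                   params = list(n_subfamilies = n_subfamilies,
                                 n_candidates = n_candidates,
                                 p_within = p_within,
                                 p_between = p_between,
                                 length = length, seed = seed)),
              class = "family_dataset")
  })
}

#' Generate a lineage-filter scenario with its expected partition
#'
#' Emits a toy expectation table and score-ranked predictions whose
#' correct kept / filtered-out / missing partition is computed here by the
#' independent sort-and-slice rule (rank per subfamily by descending
#' score, tie-break on id, keep the top `expected` entries; subfamilies
#' absent from the table are kept as unexpected).
#'
#' @param expected_counts Named integer vector: expected genes per
#'   subfamily.
#' @param predicted_counts Named integer vector: generated predictions per
#'   subfamily (names may differ from `expected_counts`).
#' @param seed Integer seed.
#' @param lineage Lineage label used in the table.
#' @return A list of class `lineage_scenario`: `table`
#'   (an `expectation_table`), `assigned` (data frame `prediction_id`,
#'   `subfamily`, `score`), and `expected` (list `kept`, `filtered_out`,
#'   `missing`).
#' @export
make_lineage_scenario <- function(expected_counts, predicted_counts, seed,
                                  lineage = "placentals") {
  stopifnot(all(expected_counts >= 0), all(predicted_counts >= 0))
  .with_seed(seed, {
    tab <- load_expectation_table(data.frame(
      lineage = lineage,
      subfamily = names(expected_counts),
      expected_count = as.integer(expected_counts)))
    rows <- list()
    i <- 0L
    for (sf in names(predicted_counts)) {
      n <- predicted_counts[[sf]]
      if (n == 0L) next
      ids <- sprintf("p%03d", i + seq_len(n))
      i <- i + n
      rows[[sf]] <- data.frame(prediction_id = ids, subfamily = sf,
                               score = round(stats::runif(n), 6))
    }
    assigned <- if (length(rows)) do.call(rbind, rows) else
      data.frame(prediction_id = character(0), subfamily = character(0),
                 score = numeric(0))
    rownames(assigned) <- NULL
    ## independent sort-and-slice oracle
    kept <- character(0); filtered <- character(0)
    missing <- stats::setNames(integer(0), character(0))
    all_sf <- union(names(expected_counts), unique(assigned$subfamily))
    for (sf in all_sf) {
      rr <- assigned[assigned$subfamily == sf, , drop = FALSE]
      rr <- rr[order(-rr$score, rr$prediction_id), , drop = FALSE]
      if (!sf %in% names(expected_counts)) {
        kept <- c(kept, rr$prediction_id)  # unexpected: kept, flagged
        next
      }
      n_exp <- expected_counts[[sf]]
      n_keep <- min(n_exp, nrow(rr))
      kept <- c(kept, utils::head(rr$prediction_id, n_keep))
      filtered <- c(filtered, utils::tail(rr$prediction_id,
                                          nrow(rr) - n_keep))
      if (nrow(rr) < n_exp) missing[sf] <- n_exp - nrow(rr)
    }
    structure(list(table = tab, assigned = assigned,
                   expected = list(kept = sort(kept),
                                   filtered_out = sort(filtered),
                                   missing = missing)),
              class = "lineage_scenario")
  })
}

#' Write a complete toy dataset to disk
#'
#' Generates a small end-to-end dataset (predictions GFF + protein FASTA,
#' database GTF, anchor FASTA, expectation CSV, species-lineage TSV) whose
#' files are consumable verbatim by the assess, orthology and lineage
#' front-ends. Byte-identical for identical seeds.
#'
#' @param dir Output directory (created if needed).
#' @param seed Integer seed.
#' @param n_predictions Number of predictions to generate.
#' @return Named character vector of the file paths written.
#' @export
write_fixture_files <- function(dir, seed = 1L, n_predictions = 8L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  statuses <- c(transcript_status_levels(), "ABSENT")
  fam <- make_family_dataset(n_subfamilies = 3L, n_candidates = 0L,
                             p_within = 0.05, p_between = 0.35,
                             length = 80L, seed = seed)
  preds <- list(); txs <- list(); prots <- character(0)
  subs <- unique(fam$anchor$subfamily)
  founder_of <- function(sf) {
    gsub("-", "", fam$anchor$seqs[fam$anchor$subfamily == sf][1L],
         fixed = TRUE)
  }
  base <- as.integer(seed) %% 1000000L  # derived seeds stay in int range
  for (i in seq_len(n_predictions)) {
    target <- statuses[1L + (i - 1L) %% length(statuses)]
    case <- make_assessment_case(target, base * 1000L + i)
    p <- case$prediction
    p$prediction_id <- sprintf("pred%02d", i)
    sf <- subs[1L + (i - 1L) %% length(subs)]
    p$family <- "FAM"
    tx <- case$annotation[[1L]]
    tx$transcript_id <- sprintf("t%02d", i)
    tx$gene_id <- sprintf("g%02d", i)
    ## keep each case on its own chromosome so cases never cross-match
    p$chrom <- sprintf("chr%d", i)
    tx$chrom <- if (target == "ABSENT") sprintf("chr%d_alt", i)
                else sprintf("chr%d", i)
    preds[[i]] <- p
    txs[[i]] <- tx
    prots[p$prediction_id] <- founder_of(sf)
  }
  paths <- c(
    predictions = file.path(dir, "predictions.gff"),
    proteins = file.path(dir, "predictions.fa"),
    annotation = file.path(dir, "annotation.gtf"),
    anchor = file.path(dir, "family.anchor.fa"),
    expectations = file.path(dir, "expectation_table.csv"),
    species = file.path(dir, "species_lineage.tsv"))
  write_gtf(preds, dialect = "gff3", file = paths[["predictions"]])
  writeLines(paste0(">", names(prots), "\n", prots), paths[["proteins"]])
  write_gtf(txs, dialect = "gtf", file = paths[["annotation"]])
  write_anchor_fasta(fam$anchor, paths[["anchor"]])
  utils::write.csv(data.frame(
    lineage = "placentals", subfamily = subs,
    expected_count = rep(2L, length(subs))),
    paths[["expectations"]], row.names = FALSE, quote = FALSE)
  utils::write.table(data.frame(
    species = c("Mus musculus", "Homo sapiens", "Danio rerio"),
    lineage = c("placentals", "placentals", "fish")),
    paths[["species"]], sep = "\t", row.names = FALSE, quote = FALSE)
  paths
}
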