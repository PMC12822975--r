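---
title: "Assessing selenoprotein gene annotations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Assessing selenoprotein gene annotations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(selannot)
```

## The problem

Selenoproteins incorporate selenocysteine (Sec, the 21st amino acid) at an
in-frame UGA codon. Because UGA normally terminates translation, gene
annotation pipelines that are not Sec-aware systematically mishandle these
genes: they truncate the coding sequence at the Sec UGA, annotate only the
region downstream of it, skip the exon containing it, or shift to a
different reading frame. `selannot` provides the machinery to measure this:
given a set of Sec-aware gene predictions (with known Sec codon positions)
and a database annotation (GTF/GFF), it classifies every annotation into a
defined status taxonomy, assigns predicted proteins to subfamilies, and
filters predicted selenoproteomes against lineage-level gene-count
expectations.

## The annotation-status taxonomy

A prediction and a database transcript form a candidate pair when their CDS
blocks overlap by at least one base on the same chromosome **and the same
strand**. Each pair receives exactly one transcript-level status:

| status | defining condition |
|---|---|
| `WELL_ANNOTATED` | all 3 Sec codon bases coding, same frame, codon not terminal |
| `STOP_CODON` | the transcript's translation ends exactly at the Sec UGA |
| `UPSTREAM` | in-frame coding overlap only 5' of the Sec codon |
| `DOWNSTREAM` | in-frame coding overlap only 3' of the Sec codon |
| `SKIPPED` | in-frame coding on both sides, codon itself not coding |
| `OUT_OF_FRAME` | no position of the CDS intersection shares the frame |
| `SPLICED` | an intron boundary inside the Sec codon where the prediction has none |

All 5'/3' language is in translation order (mRNA sense), not genomic order;
on the minus strand CDS blocks are therefore stored by descending genomic
coordinate. At gene level, a prediction with no overlapping transcript is
`ABSENT`, one with at least one well-annotated pair is `WELL_ANNOTATED`,
and anything else is a `MISANNOTATION`. Proteins with several Sec residues
(SELENOP, SELENOL) are assessed on their first Sec only; the remaining Sec
residues sit in poorly conserved C-terminal tails and would make the status
ill-defined.

### Precedence and edge cases

The classes above can co-occur structurally (a frame-shifted transcript may
also end at the Sec codon). The classifier applies a fixed precedence —
`OUT_OF_FRAME`, `SPLICED`, `WELL_ANNOTATED`, `STOP_CODON`, `SKIPPED`,
`UPSTREAM`/`DOWNSTREAM` — checking structural incompatibilities before
positional ones, so every pair gets exactly one label. Three deliberate
choices:

* *Frame agreement is positional, not global.* A single base of the CDS
  intersection coding in the same frame in both structures is enough to
  escape `OUT_OF_FRAME`. Exon-level frames can legitimately differ while
  the Sec region matches.
* *Both stop-codon dialects are accepted.* Ensembl-style GTFs exclude the
  terminal stop from the CDS; some GenBank submissions include it.
  `STOP_CODON` therefore fires either when the transcript's final CDS codon
  occupies exactly the Sec positions, or when its CDS ends at the base
  immediately 5' of the Sec codon with the codon as the next in-frame
  triplet.
* *A splice site inside the Sec codon is always a misannotation.* Even if
  the spliced product could still encode UGA, the annotated gene structure
  differs from the prediction at the codon itself, so such pairs are
  `SPLICED`, never `WELL_ANNOTATED`.

One corner is not covered by the defining conditions: an in-frame overlap
confined to a *partial* Sec codon with no flanking coding sequence. The
classifier resolves it deterministically (`UPSTREAM` if the transcript's
CDS ends within the codon, else `DOWNSTREAM`); the fixture generator never
produces it, and we have not observed a real annotation shaped this way.

## Subfamily assignment by AWSI

Families such as GPX or DIO contain several paralogous subfamilies
predicted by a single profile. `selannot` assigns predictions to
subfamilies without tree building, using a fixed reference ("anchor")
alignment whose rows carry subfamily labels:

1. **Column weights.** For column $c$ of the anchor,
   $w_c = \max_a n_{c,a} / N$, where $n_{c,a}$ counts the most frequent
   non-gap character and $N$ is the total row count. Fully conserved
   gap-free columns weigh 1; all-gap columns weigh 0. Using the total row
   count in the denominator (rather than the non-gap count) makes gappy
   columns count less even when their residues agree — gaps dilute
   conservation.
2. **Placement.** The candidate is aligned into the anchor's fixed column
   space by a profile-to-sequence Needleman–Wunsch: position-specific
   residue frequencies scored through BLOSUM62 (Sec scored via the Cys
   column), affine gaps (open 11, extend 1), deletion costs scaled by
   column occupancy, and free terminal deletions so that fragment
   candidates are not penalised for anchor span they do not cover.
   Candidate residues that would require new columns are dropped without
   penalty: anchor columns are the fixed coordinate system, and scoring
   insertions would entangle the similarity score with the aligner's gap
   model.
3. **AWSI.** For the placed candidate $x$ and each anchor row $y$, the
   average weighted sequence identity is
   $\mathrm{AWSI}(x,y) = \sum_c w_c [x_c = y_c] \,/\, \sum_c w_c$
   over columns where neither sequence is gapped. The per-subfamily score
   is the arithmetic mean over that subfamily's rows — the mean is robust
   to unequal representative counts — and the candidate is assigned to the
   argmax, ties broken lexicographically with the best-minus-second margin
   reported so callers can detect ambiguity.

Anchors are built from labelled alignments by greedy maximal-diversity
reduction: per (subfamily, lineage) group, first the two most dissimilar
rows, then repeatedly the row whose maximum identity to the chosen set is
smallest, up to `k = 12` representatives (the default anchor size; 4 and 8
are supported by the same parameter).

## Lineage-expectation filtering

Vertebrate selenoproteome composition is strongly lineage-dependent, so
extra gene copies are usually pipeline artifacts (pseudogenes, split
predictions). Given a table of expected counts per (lineage, subfamily)
and the species' lineage (explicit override, or a lookup in a packaged
editable species→lineage TSV — no taxonomy service is consulted, keeping
the tool fully offline), predictions in each subfamily are ranked by their
AWSI score to the assigned subfamily and only the top $N$ are kept, where
$N$ is the expected count. Shortfalls are reported as *missing* with their
deficit. Two deliberate choices:

* Score ties at the keep/cut boundary are broken by prediction id
  (determinism) and flagged in the report.
* Subfamilies predicted but absent from the lineage's table rows are kept
  and flagged `unexpected`, never silently dropped: a fixed expectation
  table cannot anticipate lineage-specific duplications, and deleting
  surprising genes would hide exactly the discoveries worth inspecting.

The filter conserves its input (kept plus filtered-out partition the
predictions), is idempotent, and is monotone in the expected counts; the
test suite asserts all three.

## The synthetic-fixture generator

All tests and the acceptance script run on generated data with known
ground truth; no downloads are involved.

* **Assessment cases** invert the taxonomy: a random prediction (1–5 exons
  of 30–300 bp, introns of 50–500 bp, Sec at a random internal codon lying
  fully inside one exon) is paired with a perturbed copy that satisfies one
  target status by construction — truncation at (or before) the Sec codon,
  codon excision, a +1 shift of every block, a new intron opened inside
  the codon, a 3' extension, or relocation to another chromosome. The exon
  and intron ranges are arbitrary fixed defaults chosen to cover single-
  and multi-exon geometry on both strands; they are configurable and
  nothing downstream depends on them.
* **Family datasets** evolve a random ancestor protein into subfamily
  founders (per-site substitution probability `p_between = 0.35`) and then
  members (`p_within = 0.10`), with no indels, so the true alignment is the
  identity mapping and the generator's labels are an exact oracle. At these
  defaults the residue identity is ≈0.82 within a subfamily versus ≈0.36
  between — a generous separation chosen so that assignment accuracy
  measures the correctness of the scoring machinery, not borderline
  statistical power.
  Indel realism is deliberately sacrificed for an exact oracle; the aligner
  is additionally exercised on anchors with gap columns inserted post hoc.
* **Lineage scenarios** pair random expected/predicted counts with scores
  and carry their own sort-and-slice partition as the expected answer.

Passing these tests shows the implementation is internally consistent and
matches its stated rules exactly; it does not certify performance on real
genomes, where annotation dialects are messier (partial transcripts,
shared exons across genes, non-canonical phases) and where protein
divergence includes indels and domain gain/loss.

## Problem sizes and numerical choices

The default verification runs use 400 assessment cases (8 labels × 50
seeds), 1,000 random AWSI pairs checked against a naive per-column oracle
at 10⁻¹², a 200-candidate × 4-subfamily recovery benchmark at the default
divergences, 100 lineage scenarios, 1,000 frame-computation checks, and a
100-document I/O round-trip — sizes chosen so the full suite completes in
about a minute on one core while still exercising every code path many
times. AWSI needs no tolerance machinery beyond double arithmetic; the
only tie-breaks in the package (assignment argmax, lineage boundary ties,
representative selection) are all lexicographic/first-index and therefore
deterministic. Degenerate inputs have defined behaviour rather than
errors where a value can be meaningful: AWSI with no shared non-gap column
is `NA`, a candidate with undefined AWSI against every row is
"unassignable", and an empty prediction set yields empty reports.

## Known limitations

* The assessor compares gene structures only; it never validates the
  underlying genome sequence (no check that the Sec codon is actually TGA
  in the assembly).
* Database *gene* records are ignored: transcripts are classified
  individually and aggregated per prediction, so a prediction spanning two
  annotated genes aggregates all their transcripts.
* The AWSI weight normalisation (total row count) and the treatment of
  candidate insertions (dropped, unpenalised) are this package's explicit
  conventions; other tools in this space may differ in either choice.
* The shipped species→lineage mapping and the toy expectation table cover
  test needs only; real analyses should supply curated tables.
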