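---
title: "Curating coral skeletal proteomes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Curating coral skeletal proteomes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coralsom)
```

## The curation problem

Skeletal organic matrix proteins (SOMPs) are occluded inside the aragonite
skeleton of stony corals at trace levels. After demineralisation,
purification and LC–MS/MS, a search engine assigns spectra to peptides and
peptides to proteins; what comes out is over-inclusive in two specific
ways. First, low-evidence identifications: a single weak peptide can place
a protein on the list. Second, human contamination introduced during
bench work: keratins and other handling proteins pass the search because
they are genuinely present in the sample, and a search-time contaminant
database does not catch entries that align well to real coral gene models.
`coralsom` encodes the downstream curation as explicit, testable rules and
keeps every decision in a machine-readable run report.

The pipeline stages, in order: load and validate inputs → contaminant
screen → evidence filter (per-fraction detection matrix) → method/fraction
set summaries → export and functional classification → orthology overlap
with an exact enrichment tail. The screen runs before the evidence filter;
both are per-protein predicates, so the order cannot change the curated
set — the test suite asserts this commutativity rather than assuming it.

## Evidence acceptance

Within one (method, solubility) cell a protein is accepted iff it has at
least `min_significant_peptides = 2` distinct significant peptide
sequences, or at least one significant peptide carried by
`alt_min_spectra = 10` or more spectra with an identification score of
`alt_min_score = 250` or more. Three readings had to be fixed:

* **"Peptides" are distinct sequences, not spectra.** The rule's second
  branch switches explicitly to spectra; counting repeated spectra of one
  peptide as two peptides would collapse the two branches into one.
* **The score is taken per evidence row.** Search engines differ on
  whether scores are peptide- or protein-level; consuming the value on the
  row keeps the rule local and testable, and protein-level scores are
  simply replicated across rows by the table producer.
* **Acceptance is evaluated within a fraction, and spectra are never
  summed across fractions.** Per-fraction presence is what the detection
  matrix reports, so the evidence for a cell must stand on its own. This
  is the conservative reading; the run report records
  `spectra_rule_scope: within-fraction` so users can see which convention
  produced their numbers.

Acceptance is monotone by construction: raising any spectra count or
score, or flipping a peptide to significant, can only add detections. A
randomized perturbation suite (1,000 cases) checks this, and small random
evidence sets are compared row-for-row against a naive double-loop
restatement of the rule.

## Contaminant screening

Screening is two-staged, mirroring how such filtering is actually done:
alignment statistics nominate candidates, and an exact shared-peptide rule
decides removal.

A protein is a **candidate** when any hit against the contaminant (human)
proteome satisfies, with strict inequalities, e-value < 1e-50 together
with similarity > 50%, or e-value < 1e-100, or similarity > 80%. Strictness
matters only on a measure-zero boundary but is pinned down and tested so
the behaviour at printed threshold values is never platform- or
implementation-dependent.

A candidate is **removed** only when ≥ 3 identical peptides of ≥ 7
residues are shared with a *single* contaminant protein. Matching is exact
substring matching on uppercase sequences — no isobaric I/L folding,
because the rule is about identity, not mass-spectrometric
distinguishability. Counts are never pooled across contaminant subjects:
three peptides spread over two human proteins do not justify removal,
since the rationale is that one specific human protein could explain the
coral identification.

Two peptide sources are supported. The default uses the MS-observed
peptides from the evidence table — the entities the pipeline actually has,
and the conservative choice. A fallback mode digests the target sequence
in silico (fully tryptic: cleave after K/R except before P, no missed
cleavages) for proteins lacking observed peptides. The mode is recorded in
every verdict row. Percent similarity is taken from BLAST's positives
column (`ppos`) when a 13th column is present, else percent identity as a
conservative proxy; the source column travels into the run report. Both
choices exist because upstream tools report "similarity" ambiguously;
making them explicit is the only reproducible option. Similarity is
evaluated per hit (per HSP), not averaged across HSPs.

## Set summaries

"Detected by a method" means detected in either solubility fraction of
that method; protocol families pool CF = {CF2, CF4} and ACT = {ACT1,
ACT3}. Venn region counts over 2–4 named sets are computed by membership
patterns and verified against per-element brute-force tallies (10,000
random instances in the acceptance suite). Percentages are reported to one
decimal place with half-away-from-zero rounding, the convention used when
such overlap percentages are quoted in print; base R's round-half-even
would turn 8.35 into 8.3. Inclusion–exclusion is asserted on every
reported pair.

## Export and functional classification

Export classification combines externally predicted flags — it never
predicts signal peptides, transmembrane spans or GPI anchors itself. A
signal peptide only counts when the gene model is complete at the
N-terminus: on fragmentary gene models the predictor is necessarily
silent, and counting raw SP flags would conflate prediction absence with
biological absence. The raw flag is still reported. `ecm_evidence` (SP or
TM or GPI) versus `non_classical_candidate` partitions the proteome; the
latter names proteins that, if genuinely skeletal, must leave the cell by
routes such as exosomes or other non-classical secretion.

The five functional categories (membrane processing; ECM/transmembrane;
metal binding; vesicular/secretion; protein modification) are assigned by
an explicit rule map: exact GO-identifier matches plus case-insensitive
keyword patterns over the description. No published per-protein rule list
exists for this grouping, so the package ships an editable default and
pins its MD5 hash into every report — two runs are comparable only when
their map hashes agree. Multi-assignment is expected and each protein
increments a category at most once.

## Orthology overlap and the chance argument

Ortholog pairs (any multiplicity, including BLASTP best hits for entries
absent from the orthogroup reference) are consumed from a table; per
published proteome the curated members with ≥ 1 ortholog are collected,
plus their union and intersection. The claim that the observed overlap
exceeds chance is made precise as an exact upper tail: binomial
P(X ≥ k | n, p) when the background is a proportion (default p = 0.002,
the ceiling for known skeletal matrix proteins in reference coral
proteomes), hypergeometric when counts (K, N) are known. Both are exact —
no normal approximation — and are verified against an independent
log-space summation oracle for every n ≤ 100 and against frozen
60-digit arbitrary-precision values. The two models agree to < 1e-6 in
the vanishing-sampling-fraction limit; at moderate background proportions
this requires N of order 10^6 × n, which the test uses.

For the shipped published tables (60 curated proteins, 16 with orthologs,
p = 0.002) the tail is ≈ 9.0e-30 — the "significantly greater than
chance" claim holds with enormous margin under any reasonable background.

## The synthetic generator

`generate_bundle()` writes a complete input bundle — target and
contaminant FASTA, evidence, alignment, annotation and ortholog tables —
with a ground-truth manifest. Its defaults are the study conditions used
throughout the tests: 12 true skeletal proteins, 3 contaminant-like plants
(each sharing three 9-residue peptides with its paired human-like entry at
e-value 1e-110 and 85% similarity — strictly inside the removal margins),
5 sub-threshold plants (one significant peptide at 9 spectra — strictly
below the alternative branch), ~300-residue backbones, and a 0.3
per-cell detection probability with at least one detection guaranteed.
Margins are strict on purpose: plants sit unambiguously inside or outside
every threshold so that recovery must be exactly 100%, making any
deviation a bug rather than a tie-break.

Random sequences are i.i.d. over the 20 standard residues with K/R
frequency boosted threefold so backbones digest into usable tryptic
peptides; planted e-values and similarities are written directly into the
alignment table (the screen consumes tabular statistics by contract —
simulating an aligner would test the aligner, not the screen). All
randomness flows from one integer seed; identical config and seed give
byte-identical files, which the pipeline's own determinism test relies on.

`published_shape_bundle()` plants an explicit 60-protein detection structure
with combined-CF 52, combined-ACT 13 (5 shared), ISOM 57 / SSOM 8 (5
both), per-method exclusives 12/16/1/5, orthologs 16 with 7 in all three
prior proteomes, export classes 17 SP / 8 TM / 10 GPI (25 with ECM
evidence) and 39 categorized proteins tallying 10/19/25/21/12. These are
planted set *structures*, not simulations: the bundle shows the pipeline
reproduces the arithmetic of the published comparison, not that it would
recover it from raw spectra.

What the generator does **not** emulate: spectra, mass accuracy, retention
time, peptide detectability bias, degradation-induced length distributions
or shared-peptide ambiguity between paralogs. Passing on synthetic bundles
therefore demonstrates rule correctness and end-to-end bookkeeping, not
robustness to search-engine pathologies.

## Degenerate inputs and numerical choices

Empty FASTA and empty evidence tables are warnings, not errors — an empty
curated proteome is a valid (if disappointing) result, and the run report
then carries all-zero counts. Candidate tie-breaks (several hits
satisfying the screen) select the smallest e-value, then highest
similarity, then lexicographic subject accession, so verdicts are
deterministic. All output tables are sorted by ascending accession: files
are a pure function of content, never of input order. k = 0 gives an
enrichment tail of exactly 1; p = 1 is admitted as the degenerate-certainty
edge. Percentages against an empty denominator are NA rather than 0,
keeping "nothing to report" distinct from "0%".

A known wrinkle in the shipped published table: its per-protein solubility
marks tally to 7 SSOM / 59 ISOM / 6 both, while the headline per-fraction
totals (57/8/5) come from the per-method assignment data. The package
reports whatever table it is given and never reconciles the two silently;
the fraction-structure checks therefore run on the planted bundle, whose
structure follows the headline totals, while the published table backs the
curated-total and orthology counts.

## Problem sizes in the test suite

The suite uses 1,000 monotonicity perturbations for the evidence rule,
200 random target/contaminant pairs against the substring oracle, 10,000
random Venn instances over ≤ 4 sets, the full n ≤ 100 grid for the
enrichment oracle, and 60-protein bundles end to end — sizes chosen so the
whole suite exercises every rule at realistic scale while remaining a
few-minute run on a laptop.

## Limitations

The package consumes, and does not compute, search-engine significance,
alignments and their statistics, and SP/TM/GPI/completeness predictions;
garbage in any of those propagates. The default category map is a
documented starting point, not a validated ontology mapping — studies
should curate it and report its hash. The shared-peptide rule uses exact
identity; true isobaric ambiguity (I/L) is deliberately out of scope of
the removal decision.
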