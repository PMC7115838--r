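# Cross-species (human) contaminant exclusion: alignment-statistic candidate
# flagging followed by the exact shared-peptide removal rule. A protein is a
# removal candidate when any of its alignment hits against the contaminant
# proteome satisfies (e-value < 1e-50 AND similarity > 50%) OR
# (e-value < 1e-100) OR (similarity > 80%), all strict; it is removed only if
# it additionally shares >= 3 identical peptides of >= 7 residues with a
# single contaminant protein.

#' Contaminant-screen thresholds
#'
#' @param pair_evalue_max,pair_similarity_min First candidate branch:
#'   e-value strictly below 1e-50 together with percent similarity strictly
#'   above 50.
#' @param strong_evalue_max Second branch: e-value strictly below 1e-100.
#' @param strong_similarity_min Third branch: percent similarity strictly
#'   above 80.
#' @param min_shared_peptides Identical peptides required for removal
#'   (default 3), all against one single contaminant protein.
#' @param min_peptide_length Minimum peptide length counted (default 7).
#' @return An object of class `contaminant_thresholds`.
#' @export
contaminant_thresholds <- function(pair_evalue_max = 1e-50,
                                   pair_similarity_min = 50,
                                   strong_evalue_max = 1e-100,
                                   strong_similarity_min = 80,
                                   min_shared_peptides = 3L,
                                   min_peptide_length = 7L) {
  out <- list(
    pair_evalue_max = check_number(pair_evalue_max, "pair_evalue_max", 0),
    pair_similarity_min = check_number(pair_similarity_min,
                                       "pair_similarity_min", 0, 100),
    strong_evalue_max = check_number(strong_evalue_max, "strong_evalue_max", 0),
    strong_similarity_min = check_number(strong_similarity_min,
                                         "strong_similarity_min", 0, 100),
    min_shared_peptides = check_count(min_shared_peptides,
                                      "min_shared_peptides", 1L),
    min_peptide_length = check_count(min_peptide_length,
                                     "min_peptide_length", 1L)
  )
  structure(out, class = "contaminant_thresholds")
}

hit_satisfies <- function(hits, th) {
  (hits$evalue < th$pair_evalue_max &
     hits$percent_similarity > th$pair_similarity_min) |
    hits$evalue < th$strong_evalue_max |
    hits$percent_similarity > th$strong_similarity_min
}

#' Flag a protein as a contamination candidate from its alignment hits
#'
#' @param hits Alignment hits for one protein (may have zero rows).
#' @param thresholds A [contaminant_thresholds()] object.
#' @return A list with `candidate` (logical) and `triggering_hit` (the
#'   satisfying hit with the smallest e-value, ties broken by highest
#'   similarity then lexicographic subject accession; `NULL` if not a
#'   candidate).
#' @export
flag_candidate <- function(hits, thresholds = contaminant_thresholds()) {
  if (!nrow(hits)) return(list(candidate = FALSE, triggering_hit = NULL))
  ok <- hit_satisfies(hits, thresholds)
  if (!any(ok)) return(list(candidate = FALSE, triggering_hit = NULL))
  sat <- hits[ok, , drop = FALSE]
  ord <- order(sat$evalue, -sat$percent_similarity, sat$subject_accession)
  list(candidate = TRUE, triggering_hit = sat[ord[1], , drop = FALSE])
}

#' In-silico fully tryptic digestion
#'
#' Cleaves after K or R except when the next residue is P; zero missed
#' cleavages. Used as the fallback peptide source when MS-observed peptides
#' are unavailable for a protein.
#'
#' @param sequence An uppercase amino-acid string.
#' @return Character vector of tryptic peptides in N- to C-order.
#' @export
tryptic_peptides <- function(sequence) {
  if (!nzchar(sequence)) return(character())
  marked <- gsub("([KR])(?!P)", "\\1\01", sequence, perl = TRUE)
  out <- strsplit(marked, "\01", fixed = TRUE)[[1]]
  out[nzchar(out)]
}

#' Count peptides shared verbatim with a contaminant protein
#'
#' Counts the distinct peptides of at least `min_length` residues that occur
#' as exact substrings of the contaminant sequence. Matching is exact on the
#' uppercase alphabet; isoleucine and leucine are distinct.
#'
#' @param target_peptides Character vector of the target protein's peptides
#'   (MS-observed, or in-silico tryptic in fallback mode).
#' @param contaminant A contaminant sequence string, or a one-row protein
#'   record with a `sequence` column.
#' @param min_length Minimum peptide length counted (default 7).
#' @return A list with `count` and `peptides` (the shared set, sorted).
#' @export
shared_peptides <- function(target_peptides, contaminant, min_length = 7L) {
  seqs <- if (is.character(contaminant)) contaminant else contaminant$sequence
  if (length(seqs) != 1L)
    contract_error("shared_peptides: exactly one contaminant sequence expected")
  peps <- unique(toupper(target_peptides))
  peps <- peps[nchar(peps) >= min_length]
  if (!length(peps)) return(list(count = 0L, peptides = character()))
  hit <- vapply(peps, function(p) grepl(p, seqs, fixed = TRUE), logical(1))
  shared <- sort(peps[hit])
  list(count = length(shared), peptides = shared)
}

#' Screen a candidate proteome for cross-species contaminants
#'
#' Two-stage exclusion: (1) alignment statistics flag candidates via
#' [flag_candidate()]; (2) a candidate is removed only when it shares at
#' least `min_shared_peptides` identical peptides of `min_peptide_length` or
#' more residues with at least one single aligned contaminant protein —
#' counts are never pooled across subjects. Non-candidates are retained
#' regardless of shared peptides, mirroring the two-stage procedure.
#'
#' @param proteins Character vector of candidate accessions (or a data.frame
#'   with an `accession` column).
#' @param evidence Peptide-evidence data.frame; a protein's observed peptide
#'   set is the distinct peptides over all its evidence rows.
#' @param hits Alignment-hit data.frame ([read_blast_tabular()]).
#' @param contaminant_db Contaminant protein data.frame
#'   ([read_protein_fasta()]); every hit subject must be present.
#' @param thresholds A [contaminant_thresholds()] object.
#' @param peptide_mode `"observed"` (default) uses MS-identified peptides;
#'   `"tryptic"` digests the target sequences in silico (requires
#'   `target_db`).
#' @param target_db Target protein data.frame, required for
#'   `peptide_mode = "tryptic"`.
#' @return A data.frame of verdicts: `accession`, `candidate`,
#'   `shared_peptide_count`, `removed`, `triggering_subject`,
#'   `peptide_mode`. `removed` implies `candidate`.
#' @export
screen_proteome <- function(proteins, evidence, hits, contaminant_db,
                            thresholds = contaminant_thresholds(),
                            peptide_mode = c("observed", "tryptic"),
                            target_db = NULL) {
  peptide_mode <- match.arg(peptide_mode)
  if (is.data.frame(proteins)) proteins <- proteins$accession
  proteins <- sort(unique(proteins))
  unknown <- setdiff(hits$subject_accession, contaminant_db$accession)
  if (length(unknown))
    csom_stop("coralsom_integrity_error",
              "alignment hit(s) reference unknown contaminant subject(s): %s",
              paste(unknown, collapse = ", "))
  if (peptide_mode == "tryptic" && is.null(target_db))
    config_error("peptide_mode 'tryptic' requires target_db")
  contaminant_seq <- contaminant_db$sequence
  names(contaminant_seq) <- contaminant_db$accession

  verdicts <- lapply(proteins, function(acc) {
    ph <- hits[hits$query_accession == acc, , drop = FALSE]
    flag <- flag_candidate(ph, thresholds)
    peps <- if (peptide_mode == "observed") {
      unique(evidence$peptide[evidence$protein_accession == acc])
    } else {
      seq <- target_db$sequence[target_db$accession == acc]
      if (length(seq) != 1L)
        csom_stop("coralsom_integrity_error",
                  "protein %s absent from target_db", acc)
      tryptic_peptides(seq)
    }
    shared_count <- 0L
    if (flag$candidate) {
      # triggering subject first, then every other aligned subject; removal
      # needs the threshold met against one single contaminant protein
      subjects <- unique(c(flag$triggering_hit$subject_accession,
                           ph$subject_accession))
      for (s in subjects) {
        n <- shared_peptides(peps, contaminant_seq[[s]],
                             thresholds$min_peptide_length)$count
        shared_count <- max(shared_count, n)
        if (shared_count >= thresholds$min_shared_peptides) break
      }
    }
    removed <- flag$candidate &&
      shared_count >= thresholds$min_shared_peptides
    data.frame(accession = acc, candidate = flag$candidate,
               shared_peptide_count = shared_count, removed = removed,
               triggering_subject = if (flag$candidate)
                 flag$triggering_hit$subject_accession else NA_character_,
               peptide_mode = peptide_mode, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(verdicts,
                          list(make.row.names = FALSE, stringsAsFactors = FALSE)))
  if (!is.data.frame(out))
    out <- data.frame(accession = character(), candidate = logical(),
                      shared_peptide_count = integer(), removed = logical(),
                      triggering_subject = character(),
                      peptide_mode = character(), stringsAsFactors = FALSE)
  stopifnot(all(!out$removed | out$candidate))
  out
}

#' @rdname screen_proteome
#' @param verdicts A verdict data.frame from [screen_proteome()].
#' @param path Output TSV path.
#' @export
write_screen_verdicts <- function(verdicts, path) {
  write_tsv(verdicts[order(verdicts$accession), , drop = FALSE], path)
}
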