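# Protein acceptance rule and detection-matrix construction.
#
# A protein is accepted within one (method, solubility) fraction when its
# peptide evidence there contains at least two distinct significant peptides,
# or at least one significant peptide backed by >= 10 spectra with an
# identification score of 250 or more. Acceptance is evaluated per fraction:
# presence in a fraction requires the rule to pass within that fraction, and
# spectra are never summed across fractions.

#' Evidence-rule thresholds
#'
#' @param min_significant_peptides Distinct significant peptide sequences
#'   required by the first branch (default 2).
#' @param alt_min_spectra Spectra required by the single-peptide branch
#'   (default 10).
#' @param alt_min_score Identification score required by the single-peptide
#'   branch (default 250).
#' @return An object of class `evidence_thresholds`.
#' @export
evidence_thresholds <- function(min_significant_peptides = 2L,
                                alt_min_spectra = 10L,
                                alt_min_score = 250) {
  out <- list(
    min_significant_peptides = check_count(min_significant_peptides,
                                           "min_significant_peptides", 1L),
    alt_min_spectra = check_count(alt_min_spectra, "alt_min_spectra", 1L),
    alt_min_score = check_number(alt_min_score, "alt_min_score", min = 0)
  )
  structure(out, class = "evidence_thresholds")
}

#' Apply the protein acceptance rule within one fraction
#'
#' @param evidence Peptide-evidence rows for a single protein in a single
#'   (method, solubility) fraction.
#' @param thresholds An [evidence_thresholds()] object.
#' @return `TRUE` if the protein is accepted in this fraction.
#' @examples
#' ev <- data.frame(protein_accession = "P1", peptide = c("AAAAAAAK", "CCCCCCCK"),
#'                  spectra_count = 1L, significant = TRUE, score = 50,
#'                  method = "CF2", solubility = "ISOM")
#' accept_protein(ev)  # two distinct significant peptides
#' @export
accept_protein <- function(evidence, thresholds = evidence_thresholds()) {
  if (!nrow(evidence)) return(FALSE)
  if (length(unique(evidence$protein_accession)) > 1L)
    contract_error("accept_protein: evidence mixes accessions (%s)",
                   paste(unique(evidence$protein_accession), collapse = ", "))
  if (length(unique(evidence$method)) > 1L ||
      length(unique(evidence$solubility)) > 1L)
    contract_error("accept_protein: evidence mixes fractions")
  sig <- evidence[evidence$significant, , drop = FALSE]
  if (length(unique(sig$peptide)) >= thresholds$min_significant_peptides)
    return(TRUE)
  any(sig$spectra_count >= thresholds$alt_min_spectra &
        sig$score >= thresholds$alt_min_score)
}

#' Build the protein x (method, solubility) detection matrix
#'
#' Applies [accept_protein()] to every (protein, method, solubility) cell of
#' an evidence table. Proteins accepted in no cell are dropped; the best
#' score is the maximum evidence score over accepted cells only.
#'
#' @param evidence A validated peptide-evidence data.frame
#'   (see [read_evidence_table()]).
#' @param thresholds An [evidence_thresholds()] object.
#' @return An object of class `detection_matrix`: a list with `cells` (a
#'   logical matrix, proteins x the eight `method.solubility` fractions, rows
#'   in ascending accession order) and `best_score` (named numeric).
#' @export
build_detection_matrix <- function(evidence,
                                   thresholds = evidence_thresholds()) {
  fractions <- som_fractions()
  proteins <- sort(unique(evidence$protein_accession))
  cells <- matrix(FALSE, nrow = length(proteins), ncol = length(fractions),
                  dimnames = list(proteins, fractions))
  best <- rep(-Inf, length(proteins))
  names(best) <- proteins
  if (nrow(evidence)) {
    key <- interaction(evidence$protein_accession,
                       paste(evidence$method, evidence$solubility, sep = "."),
                       drop = TRUE, sep = "\r")
    for (chunk in split(seq_len(nrow(evidence)), key)) {
      ev <- evidence[chunk, , drop = FALSE]
      if (accept_protein(ev, thresholds)) {
        p <- ev$protein_accession[1]
        f <- paste(ev$method[1], ev$solubility[1], sep = ".")
        cells[p, f] <- TRUE
        best[p] <- max(best[p], ev$score)
      }
    }
  }
  keep <- rowSums(cells) > 0L
  structure(list(cells = cells[keep, , drop = FALSE],
                 best_score = best[keep],
                 thresholds = thresholds),
            class = "detection_matrix")
}

#' @export
print.detection_matrix <- function(x, ...) {
  cat("Detection matrix:", nrow(x$cells), "proteins x",
      ncol(x$cells), "fractions\n")
  cat("  detections per fraction:\n")
  print(colSums(x$cells))
  invisible(x)
}

#' @rdname build_detection_matrix
#' @param x A `detection_matrix`.
#' @param ... Unused.
#' @export
as.data.frame.detection_matrix <- function(x, ...) {
  df <- data.frame(accession = rownames(x$cells), x$cells,
                   best_score = unname(x$best_score),
                   row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
  names(df) <- c("accession", colnames(x$cells), "best_score")
  df
}

#' @rdname build_detection_matrix
#' @param matrix A `detection_matrix`.
#' @param path Output TSV path (one row per protein, eight boolean fraction
#'   columns plus `best_score`).
#' @export
write_detection_matrix <- function(matrix, path) {
  df <- as.data.frame(matrix)
  df$best_score <- sprintf("%.2f", df$best_score)
  write_tsv(df, path)
}

# protein presence sets derived from the matrix ------------------------------

matrix_fraction_set <- function(matrix, methods = som_methods(),
                                solubilities = som_solubilities()) {
  cols <- as.vector(t(outer(methods, solubilities, paste, sep = ".")))
  cols <- intersect(colnames(matrix$cells), cols)
  rownames(matrix$cells)[rowSums(matrix$cells[, cols, drop = FALSE]) > 0L]
}
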