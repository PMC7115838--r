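# Readers and writers for every external format the pipeline touches.
# All tabular output is sorted by ascending accession so files are a pure
# function of content, never of input order.

#' Read a protein FASTA database
#'
#' Parses a standard protein FASTA file through Biostrings after a validation
#' pass that reports offending line numbers. Accessions are the first
#' whitespace-delimited token of each header and must be unique; sequences
#' are restricted to the 20 standard residues plus `X`.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `accession`, `sequence`, `description`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">P1 a coral protein", "MKLV"), fa)
#' read_protein_fasta(fa)
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) format_error("FASTA file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  content <- which(nzchar(trimws(lines)))
  if (!length(content)) {
    warning("empty FASTA file: ", path)
    return(data.frame(accession = character(), sequence = character(),
                      description = character(), stringsAsFactors = FALSE))
  }
  if (!startsWith(trimws(lines[content[1]]), ">"))
    format_error("malformed FASTA: line %d is not a header", content[1])
  for (i in content) {
    ln <- trimws(lines[i])
    if (startsWith(ln, ">")) {
      if (!nzchar(trimws(substring(ln, 2))))
        format_error("malformed FASTA header at line %d: empty accession", i)
    } else if (!is_valid_sequence(toupper(ln))) {
      format_error("illegal residue character at line %d", i)
    }
  }
  aa <- Biostrings::readAAStringSet(path)
  headers <- names(aa)
  accession <- vapply(strsplit(headers, "\\s+"), `[[`, character(1), 1L)
  dup <- accession[duplicated(accession)]
  if (length(dup))
    format_error("duplicate accession(s) in FASTA: %s",
                 paste(unique(dup), collapse = ", "))
  description <- sub("^\\S+\\s*", "", headers)
  data.frame(accession = accession,
             sequence = toupper(as.character(aa)),
             description = description,
             stringsAsFactors = FALSE)
}

#' Write a protein FASTA database
#'
#' @param proteins data.frame with `accession`, `sequence` and optionally
#'   `description` columns.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
write_protein_fasta <- function(proteins, path) {
  ord <- order(proteins$accession)
  proteins <- proteins[ord, , drop = FALSE]
  desc <- if ("description" %in% names(proteins)) proteins$description
          else rep("", nrow(proteins))
  header <- ifelse(nzchar(desc), paste(proteins$accession, desc),
                   proteins$accession)
  aa <- Biostrings::AAStringSet(proteins$sequence)
  names(aa) <- header
  Biostrings::writeXStringSet(aa, path, width = 60L)
  invisible(path)
}

evidence_columns <- c("protein_accession", "peptide", "spectra_count",
                      "significant", "score", "method", "solubility")

#' Read a peptide-evidence table
#'
#' Long-format TSV: one row per identified peptide per protein per
#' (method, solubility) fraction, with its spectra count, the search
#' engine's 1% FDR significance flag, and an identification score.
#'
#' @param path Path to a TSV with header columns `protein_accession`,
#'   `peptide`, `spectra_count`, `significant`, `score`, `method`,
#'   `solubility`.
#' @return A typed data.frame of peptide evidence.
#' @export
read_evidence_table <- function(path) {
  if (!file.exists(path)) format_error("evidence table not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  missing <- setdiff(evidence_columns, names(df))
  if (length(missing))
    format_error("evidence table missing column(s): %s",
                 paste(missing, collapse = ", "))
  df <- df[, evidence_columns, drop = FALSE]
  if (!nrow(df)) {
    df$spectra_count <- integer(); df$significant <- logical()
    df$score <- numeric()
    return(df)
  }
  rows <- seq_len(nrow(df)) + 1L  # file line numbers (header is line 1)
  df$peptide <- toupper(df$peptide)
  bad <- which(!is_valid_sequence(df$peptide))
  if (length(bad))
    invariant_error("invalid peptide '%s' (row %d)", df$peptide[bad[1]],
                    rows[bad[1]])
  sc <- suppressWarnings(as.integer(df$spectra_count))
  bad <- which(is.na(sc) | sc < 1L)
  if (length(bad))
    invariant_error("spectra_count must be a positive integer (row %d)",
                    rows[bad[1]])
  df$spectra_count <- sc
  df$significant <- parse_bool_column(df$significant, "significant", rows)
  score <- suppressWarnings(as.numeric(df$score))
  bad <- which(is.na(score) | score < 0)
  if (length(bad))
    invariant_error("score must be a non-negative number (row %d)", rows[bad[1]])
  df$score <- score
  bad <- which(!df$method %in% som_methods())
  if (length(bad))
    vocab_error("unknown method label '%s' (row %d); expected one of %s",
                df$method[bad[1]], rows[bad[1]],
                paste(som_methods(), collapse = ", "))
  bad <- which(!df$solubility %in% som_solubilities())
  if (length(bad))
    vocab_error("unknown solubility label '%s' (row %d); expected one of %s",
                df$solubility[bad[1]], rows[bad[1]],
                paste(som_solubilities(), collapse = ", "))
  bad <- which(!nzchar(df$protein_accession))
  if (length(bad))
    invariant_error("empty protein_accession (row %d)", rows[bad[1]])
  df
}

#' @rdname read_evidence_table
#' @param evidence A validated evidence data.frame.
#' @export
write_evidence_table <- function(evidence, path) {
  ord <- order(evidence$protein_accession, evidence$method,
               evidence$solubility, evidence$peptide)
  write_tsv(evidence[ord, evidence_columns, drop = FALSE], path)
}

blast12 <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
             "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Read BLAST tabular alignment hits
#'
#' Standard 12-column BLAST tabular output (`-outfmt 6`), optionally with a
#' 13th `ppos` (percent positives) column. Percent similarity is taken from
#' `ppos` when present, otherwise percent identity stands in as a
#' conservative proxy; the source is recorded in the `similarity_source`
#' column so downstream reports can state which was used.
#'
#' @param path Path to a tab-separated BLAST hit table without header.
#' @return A data.frame with columns `query_accession`, `subject_accession`,
#'   `evalue`, `percent_similarity`, `align_length`, `identical_positions`,
#'   `bitscore`, `similarity_source`.
#' @export
read_blast_tabular <- function(path) {
  if (!file.exists(path)) format_error("BLAST table not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(query_accession = character(),
                      subject_accession = character(), evalue = numeric(),
                      percent_similarity = numeric(), align_length = integer(),
                      identical_positions = integer(), bitscore = numeric(),
                      similarity_source = character(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(parts)
  bad <- which(!ncols %in% c(12L, 13L))
  if (length(bad))
    format_error("BLAST tabular line %d has %d columns; expected 12 or 13",
                 bad[1], ncols[bad[1]])
  has_ppos <- ncols == 13L
  m <- t(vapply(parts, function(p) p[seq_len(12L)], character(12L)))
  colnames(m) <- blast12
  pident <- as.numeric(m[, "pident"])
  len <- as.integer(m[, "length"])
  evalue <- as.numeric(m[, "evalue"])
  if (anyNA(evalue) || any(evalue < 0))
    format_error("unparseable or negative e-value in BLAST table")
  ppos <- rep(NA_real_, length(lines))
  ppos[has_ppos] <- as.numeric(vapply(parts[has_ppos], `[[`, character(1), 13L))
  sim <- ifelse(has_ppos, ppos, pident)
  ident <- as.integer(round(pident * len / 100))
  if (any(ident > len, na.rm = TRUE))
    invariant_error("identical positions exceed alignment length")
  data.frame(query_accession = m[, "qseqid"],
             subject_accession = m[, "sseqid"],
             evalue = evalue,
             percent_similarity = sim,
             align_length = len,
             identical_positions = ident,
             bitscore = as.numeric(m[, "bitscore"]),
             similarity_source = ifelse(has_ppos, "ppos", "pident"),
             stringsAsFactors = FALSE)
}

#' @rdname read_blast_tabular
#' @param hits A data.frame of alignment hits as returned by
#'   [read_blast_tabular()].
#' @export
write_blast_tabular <- function(hits, path) {
  ord <- order(hits$query_accession, hits$subject_accession, hits$evalue)
  hits <- hits[ord, , drop = FALSE]
  pident <- 100 * hits$identical_positions / hits$align_length
  out <- data.frame(hits$query_accession, hits$subject_accession,
                    sprintf("%.2f", pident), hits$align_length,
                    hits$align_length - hits$identical_positions, 0L,
                    1L, hits$align_length, 1L, hits$align_length,
                    format(hits$evalue, scientific = TRUE, digits = 3),
                    sprintf("%.1f", hits$bitscore),
                    sprintf("%.2f", hits$percent_similarity))
  con <- file(path, open = "wb")
  on.exit(close(con))
  write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE, eol = "\n")
  invisible(path)
}

annotation_columns <- c("accession", "n_term_complete", "signal_peptide",
                        "tm_span_count", "gpi_anchor", "go_terms")

#' Read a per-protein annotation table
#'
#' Annotation flags are consumed, not computed: signal peptides, transmembrane
#' spans, GPI anchors and N-terminus completeness come from external
#' predictors; GO terms from a functional annotation pipeline.
#'
#' @param path Path to a TSV with columns `accession`, `n_term_complete`,
#'   `signal_peptide`, `tm_span_count`, `gpi_anchor`, `go_terms`
#'   (`|`-separated GO identifiers of the form GO:NNNNNNN) and optionally
#'   `description`.
#' @return A typed data.frame, one row per protein.
#' @export
read_annotation_table <- function(path) {
  if (!file.exists(path)) format_error("annotation table not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  missing <- setdiff(annotation_columns, names(df))
  if (length(missing))
    format_error("annotation table missing column(s): %s",
                 paste(missing, collapse = ", "))
  keep <- c(annotation_columns,
            intersect("description", names(df)))
  df <- df[, keep, drop = FALSE]
  if (!nrow(df)) {
    df$n_term_complete <- logical(); df$signal_peptide <- logical()
    df$tm_span_count <- integer(); df$gpi_anchor <- logical()
    return(df)
  }
  rows <- seq_len(nrow(df)) + 1L
  if (anyDuplicated(df$accession))
    format_error("duplicate accession(s) in annotation table: %s",
                 paste(unique(df$accession[duplicated(df$accession)]),
                       collapse = ", "))
  df$n_term_complete <- parse_bool_column(df$n_term_complete,
                                          "n_term_complete", rows)
  df$signal_peptide <- parse_bool_column(df$signal_peptide,
                                         "signal_peptide", rows)
  df$gpi_anchor <- parse_bool_column(df$gpi_anchor, "gpi_anchor", rows)
  tm <- suppressWarnings(as.integer(df$tm_span_count))
  bad <- which(is.na(tm) | tm < 0L)
  if (length(bad))
    invariant_error("tm_span_count must be a non-negative integer (row %d)",
                    rows[bad[1]])
  df$tm_span_count <- tm
  terms <- split_go_terms(df$go_terms)
  bad_terms <- setdiff(unlist(terms), character(0))
  bad_terms <- bad_terms[!grepl("^GO:[0-9]{7}$", bad_terms)]
  if (length(bad_terms))
    format_error("malformed GO identifier(s): %s",
                 paste(unique(bad_terms), collapse = ", "))
  df
}

#' @rdname read_annotation_table
#' @param annotation A validated annotation data.frame.
#' @export
write_annotation_table <- function(annotation, path) {
  ord <- order(annotation$accession)
  write_tsv(annotation[ord, , drop = FALSE], path)
}

split_go_terms <- function(x) {
  lapply(strsplit(x, "|", fixed = TRUE),
         function(v) v[nzchar(v)])
}

ortholog_relations <- c("one_to_one", "one_to_many", "many_to_many",
                        "blastp_best_hit")
ortholog_columns <- c("target_accession", "other_accession", "other_proteome",
                      "relation")

#' Read an ortholog-pair table
#'
#' One row per (target protein, ortholog) pair linking the curated proteome
#' to a previously published skeletal proteome. All relation multiplicities
#' count equally for set membership; the relation is preserved for audit.
#'
#' @param path Path to a TSV with columns `target_accession`,
#'   `other_accession`, `other_proteome`, `relation`.
#' @param proteomes Optional character vector of allowed proteome labels;
#'   rows referencing other labels raise a vocabulary error.
#' @return A typed data.frame of ortholog pairs.
#' @export
read_ortholog_table <- function(path, proteomes = NULL) {
  if (!file.exists(path)) format_error("ortholog table not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  missing <- setdiff(ortholog_columns, names(df))
  if (length(missing))
    format_error("ortholog table missing column(s): %s",
                 paste(missing, collapse = ", "))
  df <- df[, ortholog_columns, drop = FALSE]
  if (!nrow(df)) return(df)
  rows <- seq_len(nrow(df)) + 1L
  bad <- which(!df$relation %in% ortholog_relations)
  if (length(bad))
    vocab_error("unknown ortholog relation '%s' (row %d)", df$relation[bad[1]],
                rows[bad[1]])
  if (!is.null(proteomes)) {
    bad <- which(!df$other_proteome %in% proteomes)
    if (length(bad))
      vocab_error("unconfigured proteome label '%s' (row %d)",
                  df$other_proteome[bad[1]], rows[bad[1]])
  }
  df
}

#' @rdname read_ortholog_table
#' @param pairs A validated ortholog-pair data.frame.
#' @export
write_ortholog_table <- function(pairs, path) {
  ord <- order(pairs$target_accession, pairs$other_proteome,
               pairs$other_accession)
  write_tsv(pairs[ord, ortholog_columns, drop = FALSE], path)
}

curated_columns <- function() {
  c("accession", "annotation", "best_score", som_solubilities(),
    som_methods(), "categories")
}

#' Write (and read back) a curated-proteome table
#'
#' The curated proteome is the final filtered, screened and classified
#' protein list: one row per protein with its best identification score,
#' per-solubility and per-method detection flags and assigned functional
#' categories (comma-separated). Rows are written in ascending accession
#' order so repeated writes of the same proteome are byte-identical. An
#' optional JSON report of summary counts is written alongside.
#'
#' @param curated A curated-proteome data.frame (see [run_curation()]).
#' @param path Output TSV path.
#' @param report Optional named list of summary counts to serialise as JSON.
#' @param report_path Path for the JSON report (default: `path` with a
#'   `.json` extension).
#' @return `path`, invisibly.
#' @export
write_curated_table <- function(curated, path, report = NULL,
                                report_path = sub("\\.tsv$", ".json", path)) {
  cols <- curated_columns()
  missing <- setdiff(cols, names(curated))
  if (length(missing))
    contract_error("curated table missing column(s): %s",
                   paste(missing, collapse = ", "))
  out <- curated[order(curated$accession), cols, drop = FALSE]
  out$best_score <- sprintf("%.2f", out$best_score)
  write_tsv(out, path)
  if (is.null(report)) report <- list(total_proteins = nrow(out))
  jsonlite::write_json(report, report_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_curated_table
#' @export
read_curated_table <- function(path) {
  if (!file.exists(path)) format_error("curated table not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character")
  missing <- setdiff(curated_columns(), names(df))
  if (length(missing))
    format_error("curated table missing column(s): %s",
                 paste(missing, collapse = ", "))
  df <- df[, curated_columns(), drop = FALSE]
  df$best_score <- as.numeric(df$best_score)
  rows <- seq_len(nrow(df)) + 1L
  for (col in c(som_solubilities(), som_methods()))
    df[[col]] <- if (nrow(df)) parse_bool_column(df[[col]], col, rows) else logical()
  df
}
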