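# Export-mechanism classification (signal peptide / transmembrane / GPI /
# non-classical candidate) and GO-derived functional categories. Annotation
# flags come from external predictors; this module only combines them.

#' The five fixed functional categories
#'
#' Lipid/phosphate/glycan-related proteins (membrane processing);
#' ECM-related and transmembrane proteins; metal-binding proteins;
#' vesicular/secretion-related proteins; protein-modification proteins.
#' A protein may belong to several categories, or to none
#' (uncharacterized for grouping purposes).
#'
#' @return Character vector of category labels.
#' @export
som_categories <- function() {
  c("membrane_processing", "ecm_tm_protein_modification", "metal_binding",
    "vesicular_secretion", "protein_modification")
}

#' Default GO-term / keyword category map
#'
#' An explicit, editable rule list mapping GO identifiers (exact match
#' against a protein's GO terms) and free-text keyword patterns
#' (case-insensitive regular expressions against the protein description)
#' to the five functional categories. The map travels with every report as
#' an MD5 hash ([category_map_digest()]) so classifications are
#' reproducible; users may supply their own map with the same columns.
#'
#' @return A data.frame with columns `field` (`"go"` or `"description"`),
#'   `pattern`, `category`.
#' @export
default_category_map <- function() {
  rule <- function(field, pattern, category)
    data.frame(field = field, pattern = pattern, category = category,
               stringsAsFactors = FALSE)
  rbind(
    # lipid / phosphate / glycan metabolism -> membrane processing
    rule("go", "GO:0006629", "membrane_processing"),  # lipid metabolic process
    rule("go", "GO:0008610", "membrane_processing"),  # lipid biosynthesis
    rule("go", "GO:0006796", "membrane_processing"),  # phosphate-compound metab.
    rule("go", "GO:0005975", "membrane_processing"),  # carbohydrate metab.
    rule("description", "phospholipase|glycosyl ?transferase",
         "membrane_processing"),
    # extracellular region/matrix, membrane-integral -> ECM/TM
    rule("go", "GO:0005576", "ecm_tm_protein_modification"),  # extracellular region
    rule("go", "GO:0031012", "ecm_tm_protein_modification"),  # extracellular matrix
    rule("go", "GO:0005615", "ecm_tm_protein_modification"),  # extracellular space
    rule("go", "GO:0016021", "ecm_tm_protein_modification"),  # integral to membrane
    rule("description", "collagen|laminin|nidogen|coadhesin|ZP domain|zona pellucida|mucin",
         "ecm_tm_protein_modification"),
    # metal / calcium ion binding
    rule("go", "GO:0046872", "metal_binding"),  # metal ion binding
    rule("go", "GO:0005509", "metal_binding"),  # calcium ion binding
    rule("go", "GO:0008270", "metal_binding"),  # zinc ion binding
    rule("description", "aspartic acid-rich|acid[- ]rich", "metal_binding"),
    # vesicles / exocytosis / secretion
    rule("go", "GO:0016192", "vesicular_secretion"),  # vesicle-mediated transport
    rule("go", "GO:0006887", "vesicular_secretion"),  # exocytosis
    rule("go", "GO:0031982", "vesicular_secretion"),  # vesicle
    rule("go", "GO:0046903", "vesicular_secretion"),  # secretion
    rule("description", "synapsin|vesicle", "vesicular_secretion"),
    # peptidases, kinases, glycosylation -> protein modification
    rule("go", "GO:0008233", "protein_modification"),  # peptidase activity
    rule("go", "GO:0004672", "protein_modification"),  # protein kinase activity
    rule("go", "GO:0006486", "protein_modification"),  # protein glycosylation
    rule("go", "GO:0036211", "protein_modification"),  # protein modification
    rule("description", "protease|peptidase|proteinase|kinase|convertase|collagenase",
         "protein_modification")
  )
}

validate_category_map <- function(map) {
  needed <- c("field", "pattern", "category")
  if (!is.data.frame(map) || !all(needed %in% names(map)))
    config_error("category map must have columns field, pattern, category")
  bad <- setdiff(unique(map$category), som_categories())
  if (length(bad))
    config_error("category map targets unknown categor%s: %s",
                 if (length(bad) > 1) "ies" else "y",
                 paste(bad, collapse = ", "))
  bad <- setdiff(unique(map$field), c("go", "description"))
  if (length(bad))
    config_error("category map field must be 'go' or 'description', got: %s",
                 paste(bad, collapse = ", "))
  for (p in map$pattern[map$field == "description"]) {
    ok <- tryCatch({suppressWarnings(grepl(p, "x", ignore.case = TRUE)); TRUE},
                   error = function(e) FALSE)
    if (!ok) config_error("malformed rule pattern: %s", p)
  }
  invisible(map)
}

#' MD5 digest of a category map
#'
#' Hashes the canonical serialisation (rules sorted by category, field,
#' pattern) so a report can pin the exact mapping that produced it.
#'
#' @param map A category map data.frame.
#' @return A length-one character MD5 string.
#' @export
category_map_digest <- function(map = default_category_map()) {
  validate_category_map(map)
  map <- map[order(map$category, map$field, map$pattern), , drop = FALSE]
  tmp <- tempfile(fileext = ".tsv")
  on.exit(unlink(tmp))
  writeLines(paste(map$field, map$pattern, map$category, sep = "\t"), tmp)
  unname(tools::md5sum(tmp))
}

#' Classify proteins by export mechanism
#'
#' A signal peptide is only counted when the gene model is complete at the
#' N-terminus (`has_sp = signal_peptide & n_term_complete`); the raw
#' predictor flag is retained separately. `ecm_evidence` is true when any of
#' signal peptide, transmembrane span or GPI anchor supports extracellular
#' localisation; otherwise the protein is a non-classical secretion
#' candidate. The two classes partition the proteome.
#'
#' @param annotation Annotation data.frame ([read_annotation_table()]).
#' @return A data.frame with columns `accession`, `signal_peptide_raw`,
#'   `has_sp`, `has_tm`, `has_gpi`, `ecm_evidence`,
#'   `non_classical_candidate`.
#' @export
classify_export <- function(annotation) {
  has_sp <- annotation$signal_peptide & annotation$n_term_complete
  has_tm <- annotation$tm_span_count >= 1L
  has_gpi <- annotation$gpi_anchor
  ecm <- has_sp | has_tm | has_gpi
  data.frame(accession = annotation$accession,
             signal_peptide_raw = annotation$signal_peptide,
             has_sp = has_sp, has_tm = has_tm, has_gpi = has_gpi,
             ecm_evidence = ecm, non_classical_candidate = !ecm,
             stringsAsFactors = FALSE)
}

#' Assign functional categories from GO terms and descriptions
#'
#' Returns, per protein, the union of categories over all matching map
#' rules. GO rules match a protein's GO identifier set exactly; description
#' rules are case-insensitive regular expressions over the free-text
#' description (skipped when the annotation has no description column).
#' An empty set means uncharacterized for grouping purposes.
#'
#' @inheritParams classify_export
#' @param map A category map (default [default_category_map()]).
#' @return A named list (by accession) of character vectors of categories.
#' @export
classify_function <- function(annotation, map = default_category_map()) {
  validate_category_map(map)
  terms <- split_go_terms(annotation$go_terms)
  desc <- if ("description" %in% names(annotation)) annotation$description
          else rep("", nrow(annotation))
  go_rules <- map[map$field == "go", , drop = FALSE]
  de_rules <- map[map$field == "description", , drop = FALSE]
  out <- lapply(seq_len(nrow(annotation)), function(i) {
    cats <- go_rules$category[go_rules$pattern %in% terms[[i]]]
    if (nzchar(desc[i]) && nrow(de_rules)) {
      hit <- vapply(de_rules$pattern, grepl, logical(1), x = desc[i],
                    ignore.case = TRUE)
      cats <- c(cats, de_rules$category[hit])
    }
    intersect(som_categories(), unique(cats))  # fixed category order
  })
  names(out) <- annotation$accession
  out
}

#' Tally functional categories and export classes
#'
#' A protein in several categories increments each of them once (never twice
#' within one); export-class counts come from [classify_export()].
#'
#' @param export Export classification data.frame ([classify_export()]).
#' @param categories Named list of per-protein category vectors
#'   ([classify_function()]).
#' @return A list with `category_counts` (all five categories, zero-filled),
#'   `n_categorized` (proteins with at least one category) and
#'   `export_counts` (`has_sp`, `has_tm`, `has_gpi`, `ecm_evidence`,
#'   `non_classical`, `signal_peptide_raw`).
#' @export
tally_categories <- function(export, categories) {
  counts <- vapply(som_categories(), function(cat)
    sum(vapply(categories, function(x) cat %in% x, logical(1))),
    integer(1))
  list(
    category_counts = as.list(counts),
    n_categorized = sum(lengths(categories) > 0L),
    export_counts = list(
      has_sp = sum(export$has_sp),
      has_tm = sum(export$has_tm),
      has_gpi = sum(export$has_gpi),
      ecm_evidence = sum(export$ecm_evidence),
      non_classical = sum(export$non_classical_candidate),
      signal_peptide_raw = sum(export$signal_peptide_raw)
    )
  )
}
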