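# End-to-end orchestration: load -> contaminant screen -> evidence filter ->
# detection matrix -> fraction summaries -> classification -> orthology ->
# outputs, with one structured JSON run report. The screen precedes the
# evidence filter; both are per-protein predicates, so the two stages
# commute on any input (asserted in the test suite).

default_config <- function() {
  list(
    inputs = list(evidence = NULL, annotation = NULL, alignments = NULL,
                  contaminant_fasta = NULL, orthologs = NULL,
                  target_fasta = NULL),
    thresholds = list(evidence = list(), contaminant = list()),
    proteomes = NULL,
    background = list(p = 0.002),
    peptide_mode = "observed",
    category_map = NULL
  )
}

#' Load a pipeline configuration
#'
#' A configuration is a named list (or a YAML file holding one) with
#' elements `inputs` (paths: `evidence` required; `annotation`,
#' `alignments` + `contaminant_fasta`, `orthologs`, `target_fasta`
#' optional), `thresholds` (`evidence`, `contaminant`: named overrides for
#' [evidence_thresholds()] / [contaminant_thresholds()]), `proteomes`
#' (allowed ortholog proteome labels), `background` (`p`, or `K` and `N`,
#' for [enrichment_test()]), `peptide_mode` and `category_map` (path to a
#' rule TSV with columns field/pattern/category).
#'
#' @param config A named list or path to a YAML file.
#' @return The merged configuration list.
#' @export
load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) config_error("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (!is.list(config)) config_error("config must be a list or YAML path")
  base <- default_config()
  out <- utils::modifyList(base, config)
  if (is.null(out$inputs$evidence))
    config_error("config must name an evidence table (inputs$evidence)")
  out
}

stage_error <- function(stage, e) {
  csom_stop("coralsom_stage_error", "[%s] %s", stage, conditionMessage(e))
}

run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) stage_error(stage, e))
}

#' Run the full curation pipeline
#'
#' Executes every stage in order and returns the curated proteome with a
#' structured run report. Outputs (curated TSV, detection matrix, screen
#' verdicts, JSON report) are only written once every stage has succeeded,
#' so a failing stage never leaves partial outputs in place.
#'
#' @param config A configuration list or YAML path ([load_config()]).
#' @param out_dir Optional output directory; when given, writes
#'   `curated_proteome.tsv`, `detection_matrix.tsv`, `screen_verdicts.tsv`
#'   and `run_report.json` there.
#' @return A list of class `curation_run` with elements `curated` (the
#'   curated-proteome data.frame), `matrix` (the `detection_matrix`),
#'   `verdicts`, `summaries`, `overlap` and `report`.
#' @export
run_curation <- function(config, out_dir = NULL) {
  config <- load_config(config)
  inp <- config$inputs

  evidence <- run_stage("load", read_evidence_table(inp$evidence))
  annotation <- if (!is.null(inp$annotation))
    run_stage("load", read_annotation_table(inp$annotation)) else NULL
  hits <- if (!is.null(inp$alignments))
    run_stage("load", read_blast_tabular(inp$alignments)) else NULL
  contaminant_db <- if (!is.null(inp$contaminant_fasta))
    run_stage("load", read_protein_fasta(inp$contaminant_fasta)) else NULL
  target_db <- if (!is.null(inp$target_fasta))
    run_stage("load", read_protein_fasta(inp$target_fasta)) else NULL
  proteomes <- config$proteomes
  pairs <- if (!is.null(inp$orthologs))
    run_stage("load", read_ortholog_table(inp$orthologs, proteomes)) else NULL
  map <- if (!is.null(config$category_map)) {
    m <- read.delim(config$category_map, sep = "\t", stringsAsFactors = FALSE)
    validate_category_map(m)
  } else default_category_map()

  ev_th <- do.call(evidence_thresholds, config$thresholds$evidence)
  ct_th <- do.call(contaminant_thresholds, config$thresholds$contaminant)

  proteins_in <- length(unique(evidence$protein_accession))
  if (!proteins_in)
    warning("evidence table is empty: curated proteome will be empty")

  # contaminant screen first (prose order); commutes with the evidence filter
  verdicts <- if (!is.null(hits) && !is.null(contaminant_db)) {
    run_stage("contamination_screen",
              screen_proteome(unique(evidence$protein_accession), evidence,
                              hits, contaminant_db, ct_th,
                              peptide_mode = config$peptide_mode,
                              target_db = target_db))
  } else {
    acc <- sort(unique(evidence$protein_accession))
    data.frame(accession = acc,
               candidate = rep(FALSE, length(acc)),
               shared_peptide_count = rep(0L, length(acc)),
               removed = rep(FALSE, length(acc)),
               triggering_subject = rep(NA_character_, length(acc)),
               peptide_mode = rep(config$peptide_mode, length(acc)),
               stringsAsFactors = FALSE)
  }
  removed <- verdicts$accession[verdicts$removed]
  retained_evidence <- evidence[!evidence$protein_accession %in% removed, ,
                                drop = FALSE]
  after_screen <- length(unique(retained_evidence$protein_accession))

  matrix <- run_stage("evidence_filter",
                      build_detection_matrix(retained_evidence, ev_th))
  curated_acc <- rownames(matrix$cells)
  n_curated <- length(curated_acc)

  summaries <- run_stage("fraction_sets", {
    if (n_curated) {
      list(methods = method_group_summary(matrix),
           per_method = venn_counts(
             stats::setNames(lapply(som_methods(), function(m)
               matrix_fraction_set(matrix, methods = m)), som_methods()),
             total = n_curated),
           solubility = solubility_summary(matrix))
    } else {
      list(methods = NULL, per_method = NULL, solubility = NULL)
    }
  })

  classification <- run_stage("feature_classify", {
    if (!is.null(annotation) && n_curated) {
      ann <- annotation[annotation$accession %in% curated_acc, , drop = FALSE]
      export <- classify_export(ann)
      cats <- classify_function(ann, map)
      list(export = export, categories = cats,
           tallies = tally_categories(export, cats))
    } else NULL
  })

  overlap <- run_stage("orthology_overlap", {
    if (!is.null(pairs) && n_curated)
      orthology_overlap(curated_acc, pairs, proteomes,
                        background = config$background)
    else NULL
  })

  curated <- curated_table(matrix, annotation, classification)

  report <- list(
    tool = "coralsom",
    version = as.character(utils::packageVersion("coralsom")),
    inputs = lapply(Filter(Negate(is.null), inp), function(p)
      list(path = p, md5 = unname(tools::md5sum(p)))),
    thresholds = list(evidence = unclass(ev_th), contaminant = unclass(ct_th)),
    peptide_mode = config$peptide_mode,
    spectra_rule_scope = "within-fraction",  # spectra never summed across fractions
    similarity_source = if (!is.null(hits) && nrow(hits))
      unique(hits$similarity_source) else character(),
    category_map_md5 = category_map_digest(map),
    stage_counts = list(proteins_in = proteins_in,
                        after_screen = after_screen,
                        curated = n_curated,
                        removed_contaminants = length(removed)),
    removed_accessions = removed,
    fraction_summary = summary_block(summaries),
    category_tallies = if (!is.null(classification)) classification$tallies
      else NULL,
    overlap = overlap_block(overlap)
  )
  stopifnot(proteins_in >= after_screen, after_screen >= n_curated)

  result <- structure(list(curated = curated, matrix = matrix,
                           verdicts = verdicts, summaries = summaries,
                           classification = classification,
                           overlap = overlap, report = report),
                      class = "curation_run")
  if (!is.null(out_dir)) write_run_outputs(result, out_dir)
  result
}

curated_table <- function(matrix, annotation, classification) {
  acc <- rownames(matrix$cells)
  if (is.null(acc)) acc <- character(0)
  sol <- vapply(som_solubilities(), function(s)
    acc %in% matrix_fraction_set(matrix, solubilities = s),
    logical(length(acc)))
  met <- vapply(som_methods(), function(m)
    acc %in% matrix_fraction_set(matrix, methods = m), logical(length(acc)))
  if (!length(acc)) {
    sol <- matrix(logical(), 0, 2, dimnames = list(NULL, som_solubilities()))
    met <- matrix(logical(), 0, 4, dimnames = list(NULL, som_methods()))
  }
  ann_text <- rep("", length(acc))
  if (!is.null(annotation) && "description" %in% names(annotation)) {
    idx <- match(acc, annotation$accession)
    ann_text <- ifelse(is.na(idx), "", annotation$description[idx])
  }
  cats <- rep("", length(acc))
  if (!is.null(classification)) {
    hit <- match(acc, names(classification$categories))
    cats <- vapply(hit, function(i)
      if (is.na(i)) "" else paste(classification$categories[[i]],
                                  collapse = ","), character(1))
  }
  df <- data.frame(accession = acc, annotation = ann_text,
                   best_score = unname(matrix$best_score), sol, met,
                   categories = cats, row.names = NULL, check.names = FALSE,
                   stringsAsFactors = FALSE)
  df[order(df$accession), , drop = FALSE]
}

summary_block <- function(summaries) {
  if (is.null(summaries$methods)) return(NULL)
  list(
    method_groups = list(totals = summaries$methods$totals,
                         percentages = summaries$methods$percentages),
    per_method = list(totals = summaries$per_method$totals),
    solubility = list(totals = summaries$solubility$totals,
                      percentages = summaries$solubility$percentages)
  )
}

overlap_block <- function(overlap) {
  if (is.null(overlap)) return(NULL)
  list(n_curated = overlap$n_curated, n_any = overlap$n_any,
       n_all = overlap$n_all,
       per_proteome = lapply(overlap$per_proteome, length),
       enrichment = overlap$enrichment)
}

write_run_outputs <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_curated_table(result$curated,
                      file.path(out_dir, "curated_proteome.tsv"),
                      report = result$report,
                      report_path = file.path(out_dir, "run_report.json"))
  write_detection_matrix(result$matrix,
                         file.path(out_dir, "detection_matrix.tsv"))
  write_screen_verdicts(result$verdicts,
                        file.path(out_dir, "screen_verdicts.tsv"))
  invisible(out_dir)
}

#' @export
print.curation_run <- function(x, ...) {
  sc <- x$report$stage_counts
  cat("Skeletal proteome curation run\n")
  cat(sprintf("  proteins in evidence: %d\n", sc$proteins_in))
  cat(sprintf("  after contaminant screen: %d (removed %d)\n",
              sc$after_screen, sc$removed_contaminants))
  cat(sprintf("  curated (evidence rule): %d\n", sc$curated))
  if (!is.null(x$overlap))
    cat(sprintf("  orthology overlap: %d any / %d all, p = %.3g\n",
                x$overlap$n_any, x$overlap$n_all,
                x$overlap$enrichment$p_value))
  invisible(x)
}
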