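# Set algebra over the detection matrix: per-method and per-solubility
# totals, Venn region counts, exclusivity percentages. "Detected by a
# method" means detected in either solubility fraction of that method.

#' Pool detection-matrix methods into named groups
#'
#' @param matrix A `detection_matrix`.
#' @param groups Named list mapping a group label to a subset of methods,
#'   e.g. `list(CF = c("CF2","CF4"), ACT = c("ACT1","ACT3"))`. A protein
#'   belongs to a group when it has a detection in any (method in group,
#'   any solubility) cell.
#' @return Named list of sorted accession vectors.
#' @export
combine_methods <- function(matrix, groups = som_method_groups()) {
  unknown <- setdiff(unlist(groups), som_methods())
  if (length(unknown))
    vocab_error("unknown method label(s): %s", paste(unknown, collapse = ", "))
  lapply(groups, function(methods)
    sort(matrix_fraction_set(matrix, methods = methods)))
}

venn_patterns <- function(set_names) {
  k <- length(set_names)
  grid <- expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE]
  names(grid) <- set_names
  grid
}

pattern_label <- function(members) paste(members, collapse = "&")

#' Venn region counts and exclusivity percentages for named protein sets
#'
#' Computes the count of every region of the Venn partition of 2--4 named
#' sets (elements belonging to exactly that combination of sets), per-set
#' totals and exclusives, all pairwise intersections, and percentages of the
#' union (or of a supplied total), rounded half-up to one decimal place.
#'
#' @param sets Named list of 2--4 character vectors.
#' @param total Optional denominator for percentages; defaults to the union
#'   size.
#' @return An object of class `fraction_summary`: a list with `totals`
#'   (per-set sizes, `union`, per-set `<name>_exclusive`, and for two sets
#'   `shared`), `regions` (exact Venn region counts keyed by `&`-joined set
#'   names), `pairwise` (full intersection counts for every pair) and
#'   `percentages`.
#' @examples
#' venn_counts(list(CF = c("a","b","c"), ACT = c("c","d")))
#' @export
venn_counts <- function(sets, total = NULL) {
  if (!length(sets)) contract_error("venn_counts: at least one set required")
  if (length(sets) > 4L) contract_error("venn_counts: at most 4 sets supported")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    contract_error("venn_counts: sets must be named")
  sets <- lapply(sets, unique)
  universe <- sort(unique(unlist(sets, use.names = FALSE)))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  if (length(universe) == 1L) member <- matrix(member, nrow = 1L,
                                               dimnames = list(NULL, names(sets)))
  if (!length(universe)) member <- matrix(logical(), 0L, length(sets),
                                          dimnames = list(NULL, names(sets)))
  nm <- names(sets)
  pat <- venn_patterns(nm)
  regions <- integer(nrow(pat))
  names(regions) <- apply(pat, 1L, function(row) pattern_label(nm[as.logical(row)]))
  # membership pattern of each element, encoded as a binary integer
  code <- as.integer(member %*% 2^(seq_along(nm) - 1L))
  pat_code <- as.integer(as.matrix(pat) %*% 2^(seq_along(nm) - 1L))
  tab <- tabulate(match(code, pat_code), nbins = length(pat_code))
  regions[] <- tab

  totals <- vapply(sets, length, integer(1))
  totals[["union"]] <- length(universe)
  exclusives <- vapply(seq_along(nm), function(i)
    sum(member[, i] & rowSums(member[, -i, drop = FALSE]) == 0L), integer(1))
  names(exclusives) <- paste0(nm, "_exclusive")
  totals <- c(totals, exclusives)
  if (length(nm) == 2L)
    totals[["shared"]] <- sum(member[, 1] & member[, 2])
  pairwise <- list()
  if (length(nm) >= 2L) {
    combs <- utils::combn(nm, 2L, simplify = FALSE)
    pairwise <- vapply(combs, function(p)
      sum(member[, p[1]] & member[, p[2]]), integer(1))
    names(pairwise) <- vapply(combs, pattern_label, character(1))
  }
  denom <- if (is.null(total)) totals[["union"]] else
    check_count(total, "total", 0L)
  percentages <- vapply(c(as.list(totals), as.list(regions)),
                        pct_of, numeric(1), total = denom)
  structure(list(totals = as.list(totals), regions = as.list(regions),
                 pairwise = as.list(pairwise),
                 percentages = as.list(percentages),
                 denominator = denom),
            class = "fraction_summary")
}

#' @export
print.fraction_summary <- function(x, ...) {
  cat("Fraction summary (denominator", x$denominator, "proteins)\n")
  for (k in names(x$totals))
    cat(sprintf("  %-18s %4d  (%s%%)\n", k, x$totals[[k]],
                format(x$percentages[[k]])))
  invisible(x)
}

#' Solubility-fraction summary of a detection matrix
#'
#' Tallies proteins with any detection in the water-insoluble (ISOM) and
#' water-soluble (SSOM) skeletal organic matrix fractions, their overlap and
#' exclusives. The union of the two equals the curated total by
#' construction (every curated protein has at least one detection).
#'
#' @param matrix A `detection_matrix`.
#' @return A `fraction_summary` over the sets `SSOM_all` and `ISOM_all`.
#' @export
solubility_summary <- function(matrix) {
  if (!nrow(matrix$cells)) contract_error("solubility_summary: empty matrix")
  sets <- list(
    SSOM_all = matrix_fraction_set(matrix, solubilities = "SSOM"),
    ISOM_all = matrix_fraction_set(matrix, solubilities = "ISOM")
  )
  venn_counts(sets, total = nrow(matrix$cells))
}

#' Method-group summary of a detection matrix
#'
#' Pools methods into protocol families ([combine_methods()]) and runs
#' [venn_counts()] on the resulting sets with the curated total as the
#' percentage denominator.
#'
#' @inheritParams solubility_summary
#' @param groups As in [combine_methods()].
#' @return A `fraction_summary`.
#' @export
method_group_summary <- function(matrix, groups = som_method_groups()) {
  venn_counts(combine_methods(matrix, groups), total = nrow(matrix$cells))
}
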