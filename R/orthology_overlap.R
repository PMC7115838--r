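# Cross-proteome orthology overlap and exact enrichment tails. Ortholog
# pairs (any multiplicity: 1:1, 1:many, many:many, BLASTP best hit) are
# consumed from a table; no orthogroup inference happens here.

#' Map a curated proteome onto previously published skeletal proteomes
#'
#' Plain set algebra over ortholog-pair endpoints restricted to curated
#' accessions: per published proteome, the curated proteins with at least
#' one ortholog there; their union (`any_overlap`) and intersection across
#' all configured proteomes (`all_overlap`).
#'
#' @param curated Character vector of curated accessions (or data.frame with
#'   an `accession` column).
#' @param pairs Ortholog-pair data.frame ([read_ortholog_table()]).
#' @param proteomes Character vector of configured proteome labels; defaults
#'   to the labels present in `pairs`. Pairs referencing other labels raise
#'   a vocabulary error.
#' @return An object of class `overlap_result`: list with `per_proteome`
#'   (named list of sorted accession vectors), `any_overlap`, `all_overlap`,
#'   and counts.
#' @export
map_orthologs <- function(curated, pairs, proteomes = NULL) {
  if (is.data.frame(curated)) curated <- curated$accession
  curated <- unique(curated)
  if (is.null(proteomes)) proteomes <- sort(unique(pairs$other_proteome))
  bad <- setdiff(unique(pairs$other_proteome), proteomes)
  if (length(bad))
    vocab_error("ortholog pair(s) reference unconfigured proteome label(s): %s",
                paste(bad, collapse = ", "))
  per <- lapply(proteomes, function(lab) {
    sort(intersect(curated,
                   pairs$target_accession[pairs$other_proteome == lab]))
  })
  names(per) <- proteomes
  any_overlap <- sort(unique(unlist(per, use.names = FALSE)))
  all_overlap <- if (length(per)) sort(Reduce(intersect, per)) else character()
  structure(list(per_proteome = per,
                 any_overlap = any_overlap,
                 all_overlap = all_overlap,
                 n_curated = length(curated),
                 n_any = length(any_overlap),
                 n_all = length(all_overlap)),
            class = "overlap_result")
}

#' @export
print.overlap_result <- function(x, ...) {
  cat("Orthology overlap:", x$n_any, "of", x$n_curated,
      "curated proteins with orthologs in any published proteome;",
      x$n_all, "in all\n")
  for (lab in names(x$per_proteome))
    cat(sprintf("  %-24s %d\n", lab, length(x$per_proteome[[lab]])))
  if (!is.null(x$enrichment))
    cat(sprintf("  enrichment p (binomial, p0=%g): %.4g\n",
                x$enrichment$background_p, x$enrichment$p_value))
  invisible(x)
}

#' Exact upper-tail enrichment test for the observed overlap
#'
#' Probability of observing at least `k` overlaps among `n` curated proteins
#' under the chance model: exact binomial upper tail when the background is
#' a proportion `p` (the fraction of known skeletal matrix proteins in the
#' reference proteomes), exact hypergeometric upper tail when it is given
#' as counts (`K` known proteins in a reference of size `N`). Both tails
#' are exact; no normal approximation is used.
#'
#' @param k Observed overlap count, `0 <= k <= n`.
#' @param n Curated proteome size.
#' @param p Background proportion in (0, 1) (binomial form).
#' @param K,N Background counts (hypergeometric form): `K` successes in a
#'   population of `N`.
#' @return A list with `p_value`, `model` (`"binomial"` or
#'   `"hypergeometric"`), `k`, `n` and the background parameters.
#' @examples
#' enrichment_test(16, 60, p = 0.002)
#' @export
enrichment_test <- function(k, n, p = NULL, K = NULL, N = NULL) {
  k <- check_count(k, "k", 0L)
  n <- check_count(n, "n", 0L)
  if (k > n) contract_error("enrichment_test: k (%d) exceeds n (%d)", k, n)
  if (!is.null(p)) {
    p <- check_number(p, "p", 0, 1)
    if (p <= 0) contract_error("enrichment_test: p must be in (0, 1]")
    pv <- if (k == 0L) 1 else pbinom(k - 1L, n, p, lower.tail = FALSE)
    return(list(p_value = pv, model = "binomial", k = k, n = n,
                background_p = p))
  }
  if (is.null(K) || is.null(N))
    config_error("enrichment_test: supply either p or both K and N")
  K <- check_count(K, "K", 0L)
  N <- check_count(N, "N", 0L)
  if (K > N) contract_error("enrichment_test: K (%d) exceeds N (%d)", K, N)
  if (n > N) contract_error("enrichment_test: n (%d) exceeds N (%d)", n, N)
  pv <- if (k == 0L) 1 else phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(p_value = pv, model = "hypergeometric", k = k, n = n, K = K, N = N)
}

#' Full orthology-overlap analysis with enrichment
#'
#' Runs [map_orthologs()] and attaches [enrichment_test()] results for the
#' observed `|any_overlap|` under both background forms when available.
#'
#' @inheritParams map_orthologs
#' @param background A list with either `p` (proportion) or `K` and `N`
#'   (counts); default `list(p = 0.002)`, the chance level for known
#'   skeletal matrix proteins in reference coral proteomes.
#' @return An `overlap_result` with an `enrichment` element.
#' @export
orthology_overlap <- function(curated, pairs, proteomes = NULL,
                              background = list(p = 0.002)) {
  res <- map_orthologs(curated, pairs, proteomes)
  res$enrichment <- enrichment_test(res$n_any, res$n_curated,
                                    p = background$p,
                                    K = background$K, N = background$N)
  if (res$enrichment$model == "binomial")
    res$enrichment$background_p <- background$p
  res
}

#' @rdname orthology_overlap
#' @param result An `overlap_result`.
#' @param path Output TSV path: one row per (curated protein, proteome) with
#'   membership, reproducing the published-comparison table layout.
#' @export
write_overlap_table <- function(result, path) {
  prots <- result$any_overlap
  rows <- lapply(names(result$per_proteome), function(lab)
    data.frame(accession = prots,
               proteome = lab,
               has_ortholog = prots %in% result$per_proteome[[lab]],
               stringsAsFactors = FALSE))
  df <- do.call(rbind, rows)
  if (is.null(df))
    df <- data.frame(accession = character(), proteome = character(),
                     has_ortholog = logical(), stringsAsFactors = FALSE)
  write_tsv(df[order(df$accession, df$proteome), , drop = FALSE], path)
}
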