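# Independent oracles and small fixture builders. Every oracle restates the
# rule it checks from scratch (naive loops, log-space summation) so it never
# shares code with the implementation under test.

ev_row <- function(accession = "P1", peptide = "AAAAAAAK", spectra = 1L,
                   significant = TRUE, score = 300, method = "CF2",
                   solubility = "ISOM") {
  data.frame(protein_accession = accession, peptide = peptide,
             spectra_count = as.integer(spectra), significant = significant,
             score = score, method = method, solubility = solubility,
             stringsAsFactors = FALSE)
}

# naive restatement of the acceptance rule over raw rows
brute_accept <- function(rows, min_sig = 2L, min_spectra = 10L,
                         min_score = 250) {
  sig_peps <- character()
  alt <- FALSE
  for (i in seq_len(nrow(rows))) {
    if (rows$significant[i]) {
      sig_peps <- union(sig_peps, rows$peptide[i])
      if (rows$spectra_count[i] >= min_spectra && rows$score[i] >= min_score)
        alt <- TRUE
    }
  }
  length(sig_peps) >= min_sig || alt
}

# double loop over (protein, method, solubility) triples
brute_detection <- function(evidence) {
  out <- list()
  for (p in unique(evidence$protein_accession)) {
    for (m in som_methods()) {
      for (s in som_solubilities()) {
        rows <- evidence[evidence$protein_accession == p &
                           evidence$method == m & evidence$solubility == s, ]
        if (nrow(rows) && brute_accept(rows))
          out[[length(out) + 1L]] <- c(p, paste(m, s, sep = "."))
      }
    }
  }
  out
}

# per-element membership-pattern tally, one element at a time
brute_venn_regions <- function(sets) {
  nm <- names(sets)
  universe <- unique(unlist(sets))
  counts <- integer(0)
  for (el in universe) {
    members <- nm[vapply(sets, function(s) el %in% s, logical(1))]
    key <- paste(members, collapse = "&")
    counts[key] <- if (key %in% names(counts)) counts[[key]] + 1L else 1L
  }
  counts
}

# position-by-position substring scan
brute_shared_count <- function(peptides, subject, min_len = 7L) {
  peptides <- unique(peptides[nchar(peptides) >= min_len])
  n <- 0L
  for (p in peptides) {
    found <- FALSE
    for (start in seq_len(max(0L, nchar(subject) - nchar(p) + 1L))) {
      if (substring(subject, start, start + nchar(p) - 1L) == p) {
        found <- TRUE
        break
      }
    }
    if (found) n <- n + 1L
  }
  n
}

# direct log-space summation of the binomial upper tail, independent of
# pbinom's incomplete-beta path
binom_tail_oracle <- function(k, n, p) {
  if (k == 0L) return(1)
  i <- k:n
  terms <- lgamma(n + 1) - lgamma(i + 1) - lgamma(n - i + 1) +
    i * log(p) + (n - i) * log1p(-p)
  m <- max(terms)
  exp(m) * sum(exp(terms - m))
}

rand_sets <- function(n_sets, universe_size = 30L) {
  universe <- sprintf("el%02d", seq_len(universe_size))
  sets <- lapply(seq_len(n_sets), function(i)
    sample(universe, sample.int(universe_size, 1L)))
  names(sets) <- LETTERS[seq_len(n_sets)]
  sets
}

extdata <- function(file) {
  system.file("extdata", file, package = "coralsom", mustWork = TRUE)
}

bundle_config_for <- function(manifest) {
  list(inputs = list(evidence = manifest$files$evidence,
                     annotation = manifest$files$annotation,
                     alignments = manifest$files$alignments,
                     contaminant_fasta = manifest$files$contaminant_fasta,
                     orthologs = manifest$files$orthologs,
                     target_fasta = manifest$files$target_fasta),
       proteomes = manifest$proteomes)
}
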