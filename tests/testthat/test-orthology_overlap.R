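proteome_labels <- c("A_digitifera", "A_millepora", "S_pistillata_prior")

test_that("published ortholog pairs reproduce the hand-counted overlaps", {
  pairs <- read_ortholog_table(extdata("coral_skeletal_orthologs.tsv"),
                               proteomes = proteome_labels)
  curated <- read.delim(extdata("spis_skeletal_proteome.tsv"),
                        stringsAsFactors = FALSE)$accession
  res <- map_orthologs(curated, pairs, proteome_labels)
  expect_equal(res$n_any, 16L)
  expect_equal(res$n_all, 7L)
  # per-proteome hand counts from the pair table
  expect_length(res$per_proteome$A_digitifera, 10L)
  expect_length(res$per_proteome$A_millepora, 12L)
  expect_length(res$per_proteome$S_pistillata_prior, 13L)
  expect_setequal(res$all_overlap,
                  c("PFX18785.1", "PFX30903.1", "XP_022780690.1",
                    "XP_022783415.1", "XP_022794736.1", "XP_022804012.1",
                    "XP_022806326.1"))
  expect_true(all(res$all_overlap %in% res$any_overlap))
  expect_true(all(res$any_overlap %in% curated))
})

test_that("set algebra handles empty tables and full membership", {
  pairs <- data.frame(target_accession = character(),
                      other_accession = character(),
                      other_proteome = character(), relation = character())
  res <- map_orthologs(c("P1", "P2"), pairs, proteome_labels)
  expect_equal(res$n_any, 0L)
  expect_equal(res$n_all, 0L)

  pairs <- data.frame(target_accession = "P1",
                      other_accession = c("a", "b", "c"),
                      other_proteome = proteome_labels,
                      relation = "one_to_one", stringsAsFactors = FALSE)
  res <- map_orthologs(c("P1", "P2"), pairs, proteome_labels)
  expect_equal(res$all_overlap, "P1")

  bad <- pairs; bad$other_proteome[1] <- "unknown_proteome"
  expect_error(map_orthologs("P1", bad, proteome_labels),
               class = "coralsom_vocab_error")
})

test_that("exact binomial tails match a frozen high-precision oracle", {
  # values frozen from a 60-digit arbitrary-precision summation
  expect_equal(enrichment_test(16, 60, p = 0.002)$p_value,
               9.02479254653950e-30, tolerance = 1e-12)
  expect_equal(enrichment_test(5, 20, p = 0.1)$p_value,
               0.04317449528446338, tolerance = 1e-12)
  expect_equal(enrichment_test(3, 10, p = 0.05)$p_value,
               0.011503557379296875, tolerance = 1e-12)
})

test_that("degenerate tails behave at the boundaries", {
  expect_equal(enrichment_test(0, 60, p = 0.002)$p_value, 1)
  expect_equal(enrichment_test(10, 10, p = 1)$p_value, 1)
  expect_error(enrichment_test(5, 3, p = 0.1),
               class = "coralsom_contract_error")
  expect_error(enrichment_test(2, 5, K = 10, N = 4),
               class = "coralsom_contract_error")
  expect_error(enrichment_test(2, 5), class = "coralsom_config_error")
})

test_that("binomial tails match log-space summation for all n up to 100", {
  for (n in 1:100) {
    for (k in unique(c(1L, ceiling(n / 2), n))) {
      for (p in c(0.002, 0.1, 0.5)) {
        expect_equal(enrichment_test(k, n, p = p)$p_value,
                     binom_tail_oracle(k, n, p),
                     tolerance = 1e-10)
      }
    }
  }
})

test_that("tails are monotone in k and in p", {
  pv_k <- vapply(0:60, function(k) enrichment_test(k, 60, p = 0.1)$p_value,
                 numeric(1))
  expect_true(all(diff(pv_k) <= 1e-15))
  ps <- c(0.001, 0.01, 0.05, 0.2, 0.5, 0.9)
  pv_p <- vapply(ps, function(p) enrichment_test(16, 60, p = p)$p_value,
                 numeric(1))
  expect_true(all(diff(pv_p) >= -1e-15))
})

test_that("hypergeometric converges to binomial in the large-population limit", {
  n <- 30L
  N <- 1000000L * n  # vanishing sampling fraction
  for (p in c(0.002, 0.05)) {
    K <- as.integer(round(p * N))
    for (k in c(1L, 5L, 15L)) {
      expect_lt(abs(enrichment_test(k, n, K = K, N = N)$p_value -
                      enrichment_test(k, n, p = K / N)$p_value), 1e-6)
    }
  }
})

test_that("the combined analysis attaches the enrichment to the overlap", {
  pairs <- read_ortholog_table(extdata("coral_skeletal_orthologs.tsv"))
  curated <- read.delim(extdata("spis_skeletal_proteome.tsv"),
                        stringsAsFactors = FALSE)$accession
  res <- orthology_overlap(curated, pairs, background = list(p = 0.002))
  expect_equal(res$enrichment$k, 16L)
  expect_equal(res$enrichment$n, 60L)
  expect_lt(res$enrichment$p_value, 1e-20)
  expect_gte(res$enrichment$p_value, 0)
})
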