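toy_matrix <- function(cells) {
  # cells: named list accession -> character vector of "METHOD.SOL" labels
  m <- matrix(FALSE, length(cells), length(som_fractions()),
              dimnames = list(names(cells), som_fractions()))
  for (p in names(cells)) m[p, cells[[p]]] <- TRUE
  structure(list(cells = m,
                 best_score = stats::setNames(rep(300, length(cells)),
                                              names(cells))),
            class = "detection_matrix")
}

test_that("method pooling assigns proteins by any-solubility detection", {
  m <- toy_matrix(list(P1 = "ACT3.ISOM",
                       P2 = c("CF2.SSOM", "ACT1.ISOM"),
                       P3 = "CF4.ISOM"))
  groups <- combine_methods(m)
  expect_equal(groups$CF, c("P2", "P3"))
  expect_equal(groups$ACT, c("P1", "P2"))
  expect_error(combine_methods(m, list(BAD = "CF9")),
               class = "coralsom_vocab_error")
})

test_that("two-set venn reproduces the headline overlap arithmetic", {
  # 52 CF proteins and 13 ACT proteins over a 60-protein union: 5 shared
  prot <- sprintf("P%02d", 1:60)
  sets <- list(CF = prot[1:52], ACT = prot[48:60])
  v <- venn_counts(sets)
  expect_equal(v$totals$union, 60L)
  expect_equal(v$totals$shared, 5L)
  expect_equal(v$percentages$shared, 8.3)
  expect_equal(v$percentages$CF_exclusive, 78.3)
  expect_equal(v$percentages$ACT_exclusive, 13.3)
  # inclusion-exclusion
  expect_equal(v$totals$CF + v$totals$ACT - v$pairwise[["CF&ACT"]],
               v$totals$union)

  v <- venn_counts(list(A = c("a", "b", "c"), B = c("d", "e", "f", "g")))
  expect_equal(v$totals$shared, 0L)
  expect_equal(v$totals$union, 7L)
  expect_error(venn_counts(list()), class = "coralsom_contract_error")
})

test_that("venn regions agree with per-element membership tallies", {
  set.seed(5)
  for (rep in 1:400) {
    sets <- rand_sets(sample(2:4, 1L))
    v <- venn_counts(sets)
    brute <- brute_venn_regions(sets)
    for (key in names(v$regions)) {
      want <- if (key %in% names(brute)) brute[[key]] else 0L
      expect_identical(v$regions[[key]], want)
    }
    expect_equal(sum(unlist(v$regions)), v$totals$union)
    # pairwise inclusion-exclusion on every pair
    for (pair in names(v$pairwise)) {
      ab <- strsplit(pair, "&", fixed = TRUE)[[1]]
      u <- length(union(sets[[ab[1]]], sets[[ab[2]]]))
      expect_equal(v$totals[[ab[1]]] + v$totals[[ab[2]]] -
                     v$pairwise[[pair]], u)
    }
  }
})

test_that("counts are invariant under protein order and set order", {
  set.seed(6)
  sets <- rand_sets(3L)
  v1 <- venn_counts(sets)
  shuffled <- lapply(sets, sample)
  v2 <- venn_counts(shuffled)
  expect_equal(v1$regions, v2$regions)
  expect_equal(v1$totals, v2$totals)
})

test_that("solubility summary counts ISOM/SSOM memberships and exclusives", {
  m <- toy_matrix(list(P1 = "CF4.ISOM"))
  s <- solubility_summary(m)
  expect_equal(s$totals$ISOM_all, 1L)
  expect_equal(s$totals$SSOM_all, 0L)

  # planted 10 ISOM-only, 2 SSOM-only, 3 in both
  cells <- c(
    stats::setNames(rep("CF2.ISOM", 10), sprintf("I%02d", 1:10)),
    stats::setNames(rep("ACT1.SSOM", 2), sprintf("S%02d", 1:2)),
    stats::setNames(rep(list(c("CF2.ISOM", "CF2.SSOM")), 3),
                    sprintf("B%02d", 1:3)))
  s <- solubility_summary(toy_matrix(as.list(cells)))
  expect_equal(s$totals$ISOM_all, 13L)
  expect_equal(s$totals$SSOM_all, 5L)
  expect_equal(s$totals$shared, 3L)
  expect_equal(s$totals$union, 15L)
  expect_equal(s$totals$ISOM_all_exclusive, 10L)
})

test_that("published solubility marks tally exactly as printed", {
  tab <- read.delim(extdata("spis_skeletal_proteome.tsv"),
                    stringsAsFactors = FALSE)
  # hand count of the solubility columns of the shipped 60-protein table
  expect_equal(sum(tab$ssom), 7L)
  expect_equal(sum(tab$isom), 59L)
  expect_equal(sum(tab$ssom & tab$isom), 6L)
  expect_equal(nrow(tab), 60L)
})

test_that("percentages round half away from zero at one decimal", {
  expect_equal(round_half_up(8.35), 8.4)
  expect_equal(round_half_up(78.333333), 78.3)
  expect_equal(round_half_up(2.25), 2.3)
  expect_equal(round_half_up(-2.25), -2.3)
  v <- venn_counts(list(A = letters[1:5], B = letters[5:8]), total = 60)
  expect_equal(v$percentages$shared, round_half_up(100 * 1 / 60))
})
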