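ann_row <- function(accession = "P1", complete = TRUE, sp = FALSE, tm = 0L,
                    gpi = FALSE, go = "", desc = "") {
  data.frame(accession = accession, n_term_complete = complete,
             signal_peptide = sp, tm_span_count = as.integer(tm),
             gpi_anchor = gpi, go_terms = go, description = desc,
             stringsAsFactors = FALSE)
}

test_that("signal peptides only count on complete N-termini", {
  # SP predicted but gene model incomplete: not counted, and with no other
  # export evidence the protein is a non-classical candidate
  x <- classify_export(ann_row(sp = TRUE, complete = FALSE))
  expect_false(x$has_sp)
  expect_true(x$signal_peptide_raw)
  expect_true(x$non_classical_candidate)

  x <- classify_export(ann_row(tm = 1L))
  expect_true(x$has_tm)
  expect_true(x$ecm_evidence)

  x <- classify_export(ann_row())
  expect_true(x$non_classical_candidate)
})

test_that("export classes partition every proteome", {
  set.seed(12)
  ann <- do.call(rbind, lapply(1:50, function(i)
    ann_row(sprintf("P%02d", i), complete = runif(1) < 0.7,
            sp = runif(1) < 0.4, tm = sample(0:2, 1),
            gpi = runif(1) < 0.2)))
  x <- classify_export(ann)
  expect_true(all(xor(x$ecm_evidence, x$non_classical_candidate)))
  expect_equal(sum(x$ecm_evidence) + sum(x$non_classical_candidate), 50L)
})

test_that("GO rules and keyword rules assign categories, possibly several", {
  cats <- classify_function(ann_row(go = "GO:0005509"))
  expect_equal(cats$P1, "metal_binding")
  # vesicle transport + calcium binding: both categories
  cats <- classify_function(ann_row(go = "GO:0016192|GO:0005509"))
  expect_setequal(cats$P1, c("metal_binding", "vesicular_secretion"))
  # no GO terms, no description match: uncharacterized (empty set)
  cats <- classify_function(ann_row())
  expect_length(cats$P1, 0)
  # keyword rule against the description
  cats <- classify_function(ann_row(desc = "Collagenase 3-like"))
  expect_true("protein_modification" %in% cats$P1)
  expect_true("ecm_tm_protein_modification" %in% cats$P1)
})

test_that("malformed maps are configuration errors", {
  bad <- data.frame(field = "description", pattern = "([", category = "metal_binding")
  expect_error(classify_function(ann_row(), bad),
               class = "coralsom_config_error")
  bad <- data.frame(field = "go", pattern = "GO:0000001", category = "nope")
  expect_error(classify_function(ann_row(), bad),
               class = "coralsom_config_error")
})

test_that("tallies count each protein once per category", {
  ann <- rbind(ann_row("P1", go = "GO:0005509"),
               ann_row("P2", go = "GO:0016192"),
               ann_row("P3", go = "GO:0008233"),
               ann_row("P4", go = "GO:0005509|GO:0016192"),
               ann_row("P5"))
  cats <- classify_function(ann)
  t <- tally_categories(classify_export(ann), cats)
  expect_equal(t$category_counts$metal_binding, 2L)
  expect_equal(t$category_counts$vesicular_secretion, 2L)
  expect_equal(t$category_counts$protein_modification, 1L)
  expect_equal(t$category_counts$membrane_processing, 0L)
  expect_equal(t$n_categorized, 4L)
  expect_true(all(unlist(t$category_counts) <= nrow(ann)))
})

test_that("planted category memberships are recovered exactly", {
  dir <- withr::local_tempdir()
  man <- generate_bundle(synthetic_config(seed = 21), dir)
  ann <- read_annotation_table(man$files$annotation)
  ann <- ann[match(man$skeletal, ann$accession), ]
  cats <- classify_function(ann)
  for (acc in man$skeletal)
    expect_setequal(cats[[acc]], man$categories[[acc]])
  t <- tally_categories(classify_export(ann), cats)
  expect_equal(t$export_counts$has_sp, man$export$has_sp)
  expect_equal(t$export_counts$has_tm, man$export$has_tm)
  expect_equal(t$export_counts$has_gpi, man$export$has_gpi)
})

test_that("the category-map digest pins the rule set", {
  d1 <- category_map_digest()
  d2 <- category_map_digest(default_category_map())
  expect_identical(d1, d2)
  altered <- default_category_map()
  altered$pattern[1] <- "GO:0099999"
  expect_false(identical(d1, category_map_digest(altered)))
  # rule order must not matter
  shuffled <- default_category_map()[sample(nrow(default_category_map())), ]
  expect_identical(d1, category_map_digest(shuffled))
})
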