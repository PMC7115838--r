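hit_row <- function(evalue, similarity, query = "P1", subject = "H1") {
  data.frame(query_accession = query, subject_accession = subject,
             evalue = evalue, percent_similarity = similarity,
             align_length = 100L, identical_positions = 80L, bitscore = 200,
             similarity_source = "ppos", stringsAsFactors = FALSE)
}

test_that("candidate flagging uses strict inequalities on all three branches", {
  expect_true(flag_candidate(hit_row(1e-60, 55))$candidate)   # branch 1
  expect_true(flag_candidate(hit_row(1e-120, 30))$candidate)  # branch 2
  expect_true(flag_candidate(hit_row(0.5, 85))$candidate)     # branch 3
  # exact boundary values fail every branch
  expect_false(flag_candidate(hit_row(1e-50, 50))$candidate)
  expect_false(flag_candidate(hit_row(1e-100, 50))$candidate)
  expect_false(flag_candidate(hit_row(1e-40, 80))$candidate)
  expect_false(flag_candidate(hit_row(1, 80))$candidate)
  expect_false(flag_candidate(hit_row(1e-60, 50)[0, ])$candidate)  # no hits
})

test_that("triggering hit is the smallest e-value, ties by similarity then subject", {
  hits <- rbind(hit_row(1e-120, 40, subject = "H2"),
                hit_row(1e-150, 60, subject = "H3"),
                hit_row(1e-150, 60, subject = "H1"),
                hit_row(1e-150, 70, subject = "H4"))
  trig <- flag_candidate(hits)$triggering_hit
  expect_equal(trig$subject_accession, "H4")  # best similarity at min e-value
  hits <- hits[hits$percent_similarity != 70, ]
  expect_equal(flag_candidate(hits)$triggering_hit$subject_accession, "H1")
})

test_that("tryptic digestion cleaves after K/R except before proline", {
  expect_equal(tryptic_peptides("MKLVNPTRGQWK"), c("MK", "LVNPTR", "GQWK"))
  expect_equal(tryptic_peptides("AKPLR"), "AKPLR")  # K before P: no cleavage
  expect_equal(tryptic_peptides("R"), "R")
  expect_equal(tryptic_peptides(""), character())
})

test_that("shared-peptide counting is exact substring matching with a length floor", {
  subject <- paste0("GGGG", "MKLVNTTR", "AA", "GQWERTYK", "CC", "AAAAAAAK", "GG")
  res <- shared_peptides(c("MKLVNTTR", "GQWERTYK", "AAAAAAAK"), subject)
  expect_equal(res$count, 3L)
  # length-6 peptide excluded by the floor even though present
  res <- shared_peptides(c("MKLVNTTR", "SHORTK"),
                         paste0("XX", "MKLVNTTR", "SHORTK"))
  expect_equal(res$count, 1L)
  expect_equal(res$peptides, "MKLVNTTR")
  # I and L are never folded together
  expect_equal(shared_peptides("AAAIAAAK", "CCAAALAAAKCC")$count, 0L)
})

test_that("shared-peptide counts match an exhaustive substring scan", {
  set.seed(7)
  for (rep in 1:200) {
    subject <- paste(sample(LETTERS[1:20], 300, TRUE), collapse = "")
    peps <- vapply(1:20, function(i)
      paste(sample(LETTERS[1:20], 8, TRUE), collapse = ""), character(1))
    # embed a few so matches actually occur
    k <- sample(0:3, 1)
    if (k > 0) {
      pos <- sample(280, k)
      for (j in seq_len(k))
        substring(subject, pos[j], pos[j] + 7) <- peps[j]
    }
    expect_equal(shared_peptides(peps, subject)$count,
                 brute_shared_count(peps, subject))
  }
})

screen_fixture <- function() {
  peps <- c("AAAAAAAQK", "CCCCCCCQK", "DDDDDDDQK")
  ev <- do.call(rbind, lapply(peps, function(p) ev_row("P1", p)))
  ev <- rbind(ev, ev_row("P2", "EEEEEEEQK"), ev_row("P3", "FFFFFFFQK"))
  db <- data.frame(
    accession = c("H1", "H2"),
    sequence = c(paste0("GGGG", paste(peps, collapse = "GG"), "GGGG"),
                 "WWWWWWWWWWWWWWWWWWWW"),
    stringsAsFactors = FALSE)
  list(ev = ev, db = db, peps = peps)
}

test_that("removal requires both a qualifying hit and three shared peptides", {
  fx <- screen_fixture()
  # P1: strong hit + 3 shared peptides -> removed
  hits <- hit_row(1e-110, 85, query = "P1", subject = "H1")
  v <- screen_proteome(c("P1", "P2", "P3"), fx$ev, hits, fx$db)
  expect_true(v$removed[v$accession == "P1"])
  expect_equal(v$shared_peptide_count[v$accession == "P1"], 3L)
  expect_equal(v$triggering_subject[v$accession == "P1"], "H1")
  # candidates without the shared-peptide quota are retained
  db2 <- fx$db
  db2$sequence[1] <- paste0("GG", fx$peps[1], "GG", fx$peps[2], "GG")
  v <- screen_proteome("P1", fx$ev, hits, db2)
  expect_false(v$removed)
  expect_equal(v$shared_peptide_count, 2L)
  expect_true(v$candidate)
  # shared peptides without any qualifying hit: retained (removal implies
  # candidate)
  weak <- hit_row(0.5, 30, query = "P1", subject = "H1")
  v <- screen_proteome("P1", fx$ev, weak, fx$db)
  expect_false(v$candidate)
  expect_false(v$removed)
  # verdict invariant on every row
  expect_true(all(!v$removed | v$candidate))
})

test_that("shared peptides must co-occur against a single contaminant protein", {
  fx <- screen_fixture()
  # split the three peptides across two subjects: never 3 against one
  db <- data.frame(
    accession = c("H1", "H2"),
    sequence = c(paste0("GG", fx$peps[1], "GG", fx$peps[2], "GG"),
                 paste0("GG", fx$peps[3], "GG")),
    stringsAsFactors = FALSE)
  hits <- rbind(hit_row(1e-110, 85, query = "P1", subject = "H1"),
                hit_row(1e-105, 82, query = "P1", subject = "H2"))
  v <- screen_proteome("P1", fx$ev, hits, db)
  expect_false(v$removed)
  expect_equal(v$shared_peptide_count, 2L)  # best single subject
})

test_that("hits referencing unknown subjects are a referential-integrity error", {
  fx <- screen_fixture()
  hits <- hit_row(1e-110, 85, query = "P1", subject = "MISSING")
  expect_error(screen_proteome("P1", fx$ev, hits, fx$db),
               class = "coralsom_integrity_error")
})

test_that("tryptic fallback mode digests the target sequence", {
  fx <- screen_fixture()
  target <- data.frame(accession = "P1",
                       sequence = paste0(fx$peps[1], fx$peps[2], fx$peps[3]),
                       stringsAsFactors = FALSE)
  hits <- hit_row(1e-110, 85, query = "P1", subject = "H1")
  v <- screen_proteome("P1", fx$ev[0, ], hits, fx$db,
                       peptide_mode = "tryptic", target_db = target)
  expect_true(v$removed)
  expect_equal(v$peptide_mode, "tryptic")
})

test_that("adding target peptides never decreases the shared count", {
  set.seed(9)
  subject <- paste(sample(LETTERS[1:20], 400, TRUE), collapse = "")
  peps <- substring(subject, seq(1, 100, 10), seq(8, 107, 10))
  counts <- vapply(seq_along(peps), function(k)
    shared_peptides(peps[seq_len(k)], subject)$count, integer(1))
  expect_true(all(diff(counts) >= 0))
})
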