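test_that("self-alignment in ungapped mode sums diagonal matrix entries", {
  s <- scoring_scheme("PAM30")
  q <- "ACDEFK"
  expect_equal(local_align_score(q, q, s, ungapped = TRUE),
               sum(diag(s$matrix[strsplit(q, "")[[1]],
                                 strsplit(q, "")[[1]]])))
  # substitution cannot raise the ungapped score
  for (m in c("BLOSUM62", "PAM30")) {
    sch <- scoring_scheme(m)
    expect_gte(local_align_score("AC", "AC", sch, ungapped = TRUE),
               local_align_score("AC", "AG", sch, ungapped = TRUE))
  }
  expect_error(local_align_score("ACB", "ACD", s, ungapped = TRUE),
               class = "abkit_input_error")
  expect_error(local_align_score("ACD", "AC", s, ungapped = TRUE),
               class = "abkit_input_error")
})

test_that("local alignment matches an independent affine-gap oracle", {
  set.seed(101)
  for (m in c("BLOSUM62", "PAM30")) {
    sch <- scoring_scheme(m)
    qs <- random_aa(12, k = 6)
    ts <- random_aa(12, k = 6)
    for (i in seq_along(qs)) {
      expect_equal(
        local_align_score(qs[i], ts[i], sch),
        oracle_local_align(qs[i], ts[i], sch$matrix, sch$gap_open,
                           sch$gap_extend),
        info = paste(m, qs[i], ts[i]))
    }
  }
})

test_that("alignment score is symmetric for symmetric matrices", {
  set.seed(102)
  sch <- scoring_scheme("BLOSUM62")
  qs <- random_aa(8, k = 7)
  ts <- random_aa(8, k = 7)
  for (i in seq_along(qs)) {
    expect_equal(local_align_score(qs[i], ts[i], sch),
                 local_align_score(ts[i], qs[i], sch))
  }
})

test_that("single-point substitution toward the template never lowers the ungapped score", {
  set.seed(103)
  sch <- scoring_scheme("PAM30")
  for (rep in 1:10) {
    q <- strsplit(random_aa(1, k = 8), "")[[1]]
    t <- strsplit(random_aa(1, k = 8), "")[[1]]
    i <- sample(8, 1)
    q2 <- q
    q2[i] <- t[i]
    expect_gte(local_align_score(paste0(q2, collapse = ""),
                                 paste0(t, collapse = ""), sch,
                                 ungapped = TRUE),
               local_align_score(paste0(q, collapse = ""),
                                 paste0(t, collapse = ""), sch,
                                 ungapped = TRUE))
  }
})

test_that("PDB exclusion is case-insensitive and proline filter symmetric", {
  hits <- tibble::tibble(pdb_id = c("1ahw", "2abc"), score = c(5, 3))
  expect_equal(filter_exclude_pdb(hits, "1AHW")$pdb_id, "2abc")
  expect_equal(filter_exclude_pdb(hits, character()), hits)
  expect_warning(out <- filter_exclude_pdb(hits, c("1ahw", "2ABC")),
                 "all hits excluded")
  expect_equal(nrow(out), 0)

  expect_true(filter_proline_mismatch("APGK", "APGK")$keep)
  f1 <- filter_proline_mismatch("APGK", "AAGK")
  expect_false(f1$keep)
  expect_equal(f1$mismatch_positions, 2L)
  expect_false(filter_proline_mismatch("AAGK", "APGK")$keep)
  expect_error(filter_proline_mismatch("AAG", "APGK"),
               class = "abkit_input_error")
})

test_that("exclude and proline filters commute", {
  set.seed(104)
  hits <- tibble::tibble(pdb_id = sprintf("x%02d", 1:6),
                         sequence = random_aa(6, k = 5))
  query <- "APGKA"
  excl <- c("X02", "x05")
  via1 <- filter_exclude_pdb(hits, excl)
  via1 <- via1[vapply(via1$sequence,
                      function(s) filter_proline_mismatch(query, s)$keep,
                      logical(1)), ]
  via2 <- hits[vapply(hits$sequence,
                      function(s) filter_proline_mismatch(query, s)$keep,
                      logical(1)), ]
  via2 <- filter_exclude_pdb(via2, excl)
  expect_equal(via1, via2)
})

test_that("template selection ranks pools like a score-all-and-sort oracle", {
  dir <- file.path(tempdir(), "abkit-seltest")
  make_fixture_corpus(4, seed = 47L, dir = dir)
  db <- build_database(dir, file.path(dir, "summary.tsv"))
  query_fx <- make_fixture_antibody(seed = 48L)
  qseqs <- region_sequences(query_fx$structure)

  sel <- select_templates(qseqs, db, proline_filter = FALSE)
  expect_true(all(unique(sel$region) %in% db$pools$region))
  # oracle: score every pool member and sort with the documented tiebreak
  h3q <- qseqs$sequence[qseqs$region == "CDR_H3"]
  pool <- db$pools |> dplyr::filter(region == "CDR_H3")
  sch <- scoring_scheme("PAM30")
  scores <- vapply(pool$sequence,
                   function(t) local_align_score(h3q, t, sch,
                                                 ungapped = TRUE),
                   numeric(1))
  oracle_order <- pool$pdb_id[order(-scores, pool$resolution,
                                    pool$avg_bfactor, pool$pdb_id)]
  got <- sel |> dplyr::filter(region == "CDR_H3")
  expect_equal(got$pdb_id, oracle_order)
  expect_equal(got$rank, seq_along(oracle_order))

  # a query matching a pool record exactly ranks it first
  self_seqs <- region_sequences(
    read_chothia_structure(file.path(dir, "f002.pdb"),
                           tibble::tibble(pdb = "f002", Hchain = "H",
                                          Lchain = "L", resolution = 2,
                                          method = "X")))
  sel_self <- select_templates(self_seqs, db, proline_filter = FALSE)
  expect_true(all((sel_self |> dplyr::filter(rank == 1))$pdb_id == "f002"))

  # excluding the query's own source promotes the second best
  sel_excl <- select_templates(self_seqs, db, exclude_pdb = "F002",
                               proline_filter = FALSE)
  expect_false(any(sel_excl$pdb_id == "f002"))

  # determinism
  expect_equal(select_templates(qseqs, db, proline_filter = FALSE), sel)

  # CDR length with no pool yields empty ranking plus warning
  odd <- qseqs
  odd$sequence[odd$region == "CDR_H3"] <- "ACDK"
  odd$length[odd$region == "CDR_H3"] <- 4L
  expect_warning(sel_odd <- select_templates(odd, db,
                                             proline_filter = FALSE),
                 "nearest available")
  expect_false("CDR_H3" %in% sel_odd$region)
})
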