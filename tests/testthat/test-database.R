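test_that("entry selection keeps the first non-scFv row", {
  rows <- tibble::tibble(pdb = "1abc",
                         Hchain = c("H", "B"), Lchain = c("L", "C"),
                         resolution = 2, method = "X-RAY DIFFRACTION")
  expect_equal(select_antibody_from_entry(rows)$Hchain, "H")
  nano <- tibble::tibble(pdb = "1abc", Hchain = "H", Lchain = NA,
                         resolution = 2, method = "X-RAY DIFFRACTION")
  expect_equal(select_antibody_from_entry(nano)$Hchain, "H")
  scfv_first <- rows
  scfv_first$Lchain[1] <- "H"
  expect_equal(select_antibody_from_entry(scfv_first)$Hchain, "B")
  all_scfv <- tibble::tibble(pdb = "1abc", Hchain = "A", Lchain = "A",
                             resolution = 2, method = "X-RAY DIFFRACTION")
  expect_error(select_antibody_from_entry(all_scfv), class = "abkit_scfv")
})

corpus_db <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dir <- file.path(tempdir(), "abkit-corpus5")
      m <- make_fixture_corpus(5, seed = 41L, dir = dir)
      cache <<- list(dir = dir,
                     db = build_database(dir, file.path(dir, "summary.tsv")))
    }
    cache
  }
})

test_that("clean distinct fixtures all enter the pools", {
  db <- corpus_db()$db
  expect_equal(db$provenance$n_accepted, 5)
  l1 <- db$pools |> dplyr::filter(region == "CDR_L1")
  expect_equal(nrow(l1), 5)
  expect_true(all(l1$length == 11))
  # pool length invariant, exhaustively
  expect_true(all(nchar(db$pools$sequence) == db$pools$length))
  # accounting: accepted + rejected covers all entries
  expect_equal(db$provenance$n_accepted +
                 length(unique(db$provenance$rejections$pdb_id)),
               db$provenance$n_entries)
})

test_that("identical Fv sequences are deduplicated, first kept", {
  dir <- withr::local_tempdir()
  make_fixture_corpus(5, seed = 42L, dir = dir, n_duplicates = 1)
  db <- build_database(dir, file.path(dir, "summary.tsv"))
  expect_equal(db$provenance$n_accepted, 4)
  rej <- db$provenance$rejections
  expect_equal(rej$criterion, "duplicate_sequence")
  expect_equal(rej$pdb_id, "f005")
  expect_true("f001" %in% db$provenance$accepted)
})

test_that("quality rejections are logged with their criterion", {
  dir <- withr::local_tempdir()
  make_fixture_corpus(4, seed = 43L, dir = dir,
                      resolutions = c(2.0, 3.2, 2.0, 2.0),
                      defects = list(
                        "3" = list(list(kind = "zero_occupancy",
                                        chain_kind = "light",
                                        resno = 40))))
  db <- build_database(dir, file.path(dir, "summary.tsv"))
  expect_equal(db$provenance$n_accepted, 2)
  rej <- db$provenance$rejections
  expect_equal(rej$criterion[rej$pdb_id == "f002"], "resolution")
  expect_equal(rej$criterion[rej$pdb_id == "f003"], "occupancy")
  expect_false(any(db$pools$pdb_id %in% c("f002", "f003")))
})

test_that("CDR chainbreaks drop the region but keep the entry", {
  dir <- withr::local_tempdir()
  make_fixture_corpus(2, seed = 44L, dir = dir,
                      defects = list(
                        "2" = list(list(kind = "long_bond",
                                        chain_kind = "light", resno = 28,
                                        distance = 4))))
  db <- build_database(dir, file.path(dir, "summary.tsv"))
  expect_equal(db$provenance$n_accepted, 2)
  l1 <- db$pools |> dplyr::filter(region == "CDR_L1")
  expect_false("f002" %in% l1$pdb_id)
  h3 <- db$pools |> dplyr::filter(region == "CDR_H3")
  expect_true("f002" %in% h3$pdb_id)
})

test_that("pool files use the database.<region>.<length> convention", {
  db <- corpus_db()$db
  out <- withr::local_tempdir()
  write_pools(db, out)
  expect_true(file.exists(file.path(out, "database.L1.11")))
  fasta <- Biostrings::readAAStringSet(file.path(out, "database.L1.11"))
  expect_equal(length(fasta), 5)
  expect_true(all(Biostrings::width(fasta) == 11))
  expect_setequal(names(fasta), sprintf("f%03d", 1:5))
  # info row counts equal accepted entries per region
  info <- readr::read_tsv(file.path(out, "info.L1.tsv"),
                          show_col_types = FALSE)
  expect_equal(nrow(info), 5)
  # round-trip through the FASTA reader
  back <- read_pools(out)
  expect_equal(dplyr::arrange(back$pools[, c("region", "length", "pdb_id",
                                             "sequence")],
                              region, length, pdb_id),
               dplyr::arrange(db$pools[, c("region", "length", "pdb_id",
                                           "sequence")],
                              region, length, pdb_id))
})

test_that("rebuilds are byte-identical and monotone under additions", {
  dir <- withr::local_tempdir()
  make_fixture_corpus(3, seed = 45L, dir = dir)
  db1 <- build_database(dir, file.path(dir, "summary.tsv"))
  out1 <- withr::local_tempdir()
  out2 <- withr::local_tempdir()
  write_pools(db1, out1)
  db2 <- build_database(dir, file.path(dir, "summary.tsv"))
  write_pools(db2, out2)
  for (f in setdiff(list.files(out1), "provenance.json")) {
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)), label = f)
  }
  # regenerating the corpus itself is byte-identical too
  dirb <- withr::local_tempdir()
  make_fixture_corpus(3, seed = 45L, dir = dirb)
  for (f in list.files(dir)) {
    expect_identical(readLines(file.path(dirb, f)),
                     readLines(file.path(dir, f)), label = f)
  }
  # adding a clean novel fixture only adds records
  fx <- make_fixture_antibody(seed = 999L, pdb_id = "g001")
  write_structure_pdb(fx$structure, file.path(dir, "g001.pdb"))
  summ <- readr::read_tsv(file.path(dir, "summary.tsv"),
                          show_col_types = FALSE)
  readr::write_tsv(dplyr::bind_rows(summ, fx$summary),
                   file.path(dir, "summary.tsv"))
  db3 <- build_database(dir, file.path(dir, "summary.tsv"))
  expect_equal(db3$provenance$n_accepted, 4)
  old_keys <- paste(db1$pools$region, db1$pools$pdb_id)
  new_keys <- paste(db3$pools$region, db3$pools$pdb_id)
  expect_true(all(old_keys %in% new_keys))
  expect_gt(nrow(db3$pools), nrow(db1$pools))
})

test_that("scFv entries are skipped with a logged reason", {
  dir <- withr::local_tempdir()
  make_fixture_corpus(2, seed = 46L, dir = dir,
                      defects = list("2" = list(list(kind = "scfv"))))
  db <- build_database(dir, file.path(dir, "summary.tsv"))
  expect_equal(db$provenance$n_accepted, 1)
  expect_equal(db$provenance$rejections$criterion, "scfv")
})
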