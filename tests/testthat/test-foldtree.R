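test_that("center of mass is the unweighted heavy-atom centroid", {
  one <- tibble::tibble(element = "C", x = 1, y = 2, z = 3)
  expect_equal(center_of_mass(one), c(1, 2, 3))
  two <- tibble::tibble(element = c("C", "N"), x = c(1, -1), y = 0, z = 0)
  expect_equal(center_of_mass(two), c(0, 0, 0))
  set.seed(201)
  rnd <- tibble::tibble(element = sample(c("C", "N", "O"), 40, TRUE),
                        x = rnorm(40), y = rnorm(40), z = rnorm(40))
  expect_equal(center_of_mass(rnd),
               c(sum(rnd$x), sum(rnd$y), sum(rnd$z)) / 40)
  withH <- dplyr::bind_rows(two, tibble::tibble(element = "H", x = 100,
                                                y = 0, z = 0))
  expect_equal(center_of_mass(withH), c(0, 0, 0))
  expect_error(center_of_mass(withH[withH$element == "Z", ]))
})

test_that("linear tree has chains-1 jumps anchored at COM-proximal residues", {
  fx <- make_fixture_antibody(seed = 61L,
                              chains = c("light", "heavy", "antigen"))
  ft <- linear_foldtree(fx$structure)
  expect_equal(nrow(ft$jumps), 2)   # 3 chains
  expect_true(all(validate_foldtree(ft)$pass))
  expect_equal(sum(ft$nodes$kind == "virtual"), 0)
  # anchors minimize distance to the chain COM
  atoms <- fx$structure$atoms
  for (jump_to in ft$jumps$to) {
    ch <- sub(":.*", "", jump_to)
    ca <- atoms[atoms$chain_id == ch & atoms$elety == "CA", ]
    com <- center_of_mass(atoms[atoms$chain_id == ch, ])
    d <- sqrt((ca$x - com[1])^2 + (ca$y - com[2])^2 + (ca$z - com[3])^2)
    anchor_res <- sub(".*:", "", jump_to)
    best <- paste0(ca$resno, ca$icode)[which.min(d)]
    expect_equal(anchor_res, best)
  }
  # single chain: zero jumps
  nano <- make_fixture_antibody(seed = 62L, chains = "heavy")
  ft1 <- linear_foldtree(nano$structure)
  expect_equal(nrow(ft1$jumps), 0)
  expect_true(all(validate_foldtree(ft1)$pass))
})

test_that("hierarchical tree has chain, group and root virtual nodes", {
  fx <- make_fixture_antibody(seed = 63L,
                              chains = c("light", "heavy", "antigen"))
  ft <- hierarchical_foldtree(fx$structure, list(c("H", "L"), "A"))
  expect_equal(sum(ft$nodes$kind == "virtual"), 3 + 2 + 1)
  expect_true(all(validate_foldtree(ft)$pass))
  expect_equal(ft$root, "V:root")
  # heavy-only group is valid with no light assumptions
  nano <- make_fixture_antibody(seed = 64L, chains = c("heavy", "antigen"))
  ftn <- hierarchical_foldtree(nano$structure, list("H", "A"))
  expect_true(all(validate_foldtree(ftn)$pass))
  expect_false(any(grepl("^L", ftn$nodes$id)))
  # degenerate: single group, single chain
  solo <- make_fixture_antibody(seed = 65L, chains = "heavy")
  fts <- hierarchical_foldtree(solo$structure, list("H"))
  expect_true(all(validate_foldtree(fts)$pass))
  expect_equal(sum(fts$nodes$kind == "virtual"), 3)  # root, group, chain
  expect_error(hierarchical_foldtree(solo$structure, list(character())))
})

test_that("jump perturbations move downstream subtrees rigidly", {
  fx <- make_fixture_antibody(seed = 66L,
                              chains = c("light", "heavy", "antigen"))
  R <- rotation_z(25)
  tr <- c(4, -2, 1)

  # linear propagation: perturbing jump 1 moves chains 2 and 3
  lt <- linear_foldtree(fx$structure)
  lt2 <- apply_jump(lt, 1, R, tr)
  moved <- function(ft0, ft1, ch) {
    a0 <- ft0$atoms[ft0$atoms$chain_id == ch, c("x", "y", "z")]
    a1 <- ft1$atoms[ft1$atoms$chain_id == ch, c("x", "y", "z")]
    max(abs(as.matrix(a0) - as.matrix(a1)))
  }
  expect_equal(moved(lt, lt2, "L"), 0)          # first chain upstream
  expect_gt(moved(lt, lt2, "H"), 1e-6)
  expect_gt(moved(lt, lt2, "A"), 1e-6)
  # relative geometry of the moved block is preserved
  block0 <- lt$atoms[lt$atoms$chain_id %in% c("H", "A"), ]
  block1 <- lt2$atoms[lt2$atoms$chain_id %in% c("H", "A"), ]
  expect_lt(max(abs(atom_dist_matrix(block0) - atom_dist_matrix(block1))),
            1e-6)

  # identity update changes nothing
  lt3 <- apply_jump(lt, 1, diag(3), c(0, 0, 0))
  expect_equal(lt3$atoms, lt$atoms)

  # hierarchical independence: inter-group jump preserves all
  # intra-antibody geometry (including H-to-L pairs) and fixes the rest
  ht <- hierarchical_foldtree(fx$structure, list(c("H", "L"), "A"))
  inter <- ht$jumps$jump_id[ht$jumps$from == "V:root"][1]
  ht2 <- apply_jump(ht, inter, R, tr)
  ab0 <- ht$atoms[ht$atoms$chain_id %in% c("H", "L"), ]
  ab1 <- ht2$atoms[ht2$atoms$chain_id %in% c("H", "L"), ]
  expect_gt(max(abs(as.matrix(ab0[, c("x", "y", "z")]) -
                      as.matrix(ab1[, c("x", "y", "z")]))), 1e-6)
  expect_lt(max(abs(atom_dist_matrix(ab0) - atom_dist_matrix(ab1))), 1e-6)
  expect_equal(moved(ht, ht2, "A"), 0)

  # perturbing the antigen group leaves the antibody untouched
  ag_jump <- ht$jumps$jump_id[ht$jumps$from == "V:root"][2]
  ht3 <- apply_jump(ht, ag_jump, R, tr)
  expect_equal(moved(ht, ht3, "H"), 0)
  expect_equal(moved(ht, ht3, "L"), 0)
  expect_gt(moved(ht, ht3, "A"), 1e-6)

  expect_error(apply_jump(ht, 999), "unknown jump")
  expect_error(apply_jump(ht, inter, diag(3) * 2), "orthonormal")
})

test_that("both builders validate across randomized chain groupings", {
  set.seed(202)
  fx <- make_fixture_antibody(seed = 67L,
                              chains = c("light", "heavy", "antigen"))
  chains <- unique(fx$structure$atoms$chain_id)
  for (rep in 1:5) {
    grouping <- split(chains, sample(seq_along(chains),
                                     length(chains), replace = TRUE))
    grouping <- grouping[lengths(grouping) > 0]
    ft <- hierarchical_foldtree(fx$structure, unname(grouping))
    expect_true(all(validate_foldtree(ft)$pass))
  }
  expect_true(all(validate_foldtree(linear_foldtree(fx$structure))$pass))
})

test_that("validation detects injected cycles and coverage gaps", {
  fx <- fixture_pair()
  ft <- linear_foldtree(fx$structure)
  bad <- ft
  bad$edges <- dplyr::bind_rows(
    bad$edges, tibble::tibble(from = bad$edges$to[5],
                              to = bad$edges$from[5],
                              type = "peptide", jump_id = NA_integer_))
  v <- validate_foldtree(bad)
  expect_false(v$pass[v$check == "acyclic"])
  gap <- ft
  drop_id <- setdiff(gap$nodes$id, gap$root)[1]
  gap$nodes <- gap$nodes[gap$nodes$id != drop_id, ]
  v2 <- validate_foldtree(gap)
  expect_false(v2$pass[v2$check == "coverage"])
})

test_that("fold trees serialize to an edge list and round-trip", {
  fx <- fixture_pair()
  ft <- hierarchical_foldtree(fx$structure, list(c("H", "L")))
  path <- withr::local_tempfile(fileext = ".txt")
  write_foldtree(ft, path)
  back <- read_foldtree(path)
  expect_equal(back$root, ft$root)
  expect_equal(back$edges[, c("from", "to", "type", "jump_id")],
               ft$edges[, c("from", "to", "type", "jump_id")])
  expect_equal(back$nodes$id, ft$nodes$id)
  expect_equal(back$nodes$x, ft$nodes$x, tolerance = 1e-6)
})
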