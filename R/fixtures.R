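#' Synthetic Chothia-numbered antibody fixtures
#'
#' Deterministic generator for antibody structures, summary tables and
#' dihedral windows, so the curation, constraint, kinematic and metric
#' machinery is testable without any external download. Backbones are
#' idealized extended traces (C-N 1.33 A, standard peptide angles) built
#' by sequential internal-coordinate placement; numbering honours the
#' Chothia region spans, with insertion codes assigned alphabetically at
#' each loop's canonical insertion position when a requested CDR length
#' exceeds the numbered span, and interior numbers skipped (geometry kept
#' continuous) when it is shorter. Glutamines are placed at L38/H39 with
#' side-chain amides constructed so both inter-chain donor-acceptor
#' distances equal `qq_distance` exactly. The global fold is not a
#' realistic immunoglobulin fold; only local geometry, numbering and the
#' glutamine pair are controlled.
#'
#' @name fixtures
NULL

# canonical insertion positions inside each CDR loop
CDR_INSERTION_POS <- c(CDR_L1 = 30L, CDR_L2 = 52L, CDR_L3 = 95L,
                       CDR_H1 = 31L, CDR_H2 = 52L, CDR_H3 = 100L)

DEFAULT_FIXTURE_SEED <- 20190215L

# NeRF-style placement: position of D given A-B-C, bond |CD|, angle BCD
# and dihedral ABCD (degrees)
place_atom <- function(a, b, c, bond, angle, dihedral) {
  th <- angle * pi / 180
  chi <- dihedral * pi / 180
  d2 <- c(-bond * cos(th), bond * sin(th) * cos(chi),
          bond * sin(th) * sin(chi))
  bc <- c - b
  bc <- bc / sqrt(sum(bc^2))
  ab <- b - a
  n <- c(ab[2] * bc[3] - ab[3] * bc[2],
         ab[3] * bc[1] - ab[1] * bc[3],
         ab[1] * bc[2] - ab[2] * bc[1])
  n <- n / sqrt(sum(n^2))
  m2 <- c(n[2] * bc[3] - n[3] * bc[2],
          n[3] * bc[1] - n[1] * bc[3],
          n[1] * bc[2] - n[2] * bc[1])
  c + cbind(bc, m2, n) %*% d2
}

# residue numbering for one chain given CDR length requests
chain_numbering <- function(chain_kind, max_resno, cdr_lengths,
                            drop_resno = integer()) {
  defs <- chothia_regions() %>%
    filter(.data$chain_kind == !!chain_kind, .data$region %in% CDR_NAMES)
  resno <- seq_len(max_resno)
  icode <- rep("", max_resno)
  for (i in seq_len(nrow(defs))) {
    r <- defs$region[i]
    span <- defs$end[i] - defs$start[i] + 1L
    want <- cdr_lengths[[r]] %||% span
    ins <- CDR_INSERTION_POS[[r]]
    if (want > span) {
      extra <- want - span
      resno <- c(resno, rep(ins, extra))
      icode <- c(icode, LETTERS[seq_len(extra)])
    } else if (want < span) {
      # skip interior numbers at the insertion position, never anchors
      drop <- seq(ins, length.out = span - want)
      keep <- !(resno %in% drop & icode == "")
      resno <- resno[keep]
      icode <- icode[keep]
    }
  }
  keep <- !(resno %in% drop_resno & icode == "")
  tbl <- tibble(resno = as.integer(resno[keep]), icode = icode[keep])
  arrange(tbl, residue_order_key(tbl$resno, tbl$icode))
}

# build one idealized extended backbone (N, CA, C, O per residue)
build_backbone <- function(n_res, phi = -139, psi = 135, omega = 180) {
  pos <- array(NA_real_, c(n_res, 4, 3),
               dimnames = list(NULL, c("N", "CA", "C", "O"), NULL))
  pos[1, "N", ] <- c(0, 0, 0)
  pos[1, "CA", ] <- c(1.458, 0, 0)
  pos[1, "C", ] <- pos[1, "CA", ] +
    1.525 * c(cos(pi * (180 - 111.2) / 180), sin(pi * (180 - 111.2) / 180), 0)
  for (i in seq_len(n_res)[-1]) {
    pos[i, "N", ] <- place_atom(pos[i - 1, "N", ], pos[i - 1, "CA", ],
                                pos[i - 1, "C", ], 1.329, 116.2, psi)
    pos[i, "CA", ] <- place_atom(pos[i - 1, "CA", ], pos[i - 1, "C", ],
                                 pos[i, "N", ], 1.458, 121.7, omega)
    pos[i, "C", ] <- place_atom(pos[i - 1, "C", ], pos[i, "N", ],
                                pos[i, "CA", ], 1.525, 111.2, phi)
  }
  for (i in seq_len(n_res)) {
    pos[i, "O", ] <- place_atom(pos[i, "N", ], pos[i, "CA", ],
                                pos[i, "C", ], 1.231, 120.5, -45)
  }
  pos
}

AA1 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
AA3 <- c(A = "ALA", C = "CYS", D = "ASP", E = "GLU", F = "PHE", G = "GLY",
         H = "HIS", I = "ILE", K = "LYS", L = "LEU", M = "MET", N = "ASN",
         P = "PRO", Q = "GLN", R = "ARG", S = "SER", T = "THR", V = "VAL",
         W = "TRP", Y = "TYR")

build_chain_atoms <- function(chain_kind, chain_id, numbering, sequence,
                              origin = c(0, 0, 0)) {
  n <- nrow(numbering)
  stopifnot(nchar(sequence) == n)
  bb <- build_backbone(n)
  aa <- strsplit(sequence, "")[[1]]
  purrr::map(seq_len(n), function(i) {
    tibble(chain_kind = chain_kind, chain_id = chain_id,
           resno = numbering$resno[i], icode = numbering$icode[i],
           resid = AA3[[aa[i]]],
           elety = c("N", "CA", "C", "O"),
           element = c("N", "C", "C", "O"),
           x = unname(bb[i, , 1]) + origin[1],
           y = unname(bb[i, , 2]) + origin[2],
           z = unname(bb[i, , 3]) + origin[3],
           o = 1, b = 0)
  }) %>% purrr::list_rbind()
}

# explicit glutamine side-chain amides facing each other across the
# interface; both donor-acceptor N-O distances equal `d` by construction
qq_sidechain_atoms <- function(light_atoms, heavy_atoms, d) {
  ca <- function(atoms, resno) {
    a <- atoms %>% filter(.data$resno == !!resno, .data$icode == "",
                          .data$elety == "CA")
    c(a$x, a$y, a$z)
  }
  ca_l <- ca(light_atoms, 38L)
  ca_h <- ca(heavy_atoms, 39L)
  c0 <- (ca_l + ca_h) / 2
  u <- ca_h - ca_l
  u <- u / sqrt(sum(u^2))
  # orthonormal frame: u (inter-chain axis), w (amide in-plane axis)
  ref <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 0, 1)
  w <- ref - sum(ref * u) * u
  w <- w / sqrt(sum(w^2))
  amide <- function(sign, ck, cid, ca_pos) {
    # mirrored in-plane offsets so each NE2 faces the partner's OE1 at d
    oe1 <- c0 + sign * (d / 2) * u + sign * 1.15 * w
    ne2 <- c0 + sign * (d / 2) * u - sign * 1.15 * w
    cd <- c0 + sign * (d / 2 + 0.44) * u
    cb <- ca_pos + 1.53 * (c0 - ca_pos) / sqrt(sum((c0 - ca_pos)^2))
    cg <- cd + 1.52 * (cb - cd) / sqrt(sum((cb - cd)^2))
    resno <- if (ck == "light") 38L else 39L
    tibble(chain_kind = ck, chain_id = cid, resno = resno, icode = "",
           resid = "GLN",
           elety = c("CB", "CG", "CD", "OE1", "NE2"),
           element = c("C", "C", "C", "O", "N"),
           x = c(cb[1], cg[1], cd[1], oe1[1], ne2[1]),
           y = c(cb[2], cg[2], cd[2], oe1[2], ne2[2]),
           z = c(cb[3], cg[3], cd[3], oe1[3], ne2[3]),
           o = 1, b = 0)
  }
  # heavy amide sits on the +u side of the midpoint, light on -u; the
  # cross pairings (NE2 of one with OE1 of the other) are both exactly d
  bind_rows(amide(-1, "light", light_atoms$chain_id[1], ca_l),
            amide(+1, "heavy", heavy_atoms$chain_id[1], ca_h))
}

#' Generate one synthetic antibody fixture
#'
#' @param seed integer seed controlling sequence and B-factor draws
#' @param pdb_id 4-character id (default derived from the seed)
#' @param chains subset of `c("light", "heavy", "antigen")`
#' @param cdr_lengths named list, e.g. `list(CDR_L1 = 11, CDR_H3 = 10)`;
#'   unspecified CDRs use their full numbered span
#' @param qq place glutamines at L38/H39 with interface amides
#' @param qq_distance donor-acceptor N-O target distance in Angstrom
#' @param resolution reported resolution (summary column)
#' @param method method string for the summary row
#' @param sequence_light,sequence_heavy optional explicit sequences (must
#'   match the numbering length); default random
#' @param c_terminal_extra residues appended beyond L109/H112 (to exercise
#'   Fv truncation)
#' @param defects list of defect descriptors, each a list with `kind` one
#'   of `"long_bond"` (fields `chain_kind`, `resno`, `distance`),
#'   `"bad_angle"` (`chain_kind`, `resno`, `angle`), `"zero_occupancy"`
#'   (`chain_kind`, `resno`, `elety`), `"missing_residue"` (`chain_kind`,
#'   `resno`), `"scfv"` (no fields)
#' @return list with `structure` (an [ab_structure]) and `summary`
#'   (one-row summary tibble)
#' @export
make_fixture_antibody <- function(seed = DEFAULT_FIXTURE_SEED,
                                  pdb_id = NULL,
                                  chains = c("light", "heavy"),
                                  cdr_lengths = list(),
                                  qq = TRUE, qq_distance = 2.91,
                                  resolution = 2.0,
                                  method = "X-RAY DIFFRACTION",
                                  sequence_light = NULL,
                                  sequence_heavy = NULL,
                                  c_terminal_extra = 0L,
                                  defects = list()) {
  stopifnot(all(chains %in% CHAIN_KINDS), length(chains) >= 1)
  if (is.null(pdb_id)) {
    pdb_id <- sprintf("s%03d", seed %% 1000L)
  }
  old <- .Random.seed_exists()
  set.seed(seed)
  on.exit(restore_seed(old), add = TRUE)

  missing_by_chain <- list(light = integer(), heavy = integer())
  scfv <- FALSE
  for (d in defects) {
    if (d$kind == "missing_residue") {
      missing_by_chain[[d$chain_kind]] <-
        c(missing_by_chain[[d$chain_kind]], d$resno)
    }
    if (d$kind == "scfv") scfv <- TRUE
  }

  rand_seq <- function(numbering, chain_kind) {
    s <- sample(AA1, nrow(numbering), replace = TRUE)
    if (qq) {
      pos38 <- if (chain_kind == "light") 38L else 39L
      s[numbering$resno == pos38 & numbering$icode == ""] <- "Q"
    }
    paste0(s, collapse = "")
  }

  atoms <- list()
  if ("light" %in% chains) {
    num_l <- chain_numbering("light", 109L + c_terminal_extra, cdr_lengths,
                             missing_by_chain$light)
    seq_l <- sequence_light %||% rand_seq(num_l, "light")
    atoms$light <- build_chain_atoms("light", "L", num_l, seq_l,
                                     origin = c(0, 0, 0))
  }
  if ("heavy" %in% chains) {
    num_h <- chain_numbering("heavy", 112L + c_terminal_extra, cdr_lengths,
                             missing_by_chain$heavy)
    seq_h <- sequence_heavy %||% rand_seq(num_h, "heavy")
    atoms$heavy <- build_chain_atoms("heavy", "H", num_h, seq_h,
                                     origin = c(0, 12, 0))
  }
  if ("antigen" %in% chains) {
    num_a <- tibble(resno = 1:20, icode = "")
    seq_a <- paste0(sample(AA1, 20, replace = TRUE), collapse = "")
    atoms$antigen <- build_chain_atoms("antigen", "A", num_a, seq_a,
                                       origin = c(0, -15, 10))
  }

  if (qq && all(c("light", "heavy") %in% chains)) {
    atoms$qq <- qq_sidechain_atoms(atoms$light, atoms$heavy, qq_distance)
  }
  at <- bind_rows(atoms)
  at$b <- round(stats::runif(nrow(at), 10, 40), 2)

  for (d in defects) {
    at <- switch(d$kind,
      long_bond = inject_long_bond(at, d$chain_kind, d$resno,
                                   d$distance %||% 2.5),
      bad_angle = inject_bad_angle(at, d$chain_kind, d$resno,
                                   d$angle %||% 150),
      zero_occupancy = inject_zero_occupancy(at, d$chain_kind, d$resno,
                                             d$elety %||% "CA"),
      missing_residue = at,  # handled at numbering time
      scfv = at,
      stopf("unknown defect kind '%s'", d$kind))
  }

  h_id <- if ("heavy" %in% chains) "H" else NA_character_
  l_id <- if ("light" %in% chains) "L" else NA_character_
  if (scfv) {
    h_id <- "A"
    l_id <- "A"
  }
  summary <- tibble(pdb = pdb_id, Hchain = h_id, Lchain = l_id,
                    resolution = resolution, method = method)
  list(structure = ab_structure(pdb_id, at, resolution, method),
       summary = summary)
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv())) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# link defects act on the peptide link between `resno` and the following
# residue of the same chain (file order)
link_index <- function(atoms, chain_kind, resno) {
  res <- residue_table(atoms) %>% filter(.data$chain_kind == !!chain_kind)
  i <- which(res$resno == resno & res$icode == "")[1]
  if (is.na(i) || i >= nrow(res)) {
    stopf("no link after %s residue %d", chain_kind, resno)
  }
  list(res = res, i = i)
}

atom_xyz <- function(atoms, chain_kind, resno, icode, elety) {
  a <- atoms %>% filter(.data$chain_kind == !!chain_kind,
                        .data$resno == !!resno, .data$icode == !!icode,
                        .data$elety == !!elety)
  c(a$x[1], a$y[1], a$z[1])
}

inject_long_bond <- function(atoms, chain_kind, resno, distance) {
  li <- link_index(atoms, chain_kind, resno)
  res <- li$res; i <- li$i
  c_cur <- atom_xyz(atoms, chain_kind, res$resno[i], res$icode[i], "C")
  n_next <- atom_xyz(atoms, chain_kind, res$resno[i + 1], res$icode[i + 1],
                     "N")
  u <- (n_next - c_cur) / sqrt(sum((n_next - c_cur)^2))
  shift <- (distance - sqrt(sum((n_next - c_cur)^2))) * u
  key <- residue_order_key(atoms$resno, atoms$icode)
  move <- atoms$chain_kind == chain_kind &
    key >= residue_order_key(res$resno[i + 1], res$icode[i + 1])
  atoms$x[move] <- atoms$x[move] + shift[1]
  atoms$y[move] <- atoms$y[move] + shift[2]
  atoms$z[move] <- atoms$z[move] + shift[3]
  atoms
}

inject_bad_angle <- function(atoms, chain_kind, resno, angle) {
  li <- link_index(atoms, chain_kind, resno)
  res <- li$res; i <- li$i
  ca <- atom_xyz(atoms, chain_kind, res$resno[i], res$icode[i], "CA")
  cc <- atom_xyz(atoms, chain_kind, res$resno[i], res$icode[i], "C")
  nn <- atom_xyz(atoms, chain_kind, res$resno[i + 1], res$icode[i + 1], "N")
  v <- (ca - cc) / sqrt(sum((ca - cc)^2))
  u <- nn - cc
  bond <- sqrt(sum(u^2))
  u <- u / bond
  w <- u - sum(u * v) * v
  w <- w / sqrt(sum(w^2))
  th <- angle * pi / 180
  n_new <- cc + bond * (cos(th) * v + sin(th) * w)
  sel <- atoms$chain_kind == chain_kind & atoms$resno == res$resno[i + 1] &
    atoms$icode == res$icode[i + 1] & atoms$elety == "N"
  atoms$x[sel] <- n_new[1]
  atoms$y[sel] <- n_new[2]
  atoms$z[sel] <- n_new[3]
  atoms
}

inject_zero_occupancy <- function(atoms, chain_kind, resno, elety) {
  sel <- atoms$chain_kind == chain_kind & atoms$resno == resno &
    atoms$elety == elety
  if (!any(sel)) stopf("no atom %s in %s residue %d", elety, chain_kind,
                       resno)
  atoms$o[sel] <- 0
  atoms
}

#' Generate a corpus of fixture structures on disk
#'
#' Writes `n` PDB files plus a `summary.tsv` into `dir`. Sequence
#' diversity is random under the seed; `n_duplicates` of the structures
#' (at the end of the corpus) reuse the full Fv sequence of the first
#' structure, exercising the non-redundancy filter. Per-structure defects
#' can be injected via `defects` (a list mapping structure index to a
#' defect list as in [make_fixture_antibody()]), and per-structure
#' resolutions via `resolutions`.
#'
#' @param n number of structures (>= 1)
#' @param seed corpus seed
#' @param dir output directory (created if needed)
#' @param n_duplicates how many trailing structures duplicate the first
#'   structure's Fv sequence
#' @param defects named list: index -> list of defect descriptors
#' @param resolutions optional numeric vector of length `n`
#' @return manifest tibble: `pdb`, `path`, plus the summary columns
#' @export
make_fixture_corpus <- function(n, seed = DEFAULT_FIXTURE_SEED,
                                dir = tempfile("corpus"),
                                n_duplicates = 0, defects = list(),
                                resolutions = NULL) {
  stopifnot(n >= 1, n_duplicates < n)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  first_seqs <- NULL
  rows <- purrr::map(seq_len(n), function(i) {
    args <- list(seed = seed + i, pdb_id = sprintf("f%03d", i),
                 resolution = if (is.null(resolutions)) 2.0 else
                   resolutions[i],
                 defects = defects[[as.character(i)]] %||% list())
    if (i > n - n_duplicates) {
      args$sequence_light <- first_seqs$light
      args$sequence_heavy <- first_seqs$heavy
    }
    fx <- do.call(make_fixture_antibody, args)
    if (i == 1) {
      res <- residue_table(fx$structure$atoms)
      first_seqs <<- list(
        light = paste0(res$aa[res$chain_kind == "light"], collapse = ""),
        heavy = paste0(res$aa[res$chain_kind == "heavy"], collapse = ""))
    }
    path <- file.path(dir, paste0(fx$summary$pdb, ".pdb"))
    write_structure_pdb(fx$structure, path)
    mutate(fx$summary, path = path)
  }) %>% purrr::list_rbind()
  readr::write_tsv(rows %>% select(-"path"), file.path(dir, "summary.tsv"))
  rows
}

#' Build a set of fragment windows by offsetting a loop window
#'
#' Each offset entry produces one fragment equal to the loop with every
#' (phi, psi) shifted by the per-position offsets, wrapped to (-180, 180].
#'
#' @param loop_window data frame with columns `phi`, `psi` (degrees)
#' @param offsets list; each element either a single number (applied to
#'   all dihedrals) or a list/data frame with `phi` and `psi` vectors of
#'   the window length
#' @return list of fragment-window tibbles
#' @export
make_fragment_set <- function(loop_window, offsets) {
  n <- nrow(loop_window)
  purrr::map(offsets, function(off) {
    if (is.numeric(off) && length(off) == 1) {
      off <- list(phi = rep(off, n), psi = rep(off, n))
    }
    if (length(off$phi) != n || length(off$psi) != n) {
      stopf("offset length does not match window length %d", n)
    }
    tibble(phi = wrap_angle(loop_window$phi + off$phi),
           psi = wrap_angle(loop_window$psi + off$psi))
  })
}
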