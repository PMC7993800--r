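#' Flat-harmonic distance constraint
#'
#' Penalty on an inter-atomic distance x that is zero on the flat bottom
#' \[x0 - dm, x0 + dm\] and quadratic outside it:
#' \deqn{f(x) = ((|x - x0| - dm) / \sigma)^2 \ \mathrm{if}\ |x - x0| > dm,
#'   \ \mathrm{else}\ 0.}
#' Shipped defaults for the V_H-V_L glutamine-glutamine hydrogen bonds
#' are x0 = 2.91 A and sigma = 0.23 A (fit over donor-acceptor N-O
#' distances in a curated antibody database), with dm = 0.5 sigma so that
#' no penalty applies within half a standard deviation of the mean.
#'
#' @param x0 target distance (A), the observed mean
#' @param sigma observed standard deviation (A), > 0
#' @param dm flat-bottom half-width (A), >= 0 (default 0.5 sigma)
#' @param atom1,atom2 optional atom descriptors: lists with `elety`,
#'   `resno`, `chain_id` and optionally `icode`
#' @return object of class `ab_flat_harmonic`
#' @export
flat_harmonic <- function(x0 = 2.91, sigma = 0.23, dm = 0.5 * sigma,
                          atom1 = NULL, atom2 = NULL) {
  stopifnot(sigma > 0, dm >= 0, x0 >= 0)
  structure(list(x0 = x0, sigma = sigma, dm = dm,
                 atom1 = atom1, atom2 = atom2),
            class = "ab_flat_harmonic")
}

#' @export
print.ab_flat_harmonic <- function(x, ...) {
  cat(sprintf("<flat_harmonic x0=%.3f sigma=%.3f dm=%.3f>\n",
              x$x0, x$sigma, x$dm))
  invisible(x)
}

#' Evaluate a flat-harmonic constraint
#'
#' @param constraint an `ab_flat_harmonic`
#' @param x distances in Angstrom (vectorized)
#' @return penalties (score units); 0 on the flat bottom, the boundary
#'   |x - x0| = dm included in the zero branch
#' @export
eval_flat_harmonic <- function(constraint, x) {
  dev <- abs(x - constraint$x0)
  ifelse(dev > constraint$dm,
         ((dev - constraint$dm) / constraint$sigma)^2, 0)
}

#' Fit flat-harmonic parameters from observed distances
#'
#' x0 is the sample mean, sigma the sample (n-1) standard deviation, and
#' dm = 0.5 sigma. Degenerate inputs (fewer than two values, or zero
#' variance) are rejected.
#'
#' @param distances numeric vector of donor-acceptor distances (A)
#' @return object of class `qq_fit` with elements `x0`, `sigma`, `dm`,
#'   `n`; has [generics::tidy()] and [generics::glance()] methods
#' @export
fit_qq_parameters <- function(distances) {
  distances <- distances[is.finite(distances)]
  if (length(distances) < 2) {
    stopf("need at least two finite distances to fit",
          class = "abkit_fit_error")
  }
  s <- stats::sd(distances)
  if (s <= 0) {
    stopf("zero variance in distances; flat-harmonic fit is degenerate",
          class = "abkit_fit_error")
  }
  structure(list(x0 = mean(distances), sigma = s, dm = 0.5 * s,
                 n = length(distances)),
            class = "qq_fit")
}

#' @export
print.qq_fit <- function(x, ...) {
  cat(sprintf("Q-Q flat-harmonic fit (n = %d): x0 = %.3f A, sigma = %.3f A, dm = %.3f A\n",
              x$n, x$x0, x$sigma, x$dm))
  invisible(x)
}

# side-chain amide atoms of glutamine
QQ_DONOR <- "NE2"
QQ_ACCEPTOR <- "OE1"

#' Find the glutamine-glutamine donor-acceptor pairs of an Fv
#'
#' When light residue 38 and heavy residue 39 are both glutamine with
#' complete side-chain amides, there are two possible inter-chain
#' hydrogen bonds: each glutamine's amide nitrogen (NE2) paired with the
#' other's amide oxygen (OE1). Absence of either glutamine (including
#' nanobodies with no light chain) disables the constraint and returns
#' `NULL`.
#'
#' @param structure an [ab_structure]
#' @return tibble with one row per pairing (`donor_chain`, `donor_resno`,
#'   `donor_atom`, `acceptor_chain`, `acceptor_resno`, `acceptor_atom`,
#'   `distance`), or `NULL`
#' @export
find_qq_pairs <- function(structure) {
  pick <- function(kind, resno) {
    structure$atoms %>%
      filter(.data$chain_kind == kind, .data$resno == resno,
             .data$icode == "", .data$resid == "GLN",
             .data$elety %in% c(QQ_DONOR, QQ_ACCEPTOR))
  }
  l <- pick("light", 38L)
  h <- pick("heavy", 39L)
  if (!all(c(QQ_DONOR, QQ_ACCEPTOR) %in% l$elety) ||
      !all(c(QQ_DONOR, QQ_ACCEPTOR) %in% h$elety)) {
    return(NULL)
  }
  xyz <- function(tbl, elety) {
    a <- tbl[tbl$elety == elety, ][1, ]
    c(a$x, a$y, a$z)
  }
  dist <- function(a, b) sqrt(sum((a - b)^2))
  tibble(donor_chain = c(l$chain_id[1], h$chain_id[1]),
         donor_kind = c("light", "heavy"),
         donor_resno = c(38L, 39L),
         donor_atom = QQ_DONOR,
         acceptor_chain = c(h$chain_id[1], l$chain_id[1]),
         acceptor_kind = c("heavy", "light"),
         acceptor_resno = c(39L, 38L),
         acceptor_atom = QQ_ACCEPTOR,
         distance = c(dist(xyz(l, QQ_DONOR), xyz(h, QQ_ACCEPTOR)),
                      dist(xyz(h, QQ_DONOR), xyz(l, QQ_ACCEPTOR))))
}

#' Build the automatic Q-Q constraints for a structure
#'
#' @param structure an [ab_structure]
#' @param x0,sigma,dm flat-harmonic parameters (defaults: database fit)
#' @return list of two `ab_flat_harmonic` constraints, or `NULL` when the
#'   glutamine pair is absent
#' @export
qq_constraints <- function(structure, x0 = 2.91, sigma = 0.23,
                           dm = 0.5 * sigma) {
  pairs <- find_qq_pairs(structure)
  if (is.null(pairs)) return(NULL)
  purrr::pmap(pairs, function(donor_chain, donor_resno, donor_atom,
                              acceptor_chain, acceptor_resno,
                              acceptor_atom, ...) {
    flat_harmonic(x0, sigma, dm,
                  atom1 = list(elety = donor_atom, resno = donor_resno,
                               chain_id = donor_chain),
                  atom2 = list(elety = acceptor_atom,
                               resno = acceptor_resno,
                               chain_id = acceptor_chain))
  })
}

#' Geometric hydrogen-bond presence criterion
#'
#' A donor-acceptor pairing is counted as hydrogen-bonded when the N-O
#' distance is at most `max_dist` (default 3.5 A).
#'
#' @param pairs output of [find_qq_pairs()]
#' @param max_dist distance cutoff in Angstrom
#' @return logical vector (one per pairing), or `NULL` when `pairs` is
#' @export
qq_hbond_present <- function(pairs, max_dist = 3.5) {
  if (is.null(pairs)) return(NULL)
  pairs$distance <= max_dist
}

#' K-of-N composite constraint
#'
#' Scores only the K lowest-penalty members of a set of N constraints --
#' used e.g. to restrain an epitope residue to its nearest paratope
#' residues when the exact partner is unknown.
#'
#' @param k number of members counted (1 <= k <= length(members))
#' @param members list of `ab_flat_harmonic` constraints
#' @return object of class `ab_kofn`
#' @export
kofn_constraint <- function(k, members) {
  if (k < 1 || k > length(members)) {
    stopf("k = %d outside 1..N (N = %d)", k, length(members),
          class = "abkit_config_error")
  }
  structure(list(k = as.integer(k), members = members), class = "ab_kofn")
}

#' Evaluate a K-of-N constraint
#'
#' Each member's flat harmonic is evaluated at its distance; the K
#' smallest penalties are summed.
#'
#' @param kofn an `ab_kofn`
#' @param distances numeric vector, one distance per member
#' @return total penalty
#' @export
eval_kofn <- function(kofn, distances) {
  if (length(distances) != length(kofn$members)) {
    stopf("expected %d distances, got %d", length(kofn$members),
          length(distances))
  }
  vals <- purrr::map2_dbl(kofn$members, distances, eval_flat_harmonic)
  sum(sort(vals)[seq_len(kofn$k)])
}

atom_token <- function(atom) {
  sprintf("%s %d%s%s", atom$elety, atom$resno, atom$icode %||% "",
          atom$chain_id)
}

fh_line <- function(c) {
  sprintf("AtomPair %s %s FLAT_HARMONIC %.3f %.3f %.3f",
          atom_token(c$atom1), atom_token(c$atom2), c$x0, c$sigma, c$dm)
}

#' Write constraints to a Rosetta-compatible text file
#'
#' Flat-harmonic atom-pair constraints are one per line:
#' `AtomPair <atom1> <res1><chain1> <atom2> <res2><chain2> FLAT_HARMONIC
#' <x0> <sigma> <dm>` (numeric fields with three decimals). K-of-N
#' constraints wrap their member lines between `KofNConstraint <K>` and
#' `End`. Lines beginning with `#` are comments.
#'
#' @param constraints list of `ab_flat_harmonic` / `ab_kofn` objects
#' @param path output file
#' @return `path`, invisibly
#' @export
write_constraint_file <- function(constraints, path) {
  if (length(constraints) == 0) {
    warn("writing empty constraint file")
    writeLines(character(), path)
    return(invisible(path))
  }
  lines <- purrr::map(constraints, function(c) {
    if (inherits(c, "ab_flat_harmonic")) {
      fh_line(c)
    } else if (inherits(c, "ab_kofn")) {
      c(sprintf("KofNConstraint %d", c$k),
        purrr::map_chr(c$members, fh_line), "End")
    } else {
      stopf("unsupported constraint class: %s", class(c)[1])
    }
  })
  writeLines(unlist(lines), path)
  invisible(path)
}

parse_atom_token <- function(elety, restoken) {
  m <- stringr::str_match(restoken, "^(\\d+)([A-Za-z]?)([A-Za-z])$")
  if (is.na(m[1, 1])) stopf("bad residue token '%s'", restoken)
  # token is <resno><icode?><chain>; with two letters the first is icode
  list(elety = elety, resno = as.integer(m[1, 2]),
       icode = if (m[1, 3] == "") "" else m[1, 3],
       chain_id = m[1, 4])
}

#' Read a constraint file written by [write_constraint_file()]
#'
#' @param path constraint file
#' @return list of constraint objects
#' @export
read_constraint_file <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  out <- list()
  i <- 1
  parse_fh <- function(line) {
    f <- strsplit(line, "\\s+")[[1]]
    stopifnot(f[1] == "AtomPair", f[6] == "FLAT_HARMONIC")
    flat_harmonic(x0 = as.numeric(f[7]), sigma = as.numeric(f[8]),
                  dm = as.numeric(f[9]),
                  atom1 = parse_atom_token(f[2], f[3]),
                  atom2 = parse_atom_token(f[4], f[5]))
  }
  while (i <= length(lines)) {
    if (startsWith(lines[i], "KofNConstraint")) {
      k <- as.integer(strsplit(lines[i], "\\s+")[[1]][2])
      j <- i + 1
      members <- list()
      while (j <= length(lines) && lines[j] != "End") {
        members <- c(members, list(parse_fh(lines[j])))
        j <- j + 1
      }
      out <- c(out, list(kofn_constraint(k, members)))
      i <- j + 1
    } else {
      out <- c(out, list(parse_fh(lines[i])))
      i <- i + 1
    }
  }
  out
}
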