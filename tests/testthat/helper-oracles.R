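# Independent oracles used to cross-check package computations.

# Gotoh-style affine-gap local alignment, written independently of the
# package's alignment backend: a gap of length L costs open + L * ext.
oracle_local_align <- function(q, t, mat, open, ext) {
  qa <- strsplit(q, "")[[1]]
  ta <- strsplit(t, "")[[1]]
  n <- length(qa)
  m <- length(ta)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)     # best ending in a match column
  X <- matrix(NEG, n + 1, m + 1)   # gap in template (query consumed)
  Y <- matrix(NEG, n + 1, m + 1)   # gap in query
  best <- 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- mat[qa[i], ta[j]]
      M[i + 1, j + 1] <- max(0, M[i, j], X[i, j], Y[i, j]) + s
      X[i + 1, j + 1] <- max(M[i, j + 1] - open - ext,
                             X[i, j + 1] - ext)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - open - ext,
                             Y[i + 1, j] - ext)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

# independent chord-distance evaluation straight from the printed formulas
oracle_mean_chord <- function(loop, frag) {
  dsq <- function(a, b) 2 - 2 * cos((b - a) * pi / 180)
  mean((dsq(loop$phi, frag$phi) + dsq(loop$psi, frag$psi)) / 2)
}

random_aa <- function(n, k = 6) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  replicate(n, paste0(sample(aa, k, replace = TRUE), collapse = ""))
}

# small clean fixture shared across tests (generated once per run)
fixture_pair <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- abkit::make_fixture_antibody(seed = 7L)
    cache
  }
})

atom_dist_matrix <- function(atoms) {
  as.matrix(stats::dist(atoms[, c("x", "y", "z")]))
}

rotation_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
         nrow = 3, byrow = TRUE)
}
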