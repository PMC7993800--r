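#' Wrap angles to the interval (-180, 180]
#'
#' @param x angles in degrees
#' @return wrapped angles
#' @export
wrap_angle <- function(x) {
  m <- x %% 360
  ifelse(m > 180, m - 360, m)
}

#' Squared chord distance between two dihedral angles
#'
#' D^2(theta1, theta2) = 2 - 2 cos(theta2 - theta1); 0 for identical
#' angles, 4 for angles 180 degrees apart. Periodic in both arguments.
#'
#' @param theta1,theta2 angles in degrees (vectorized)
#' @return values in \[0, 4\]
#' @export
chord_sq <- function(theta1, theta2) {
  2 - 2 * cos((theta2 - theta1) * pi / 180)
}

#' Mean chord distance between a loop window and a fragment window
#'
#' Averages the per-position squared chord distances of phi and psi:
#' \eqn{\langle D\rangle = \frac{1}{n}\sum_i (D^2_{\phi,i} + D^2_{\psi,i})/2}.
#' 0 when the fragment matches the loop exactly; 4 when every dihedral
#' differs by 180 degrees.
#'
#' @param loop,fragment data frames with columns `phi`, `psi` (degrees),
#'   equal number of rows (windows of length 3 or 9 typically)
#' @return mean chord distance in \[0, 4\]
#' @export
mean_chord_distance <- function(loop, fragment) {
  if (nrow(loop) != nrow(fragment)) {
    stopf("window lengths differ (%d vs %d)", nrow(loop), nrow(fragment))
  }
  mean((chord_sq(loop$phi, fragment$phi) +
          chord_sq(loop$psi, fragment$psi)) / 2)
}

#' Empirical CDF of fragment chord distances
#'
#' The cumulative distribution of loop-fragment mean chord distances:
#' the fraction of fragments within a given chord distance of their loop.
#'
#' @param distances numeric vector of mean chord distances (>= 1 value)
#' @return tibble of class `ab_cdf` with columns `distance` (sorted
#'   unique values) and `fraction` (cumulative, reaching 1 at the max)
#' @export
similarity_cdf <- function(distances) {
  if (length(distances) == 0) stopf("no distances supplied")
  xs <- sort(unique(distances))
  out <- tibble(distance = xs,
                fraction = stats::ecdf(distances)(xs))
  class(out) <- c("ab_cdf", class(out))
  out
}

# Kabsch least-squares superposition: returns P aligned onto Q
kabsch_align <- function(P, Q) {
  pbar <- colMeans(P)
  qbar <- colMeans(Q)
  Pc <- sweep(P, 2, pbar)
  Qc <- sweep(Q, 2, qbar)
  s <- svd(t(Pc) %*% Qc)
  d <- sign(det(s$u %*% t(s$v)))
  R <- s$u %*% diag(c(1, 1, d)) %*% t(s$v)
  list(R = R, pbar = pbar, qbar = qbar,
       apply = function(X) sweep(sweep(X, 2, pbar) %*% R, 2, qbar, `+`))
}

backbone_coords <- function(structure, regions) {
  defs <- chothia_regions() %>% filter(.data$region %in% regions)
  structure$atoms %>%
    filter(.data$elety %in% c("N", "CA", "C", "O")) %>%
    inner_join(defs, by = "chain_kind", relationship = "many-to-many") %>%
    filter(.data$resno >= .data$start, .data$resno <= .data$end) %>%
    distinct(.data$chain_kind, .data$resno, .data$icode, .data$elety,
             .keep_all = TRUE) %>%
    select("chain_kind", "resno", "icode", "elety", "x", "y", "z")
}

#' Per-region backbone RMSD after framework superposition
#'
#' Superimposes the model onto the native by least squares over the
#' framework (FRL + FRH) backbone atoms (N, CA, C, O), then computes the
#' RMSD over the named region's backbone atoms without re-fitting -- the
#' standard convention for reporting CDR accuracy. Atoms are matched by
#' (chain, Chothia number, insertion code, atom name); only atoms present
#' in both structures contribute.
#'
#' @param model,native [ab_structure] objects sharing Chothia numbering
#' @param region region to measure (any of the nine definitions)
#' @param fit_regions regions used for the superposition fit (default the
#'   frameworks present in both structures)
#' @return RMSD in Angstrom
#' @export
backbone_rmsd <- function(model, native, region,
                          fit_regions = c("FRL", "FRH")) {
  key <- c("chain_kind", "resno", "icode", "elety")
  fit <- inner_join(backbone_coords(model, fit_regions),
                    backbone_coords(native, fit_regions),
                    by = key, suffix = c("_m", "_n"))
  if (nrow(fit) < 3) stopf("too few common framework atoms to fit")
  aln <- kabsch_align(as.matrix(fit[, c("x_m", "y_m", "z_m")]),
                      as.matrix(fit[, c("x_n", "y_n", "z_n")]))
  reg <- inner_join(backbone_coords(model, region),
                    backbone_coords(native, region),
                    by = key, suffix = c("_m", "_n"))
  if (nrow(reg) == 0) {
    stopf("no common residues in region %s", region,
          class = "abkit_missing_region")
  }
  m <- aln$apply(as.matrix(reg[, c("x_m", "y_m", "z_m")]))
  n <- as.matrix(reg[, c("x_n", "y_n", "z_n")])
  sqrt(mean(rowSums((m - n)^2)))
}

#' Grafting-style benchmark over model/native pairs
#'
#' For every manifest row, reads the model and native structures, and
#' reports the per-region backbone RMSD (framework-superposed). A target
#' whose files cannot be read yields failure rows and the run continues.
#'
#' @param manifest data frame with columns `target_id`, `model_path`,
#'   `native_path`; files must use chain ids `H`/`L`
#' @param regions regions to evaluate
#' @param thresholds optional named numeric vector of per-region RMSD
#'   thresholds in Angstrom; regions without a threshold pass by default
#' @return tibble of class `ab_benchmark`: `target_id`, `region`, `rmsd`,
#'   `threshold`, `pass`
#' @export
benchmark_report <- function(manifest,
                             regions = c(CDR_NAMES, "FRL", "FRH"),
                             thresholds = NULL) {
  read_pair_member <- function(path, id) {
    read_chothia_structure(path, tibble(pdb = id, Hchain = "H",
                                        Lchain = "L",
                                        resolution = NA_real_,
                                        method = NA_character_))
  }
  out <- purrr::pmap(manifest[, c("target_id", "model_path", "native_path")],
                     function(target_id, model_path, native_path) {
    rows <- tryCatch({
      model <- read_pair_member(model_path, target_id)
      native <- read_pair_member(native_path, target_id)
      purrr::map(regions, function(r) {
        rmsd <- tryCatch(backbone_rmsd(model, native, r),
                         abkit_missing_region = function(e) NA_real_)
        tibble(target_id = target_id, region = r, rmsd = rmsd)
      }) %>% purrr::list_rbind()
    }, error = function(e) {
      warn(sprintf("target %s failed: %s", target_id, conditionMessage(e)))
      tibble(target_id = target_id, region = regions, rmsd = NA_real_)
    })
    rows
  }) %>% purrr::list_rbind()
  out <- out %>%
    mutate(threshold = if (is.null(thresholds)) NA_real_ else
             unname(thresholds[.data$region]),
           pass = !is.na(.data$rmsd) &
             (is.na(.data$threshold) | .data$rmsd <= .data$threshold)) %>%
    arrange(.data$target_id, match(.data$region, REGION_NAMES))
  class(out) <- c("ab_benchmark", class(out))
  out
}

#' Write a benchmark report as TSV
#'
#' @param report an `ab_benchmark`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_benchmark_report <- function(report, path) {
  readr::write_tsv(as_tibble(report), path)
  invisible(path)
}
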