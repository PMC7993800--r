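#' Quality-control filters for template-database curation
#'
#' Structures entering the template database must satisfy: resolution
#' strictly below 3 A; loadability (parseable, complete N/CA/C/O backbone,
#' recognizable residue codes); backbone geometry (no C-N bond longer than
#' 2 A, CA-C-N angles within 89.5-144.5 degrees, C-N-CA within 95-151
#' degrees) outside the CDRs; no zero-occupancy atoms; and no missing
#' conserved anchor residues (the region-boundary positions plus the
#' orientation anchors L5/L104 and H5/H109). Geometry violations inside a
#' CDR do not reject the structure; they mark that CDR as chainbreak and
#' exclude it from pooling.
#'
#' @name qc
NULL

QC_GEOM <- list(max_cn = 2.0,
                ca_c_n = c(89.5, 144.5),
                c_n_ca = c(95.0, 151.0))

criterion_row <- function(criterion, pass, detail = "") {
  tibble(criterion = criterion, pass = pass, detail = detail)
}

#' @rdname qc
#' @param structure an [ab_structure]
#' @param cutoff resolution cutoff in Angstrom (strict upper bound)
#' @return each `check_*` returns a one-row tibble (`criterion`, `pass`,
#'   `detail`); [quality_report()] stacks all of them
#' @export
check_resolution <- function(structure, cutoff = 3.0) {
  res <- structure$resolution
  pass <- !is.na(res) && res < cutoff
  criterion_row("resolution", pass,
                ifelse(is.na(res), "resolution not reported",
                       sprintf("%.2f A vs cutoff %.2f A", res, cutoff)))
}

#' @rdname qc
#' @export
check_loadability <- function(structure) {
  res <- residue_table(structure$atoms) %>%
    filter(.data$chain_kind != "antigen")
  if (nrow(res) == 0) {
    return(criterion_row("loadability", FALSE, "no antibody residues"))
  }
  bb <- structure$atoms %>%
    filter(.data$chain_kind != "antigen",
           .data$elety %in% c("N", "CA", "C", "O")) %>%
    count(.data$chain_kind, .data$resno, .data$icode)
  incomplete <- nrow(res) - sum(bb$n == 4)
  unknown <- sum(is.na(suppressWarnings(bio3d::aa321(res$resid))))
  pass <- incomplete == 0 && unknown == 0
  criterion_row("loadability", pass,
                sprintf("%d residues missing backbone atoms; %d unknown codes",
                        incomplete, unknown))
}

vec_angle <- function(a, b, c) {
  u <- a - b; v <- c - b
  cosang <- sum(u * v) / sqrt(sum(u^2) * sum(v^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

# per-link peptide geometry between consecutive present residues of the
# antibody chains; missing backbone atoms count as violations
geometry_links <- function(structure) {
  atoms <- structure$atoms %>% filter(.data$chain_kind != "antigen")
  res <- residue_table(atoms)
  wide <- atoms %>%
    filter(.data$elety %in% c("N", "CA", "C")) %>%
    distinct(.data$chain_kind, .data$resno, .data$icode, .data$elety,
             .keep_all = TRUE) %>%
    tidyr::pivot_wider(id_cols = c("chain_kind", "resno", "icode"),
                       names_from = "elety",
                       values_from = c("x", "y", "z"))
  res <- res %>% left_join(wide, by = c("chain_kind", "resno", "icode"))
  split(res, chain_kind_factor(res$chain_kind), drop = TRUE) %>%
    purrr::imap(function(cr, kind) {
      n <- nrow(cr)
      if (n < 2) return(NULL)
      i <- seq_len(n - 1)
      xyz <- function(rows, at) {
        cbind(cr[[paste0("x_", at)]][rows], cr[[paste0("y_", at)]][rows],
              cr[[paste0("z_", at)]][rows])
      }
      ca1 <- xyz(i, "CA"); c1 <- xyz(i, "C")
      n2 <- xyz(i + 1, "N"); ca2 <- xyz(i + 1, "CA")
      ang <- function(a, b, c) {
        u <- a - b; v <- c - b
        cosang <- rowSums(u * v) /
          sqrt(rowSums(u^2) * rowSums(v^2))
        acos(pmin(1, pmax(-1, cosang))) * 180 / pi
      }
      d <- sqrt(rowSums((n2 - c1)^2))
      a1 <- ang(ca1, c1, n2)   # CA-C-N
      a2 <- ang(c1, n2, ca2)   # C-N-CA
      missing_atom <- is.na(d) | is.na(a1) | is.na(a2)
      violation <- missing_atom | d > QC_GEOM$max_cn |
        a1 < QC_GEOM$ca_c_n[1] | a1 > QC_GEOM$ca_c_n[2] |
        a2 < QC_GEOM$c_n_ca[1] | a2 > QC_GEOM$c_n_ca[2]
      tibble(chain_kind = kind,
             resno1 = cr$resno[i], icode1 = cr$icode[i],
             resno2 = cr$resno[i + 1], icode2 = cr$icode[i + 1],
             cn_dist = unname(d), ca_c_n = unname(a1),
             c_n_ca = unname(a2), violation = unname(violation),
             region1 = assign_region(kind, cr$resno[i]),
             region2 = assign_region(kind, cr$resno[i + 1]))
    }) %>%
    purrr::list_rbind()
}

#' @rdname qc
#' @export
check_backbone_geometry <- function(structure) {
  links <- geometry_links(structure)
  if (is.null(links) || nrow(links) == 0) {
    return(criterion_row("backbone_geometry", FALSE, "no consecutive residues"))
  }
  # violations with a CDR flank are chainbreaks, handled per region
  non_cdr <- links %>%
    filter(.data$violation,
           !(.data$region1 %in% CDR_NAMES | .data$region2 %in% CDR_NAMES))
  out <- criterion_row("backbone_geometry", nrow(non_cdr) == 0,
                       ifelse(nrow(non_cdr) == 0, "all links within windows",
                              sprintf("%d framework link violation(s), first at %s %d-%d",
                                      nrow(non_cdr), non_cdr$chain_kind[1],
                                      non_cdr$resno1[1], non_cdr$resno2[1])))
  attr(out, "links") <- links
  out
}

#' @rdname qc
#' @export
check_occupancy <- function(structure) {
  n_zero <- sum(structure$atoms$o <= 0)
  criterion_row("occupancy", n_zero == 0,
                sprintf("%d zero-occupancy atom(s)", n_zero))
}

# conserved positions whose absence disqualifies a template: every region
# boundary in the definition table, including the orientation anchors
anchor_positions <- function() {
  chothia_regions() %>%
    tidyr::pivot_longer(c("start", "end"), values_to = "resno") %>%
    distinct(.data$chain_kind, .data$resno)
}

#' @rdname qc
#' @export
check_anchor_residues <- function(structure) {
  res <- residue_table(structure$atoms)
  kinds <- intersect(c("light", "heavy"), unique(res$chain_kind))
  need <- anchor_positions() %>% filter(.data$chain_kind %in% kinds)
  have <- res %>% distinct(.data$chain_kind, .data$resno)
  missing <- anti_join(need, have, by = c("chain_kind", "resno"))
  criterion_row("anchors", nrow(missing) == 0,
                ifelse(nrow(missing) == 0, "all anchor residues present",
                       paste("missing:",
                             paste(sprintf("%s%d",
                                           toupper(substr(missing$chain_kind, 1, 1)),
                                           missing$resno), collapse = " "))))
}

#' Detect CDR loops interrupted by chainbreaks
#'
#' A CDR is flagged when a peptide link with at least one flanking residue
#' inside the loop violates the backbone-geometry windows (C-N > 2 A or
#' angles outside range), or when an interior Chothia number of the range
#' is absent while its immediate neighbours are present but spatially
#' discontinuous. Terminal absences are truncation, not breaks; short
#' loops that skip interior numbers with continuous geometry are not
#' flagged. Only CDRs are reported; framework breaks are handled by
#' [check_backbone_geometry()].
#'
#' @param structure an [ab_structure]
#' @return character vector of CDR names with breaks (possibly empty)
#' @export
detect_cdr_chainbreaks <- function(structure) {
  links <- geometry_links(structure)
  if (is.null(links) || nrow(links) == 0) return(character())
  bad <- links %>%
    filter(.data$violation,
           .data$region1 %in% CDR_NAMES | .data$region2 %in% CDR_NAMES)
  unique(c(bad$region1[bad$region1 %in% CDR_NAMES],
           bad$region2[bad$region2 %in% CDR_NAMES]))
}

#' Average B-factor over all atoms of a CDR loop
#'
#' @param structure an [ab_structure]
#' @param region a CDR region name
#' @return mean B-factor in A^2
#' @export
average_cdr_bfactor <- function(structure, region) {
  stopifnot(region %in% CDR_NAMES)
  ranges <- region_ranges(region)
  at <- structure$atoms %>%
    filter(.data$chain_kind == ranges$chain_kind[1],
           .data$resno >= ranges$start[1], .data$resno <= ranges$end[1])
  if (nrow(at) == 0) {
    stopf("region %s empty in %s", region, structure$pdb_id,
          class = "abkit_missing_region")
  }
  mean(at$b)
}

#' Full quality report for one structure
#'
#' Runs every configured criterion (resolution, loadability, backbone
#' geometry, occupancy, anchors) and stacks the results; every criterion
#' appears exactly once, pass or fail.
#'
#' @inheritParams check_resolution
#' @return tibble of class `ab_quality_report` with columns `pdb_id`,
#'   `criterion`, `pass`, `detail`
#' @export
quality_report <- function(structure, cutoff = 3.0) {
  out <- bind_rows(check_resolution(structure, cutoff),
                   check_loadability(structure),
                   check_backbone_geometry(structure),
                   check_occupancy(structure),
                   check_anchor_residues(structure)) %>%
    mutate(pdb_id = structure$pdb_id, .before = 1)
  class(out) <- c("ab_quality_report", class(out))
  out
}

#' Write a quality report as TSV (one criterion per row)
#'
#' @param report an `ab_quality_report`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_quality_report <- function(report, path) {
  readr::write_tsv(as_tibble(report), path)
  invisible(path)
}
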