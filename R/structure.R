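#' Antibody structure container
#'
#' A light wrapper around a tidy atom table plus entry metadata. `atoms` is
#' a tibble with one row per atom and columns `chain_kind` (light / heavy /
#' antigen), `chain_id`, `resno`, `icode`, `resid`, `elety`, `element`,
#' `x`, `y`, `z`, `o` (occupancy) and `b` (B-factor). Residues are kept
#' strictly ordered by chain kind then (number, insertion code).
#'
#' @param pdb_id 4-character PDB identifier
#' @param atoms atom tibble as described above
#' @param resolution resolution in Angstrom, or `NA` when not reported
#'   (NMR / low-resolution EM style entries)
#' @param method experimental method string
#' @return an object of class `ab_structure`
#' @export
ab_structure <- function(pdb_id, atoms, resolution = NA_real_,
                         method = "X-RAY DIFFRACTION") {
  stopifnot(is.data.frame(atoms))
  need <- c("chain_kind", "chain_id", "resno", "icode", "resid", "elety",
            "element", "x", "y", "z", "o", "b")
  missing_cols <- setdiff(need, names(atoms))
  if (length(missing_cols) > 0) {
    stopf("atom table lacks columns: %s", paste(missing_cols, collapse = ", "))
  }
  atoms <- as_tibble(atoms) %>% arrange_residues()
  structure(list(pdb_id = pdb_id, atoms = atoms,
                 resolution = as.numeric(resolution), method = method),
            class = "ab_structure")
}

#' @export
print.ab_structure <- function(x, ...) {
  res <- residue_table(x$atoms)
  counts <- table(factor(res$chain_kind, levels = CHAIN_KINDS))
  cat(sprintf("<ab_structure %s>  resolution %s A, %s\n", x$pdb_id,
              ifelse(is.na(x$resolution), "NA", format(x$resolution)),
              x$method))
  cat(sprintf("  residues: light %d, heavy %d, antigen %d; atoms %d\n",
              counts[["light"]], counts[["heavy"]], counts[["antigen"]],
              nrow(x$atoms)))
  invisible(x)
}

#' Read a SAbDab-style summary table
#'
#' Tab-delimited with header `pdb  Hchain  Lchain  resolution  method`.
#' Chain ids are single characters; absent chains are `NA`.
#'
#' @param path TSV file
#' @return tibble with those five columns
#' @export
read_summary_table <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    pdb = readr::col_character(),
                    Hchain = readr::col_character(),
                    Lchain = readr::col_character(),
                    resolution = readr::col_double(),
                    method = readr::col_character())) %>%
    mutate(across(c("Hchain", "Lchain"), ~ ifelse(.x %in% c("", "NA"), NA, .x)))
}

#' Read a Chothia-numbered antibody PDB entry
#'
#' Parses PDB-format coordinates (ATOM/TER/END records) and keeps the
#' heavy and light chains named in the summary record; all other chains
#' are antigen and dropped here. Alternate locations other than blank or
#' "A" are discarded. Resolution and method come from the summary record,
#' not from REMARKs. A record naming the same chain as both heavy and
#' light is a single-chain Fv and is rejected.
#'
#' @param coordinates path to a PDB file, or a character vector of PDB
#'   lines
#' @param summary one-row data frame with columns `pdb`, `Hchain`,
#'   `Lchain`, `resolution`, `method`
#' @param keep_antigen keep unnamed chains as antigen instead of dropping
#'   them (used for docking fold trees)
#' @return an [ab_structure]
#' @export
read_chothia_structure <- function(coordinates, summary,
                                   keep_antigen = FALSE) {
  summary <- as.list(summary[1, , drop = FALSE])
  h_id <- summary$Hchain
  l_id <- summary$Lchain
  if (!is.na(h_id) && !is.na(l_id) && h_id == l_id) {
    stopf("entry %s: heavy and light share chain id '%s' (scFv); ignored",
          summary$pdb, h_id, class = "abkit_scfv")
  }
  atoms <- parse_pdb_atoms(coordinates)
  for (id in c(h_id, l_id)) {
    if (!is.na(id) && !id %in% atoms$chain_id) {
      stopf("entry %s: chain '%s' named in summary absent from coordinates",
            summary$pdb, id, class = "abkit_missing_chain")
    }
  }
  atoms <- atoms %>%
    mutate(chain_kind = case_when(
      !is.na(h_id) & .data$chain_id == h_id ~ "heavy",
      !is.na(l_id) & .data$chain_id == l_id ~ "light",
      TRUE ~ "antigen"))
  if (!keep_antigen) atoms <- atoms %>% filter(.data$chain_kind != "antigen")
  ab_structure(summary$pdb, atoms,
               resolution = summary$resolution %||% NA_real_,
               method = summary$method %||% NA_character_)
}

# bio3d-backed PDB parsing -> tidy atom table
parse_pdb_atoms <- function(coordinates) {
  path <- coordinates
  if (length(coordinates) > 1 || grepl("\n", coordinates[1], fixed = TRUE) ||
      startsWith(coordinates[1], "ATOM")) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(unlist(strsplit(coordinates, "\n", fixed = TRUE)), path)
  } else if (!file.exists(path)) {
    stopf("coordinate file not found: %s", path, class = "abkit_parse_error")
  }
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE)),
                  error = function(e) {
                    stopf("PDB parse failed: %s", conditionMessage(e),
                          class = "abkit_parse_error")
                  })
  at <- pdb$atom %>%
    as_tibble() %>%
    filter(.data$type == "ATOM", is.na(.data$alt) | .data$alt == "A")
  if (nrow(at) == 0 || anyNA(at$x) || anyNA(at$y) || anyNA(at$z)) {
    stopf("malformed ATOM records (missing coordinates)",
          class = "abkit_parse_error")
  }
  at %>%
    transmute(chain_kind = "antigen",
              chain_id = .data$chain,
              resno = as.integer(.data$resno),
              icode = ifelse(is.na(.data$insert), "", .data$insert),
              resid = .data$resid,
              elety = .data$elety,
              element = ifelse(is.na(.data$elesy) | .data$elesy == "",
                               substr(trimws(.data$elety), 1, 1),
                               .data$elesy),
              x = .data$x, y = .data$y, z = .data$z,
              o = ifelse(is.na(.data$o), 1, .data$o),
              b = ifelse(is.na(.data$b), 0, .data$b))
}

#' Truncate an antibody structure to the Fv
#'
#' Keeps light-chain residues numbered 1-109 and heavy-chain residues
#' 1-112 (inclusive, insertion codes included); everything else on the
#' antibody chains is removed. Antigen chains are untouched. Idempotent.
#'
#' @param structure an [ab_structure]
#' @return truncated [ab_structure]
#' @export
truncate_fv <- function(structure) {
  atoms <- structure$atoms %>%
    filter(.data$chain_kind == "antigen" |
             (.data$chain_kind == "light" &
                .data$resno >= 1 & .data$resno <= 109) |
             (.data$chain_kind == "heavy" &
                .data$resno >= 1 & .data$resno <= 112))
  ab_structure(structure$pdb_id, atoms, structure$resolution,
               structure$method)
}

#' Write an ab_structure back to PDB format
#'
#' @param structure an [ab_structure]
#' @param path output file
#' @return `path`, invisibly
#' @export
write_structure_pdb <- function(structure, path) {
  at <- structure$atoms
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(at[, c("x", "y", "z")]))),
                   resno = at$resno, resid = at$resid, insert = at$icode,
                   chain = at$chain_id, elety = at$elety,
                   eleno = seq_len(nrow(at)), o = at$o, b = at$b,
                   elesy = at$element)
  invisible(path)
}
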