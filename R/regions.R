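#' Chothia structural-region definitions for the antibody Fv
#'
#' The variable fragment is partitioned into six CDR loops and two
#' framework regions, each defined as inclusive Chothia residue-number
#' ranges; an additional Orientation region (L5-L104, H5-H109) anchors
#' relative heavy/light placement. Framework definitions do not exactly
#' complement the CDRs: a few non-CDR loops belong to neither, and
#' positions outside every range are "unassigned".
#'
#' @return a tibble with columns `region`, `chain_kind`, `start`, `end`
#'   (one row per inclusive range)
#' @examples
#' chothia_regions()
#' @export
chothia_regions <- function() {
  tibble::tribble(
    ~region,       ~chain_kind, ~start, ~end,
    "CDR_L1",      "light",     24L,    34L,
    "CDR_L2",      "light",     50L,    56L,
    "CDR_L3",      "light",     89L,    97L,
    "FRL",         "light",     10L,    23L,
    "FRL",         "light",     35L,    39L,
    "FRL",         "light",     46L,    49L,
    "FRL",         "light",     57L,    66L,
    "FRL",         "light",     71L,    88L,
    "FRL",         "light",     98L,    104L,
    "CDR_H1",      "heavy",     26L,    35L,
    "CDR_H2",      "heavy",     50L,    65L,
    "CDR_H3",      "heavy",     95L,    102L,
    "FRH",         "heavy",     10L,    25L,
    "FRH",         "heavy",     36L,    39L,
    "FRH",         "heavy",     46L,    49L,
    "FRH",         "heavy",     66L,    94L,
    "FRH",         "heavy",     103L,   109L,
    "Orientation", "light",     5L,     104L,
    "Orientation", "heavy",     5L,     109L
  )
}

REGION_NAMES <- c("CDR_L1", "CDR_L2", "CDR_L3", "FRL",
                  "CDR_H1", "CDR_H2", "CDR_H3", "FRH", "Orientation")
CDR_NAMES <- c("CDR_L1", "CDR_L2", "CDR_L3", "CDR_H1", "CDR_H2", "CDR_H3")

# short pool labels used in database file names (database.L1.11 etc.)
region_pool_label <- function(region) {
  c(CDR_L1 = "L1", CDR_L2 = "L2", CDR_L3 = "L3",
    CDR_H1 = "H1", CDR_H2 = "H2", CDR_H3 = "H3",
    FRL = "FRL", FRH = "FRH", Orientation = "orientation")[region]
}

#' Look up the residue ranges of one structural region
#'
#' @param name one of `"CDR_L1"`, `"CDR_L2"`, `"CDR_L3"`, `"FRL"`,
#'   `"CDR_H1"`, `"CDR_H2"`, `"CDR_H3"`, `"FRH"`, `"Orientation"`
#' @return tibble of ranges (subset of [chothia_regions()])
#' @examples
#' region_ranges("CDR_L1")   # 24-34 on the light chain
#' @export
region_ranges <- function(name) {
  if (length(name) != 1 || !name %in% REGION_NAMES) {
    stopf("unknown region name '%s'", paste(name, collapse = ","),
          class = "abkit_region_error")
  }
  chothia_regions() %>% filter(.data$region == name)
}

#' Assign Chothia residues to structural regions
#'
#' Vectorized inverse of the region table: each (chain kind, number) pair
#' maps to the unique CDR or framework region whose range contains the
#' number, or `"unassigned"` when outside all ranges (non-CDR loops are
#' excluded from the frameworks, and antigen chains never receive antibody
#' regions). Insertion-coded residues inherit the region of their parent
#' number, so no insertion code argument is needed.
#'
#' @param chain_kind `"light"`, `"heavy"` or `"antigen"` (recycled)
#' @param resno integer Chothia numbers
#' @return character vector of region names / `"unassigned"`
#' @examples
#' assign_region("light", 24)       # CDR_L1
#' assign_region("heavy", c(100, 45))
#' @export
assign_region <- function(chain_kind, resno) {
  stopifnot(all(chain_kind %in% CHAIN_KINDS))
  defs <- chothia_regions() %>% filter(.data$region != "Orientation")
  purrr::map2_chr(rep_len(chain_kind, length(resno)), resno, function(ck, n) {
    hit <- defs$region[defs$chain_kind == ck & defs$start <= n & defs$end >= n]
    if (length(hit) == 0) "unassigned" else hit[[1]]
  })
}

#' Extract the sequence of one structural region from a structure
#'
#' Concatenates the one-letter codes of all residues whose Chothia number
#' falls inside the region's ranges, in Chothia order with insertion-coded
#' residues included (insertions lengthen the sequence, missing numbers
#' shorten it). Non-standard residues appear as `"X"`.
#'
#' @param structure an [ab_structure] object
#' @param region region name (see [chothia_regions()])
#' @return one-row tibble: `region`, `sequence`, `length`, `source_id`
#' @export
extract_region_sequence <- function(structure, region) {
  ranges <- region_ranges(region)
  res <- residue_table(structure$atoms) %>%
    inner_join(ranges, by = "chain_kind",
               relationship = "many-to-many") %>%
    filter(.data$resno >= .data$start, .data$resno <= .data$end) %>%
    distinct(.data$chain_kind, .data$resno, .data$icode, .data$aa) %>%
    arrange_residues()
  if (nrow(res) == 0) {
    stopf("region %s has no residues in structure %s", region,
          structure$pdb_id, class = "abkit_missing_region")
  }
  tibble(region = region,
         sequence = paste0(res$aa, collapse = ""),
         length = nrow(res),
         source_id = structure$pdb_id)
}

#' All region sequences of a structure
#'
#' @param structure an [ab_structure]
#' @param regions region names to extract (default: all that apply to the
#'   chains present, Orientation excluded)
#' @return tibble with one row per region present; regions entirely absent
#'   from the structure are silently omitted
#' @export
region_sequences <- function(structure, regions = NULL) {
  if (is.null(regions)) {
    kinds <- unique(residue_table(structure$atoms)$chain_kind)
    regions <- chothia_regions() %>%
      filter(.data$region != "Orientation", .data$chain_kind %in% kinds) %>%
      distinct(.data$region) %>%
      pull()
  }
  purrr::map(regions, function(r) {
    tryCatch(extract_region_sequence(structure, r),
             abkit_missing_region = function(e) NULL)
  }) %>%
    purrr::compact() %>%
    purrr::list_rbind()
}

#' Write the region-definition table as TSV
#'
#' Machine-readable export (columns region, chain, start, end) for
#' documentation and fixtures.
#'
#' @param path output file
#' @return `path`, invisibly
#' @export
write_region_table <- function(path) {
  readr::write_tsv(chothia_regions() %>% rename(chain = "chain_kind"), path)
  invisible(path)
}
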