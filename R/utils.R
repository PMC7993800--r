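#' @importFrom rlang .data abort warn %||%
#' @import dplyr
#' @importFrom tibble tibble as_tibble
NULL

# order chain kinds as light < heavy < antigen throughout
CHAIN_KINDS <- c("light", "heavy", "antigen")

chain_kind_factor <- function(x) factor(x, levels = CHAIN_KINDS)

#' Residue ordering key
#'
#' Chothia residues sort by (number, insertion code), the blank insertion
#' code sorting before "A" < "B" < ... This returns an integer key usable
#' with `order()` or `dplyr::arrange()` within a chain.
#'
#' @param resno integer Chothia numbers (>= 1)
#' @param icode insertion codes, `""` for none
#' @return numeric sort key
#' @export
residue_order_key <- function(resno, icode = "") {
  icode <- ifelse(is.na(icode) | icode == "", " ", toupper(icode))
  resno * 100 + match(icode, c(" ", LETTERS))
}

arrange_residues <- function(tbl) {
  tbl %>%
    arrange(chain_kind_factor(.data$chain_kind),
            residue_order_key(.data$resno, .data$icode))
}

aa_three_to_one <- function(resid) {
  out <- suppressWarnings(bio3d::aa321(resid))
  out[is.na(out) | !out %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  out
}

stopf <- function(fmt, ..., class = "abkit_error") {
  abort(sprintf(fmt, ...), class = class)
}

# distinct residue table (one row per residue) from an atom table
residue_table <- function(atoms) {
  atoms %>%
    distinct(.data$chain_kind, .data$chain_id, .data$resno, .data$icode,
             .data$resid) %>%
    mutate(aa = aa_three_to_one(.data$resid)) %>%
    arrange_residues()
}
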