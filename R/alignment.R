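#' Alignment scoring schemes for template selection
#'
#' Framework templates are ranked by gapped local alignment under
#' BLOSUM62; CDR templates by ungapped full-length scoring under PAM30
#' (pools are length-partitioned, so CDR comparisons never need gaps).
#' Gap costs follow the convention that a gap of length L costs
#' `gap_open + L * gap_extend`.
#'
#' @param matrix_name `"BLOSUM62"` or `"PAM30"`
#' @param gap_open,gap_extend non-negative penalties; defaults are the
#'   conventional pairings (11/1 for BLOSUM62, 9/1 for PAM30)
#' @return object of class `ab_scoring_scheme`
#' @export
scoring_scheme <- function(matrix_name = c("BLOSUM62", "PAM30"),
                           gap_open = NULL, gap_extend = NULL) {
  matrix_name <- match.arg(matrix_name)
  defaults <- list(BLOSUM62 = c(11, 1), PAM30 = c(9, 1))[[matrix_name]]
  gap_open <- gap_open %||% defaults[1]
  gap_extend <- gap_extend %||% defaults[2]
  stopifnot(gap_open >= 0, gap_extend >= 0)
  structure(list(matrix_name = matrix_name,
                 matrix = substitution_matrix(matrix_name),
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "ab_scoring_scheme")
}

substitution_matrix <- function(name) {
  env <- new.env()
  utils::data(list = name, package = "Biostrings", envir = env)
  m <- get(name, envir = env)
  m[AA1, AA1]
}

check_standard <- function(seq, what) {
  bad <- setdiff(strsplit(seq, "")[[1]], AA1)
  if (nchar(seq) == 0 || length(bad) > 0) {
    stopf("%s contains non-standard characters: %s", what,
          paste(bad, collapse = ""), class = "abkit_input_error")
  }
}

#' Local alignment score between a query and a template sequence
#'
#' Smith-Waterman local alignment under the scheme's substitution matrix
#' and affine gap costs; with `ungapped = TRUE` the two sequences must
#' have equal length and the score is the sum of matrix entries over
#' aligned positions (the CDR pool mode).
#'
#' @param query,template amino-acid strings (standard 20 letters)
#' @param scheme an [scoring_scheme()]
#' @param ungapped use full-length ungapped scoring
#' @return alignment score
#' @export
local_align_score <- function(query, template,
                              scheme = scoring_scheme("BLOSUM62"),
                              ungapped = FALSE) {
  check_standard(query, "query")
  check_standard(template, "template")
  if (ungapped) {
    if (nchar(query) != nchar(template)) {
      stopf("ungapped mode requires equal lengths",
            class = "abkit_input_error")
    }
    q <- strsplit(query, "")[[1]]
    t <- strsplit(template, "")[[1]]
    return(sum(scheme$matrix[cbind(q, t)]))
  }
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(template),
    type = "local", substitutionMatrix = scheme$matrix,
    gapOpening = scheme$gap_open, gapExtension = scheme$gap_extend,
    scoreOnly = TRUE))
}

#' Remove excluded PDB ids from a hit table
#'
#' Case-insensitive; excluded hits gain the `excluded_pdb` flag and are
#' dropped from the ranking (useful for benchmarking, where the query's
#' own crystal structure must not serve as its template).
#'
#' @param hits tibble with a `pdb_id` column
#' @param excluded_ids character vector of PDB ids
#' @return filtered hits; warns when nothing survives
#' @export
filter_exclude_pdb <- function(hits, excluded_ids) {
  if (length(excluded_ids) == 0 || nrow(hits) == 0) return(hits)
  keep <- !tolower(hits$pdb_id) %in% tolower(excluded_ids)
  if (!any(keep) && nrow(hits) > 0) {
    warn("all hits excluded by PDB filter")
  }
  hits[keep, , drop = FALSE]
}

#' Proline-mismatch filter for CDR templates
#'
#' Prolines occupy a distinct region of Ramachandran space, and the
#' substitution matrices do not penalize proline mismatches enough; a
#' template is dropped when any aligned position has proline in exactly
#' one of query and template. Only applicable to equal-length (CDR)
#' comparisons; framework alignments are exempt.
#'
#' @param query,template equal-length region sequences
#' @return list with `keep` (logical) and `mismatch_positions` (integer)
#' @export
filter_proline_mismatch <- function(query, template) {
  if (nchar(query) != nchar(template)) {
    stopf("proline filter requires equal-length sequences",
          class = "abkit_input_error")
  }
  q <- strsplit(query, "")[[1]]
  t <- strsplit(template, "")[[1]]
  pos <- which(xor(q == "P", t == "P"))
  list(keep = length(pos) == 0, mismatch_positions = pos)
}

#' Select structural templates for a query, per region
#'
#' CDR queries search only the pool of matching length with ungapped
#' PAM30 scoring; framework (and orientation) queries search all pool
#' lengths of their region with gapped BLOSUM62. Hits excluded by the
#' PDB filter or (for CDRs) the proline filter are flagged; flagged hits
#' are dropped from the ranking unless `verbose = TRUE`, in which case
#' they remain with non-empty `flags`. Ties are broken by higher score,
#' then lower template resolution, then lower average CDR B-factor, then
#' lexicographic PDB id.
#'
#' @param query an [ab_structure] or a region-sequence tibble (columns
#'   `region`, `sequence`, `length`) as from [region_sequences()]
#' @param db an `ab_template_db` from [build_database()]
#' @param exclude_pdb PDB ids to exclude (case-insensitive)
#' @param proline_filter apply the CDR proline-mismatch filter
#' @param top_n hits to keep per region
#' @param verbose keep flagged hits in the output
#' @return tibble: `region`, `rank`, `pdb_id`, `score`,
#'   `template_sequence`, `flags` (comma-separated, empty when clean);
#'   regions with no pool of matching length yield zero rows plus a
#'   warning naming the nearest available lengths
#' @export
select_templates <- function(query, db, exclude_pdb = character(),
                             proline_filter = TRUE, top_n = 10,
                             verbose = FALSE) {
  qseqs <- if (inherits(query, "ab_structure")) {
    region_sequences(query)
  } else {
    as_tibble(query)
  }
  pools <- db$pools
  rank_one <- function(qr, qs, ql) {
    is_cdr <- qr %in% CDR_NAMES
    pool <- pools[pools$region == qr, , drop = FALSE]
    if (is_cdr) {
      avail <- sort(unique(pool$length))
      pool <- pool[pool$length == ql, , drop = FALSE]
      if (nrow(pool) == 0) {
        near <- avail[order(abs(avail - ql))]
        warn(sprintf("no %s pool of length %d; nearest available: %s",
                     qr, ql,
                     paste(utils::head(near, 3), collapse = ", ")))
        return(NULL)
      }
      scheme <- scoring_scheme("PAM30")
    } else {
      scheme <- scoring_scheme("BLOSUM62")
    }
    if (nrow(pool) == 0) return(NULL)
    hits <- pool %>%
      rename(template_sequence = "sequence") %>%
      mutate(score = purrr::map_dbl(.data$template_sequence,
                                    ~ local_align_score(qs, .x, scheme,
                                                        ungapped = is_cdr)),
             flags = "")
    excluded <- tolower(hits$pdb_id) %in% tolower(exclude_pdb)
    hits$flags[excluded] <- "excluded_pdb"
    if (is_cdr && proline_filter) {
      pro <- purrr::map_lgl(hits$template_sequence,
                            ~ !filter_proline_mismatch(qs, .x)$keep)
      hits$flags[pro] <- paste0(
        ifelse(hits$flags[pro] == "", "", paste0(hits$flags[pro], ",")),
        "proline_mismatch")
    }
    if (!verbose) hits <- hits[hits$flags == "", , drop = FALSE]
    hits %>%
      arrange(desc(.data$score), .data$resolution, .data$avg_bfactor,
              .data$pdb_id) %>%
      slice_head(n = top_n) %>%
      mutate(rank = row_number(), region = qr) %>%
      select("region", "rank", "pdb_id", "score", "template_sequence",
             "flags")
  }
  purrr::pmap(list(qseqs$region, qseqs$sequence, qseqs$length),
              rank_one) %>%
    purrr::compact() %>%
    purrr::list_rbind()
}
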