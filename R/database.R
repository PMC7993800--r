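#' Choose the antibody to curate from one entry's summary rows
#'
#' A crystal structure can contain several distinct antibodies; to avoid
#' ambiguity the first row reported in the summary file is retained.
#' Single-chain rows (heavy-only nanobodies, or light-only) are kept;
#' scFv rows (heavy and light ids equal) are rejected, and an entry whose
#' rows are all scFv is skipped.
#'
#' @param rows summary tibble rows for one PDB id, in file order
#' @return the chosen one-row tibble
#' @export
select_antibody_from_entry <- function(rows) {
  stopifnot(nrow(rows) >= 1)
  ok <- is.na(rows$Hchain) | is.na(rows$Lchain) | rows$Hchain != rows$Lchain
  if (!any(ok)) {
    stopf("entry %s: all rows are scFv; skipped", rows$pdb[1],
          class = "abkit_scfv")
  }
  rows[which(ok)[1], , drop = FALSE]
}

fv_sequence_key <- function(structure) {
  res <- residue_table(structure$atoms) %>%
    filter(.data$chain_kind %in% c("light", "heavy"))
  paste0(res$aa, collapse = "")
}

#' Build the per-region, per-length template database
#'
#' Runs the full curation pipeline over a directory of Chothia-numbered
#' PDB files driven by a summary table. Per entry: select the antibody
#' row, parse, truncate to the Fv, apply the quality criteria
#' (resolution, loadability, backbone geometry, occupancy, anchors),
#' drop entries whose full Fv sequence duplicates an already-accepted
#' one, detect CDR chainbreaks (those CDRs are omitted from pooling),
#' exclude region sequences containing non-standard residues, compute
#' CDR B-factor averages, and pool sequences by (region, length). Every
#' rejection is recorded with its criterion.
#'
#' @param structures_dir directory containing `<pdb>.pdb` files
#' @param summary_path summary TSV (see [read_summary_table()])
#' @param resolution_cutoff strict resolution bound in Angstrom
#' @return object of class `ab_template_db`: `pools` (tibble `region`,
#'   `length`, `pdb_id`, `sequence`, `avg_bfactor`, `resolution`),
#'   `info` (per-region tables), `provenance` (accepted ids, rejection
#'   log, input counts, build date)
#' @export
build_database <- function(structures_dir, summary_path,
                           resolution_cutoff = 3.0) {
  summary <- read_summary_table(summary_path)
  if (nrow(summary) == 0) stopf("empty summary table: %s", summary_path)
  rejections <- list()
  pool_rows <- list()
  accepted <- character()
  seen_seqs <- character()
  reject <- function(pdb, criterion, detail = "") {
    rejections[[length(rejections) + 1]] <<-
      tibble(pdb_id = pdb, criterion = criterion, detail = detail)
  }

  for (pdb in unique(summary$pdb)) {
    rows <- summary %>% filter(.data$pdb == !!pdb)
    record <- tryCatch(select_antibody_from_entry(rows),
                       abkit_scfv = function(e) {
                         reject(pdb, "scfv", conditionMessage(e))
                         NULL
                       })
    if (is.null(record)) next
    path <- file.path(structures_dir, paste0(pdb, ".pdb"))
    st <- tryCatch(read_chothia_structure(path, record),
                   error = function(e) {
                     reject(pdb, "load", conditionMessage(e))
                     NULL
                   })
    if (is.null(st)) next
    st <- truncate_fv(st)
    qc <- quality_report(st, cutoff = resolution_cutoff)
    if (!all(qc$pass)) {
      failed <- qc %>% filter(!.data$pass)
      reject(pdb, failed$criterion[1],
             paste(failed$detail, collapse = "; "))
      next
    }
    key <- fv_sequence_key(st)
    if (key %in% seen_seqs) {
      reject(pdb, "duplicate_sequence", "identical Fv sequence retained earlier")
      next
    }
    seen_seqs <- c(seen_seqs, key)
    broken <- detect_cdr_chainbreaks(st)
    if (length(broken) > 0) {
      reject(pdb, "cdr_chainbreak",
             paste("omitted regions:", paste(broken, collapse = ",")))
      # entry stays accepted; only the broken CDRs are dropped
    }
    seqs <- region_sequences(st)
    kinds <- unique(residue_table(st$atoms)$chain_kind)
    if (all(c("light", "heavy") %in% kinds)) {
      ori <- tryCatch(extract_region_sequence(st, "Orientation"),
                      abkit_missing_region = function(e) NULL)
      if (!is.null(ori)) seqs <- bind_rows(seqs, ori)
    }
    seqs <- seqs %>% filter(!.data$region %in% broken)
    dropped_x <- seqs %>%
      filter(stringr::str_detect(.data$sequence, "X"))
    if (nrow(dropped_x) > 0) {
      reject(pdb, "nonstandard_residue",
             paste("regions with X excluded:",
                   paste(dropped_x$region, collapse = ",")))
    }
    seqs <- seqs %>% filter(!stringr::str_detect(.data$sequence, "X"))
    if (nrow(seqs) == 0) {
      reject(pdb, "no_regions", "no poolable region sequences")
      next
    }
    bf <- purrr::map_dbl(seqs$region, function(r) {
      if (r %in% CDR_NAMES) average_cdr_bfactor(st, r) else NA_real_
    })
    accepted <- c(accepted, pdb)
    pool_rows[[length(pool_rows) + 1]] <- seqs %>%
      transmute(region = .data$region, length = .data$length,
                pdb_id = pdb, sequence = .data$sequence,
                avg_bfactor = round(bf, 2),
                resolution = st$resolution)
  }

  pools <- purrr::list_rbind(pool_rows) %||%
    tibble(region = character(), length = integer(),
           pdb_id = character(), sequence = character(),
           avg_bfactor = numeric(), resolution = numeric())
  if (nrow(pools) > 0) {
    pools <- pools %>%
      arrange(match(.data$region, REGION_NAMES), .data$length,
              .data$pdb_id)
  }
  rejections <- purrr::list_rbind(rejections) %||%
    tibble(pdb_id = character(), criterion = character(),
           detail = character())
  structure(list(
    pools = pools,
    info = split(pools %>%
                   select("region", "pdb_id", "sequence", "length",
                          "avg_bfactor", "resolution"),
                 pools$region),
    provenance = list(
      build_date = format(Sys.Date()),
      n_entries = length(unique(summary$pdb)),
      n_accepted = length(accepted),
      accepted = accepted,
      rejections = rejections)),
    class = "ab_template_db")
}

#' @export
print.ab_template_db <- function(x, ...) {
  cat(sprintf("<ab_template_db> %d/%d entries accepted; %d pools\n",
              x$provenance$n_accepted, x$provenance$n_entries,
              nrow(distinct(x$pools, .data$region, .data$length))))
  invisible(x)
}

#' Write database pools and info tables to disk
#'
#' One FASTA file per (region, length) pool, named
#' `database.<region>.<length>` (e.g. `database.L1.11` for all length-11
#' first light-chain CDR sequences) with headers carrying the PDB id;
#' one tab-delimited info file per region; a TSV rejection log; and a
#' JSON provenance manifest. Empty pools emit no file.
#'
#' @param db an `ab_template_db`
#' @param out_dir output directory (created if needed)
#' @return tibble listing the files written, invisibly
#' @export
write_pools <- function(db, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- list()
  pools <- db$pools %>%
    mutate(label = region_pool_label(.data$region))
  for (grp in split(pools, ~ label + length, drop = TRUE)) {
    if (nrow(grp) == 0) next
    fname <- file.path(out_dir,
                       sprintf("database.%s.%d", grp$label[1],
                               grp$length[1]))
    writeLines(paste0(">", grp$pdb_id, "\n", grp$sequence), fname)
    files[[length(files) + 1]] <- tibble(kind = "pool", path = fname)
  }
  for (r in names(db$info)) {
    fname <- file.path(out_dir,
                       sprintf("info.%s.tsv", region_pool_label(r)))
    readr::write_tsv(db$info[[r]] %>% select(-"region"), fname)
    files[[length(files) + 1]] <- tibble(kind = "info", path = fname)
  }
  rej <- file.path(out_dir, "rejections.tsv")
  readr::write_tsv(db$provenance$rejections, rej)
  prov <- file.path(out_dir, "provenance.json")
  jsonlite::write_json(db$provenance, prov, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(purrr::list_rbind(files) %>%
              bind_rows(tibble(kind = c("rejections", "provenance"),
                               path = c(rej, prov))))
}

#' Read pool FASTA files back into a pools tibble
#'
#' Inverse of the FASTA part of [write_pools()]; used by the template
#' selector when working from an on-disk database.
#'
#' @param dir directory written by [write_pools()]
#' @return `ab_template_db`-shaped list with `pools` and `info`
#' @export
read_pools <- function(dir) {
  label_to_region <- c(L1 = "CDR_L1", L2 = "CDR_L2", L3 = "CDR_L3",
                       H1 = "CDR_H1", H2 = "CDR_H2", H3 = "CDR_H3",
                       FRL = "FRL", FRH = "FRH",
                       orientation = "Orientation")
  pool_files <- list.files(dir, pattern = "^database\\.", full.names = TRUE)
  pools <- purrr::map(pool_files, function(f) {
    parts <- strsplit(basename(f), ".", fixed = TRUE)[[1]]
    seqs <- Biostrings::readAAStringSet(f)
    tibble(region = unname(label_to_region[parts[2]]),
           length = as.integer(parts[3]),
           pdb_id = names(seqs),
           sequence = unname(as.character(seqs)))
  }) %>% purrr::list_rbind()
  info_files <- list.files(dir, pattern = "^info\\..*\\.tsv$",
                           full.names = TRUE)
  info <- purrr::map(info_files, readr::read_tsv,
                     show_col_types = FALSE) %>%
    stats::setNames(purrr::map_chr(info_files, function(f) {
      unname(label_to_region[strsplit(basename(f), ".",
                                      fixed = TRUE)[[1]][2]])
    }))
  meta <- purrr::map(names(info), function(r) {
    info[[r]] %>% mutate(region = r)
  }) %>% purrr::list_rbind()
  pools <- pools %>%
    left_join(meta %>% select("region", "pdb_id", "avg_bfactor",
                              "resolution"),
              by = c("region", "pdb_id"))
  structure(list(pools = pools, info = info,
                 provenance = list(source = dir)),
            class = "ab_template_db")
}
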