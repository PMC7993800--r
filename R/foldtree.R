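#' Fold-tree kinematics with virtual residues
#'
#' A fold tree is a directed acyclic graph over the residues of a
#' complex: peptide edges connect consecutive residues within a chain,
#' and jump edges carry rigid-body transforms between non-bonded
#' anchors. Moving a jump moves everything downstream of it rigidly.
#' The classic linear tree chains the proteins in file order (A-B-C-D),
#' so perturbing an upstream jump drags every later chain along; the
#' hierarchical tree instead places virtual residues -- position-only
#' nodes that never contribute to energies or quality checks -- at each
#' chain's and each group's center of mass, with jumps root -> group ->
#' chain, so subcomplexes (e.g. the two antibody chains versus the
#' antigen chains) dock independently. The hierarchical construction
#' makes no assumption about chain identity, so heavy-chain-only
#' antibodies are supported.
#'
#' @name foldtree
NULL

node_id <- function(chain_id, resno, icode) {
  paste0(chain_id, ":", resno, icode)
}

#' Unweighted center of mass of a set of atoms
#'
#' Mean of heavy-atom (non-hydrogen) positions.
#'
#' @param atoms atom tibble (columns `element`, `x`, `y`, `z`)
#' @return 3-vector in Angstrom
#' @export
center_of_mass <- function(atoms) {
  heavy <- atoms %>% filter(.data$element != "H")
  if (nrow(heavy) == 0) stopf("no heavy atoms")
  c(mean(heavy$x), mean(heavy$y), mean(heavy$z))
}

# per-chain residue table with CA position and distance to the chain COM
chain_residues <- function(atoms, chain) {
  ca <- atoms %>%
    filter(.data$chain_id == chain, .data$elety == "CA") %>%
    arrange(residue_order_key(.data$resno, .data$icode))
  com <- center_of_mass(atoms %>% filter(.data$chain_id == chain))
  ca %>%
    mutate(id = node_id(.data$chain_id, .data$resno, .data$icode),
           d_com = sqrt((.data$x - com[1])^2 + (.data$y - com[2])^2 +
                          (.data$z - com[3])^2))
}

new_foldtree <- function(nodes, edges, jumps, root, atoms) {
  structure(list(nodes = nodes, edges = edges, jumps = jumps,
                 root = root, atoms = atoms),
            class = "ab_foldtree")
}

#' @export
print.ab_foldtree <- function(x, ...) {
  cat(sprintf("<ab_foldtree> root %s; %d nodes (%d virtual), %d peptide edges, %d jumps\n",
              x$root, nrow(x$nodes), sum(x$nodes$kind == "virtual"),
              sum(x$edges$type == "peptide"), nrow(x$jumps)))
  invisible(x)
}

residue_nodes <- function(atoms, chains) {
  purrr::map(chains, function(ch) {
    chain_residues(atoms, ch) %>%
      transmute(id = .data$id, kind = "residue",
                chain_id = .data$chain_id,
                x = .data$x, y = .data$y, z = .data$z)
  }) %>% purrr::list_rbind()
}

# peptide edges radiating from the anchor residue toward both termini,
# preserving the single-parent property
chain_peptide_edges <- function(res_tbl, anchor_idx) {
  n <- nrow(res_tbl)
  up <- if (anchor_idx > 1) {
    tibble(from = res_tbl$id[anchor_idx:2],
           to = res_tbl$id[(anchor_idx - 1):1])
  }
  down <- if (anchor_idx < n) {
    tibble(from = res_tbl$id[anchor_idx:(n - 1)],
           to = res_tbl$id[(anchor_idx + 1):n])
  }
  bind_rows(up, down) %>% mutate(type = "peptide", jump_id = NA_integer_)
}

identity_jump <- function(jump_id, from, to) {
  tibble(jump_id = jump_id, from = from, to = to,
         rot = list(diag(3)), trans = list(c(0, 0, 0)))
}

#' Linear fold tree over chains in file order
#'
#' Jumps connect the center-of-mass-proximal residues of consecutive
#' chains (A to B to C ...); chains - 1 jumps in total. The root is the
#' first chain's anchor residue.
#'
#' @param structure an [ab_structure] (all chains participate, in order
#'   of first appearance in the atom table)
#' @return an `ab_foldtree`
#' @export
linear_foldtree <- function(structure) {
  atoms <- structure$atoms
  chains <- unique(atoms$chain_id)
  if (length(chains) == 0) stopf("empty complex")
  res_tbls <- purrr::map(chains, ~ chain_residues(atoms, .x))
  anchors <- purrr::map_int(res_tbls, ~ which.min(.x$d_com))
  nodes <- residue_nodes(atoms, chains)
  edges <- purrr::map2(res_tbls, anchors, chain_peptide_edges) %>%
    purrr::list_rbind()
  jumps <- if (length(chains) > 1) {
    purrr::map(seq_along(chains)[-1], function(i) {
      identity_jump(i - 1L,
                    res_tbls[[i - 1]]$id[anchors[i - 1]],
                    res_tbls[[i]]$id[anchors[i]])
    }) %>% purrr::list_rbind()
  } else {
    empty_jumps()
  }
  edges <- bind_rows(edges,
                     jumps %>% transmute(from = .data$from, to = .data$to,
                                         type = "jump",
                                         jump_id = .data$jump_id))
  new_foldtree(nodes, edges, jumps, res_tbls[[1]]$id[anchors[1]], atoms)
}

empty_jumps <- function() {
  tibble(jump_id = integer(), from = character(), to = character(),
         rot = list(), trans = list())
}

#' Hierarchical fold tree with virtual residues at centers of mass
#'
#' One virtual node per chain (at the chain COM), one per group (at the
#' group COM) and a root virtual node at the complex COM. Jumps run
#' root -> group virtuals, group virtual -> member chain virtuals, and
#' chain virtual -> the chain's COM-proximal residue; peptide edges
#' radiate from that anchor within each chain. Virtual nodes carry
#' positions but no atoms and never enter energy or quality
#' calculations.
#'
#' @param structure an [ab_structure]
#' @param groups list of character vectors of chain ids, e.g.
#'   `list(c("H", "L"), "A")` for antibody versus antigen; a single-chain
#'   group (nanobody) is valid
#' @return an `ab_foldtree`
#' @export
hierarchical_foldtree <- function(structure, groups) {
  atoms <- structure$atoms
  if (length(groups) == 0 || any(lengths(groups) == 0)) {
    stopf("groups must be a non-empty list of non-empty chain sets")
  }
  all_chains <- unlist(groups)
  missing <- setdiff(all_chains, unique(atoms$chain_id))
  if (length(missing) > 0) {
    stopf("chains not in structure: %s", paste(missing, collapse = ","))
  }
  root_id <- "V:root"
  com_root <- center_of_mass(atoms %>%
                               filter(.data$chain_id %in% all_chains))
  vnodes <- list(tibble(id = root_id, kind = "virtual",
                        chain_id = NA_character_,
                        x = com_root[1], y = com_root[2], z = com_root[3]))
  edges <- list()
  jumps <- list()
  jid <- 0L
  nodes <- residue_nodes(atoms, all_chains)
  for (gi in seq_along(groups)) {
    g_id <- sprintf("V:group%d", gi)
    com_g <- center_of_mass(atoms %>%
                              filter(.data$chain_id %in% groups[[gi]]))
    vnodes[[length(vnodes) + 1]] <-
      tibble(id = g_id, kind = "virtual", chain_id = NA_character_,
             x = com_g[1], y = com_g[2], z = com_g[3])
    jid <- jid + 1L
    jumps[[length(jumps) + 1]] <- identity_jump(jid, root_id, g_id)
    for (ch in groups[[gi]]) {
      c_id <- sprintf("V:chain%s", ch)
      com_c <- center_of_mass(atoms %>% filter(.data$chain_id == ch))
      vnodes[[length(vnodes) + 1]] <-
        tibble(id = c_id, kind = "virtual", chain_id = ch,
               x = com_c[1], y = com_c[2], z = com_c[3])
      jid <- jid + 1L
      jumps[[length(jumps) + 1]] <- identity_jump(jid, g_id, c_id)
      res_tbl <- chain_residues(atoms, ch)
      anchor <- which.min(res_tbl$d_com)
      jid <- jid + 1L
      jumps[[length(jumps) + 1]] <- identity_jump(jid, c_id,
                                                  res_tbl$id[anchor])
      edges[[length(edges) + 1]] <- chain_peptide_edges(res_tbl, anchor)
    }
  }
  jumps <- purrr::list_rbind(jumps)
  edges <- bind_rows(purrr::list_rbind(edges),
                     jumps %>% transmute(from = .data$from, to = .data$to,
                                         type = "jump",
                                         jump_id = .data$jump_id))
  new_foldtree(bind_rows(purrr::list_rbind(vnodes), nodes), edges, jumps,
               root_id, atoms %>% filter(.data$chain_id %in% all_chains))
}

# node ids reachable from `start` (inclusive) following edges downstream
downstream_nodes <- function(ft, start) {
  children <- split(ft$edges$to, ft$edges$from)
  seen <- character()
  stack <- start
  while (length(stack) > 0) {
    cur <- stack[[1]]
    stack <- stack[-1]
    if (cur %in% seen) next
    seen <- c(seen, cur)
    stack <- c(stack, children[[cur]])
  }
  seen
}

#' Perturb a jump and propagate rigidly downstream
#'
#' Applies a rigid-body update (rotation about the jump's downstream
#' anchor, then translation) to every node in the downstream subtree of
#' the jump, and to the atoms of every downstream physical residue.
#' Upstream nodes never move; within-subtree geometry is preserved
#' exactly.
#'
#' @param ft an `ab_foldtree`
#' @param jump_id jump to update
#' @param rotation 3x3 rotation matrix (orthonormal, det +1)
#' @param translation length-3 translation in Angstrom
#' @return the updated `ab_foldtree`
#' @export
apply_jump <- function(ft, jump_id, rotation = diag(3),
                       translation = c(0, 0, 0)) {
  j <- ft$jumps %>% filter(.data$jump_id == !!jump_id)
  if (nrow(j) == 0) stopf("unknown jump id %s", jump_id)
  if (abs(det(rotation) - 1) > 1e-8 ||
      max(abs(t(rotation) %*% rotation - diag(3))) > 1e-8) {
    stopf("rotation must be orthonormal with determinant +1")
  }
  sub <- downstream_nodes(ft, j$to[[1]])
  pivot_row <- ft$nodes %>% filter(.data$id == j$to[[1]])
  pivot <- c(pivot_row$x, pivot_row$y, pivot_row$z)
  move_xyz <- function(x, y, z) {
    p <- t(rotation %*% t(cbind(x - pivot[1], y - pivot[2],
                                z - pivot[3])))
    list(x = p[, 1] + pivot[1] + translation[1],
         y = p[, 2] + pivot[2] + translation[2],
         z = p[, 3] + pivot[3] + translation[3])
  }
  sel_n <- ft$nodes$id %in% sub
  moved <- move_xyz(ft$nodes$x[sel_n], ft$nodes$y[sel_n],
                    ft$nodes$z[sel_n])
  ft$nodes$x[sel_n] <- moved$x
  ft$nodes$y[sel_n] <- moved$y
  ft$nodes$z[sel_n] <- moved$z
  atom_ids <- node_id(ft$atoms$chain_id, ft$atoms$resno, ft$atoms$icode)
  sel_a <- atom_ids %in% sub
  if (any(sel_a)) {
    moved <- move_xyz(ft$atoms$x[sel_a], ft$atoms$y[sel_a],
                      ft$atoms$z[sel_a])
    ft$atoms$x[sel_a] <- moved$x
    ft$atoms$y[sel_a] <- moved$y
    ft$atoms$z[sel_a] <- moved$z
  }
  # compose the stored transform so the jump records its cumulative move
  idx <- which(ft$jumps$jump_id == jump_id)
  ft$jumps$rot[[idx]] <- rotation %*% ft$jumps$rot[[idx]]
  ft$jumps$trans[[idx]] <- as.numeric(ft$jumps$trans[[idx]] + translation)
  ft
}

#' Validate fold-tree structural invariants
#'
#' Checks acyclicity, connectivity from the root, the single-parent
#' property, and residue coverage (every physical residue of the complex
#' is a node).
#'
#' @param ft an `ab_foldtree`
#' @return tibble (`check`, `pass`, `detail`)
#' @export
validate_foldtree <- function(ft) {
  reach <- downstream_nodes(ft, ft$root)
  connected <- setdiff(ft$nodes$id, reach)
  parents <- table(ft$edges$to)
  multi <- names(parents)[parents > 1]
  rooted_in <- ft$root %in% ft$edges$to
  # cycle: an edge whose source is reachable from its target (back-edge)
  has_cycle <- any(purrr::map2_lgl(ft$edges$from, ft$edges$to,
                                   function(f, t) {
                                     f %in% downstream_nodes(ft, t)
                                   }))
  res_ids <- unique(node_id(ft$atoms$chain_id, ft$atoms$resno,
                            ft$atoms$icode))
  missing <- setdiff(res_ids, ft$nodes$id)
  tibble(
    check = c("acyclic", "connected", "single_parent", "coverage"),
    pass = c(!has_cycle && !rooted_in, length(connected) == 0,
             length(multi) == 0, length(missing) == 0),
    detail = c(
      ifelse(!has_cycle && !rooted_in, "", "cycle or rooted back-edge"),
      ifelse(length(connected) == 0, "",
             paste("unreachable:", paste(utils::head(connected, 5),
                                         collapse = ","))),
      ifelse(length(multi) == 0, "",
             paste("multiple parents:", paste(utils::head(multi, 5),
                                              collapse = ","))),
      ifelse(length(missing) == 0, "",
             paste("uncovered residues:", paste(utils::head(missing, 5),
                                                collapse = ",")))))
}

#' Serialize a fold tree as a plain-text edge list
#'
#' One line per edge: `EDGE <from> <to> peptide` or
#' `EDGE <from> <to> jump <id>`, preceded by `ROOT <id>` and `NODE`
#' lines carrying kinds and positions. [read_foldtree()] round-trips
#' exactly.
#'
#' @param ft an `ab_foldtree`
#' @param path output file
#' @return `path`, invisibly
#' @export
write_foldtree <- function(ft, path) {
  lines <- c(
    paste("ROOT", ft$root),
    sprintf("NODE %s %s %.6f %.6f %.6f", ft$nodes$id, ft$nodes$kind,
            ft$nodes$x, ft$nodes$y, ft$nodes$z),
    ifelse(ft$edges$type == "peptide",
           sprintf("EDGE %s %s peptide", ft$edges$from, ft$edges$to),
           sprintf("EDGE %s %s jump %d", ft$edges$from, ft$edges$to,
                   ft$edges$jump_id)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a fold tree written by [write_foldtree()]
#'
#' @param path edge-list file
#' @return an `ab_foldtree` (without the atom table; node geometry only)
#' @export
read_foldtree <- function(path) {
  lines <- readLines(path)
  root <- sub("^ROOT ", "", lines[startsWith(lines, "ROOT")])
  nd <- stringr::str_match(lines[startsWith(lines, "NODE")],
                           "^NODE (\\S+) (\\S+) (\\S+) (\\S+) (\\S+)$")
  nodes <- tibble(id = nd[, 2], kind = nd[, 3],
                  chain_id = NA_character_,
                  x = as.numeric(nd[, 4]), y = as.numeric(nd[, 5]),
                  z = as.numeric(nd[, 6]))
  ed <- stringr::str_match(lines[startsWith(lines, "EDGE")],
                           "^EDGE (\\S+) (\\S+) (\\S+)( (\\d+))?$")
  edges <- tibble(from = ed[, 2], to = ed[, 3], type = ed[, 4],
                  jump_id = as.integer(ed[, 6]))
  jumps <- edges %>%
    filter(.data$type == "jump") %>%
    transmute(jump_id = .data$jump_id, from = .data$from, to = .data$to,
              rot = purrr::map(.data$jump_id, ~ diag(3)),
              trans = purrr::map(.data$jump_id, ~ c(0, 0, 0)))
  new_foldtree(nodes, edges, jumps, root,
               tibble(chain_id = character(), resno = integer(),
                      icode = character(), element = character(),
                      x = numeric(), y = numeric(), z = numeric()))
}
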