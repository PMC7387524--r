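#' Molecular graphs
#'
#' A molecular graph is the heavy-atom (hydrogen-free) connectivity of a
#' ligand or amino-acid scaffold: an atom table (`atom_id`, `element`,
#' optional `name`, `role` flag `backbone`/`side_chain`/`other`) plus a bond
#' table of unordered atom-id pairs. Bond orders and aromaticity are
#' deliberately not modelled: substructure matching uses elements and
#' connectivity only, so AMP esters and sulfamoyl analogs of an aminoacyl
#' ligand match the same scaffold regardless of dictionary conventions.
#'
#' @param atoms data frame with columns `atom_id`, `element` and optionally
#'   `name`, `role`.
#' @param bonds data frame with columns `from`, `to` (atom ids).
#' @param validate check invariants (bond endpoints exist, no hydrogens, no
#'   duplicate atom ids).
#' @return an object of class `"molecular_graph"`.
#' @examples
#' g <- molecular_graph(
#'   atoms = data.frame(atom_id = c("C1", "O1"), element = c("C", "O")),
#'   bonds = data.frame(from = "C1", to = "O1"))
#' g
#' @export
molecular_graph <- function(atoms, bonds, validate = TRUE) {
  atoms <- tibble::as_tibble(atoms)
  bonds <- tibble::as_tibble(bonds)
  if (!"name" %in% names(atoms)) atoms$name <- atoms$atom_id
  if (!"role" %in% names(atoms)) atoms$role <- "other"
  atoms <- atoms[, c("atom_id", "element", "name", "role")]
  atoms$atom_id <- as.character(atoms$atom_id)
  if (nrow(bonds) > 0) {
    bonds <- tibble::tibble(from = as.character(bonds$from),
                            to = as.character(bonds$to))
    # canonical unordered representation, deduplicated
    swap <- bonds$from > bonds$to
    tmp <- bonds$from[swap]; bonds$from[swap] <- bonds$to[swap]
    bonds$to[swap] <- tmp
    bonds <- dplyr::distinct(bonds)
    bonds <- dplyr::arrange(bonds, .data$from, .data$to)
  } else {
    bonds <- tibble::tibble(from = character(), to = character())
  }
  g <- structure(list(atoms = atoms, bonds = bonds),
                 class = "molecular_graph")
  if (validate) {
    if (anyDuplicated(atoms$atom_id)) {
      stop("duplicate atom ids in molecular graph", call. = FALSE)
    }
    if (any(toupper(atoms$element) == "H")) {
      stop("molecular graphs are heavy-atom only; strip hydrogens",
           call. = FALSE)
    }
    missing <- setdiff(c(bonds$from, bonds$to), atoms$atom_id)
    if (length(missing) > 0) {
      stop("bond endpoint(s) not in atom table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
  }
  g
}

#' @export
print.molecular_graph <- function(x, ...) {
  cat("<molecular_graph> ", nrow(x$atoms), " atoms, ", nrow(x$bonds),
      " bonds\n", sep = "")
  invisible(x)
}

graph_adjacency <- function(g) {
  ids <- g$atoms$atom_id
  adj <- stats::setNames(vector("list", length(ids)), ids)
  for (i in seq_len(nrow(g$bonds))) {
    a <- g$bonds$from[i]; b <- g$bonds$to[i]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

graph_is_connected <- function(g) {
  n <- nrow(g$atoms)
  if (n <= 1) return(TRUE)
  adj <- graph_adjacency(g)
  seen <- g$atoms$atom_id[1]
  frontier <- seen
  while (length(frontier) > 0) {
    nxt <- setdiff(unique(unlist(adj[frontier], use.names = FALSE)), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  length(seen) == n
}

#' Build an amino-acid scaffold graph
#'
#' Returns the heavy-atom graph of an amino-acid ligand with the terminal
#' carboxyl hydroxyl oxygen removed -- the group cleaved during amino acid
#' activation, which must be ignored for substructure matching (in
#' post-activation aminoacyl ligands the corresponding position is the ester
#' bridge oxygen, likewise not part of the scaffold). The carbonyl oxygen is
#' retained and backbone atoms (N, CA, C, O) are flagged.
#'
#' Scaffold connectivity is embedded in the package as plain data tables;
#' no SMILES parsing happens at runtime.
#'
#' @param ligand_code one of the 22 three-letter ligand codes
#'   (see [ligand_codes()]).
#' @return a [molecular_graph()].
#' @examples
#' build_scaffold("Gly")   # 4 heavy atoms: N, CA, C, O
#' build_scaffold("Ser")   # adds CB and the side-chain OG
#' @export
build_scaffold <- function(ligand_code) {
  stopifnot(length(ligand_code) == 1)
  stop_unknown_ligand(ligand_code)
  tabs <- scaffold_tables()
  molecular_graph(
    atoms = tabs$atoms[tabs$atoms$ligand == ligand_code,
                       c("atom_id", "element", "role")],
    bonds = tabs$bonds[tabs$bonds$ligand == ligand_code, c("from", "to")])
}

scaffold_tables <- function() {
  if (is.null(.aarsfp_cache$scaffolds)) {
    dir <- system.file("extdata", package = "aarsfp", mustWork = TRUE)
    .aarsfp_cache$scaffolds <- list(
      atoms = utils::read.csv(file.path(dir, "scaffold_atoms.csv")),
      bonds = utils::read.csv(file.path(dir, "scaffold_bonds.csv")))
  }
  .aarsfp_cache$scaffolds
}

.aarsfp_cache <- new.env(parent = emptyenv())

#' Enumerate subgraph isomorphisms of a scaffold into a ligand graph
#'
#' Finds every injective, element-preserving, bond-preserving assignment of
#' pattern atoms to target atoms (a subgraph monomorphism: every pattern
#' bond must map onto a target bond; extra target bonds among mapped atoms
#' are permitted). All automorphic duplicates are kept -- downstream
#' occupancy mapping takes the union over isomorphisms, so symmetric atoms
#' such as the two valine methyls are treated as equivalent.
#'
#' The enumeration is exhaustive, exactly deduplicated, and returned in
#' deterministic lexicographic order of the assignment (pattern atoms sorted
#' by id, then mapped target ids compared in that order).
#'
#' @param pattern,target [molecular_graph()] objects; `pattern` non-empty.
#' @return list of named character vectors (names: pattern atom ids sorted,
#'   values: matched target atom ids); empty list when no match exists.
#' @examples
#' gly <- build_scaffold("Gly")
#' ala <- build_scaffold("Ala")
#' length(find_subgraph_isomorphisms(gly, ala))
#' @export
find_subgraph_isomorphisms <- function(pattern, target) {
  stopifnot(inherits(pattern, "molecular_graph"),
            inherits(target, "molecular_graph"))
  np <- nrow(pattern$atoms)
  if (np == 0) stop("pattern graph is empty", call. = FALSE)
  if (np > nrow(target$atoms)) return(list())

  t_elem <- stats::setNames(target$atoms$element, target$atoms$atom_id)
  t_adj <- graph_adjacency(target)
  p_adj <- graph_adjacency(pattern)

  # candidate target atoms per pattern atom: same element, degree >= pattern
  t_deg <- lengths(t_adj)
  cand <- lapply(seq_len(np), function(i) {
    pid <- pattern$atoms$atom_id[i]
    ok <- target$atoms$atom_id[t_elem[target$atoms$atom_id] ==
                                 pattern$atoms$element[i] &
                                 t_deg[target$atoms$atom_id] >=
                                 length(p_adj[[pid]])]
    sort(ok)
  })
  names(cand) <- pattern$atoms$atom_id
  if (any(lengths(cand) == 0)) return(list())

  # order pattern atoms: most constrained first, then by connectivity to
  # already-placed atoms so that bond pruning bites early
  order_ids <- character(0)
  remaining <- pattern$atoms$atom_id
  while (length(remaining) > 0) {
    touching <- remaining[vapply(remaining, function(a) {
      any(p_adj[[a]] %in% order_ids)
    }, logical(1))]
    pool <- if (length(order_ids) == 0 || length(touching) == 0) {
      remaining
    } else {
      touching
    }
    nxt <- pool[order(lengths(cand[pool]), pool)][1]
    order_ids <- c(order_ids, nxt)
    remaining <- setdiff(remaining, nxt)
  }

  results <- list()
  assign_env <- new.env(parent = emptyenv())
  used <- character(0)
  assignment <- stats::setNames(rep(NA_character_, np), order_ids)

  recurse <- function(depth) {
    if (depth > np) {
      results[[length(results) + 1L]] <<- assignment
      return(invisible())
    }
    pid <- order_ids[depth]
    placed_nbrs <- intersect(p_adj[[pid]], order_ids[seq_len(depth - 1L)])
    for (tid in cand[[pid]]) {
      if (tid %in% used) next
      ok <- all(vapply(placed_nbrs, function(nb) {
        assignment[[nb]] %in% t_adj[[tid]]
      }, logical(1)))
      if (!ok) next
      assignment[[pid]] <<- tid
      used <<- c(used, tid)
      recurse(depth + 1L)
      used <<- setdiff(used, tid)
      assignment[[pid]] <<- NA_character_
    }
    invisible()
  }
  recurse(1L)

  if (length(results) == 0) return(list())
  key_ids <- sort(pattern$atoms$atom_id)
  results <- lapply(results, function(a) a[key_ids])
  keys <- vapply(results, function(a) paste(a, collapse = "\r"),
                 character(1))
  results <- results[!duplicated(keys)]
  results[order(keys[!duplicated(keys)])]
}

# Automorphism orbits of a graph: atoms equivalent under some automorphism
# share an orbit (e.g. valine CG1/CG2). Used by the synthetic generator and
# the parameter-recovery analysis.
graph_automorphism_orbits <- function(g) {
  autos <- find_subgraph_isomorphisms(g, g)
  ids <- sort(g$atoms$atom_id)
  orbit <- stats::setNames(ids, ids)
  for (a in autos) {
    for (i in seq_along(a)) {
      x <- names(a)[i]; y <- a[[i]]
      rx <- orbit[[x]]; ry <- orbit[[y]]
      if (rx != ry) orbit[orbit == ry] <- rx
    }
  }
  orbit
}

# Simple cycles (rings) of length 5 or 6 in a molecular graph, returned as a
# list of atom-id vectors. Graphs here are tiny, so a straightforward DFS is
# adequate. Used for pi-stacking validation and ring feature assignment.
graph_rings <- function(g, sizes = c(5L, 6L)) {
  adj <- graph_adjacency(g)
  ids <- g$atoms$atom_id
  found <- list()
  seen_keys <- character(0)
  walk <- function(path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb == path[1] && length(path) %in% sizes) {
        key <- paste(sort(path), collapse = "\r")
        if (!key %in% seen_keys) {
          seen_keys <<- c(seen_keys, key)
          found[[length(found) + 1L]] <<- path
        }
      } else if (!nb %in% path && length(path) < max(sizes) &&
                 nb > path[1]) {
        walk(c(path, nb))
      }
    }
  }
  for (start in ids) walk(start)
  found
}
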