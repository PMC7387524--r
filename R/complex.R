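#' Construct a structure complex
#'
#' A structure complex is one aaRS protein chain together with its
#' amino-acid-bearing ligand: the ligand's heavy-atom graph, the annotated
#' non-covalent interaction records, and metadata (reaction state, kingdom,
#' optional binding-cavity volume in A^3 and optional ligand atom
#' coordinates).
#'
#' @param structure_id PDB-style identifier plus chain, e.g. `"1f7u_A"`.
#' @param aars one of the 22 aaRS labels; determines the aaRS class.
#' @param ligand_graph a [molecular_graph()] of the full ligand.
#' @param interactions a data frame of interaction records, see
#'   [interaction_records()].
#' @param reaction_state `"pre_activation"` (free amino acid) or
#'   `"post_activation"` (aminoacyl-adenylate or analog).
#' @param kingdom `"bacteria"`, `"archaea"`, `"eukaryota"` or `"synthetic"`.
#' @param cavity_volume optional binding-cavity volume (A^3, > 0).
#' @param coordinates optional data frame `atom_id`, `x`, `y`, `z` (A).
#' @return a list of class `"structure_complex"`.
#' @export
structure_complex <- function(structure_id, aars, ligand_graph,
                              interactions = interaction_records(),
                              reaction_state = c("pre_activation",
                                                 "post_activation"),
                              kingdom = c("synthetic", "bacteria",
                                          "archaea", "eukaryota"),
                              cavity_volume = NA_real_,
                              coordinates = NULL) {
  reaction_state <- match.arg(reaction_state)
  kingdom <- match.arg(kingdom)
  stop_unknown_aars(aars)
  structure(
    list(structure_id = as.character(structure_id),
         aars = aars,
         aars_class = aars_class(aars),
         reaction_state = reaction_state,
         kingdom = kingdom,
         ligand_graph = ligand_graph,
         interactions = as_interaction_records(interactions),
         cavity_volume = as.numeric(cavity_volume),
         coordinates = if (is.null(coordinates)) NULL else
           tibble::as_tibble(coordinates)),
    class = "structure_complex")
}

#' Interaction record table
#'
#' One row per typed non-covalent contact between a protein residue (or a
#' metal ion) and one or more ligand atoms. For pi-stacking the
#' `ligand_atom_ids` entry holds all atoms of the aromatic ring. Water
#' bridges are kept on read but flagged `excluded` and left out of all
#' downstream statistics by default.
#'
#' @param itype interaction type code, see [interaction_types()].
#' @param protein_residue_type three-letter residue code, or a metal element
#'   label (e.g. `"ZN"`) when the protein-side partner is the ion itself.
#' @param protein_residue_number author residue number.
#' @param chain_id protein chain identifier.
#' @param ligand_atom_ids list of character vectors of ligand-graph atom ids.
#' @param midpoint optional list of numeric length-3 interaction midpoints.
#' @param excluded logical; defaults to `TRUE` for water bridges.
#' @return a tibble of class `"interaction_records"`.
#' @export
interaction_records <- function(itype = character(),
                                protein_residue_type = character(),
                                protein_residue_number = integer(),
                                chain_id = character(),
                                ligand_atom_ids = list(),
                                midpoint = NULL,
                                excluded = NULL) {
  n <- length(itype)
  if (is.null(excluded)) excluded <- itype == "water_bridge"
  if (is.null(midpoint)) midpoint <- rep(list(NULL), n)
  out <- tibble::tibble(
    itype = as.character(itype),
    protein_residue_type = as.character(protein_residue_type),
    protein_residue_number = as.integer(protein_residue_number),
    chain_id = as.character(chain_id),
    ligand_atom_ids = lapply(ligand_atom_ids, as.character),
    midpoint = midpoint,
    excluded = as.logical(excluded))
  class(out) <- c("interaction_records", class(out))
  out
}

as_interaction_records <- function(x) {
  if (inherits(x, "interaction_records")) return(x)
  x <- tibble::as_tibble(x)
  if (nrow(x) == 0) return(interaction_records())
  interaction_records(
    itype = x$itype,
    protein_residue_type = x$protein_residue_type,
    protein_residue_number = x$protein_residue_number,
    chain_id = if ("chain_id" %in% names(x)) x$chain_id else "A",
    ligand_atom_ids = x$ligand_atom_ids,
    midpoint = if ("midpoint" %in% names(x)) x$midpoint else NULL,
    excluded = if ("excluded" %in% names(x)) x$excluded else NULL)
}

#' @export
print.structure_complex <- function(x, ...) {
  cat("<structure_complex> ", x$structure_id, " (", x$aars, ", Class ",
      x$aars_class, ", ", x$reaction_state, ")\n", sep = "")
  cat("  ligand: ", nrow(x$ligand_graph$atoms), " atoms; interactions: ",
      nrow(x$interactions), "; cavity volume: ",
      ifelse(is.na(x$cavity_volume), "none",
             sprintf("%.1f A^3", x$cavity_volume)), "\n", sep = "")
  invisible(x)
}

#' Bind structure complexes into a tidy complex set
#'
#' The pipeline's central container is a tibble with one row per complex and
#' list-columns for the nested parts, so results chain with dplyr verbs.
#'
#' @param complexes list of [structure_complex()] objects (or a single one).
#' @return a tibble of class `"complex_set"` with columns `structure_id`,
#'   `aars`, `aars_class`, `reaction_state`, `kingdom`, `cavity_volume` and
#'   list-columns `ligand_graph`, `interactions`, `coordinates`.
#' @export
complex_set <- function(complexes) {
  if (inherits(complexes, "structure_complex")) complexes <- list(complexes)
  out <- tibble::tibble(
    structure_id = vapply(complexes, `[[`, character(1), "structure_id"),
    aars = vapply(complexes, `[[`, character(1), "aars"),
    aars_class = vapply(complexes, `[[`, character(1), "aars_class"),
    reaction_state = vapply(complexes, `[[`, character(1),
                            "reaction_state"),
    kingdom = vapply(complexes, `[[`, character(1), "kingdom"),
    cavity_volume = vapply(complexes, `[[`, numeric(1), "cavity_volume"),
    ligand_graph = lapply(complexes, `[[`, "ligand_graph"),
    interactions = lapply(complexes, `[[`, "interactions"),
    coordinates = lapply(complexes, `[[`, "coordinates"))
  class(out) <- c("complex_set", class(out))
  out
}

set_to_complexes <- function(x) {
  lapply(seq_len(nrow(x)), function(i) {
    structure(
      list(structure_id = x$structure_id[i],
           aars = x$aars[i],
           aars_class = x$aars_class[i],
           reaction_state = x$reaction_state[i],
           kingdom = x$kingdom[i],
           ligand_graph = x$ligand_graph[[i]],
           interactions = x$interactions[[i]],
           cavity_volume = x$cavity_volume[i],
           coordinates = x$coordinates[[i]]),
      class = "structure_complex")
  })
}

#' Validate a structure complex
#'
#' Checks every type invariant and returns human-readable violation
#' descriptions instead of raising: unknown vocabulary entries, interaction
#' atoms absent from the ligand graph, non-positive cavity volumes, and
#' pi-stacking records that do not reference all atoms of one aromatic ring
#' of the ligand.
#'
#' @param x a [structure_complex()] (or one row of a [complex_set()]).
#' @return character vector of violations; empty when all invariants hold.
#' @export
validate_complex <- function(x) {
  if (inherits(x, "complex_set")) x <- set_to_complexes(x)[[1]]
  v <- character(0)
  if (!x$aars %in% aars_labels()) {
    v <- c(v, paste0("aars: unknown label '", x$aars, "'"))
  } else if (x$aars_class != aars_class(x$aars)) {
    v <- c(v, paste0("aars_class: '", x$aars_class,
                     "' inconsistent with aars '", x$aars, "'"))
  }
  if (!x$reaction_state %in% c("pre_activation", "post_activation")) {
    v <- c(v, paste0("reaction_state: unknown value '", x$reaction_state,
                     "'"))
  }
  if (!is.na(x$cavity_volume) && x$cavity_volume <= 0) {
    v <- c(v, paste0("cavity_volume: must be > 0, got ", x$cavity_volume))
  }
  lig_atoms <- x$ligand_graph$atoms$atom_id
  rings <- NULL
  for (i in seq_len(nrow(x$interactions))) {
    rec <- x$interactions[i, ]
    if (!rec$itype %in% interaction_types()) {
      v <- c(v, paste0("interactions[", i, "].itype: unknown type '",
                       rec$itype, "'"))
      next
    }
    ids <- rec$ligand_atom_ids[[1]]
    if (length(ids) == 0) {
      v <- c(v, paste0("interactions[", i,
                       "].ligand_atom_ids: must be non-empty"))
      next
    }
    outside <- setdiff(ids, lig_atoms)
    if (length(outside) > 0) {
      v <- c(v, paste0("interactions[", i, "].ligand_atom_ids: not in ",
                       "ligand graph: ", paste(outside, collapse = ", ")))
      next
    }
    if (rec$itype == "pi_stacking") {
      if (is.null(rings)) rings <- graph_rings(x$ligand_graph)
      ok <- any(vapply(rings, function(r) setequal(r, ids), logical(1)))
      if (!ok) {
        v <- c(v, paste0("interactions[", i, "].ligand_atom_ids: ",
                         "pi_stacking must reference all atoms of one ",
                         "aromatic ring of the ligand"))
      }
    }
  }
  v
}
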