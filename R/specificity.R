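#' Restrict interactions to the specificity-conferring amino-acid
#' substructure
#'
#' Matches the aaRS's amino-acid scaffold (see [build_scaffold()]) against
#' each complex's full ligand graph by subgraph isomorphism and annotates
#' every interaction record with the scaffold atoms it touches. Ligand atoms
#' are mapped to the UNION of scaffold atoms over all isomorphisms, so a
#' contact on one of two symmetric atoms (e.g. a valine gamma-methyl) is
#' assigned to both -- ambiguous isomorphism never discards information.
#' Records touching only non-substructure atoms (the adenosine/phosphate
#' moiety, the free carboxyl hydroxyl) are dropped: only interactions with
#' the amino-acid substructure confer specificity.
#'
#' @param complexes a [complex_set()].
#' @return the same tibble with each `interactions` table gaining a
#'   `scaffold_atoms` list-column and non-substructure records removed.
#'   A complex whose ligand graph does not contain its scaffold at all is an
#'   error (wrong ligand or corrupt graph).
#' @export
assign_specificity_interactions <- function(complexes) {
  stopifnot(inherits(complexes, "complex_set"))
  iso_cache <- new.env(parent = emptyenv())
  complexes$interactions <- purrr::map(
    seq_len(nrow(complexes)),
    function(i) {
      aars <- complexes$aars[i]
      lig <- complexes$ligand_graph[[i]]
      scaffold <- build_scaffold(aars_ligand(aars))
      key <- paste0(aars, "\r", graph_signature(lig))
      isos <- iso_cache[[key]]
      if (is.null(isos)) {
        isos <- find_subgraph_isomorphisms(scaffold, lig)
        iso_cache[[key]] <- isos
      }
      if (length(isos) == 0) {
        stop("no scaffold isomorphism for complex '",
             complexes$structure_id[i], "' (", aars,
             "): wrong ligand or corrupt graph", call. = FALSE)
      }
      # ligand atom id -> union of scaffold atom ids over all isomorphisms
      lig2scaf <- list()
      for (iso in isos) {
        for (j in seq_along(iso)) {
          lig2scaf[[iso[[j]]]] <- union(lig2scaf[[iso[[j]]]], names(iso)[j])
        }
      }
      rec <- complexes$interactions[[i]]
      rec$scaffold_atoms <- lapply(rec$ligand_atom_ids, function(ids) {
        sort(unique(unlist(lig2scaf[intersect(ids, names(lig2scaf))],
                           use.names = FALSE)))
      })
      rec[lengths(rec$scaffold_atoms) > 0, ]
    })
  attr(complexes, "specificity_assigned") <- TRUE
  complexes
}

graph_signature <- function(g) {
  paste(c(paste(g$atoms$atom_id, g$atoms$element, sep = ":"),
          paste(g$bonds$from, g$bonds$to, sep = "-")), collapse = ";")
}

assert_assigned <- function(complexes, what) {
  ok <- nrow(complexes) == 0 ||
    all(vapply(complexes$interactions, function(r) {
      "scaffold_atoms" %in% names(r)
    }, logical(1)))
  if (!ok) {
    stop(what, " requires specificity-assigned interactions; run ",
         "assign_specificity_interactions() first", call. = FALSE)
  }
  invisible(complexes)
}

# Interactions entering statistics: specificity-assigned, not excluded
# (water bridges are excluded by default).
active_interactions <- function(rec) {
  rec[!rec$excluded & rec$itype %in% table_interaction_types(), ,
      drop = FALSE]
}
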