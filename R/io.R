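#' Read a PLIP XML report
#'
#' Parses the interaction subset of a PLIP report (the rule-based
#' protein-ligand interaction profiler): hydrogen bonds, hydrophobic
#' interactions, salt bridges, pi-stacks, metal complexes and water bridges.
#' Water-bridge records are kept but flagged `excluded`. Unknown interaction
#' elements (e.g. halogen bonds) are skipped with a warning, as are contacts
#' without ligand atom serials. Residue numbering is taken verbatim
#' ("author" numbering); no renumbering happens at read time.
#'
#' @param path path to a PLIP XML report.
#' @param atom_map optional named character vector translating ligand atom
#'   serials to ligand-graph atom ids; unmapped serials are kept as-is.
#' @return an [interaction_records()] tibble.
#' @export
read_plip_report <- function(path, atom_map = NULL) {
  doc <- xml2::read_xml(path)
  known <- c(hydrogen_bond = "hydrogen_bond",
             hydrophobic_interaction = "hydrophobic",
             salt_bridge = "salt_bridge",
             pi_stack = "pi_stacking",
             pi_cation_interaction = "pi_cation",
             metal_complex = "metal_complex",
             water_bridge = "water_bridge")
  contacts <- xml2::xml_find_all(
    doc, "//bindingsite//interactions/*/*")
  rows <- list()
  skipped <- character(0)
  for (node in contacts) {
    tag <- xml2::xml_name(node)
    if (!tag %in% names(known)) {
      skipped <- union(skipped, tag)
      next
    }
    itype <- known[[tag]]
    txt <- function(sel) xml2::xml_text(xml2::xml_find_first(node, sel))
    restype <- txt("restype")
    resnr <- suppressWarnings(as.integer(txt("resnr")))
    chain <- txt("reschain")
    serials <- plip_ligand_serials(node, tag)
    if (length(serials) == 0 || all(is.na(serials))) {
      warning("skipping ", tag, " record without ligand atom serial(s) in ",
              basename(path), call. = FALSE)
      next
    }
    if (itype == "metal_complex") {
      metal <- txt("metal_type")
      if (!is.na(metal) && nzchar(metal)) restype <- toupper(metal)
    }
    ids <- as.character(serials)
    if (!is.null(atom_map)) {
      hit <- !is.na(atom_map[ids])
      ids[hit] <- atom_map[ids[hit]]
    }
    rows[[length(rows) + 1L]] <- list(
      itype = itype, protein_residue_type = restype,
      protein_residue_number = resnr, chain_id = chain,
      ligand_atom_ids = ids)
  }
  if (length(skipped) > 0) {
    warning("unknown interaction element(s) skipped: ",
            paste(skipped, collapse = ", "), call. = FALSE)
  }
  if (length(rows) == 0) return(interaction_records())
  interaction_records(
    itype = vapply(rows, `[[`, character(1), "itype"),
    protein_residue_type = vapply(rows, `[[`, character(1),
                                  "protein_residue_type"),
    protein_residue_number = vapply(rows, `[[`, integer(1),
                                    "protein_residue_number"),
    chain_id = vapply(rows, `[[`, character(1), "chain_id"),
    ligand_atom_ids = lapply(rows, `[[`, "ligand_atom_ids"))
}

plip_ligand_serials <- function(node, tag) {
  txt <- function(sel) xml2::xml_text(xml2::xml_find_first(node, sel))
  if (tag == "hydrogen_bond" || tag == "water_bridge") {
    protisdon <- tolower(txt("protisdon")) %in% c("true", "1")
    don <- txt("donoridx"); acc <- txt("acceptoridx")
    if (is.na(don)) don <- txt("donor_idx")
    if (is.na(acc)) acc <- txt("acceptor_idx")
    out <- if (protisdon) acc else don
    out[!is.na(out) & nzchar(out)]
  } else if (tag == "hydrophobic_interaction") {
    out <- txt("ligcarbonidx")
    out[!is.na(out) & nzchar(out)]
  } else if (tag %in% c("salt_bridge", "pi_stack",
                        "pi_cation_interaction")) {
    xml2::xml_text(xml2::xml_find_all(node, "lig_idx_list/idx"))
  } else if (tag == "metal_complex") {
    out <- txt("target_idx")
    out[!is.na(out) & nzchar(out)]
  } else {
    character(0)
  }
}

#' Read a multiple sequence alignment from FASTA
#'
#' All sequences must have equal (gapped) width; the gap character is `-`.
#'
#' @param path FASTA file.
#' @return named character vector of aligned rows, with attribute `width`.
#' @export
read_msa <- function(path) {
  seqs <- Biostrings::readAAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in ", path, call. = FALSE)
  widths <- Biostrings::width(seqs)
  if (length(unique(widths)) != 1) {
    bad <- names(seqs)[widths != widths[1]][1]
    stop("ragged alignment: sequence '", bad, "' has width ",
         widths[widths != widths[1]][1], ", expected ", widths[1],
         call. = FALSE)
  }
  out <- stats::setNames(as.character(seqs), names(seqs))
  attr(out, "width") <- widths[1]
  out
}

#' Read ligand atom coordinates
#'
#' From a PDB file (via bio3d, selecting a ligand residue by name) or from
#' a plain coordinate table with columns `atom_id`, `x`, `y`, `z`.
#' Duplicate atom ids resolve last-wins with a warning.
#'
#' @param path PDB (`.pdb`/`.ent`) or CSV table.
#' @param ligand_resname residue name of the ligand in a PDB file.
#' @return tibble `atom_id`, `x`, `y`, `z` (A).
#' @export
read_coordinates <- function(path, ligand_resname = NULL) {
  if (grepl("\\.(pdb|ent)$", path, ignore.case = TRUE)) {
    if (!requireNamespace("bio3d", quietly = TRUE)) {
      stop("reading PDB files requires the bio3d package", call. = FALSE)
    }
    pdb <- bio3d::read.pdb(path)
    at <- pdb$atom
    if (!is.null(ligand_resname)) {
      at <- at[at$resid == ligand_resname, , drop = FALSE]
      if (nrow(at) == 0) {
        stop("ligand '", ligand_resname, "' not found in ", path,
             call. = FALSE)
      }
    }
    out <- tibble::tibble(atom_id = trimws(at$elety),
                          x = at$x, y = at$y, z = at$z)
  } else {
    tab <- utils::read.csv(path)
    need <- c("atom_id", "x", "y", "z")
    if (!all(need %in% names(tab))) {
      stop("coordinate table needs columns: ",
           paste(need, collapse = ", "), call. = FALSE)
    }
    out <- tibble::as_tibble(tab[, need])
    out$atom_id <- as.character(out$atom_id)
  }
  if (anyDuplicated(out$atom_id)) {
    warning("duplicate atom id(s): ",
            paste(unique(out$atom_id[duplicated(out$atom_id)]),
                  collapse = ", "), "; last occurrence wins",
            call. = FALSE)
    out <- out[!duplicated(out$atom_id, fromLast = TRUE), ]
  }
  out
}

#' Write / read complex sets in the package's JSON format
#'
#' The internal tabular format serializes every field of every complex
#' (metadata, ligand graph, interaction records, coordinates); a write
#' followed by a read is the identity.
#'
#' @param complexes a [complex_set()].
#' @param path JSON file path.
#' @return `write_complexes()`: `path`, invisibly; `read_complexes()`: a
#'   [complex_set()].
#' @export
write_complexes <- function(complexes, path) {
  stopifnot(inherits(complexes, "complex_set"))
  objs <- set_to_complexes(complexes)
  payload <- lapply(objs, function(cx) {
    rec <- cx$interactions
    list(
      structure_id = cx$structure_id,
      aars = cx$aars,
      reaction_state = cx$reaction_state,
      kingdom = cx$kingdom,
      cavity_volume = cx$cavity_volume,
      ligand_graph = list(
        atoms = as.data.frame(cx$ligand_graph$atoms),
        bonds = as.data.frame(cx$ligand_graph$bonds)),
      interactions = list(
        itype = rec$itype,
        protein_residue_type = rec$protein_residue_type,
        protein_residue_number = rec$protein_residue_number,
        chain_id = rec$chain_id,
        ligand_atom_ids = rec$ligand_atom_ids,
        midpoint = rec$midpoint,
        excluded = rec$excluded),
      coordinates = if (is.null(cx$coordinates)) NULL else
        as.data.frame(cx$coordinates))
  })
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_complexes
#' @export
read_complexes <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = FALSE)
  objs <- lapply(payload, function(p) {
    atoms <- dplyr::bind_rows(lapply(p$ligand_graph$atoms, tibble::as_tibble))
    bonds <- if (length(p$ligand_graph$bonds) == 0) {
      tibble::tibble(from = character(), to = character())
    } else {
      dplyr::bind_rows(lapply(p$ligand_graph$bonds, tibble::as_tibble))
    }
    ints <- p$interactions
    n <- length(ints$itype)
    rec <- interaction_records(
      itype = unlist(ints$itype),
      protein_residue_type = unlist(ints$protein_residue_type),
      protein_residue_number = unlist(ints$protein_residue_number),
      chain_id = unlist(ints$chain_id),
      ligand_atom_ids = lapply(ints$ligand_atom_ids, unlist),
      midpoint = if (is.null(ints$midpoint)) NULL else
        lapply(ints$midpoint, function(m) {
          if (is.null(m)) NULL else as.numeric(unlist(m))
        }),
      excluded = unlist(ints$excluded))
    if (n == 0) rec <- interaction_records()
    structure_complex(
      structure_id = p$structure_id,
      aars = p$aars,
      reaction_state = p$reaction_state,
      kingdom = p$kingdom,
      ligand_graph = molecular_graph(atoms, bonds),
      interactions = rec,
      cavity_volume = if (is.null(p$cavity_volume)) NA_real_ else
        p$cavity_volume,
      coordinates = if (is.null(p$coordinates)) NULL else
        dplyr::bind_rows(lapply(p$coordinates, tibble::as_tibble)))
  })
  complex_set(objs)
}

#' Export an occupancy profile or frequency table as CSV
#'
#' @param x an `occupancy_profile` or `class_frequency_table`.
#' @param path output path (`.csv`, or `.json` for occupancy profiles).
#' @return `path`, invisibly.
#' @export
export_table <- function(x, path) {
  if (grepl("\\.json$", path) && inherits(x, "occupancy_profile")) {
    jsonlite::write_json(
      list(aars = attr(x, "aars"), n_structures = attr(x, "n_structures"),
           entries = as.data.frame(x)),
      path, auto_unbox = TRUE, digits = NA)
  } else {
    utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  }
  invisible(path)
}
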