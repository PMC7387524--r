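#' Generator specification for synthetic aaRS complexes
#'
#' The synthetic generator emulates the statistical structure of a
#' crystallographic aaRS dataset: per-aaRS interaction templates (each
#' scaffold atom contact realized independently with its occupancy
#' probability, residue types drawn from a per-entry distribution),
#' class-dependent binding-cavity volumes (truncated normal), a small rate
#' of spurious off-template interactions, and a pre-/post-activation
#' reaction-state mix. The default spec encodes the qualitative recognition
#' structure reported for crystallographic aaRS surveys: high-probability backbone-amine
#' hydrogen bonds in both classes (0.85 Class I / 0.92 Class II),
#' hydrophobic side-chain contacts skewed to Class I, hydrogen bonds and
#' salt bridges skewed to Class II, pi-stacking only for the aromatic-ligand
#' handlers (PheRS, TyrRS, TrpRS), zinc complexes for CysRS/ThrRS/SerRS,
#' and volumes Normal(143.40, 39.62^2) for Class I versus
#' Normal(90.36, 32.09^2) for Class II (A^3, truncated at 10 A^3).
#'
#' Templates are declarative data (JSON), not code; point
#' `read_generator_spec()` at your own file to re-parameterize.
#'
#' @param path JSON generator spec.
#' @return a `generator_spec` list: `templates`, `volume_model`,
#'   `noise_rate`, `pre_activation_fraction`.
#' @export
read_generator_spec <- function(path) {
  spec <- jsonlite::read_json(path, simplifyVector = FALSE)
  for (a in names(spec$templates)) {
    stop_unknown_aars(a)
    for (e in spec$templates[[a]]$entries) {
      if (e$p < 0 || e$p > 1) {
        stop("template probability out of [0,1] for ", a, call. = FALSE)
      }
      scaffold <- build_scaffold(aars_ligand(a))
      bad <- setdiff(unlist(e$atoms), scaffold$atoms$atom_id)
      if (length(bad) > 0) {
        stop("template atom(s) not in ", a, " scaffold: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
    }
  }
  for (cl in c("I", "II")) {
    if (spec$volume_model[[cl]]$sd <= 0) {
      stop("volume model sd must be > 0", call. = FALSE)
    }
  }
  structure(spec, class = "generator_spec")
}

#' @rdname read_generator_spec
#' @export
default_spec <- function() {
  read_generator_spec(system.file("extdata", "default_generator_spec.json",
                                  package = "aarsfp", mustWork = TRUE))
}

#' Generate synthetic structure complexes
#'
#' Draws `n_per_aars` complexes for every aaRS in the spec's templates.
#' Each template entry is realized as an interaction record with its
#' occupancy probability; the residue type is sampled from the entry's
#' distribution. With probability `noise_rate` a complex additionally gains
#' one spurious record with a uniformly random (ligand atom, type, residue)
#' triple -- exercising the occupancy-cutoff filtering downstream. Ligands
#' are the amino-acid scaffold plus the free carboxyl hydroxyl
#' (pre-activation) or a truncated adenylate stub (post-activation), so the
#' specificity-assignment stage has real matching work to do. Fully
#' reproducible for a fixed seed.
#'
#' @param spec a `generator_spec` (default [default_spec()]).
#' @param n_per_aars complexes per aaRS (>= 1).
#' @param seed integer seed.
#' @return a [complex_set()] with `n_per_aars * length(templates)` rows.
#' @export
generate_complexes <- function(spec = default_spec(), n_per_aars = 20,
                               seed = 42L) {
  stopifnot(inherits(spec, "generator_spec"), n_per_aars >= 1)
  set.seed(as.integer(seed))
  out <- list()
  for (a in names(spec$templates)) {
    lig <- aars_ligand(a)
    cls <- aars_class(a)
    vm <- spec$volume_model[[cls]]
    entries <- spec$templates[[a]]$entries
    for (i in seq_len(n_per_aars)) {
      state <- if (stats::runif(1) < spec$pre_activation_fraction) {
        "pre_activation"
      } else {
        "post_activation"
      }
      graph <- synthetic_ligand_graph(lig, state)
      recs <- list()
      for (e in entries) {
        if (stats::runif(1) > e$p) next
        res_names <- names(e$residues)
        res <- sample(res_names, 1,
                      prob = unlist(e$residues, use.names = FALSE))
        recs[[length(recs) + 1L]] <- list(
          itype = e$itype, protein_residue_type = res,
          protein_residue_number = as.integer(e$resnr),
          ligand_atom_ids = unlist(e$atoms))
      }
      if (stats::runif(1) < spec$noise_rate) {
        atom <- sample(graph$atoms$atom_id, 1)
        recs[[length(recs) + 1L]] <- list(
          itype = sample(setdiff(table_interaction_types(), "pi_stacking"),
                         1),
          protein_residue_type = sample(standard_residues(), 1),
          protein_residue_number = 700L + sample.int(50L, 1),
          ligand_atom_ids = atom)
      }
      rec <- if (length(recs) == 0) interaction_records() else
        interaction_records(
          itype = vapply(recs, `[[`, character(1), "itype"),
          protein_residue_type = vapply(recs, `[[`, character(1),
                                        "protein_residue_type"),
          protein_residue_number = vapply(recs, `[[`, integer(1),
                                          "protein_residue_number"),
          chain_id = "A",
          ligand_atom_ids = lapply(recs, `[[`, "ligand_atom_ids"))
      vol <- rtrunc_normal(1, vm$mean, vm$sd,
                           spec$volume_model$floor %||% 10)
      out[[length(out) + 1L]] <- structure_complex(
        structure_id = sprintf("SYN-%s-%03d_A", a, i),
        aars = a, ligand_graph = graph, interactions = rec,
        reaction_state = state, kingdom = "synthetic",
        cavity_volume = vol)
    }
  }
  complex_set(out)
}

# scaffold + carboxyl hydroxyl (pre) or truncated adenylate stub (post)
synthetic_ligand_graph <- function(ligand_code, reaction_state) {
  g <- build_scaffold(ligand_code)
  if (reaction_state == "pre_activation") {
    extra_atoms <- tibble::tibble(atom_id = "OXT", element = "O",
                                  name = "OXT", role = "other")
    extra_bonds <- tibble::tibble(from = "C", to = "OXT")
  } else {
    extra_atoms <- tibble::tibble(
      atom_id = c("O3A", "PA", "O1A", "O2A", "O5'", "C5'", "C4'"),
      element = c("O", "P", "O", "O", "O", "C", "C"),
      name = c("O3A", "PA", "O1A", "O2A", "O5'", "C5'", "C4'"),
      role = "other")
    extra_bonds <- tibble::tibble(
      from = c("C", "O3A", "PA", "PA", "PA", "O5'", "C5'"),
      to = c("O3A", "PA", "O1A", "O2A", "O5'", "C5'", "C4'"))
  }
  molecular_graph(atoms = dplyr::bind_rows(g$atoms, extra_atoms),
                  bonds = dplyr::bind_rows(g$bonds, extra_bonds))
}

rtrunc_normal <- function(n, mean, sd, floor) {
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(n - length(out), mean, sd)
    out <- c(out, draw[draw > floor])
  }
  out
}

#' Build a toy post-activation ligand with a prescribed torsion
#'
#' Constructs coordinates for the default torsion quadruple
#' (O5'-P-O3A-C, see [torsion_spec()]) with the given dihedral angle, using
#' internal-coordinate (NeRF) placement. Intended for validating torsion
#' recovery; not a physical conformer.
#'
#' @param angle dihedral in degrees.
#' @param aars aaRS label for the carrier complex.
#' @param mirror reflect the coordinates (flips the torsion sign).
#' @return a [structure_complex()] in post-activation state with a
#'   `coordinates` table covering the quadruple.
#' @export
simulate_torsion_ligand <- function(angle, aars = "AlaRS",
                                    mirror = FALSE) {
  p1 <- c(0, 0, 0)                       # O5'
  p2 <- c(1.6, 0, 0)                     # PA
  theta <- (180 - 109.5) * pi / 180
  p3 <- p2 + 1.6 * c(cos(theta), sin(theta), 0)   # O3A
  p4 <- place_by_torsion(p1, p2, p3, 1.4, 109.5, angle)  # C
  co <- tibble::tibble(
    atom_id = c("O5'", "PA", "O3A", "C"),
    x = c(p1[1], p2[1], p3[1], p4[1]),
    y = c(p1[2], p2[2], p3[2], p4[2]),
    z = c(p1[3], p2[3], p3[3], p4[3]))
  if (mirror) co$z <- -co$z
  structure_complex(
    structure_id = sprintf("TOY-%s-torsion", aars),
    aars = aars,
    ligand_graph = synthetic_ligand_graph(aars_ligand(aars),
                                          "post_activation"),
    reaction_state = "post_activation",
    coordinates = co)
}

# natural-extension reference frame placement of a fourth atom, calibrated
# so the recovered dihedral() equals the requested torsion
place_by_torsion <- function(a, b, c_, bond, bond_angle, torsion) {
  ang <- bond_angle * pi / 180
  tor <- torsion * pi / 180
  d2 <- c(-bond * cos(ang), bond * cos(tor) * sin(ang),
          bond * sin(tor) * sin(ang))
  bc <- (c_ - b) / sqrt(sum((c_ - b)^2))
  n <- cross3(b - a, bc)
  n <- n / sqrt(sum(n^2))
  m <- cbind(bc, cross3(n, bc), n)
  as.numeric(m %*% d2 + c_)
}

#' Write interaction records as a PLIP-style XML report
#'
#' Emits the subset of the PLIP report schema that [read_plip_report()]
#' consumes; useful for round-trip testing of the reader against generated
#' data.
#'
#' @param records an [interaction_records()] tibble.
#' @param path output XML file.
#' @return `path`, invisibly.
#' @export
write_plip_xml <- function(records, path) {
  tagmap <- c(hydrogen_bond = "hydrogen_bond",
              hydrophobic = "hydrophobic_interaction",
              salt_bridge = "salt_bridge",
              pi_stacking = "pi_stack",
              pi_cation = "pi_cation_interaction",
              metal_complex = "metal_complex",
              water_bridge = "water_bridge")
  doc <- xml2::xml_new_root("report")
  bs <- xml2::xml_add_child(doc, "bindingsite")
  ints <- xml2::xml_add_child(bs, "interactions")
  groups <- list()
  for (i in seq_len(nrow(records))) {
    tag <- tagmap[[records$itype[i]]]
    parent_name <- paste0(tag, "s")
    if (is.null(groups[[parent_name]])) {
      groups[[parent_name]] <- xml2::xml_add_child(ints, parent_name)
    }
    node <- xml2::xml_add_child(groups[[parent_name]], tag)
    xml2::xml_add_child(node, "restype",
                        records$protein_residue_type[i])
    xml2::xml_add_child(node, "resnr",
                        as.character(records$protein_residue_number[i]))
    xml2::xml_add_child(node, "reschain", records$chain_id[i])
    ids <- records$ligand_atom_ids[[i]]
    if (tag %in% c("hydrogen_bond", "water_bridge")) {
      xml2::xml_add_child(node, "protisdon", "True")
      xml2::xml_add_child(node, "acceptoridx", ids[1])
      xml2::xml_add_child(node, "donoridx", "0")
    } else if (tag == "hydrophobic_interaction") {
      xml2::xml_add_child(node, "ligcarbonidx", ids[1])
    } else if (tag == "metal_complex") {
      xml2::xml_add_child(node, "metal_type",
                          records$protein_residue_type[i])
      xml2::xml_add_child(node, "target_idx", ids[1])
    } else {
      lst <- xml2::xml_add_child(node, "lig_idx_list")
      for (id in ids) xml2::xml_add_child(lst, "idx", id)
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
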