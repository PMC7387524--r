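#' Per-atom interaction occupancy profile of one aaRS
#'
#' For each (scaffold atom, interaction type) pair, the occupancy is the
#' fraction of the aaRS's structures in which that contact occurs. An
#' interaction is counted at most once per structure per (atom, type) pair,
#' so duplicate records within a structure do not inflate the profile.
#' Entries with occupancy below the cutoff are neglected (the default 0.1
#' keeps an entry observed in exactly 10% of structures).
#'
#' @param complexes a specificity-assigned [complex_set()] for a single
#'   aaRS (mixed labels are an error).
#' @param cutoff minimum occupancy retained; default from
#'   [analysis_config()].
#' @return a tibble of class `"occupancy_profile"` with columns
#'   `scaffold_atom`, `itype`, `n_present`, `occupancy`, plus attributes
#'   `aars` and `n_structures`.
#' @export
compute_occupancy <- function(complexes,
                              cutoff = analysis_config()$occupancy_cutoff) {
  stopifnot(inherits(complexes, "complex_set"), nrow(complexes) >= 1)
  assert_assigned(complexes, "compute_occupancy()")
  aars <- unique(complexes$aars)
  if (length(aars) != 1) {
    stop("compute_occupancy() expects complexes of a single aaRS, got: ",
         paste(aars, collapse = ", "), call. = FALSE)
  }
  n <- nrow(complexes)
  per_structure <- purrr::map_dfr(seq_len(n), function(i) {
    rec <- active_interactions(complexes$interactions[[i]])
    if (nrow(rec) == 0) return(tibble::tibble())
    tidyr::unnest(
      tibble::tibble(itype = rec$itype,
                     scaffold_atom = rec$scaffold_atoms),
      "scaffold_atom") |>
      dplyr::distinct() |>
      dplyr::mutate(structure_id = complexes$structure_id[i])
  })
  prof <- if (nrow(per_structure) == 0) {
    tibble::tibble(scaffold_atom = character(), itype = character(),
                   n_present = integer(), occupancy = numeric())
  } else {
    per_structure |>
      dplyr::count(.data$scaffold_atom, .data$itype, name = "n_present") |>
      dplyr::mutate(occupancy = .data$n_present / n) |>
      dplyr::filter(.data$occupancy >= cutoff) |>
      dplyr::arrange(.data$scaffold_atom, .data$itype)
  }
  attr(prof, "aars") <- aars
  attr(prof, "n_structures") <- n
  attr(prof, "cutoff") <- cutoff
  class(prof) <- c("occupancy_profile", class(prof))
  prof
}

# Round half away from zero to `digits` decimals (printed-table convention;
# base round() is round-half-even).
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Class-level interaction frequency table
#'
#' Counts every specificity-conferring interaction record (water bridges and
#' pi-cation records excluded) per aaRS class and interaction type, with
#' relative frequencies in percent of the class total. Unlike occupancy
#' profiles, which count structures, this table counts interaction records.
#' Percentages are rounded half-up to 2 decimals.
#'
#' @param complexes a specificity-assigned [complex_set()] containing at
#'   least one complex per class present.
#' @return tibble of class `"class_frequency_table"`: `aars_class`, `itype`,
#'   `count`, `percent`, plus per-class `total` rows accessible via
#'   `attr(, "totals")`.
#' @export
class_frequency_table <- function(complexes) {
  stopifnot(inherits(complexes, "complex_set"))
  assert_assigned(complexes, "class_frequency_table()")
  counts <- purrr::map_dfr(seq_len(nrow(complexes)), function(i) {
    rec <- active_interactions(complexes$interactions[[i]])
    tibble::tibble(aars_class = complexes$aars_class[i], itype = rec$itype)
  }) |>
    dplyr::count(.data$aars_class, .data$itype, name = "count")
  full <- tidyr::expand_grid(aars_class = sort(unique(counts$aars_class)),
                             itype = table_interaction_types()) |>
    dplyr::left_join(counts, by = c("aars_class", "itype")) |>
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) |>
    dplyr::group_by(.data$aars_class) |>
    dplyr::mutate(percent = interaction_percentages(.data$count)) |>
    dplyr::ungroup()
  totals <- full |>
    dplyr::group_by(.data$aars_class) |>
    dplyr::summarise(total = sum(.data$count), .groups = "drop")
  attr(full, "totals") <- totals
  class(full) <- c("class_frequency_table", class(full))
  full
}

#' Relative interaction frequencies from raw counts
#'
#' Converts per-type interaction counts into percentages of their total,
#' rounded half-up to 2 decimals, as printed in class-level summary tables.
#'
#' @param counts non-negative integer vector.
#' @return numeric vector of percentages (sums to 100 up to rounding slack).
#' @examples
#' interaction_percentages(c(468, 550, 153, 59, 3))
#' @export
interaction_percentages <- function(counts) {
  stopifnot(all(counts >= 0))
  if (sum(counts) == 0) return(rep(NA_real_, length(counts)))
  round_half_up(100 * counts / sum(counts), 2)
}

#' Side-chain recognition summary
#'
#' Per-aaRS list of the binding-site residues that contact side-chain atoms
#' of the amino-acid ligand, with residue positions unified to MSA numbering
#' where a renumbering map is available. Backbone-atom contacts are
#' excluded. Entries whose structure lacks a renumbering map keep the
#' original author numbering and are flagged (`msa_mapped = FALSE`, with a
#' warning).
#'
#' @param complexes a specificity-assigned [complex_set()].
#' @param renumber_maps named list (by `structure_id`) of [msa_renumber()]
#'   maps; may be missing entries.
#' @param min_occupancy drop (atom, type) contacts below this occupancy
#'   within their aaRS; default 0 keeps everything.
#' @return tibble: `aars`, `position`, `msa_mapped`, `residue_type`,
#'   `itype`, `n_structures` (support).
#' @export
summarize_side_chain_recognition <- function(complexes,
                                             renumber_maps = list(),
                                             min_occupancy = 0) {
  stopifnot(inherits(complexes, "complex_set"))
  assert_assigned(complexes, "summarize_side_chain_recognition()")
  rows <- purrr::map_dfr(seq_len(nrow(complexes)), function(i) {
    rec <- active_interactions(complexes$interactions[[i]])
    if (nrow(rec) == 0) return(tibble::tibble())
    scaffold <- build_scaffold(aars_ligand(complexes$aars[i]))
    side <- scaffold$atoms$atom_id[scaffold$atoms$role == "side_chain"]
    keep <- vapply(rec$scaffold_atoms, function(a) any(a %in% side),
                   logical(1))
    rec <- rec[keep, , drop = FALSE]
    if (nrow(rec) == 0) return(tibble::tibble())
    tibble::tibble(aars = complexes$aars[i],
                   structure_id = complexes$structure_id[i],
                   residue_type = rec$protein_residue_type,
                   residue_number = rec$protein_residue_number,
                   itype = rec$itype,
                   scaffold_atoms = rec$scaffold_atoms)
  })
  if (nrow(rows) == 0) {
    return(tibble::tibble(aars = character(), position = integer(),
                          msa_mapped = logical(), residue_type = character(),
                          itype = character(), n_structures = integer()))
  }
  if (min_occupancy > 0) {
    occ <- purrr::map_dfr(split(seq_len(nrow(complexes)), complexes$aars),
                          function(idx) {
      p <- compute_occupancy(complexes[idx, ], cutoff = min_occupancy)
      tibble::tibble(aars = attr(p, "aars"), scaffold_atom = p$scaffold_atom,
                     itype = p$itype)
    })
    keep <- vapply(seq_len(nrow(rows)), function(j) {
      any(occ$aars == rows$aars[j] & occ$itype == rows$itype[j] &
            occ$scaffold_atom %in% rows$scaffold_atoms[[j]])
    }, logical(1))
    rows <- rows[keep, , drop = FALSE]
  }
  unmapped <- character(0)
  pos <- purrr::map2(rows$structure_id, rows$residue_number, function(s, r) {
    m <- renumber_maps[[s]]
    if (is.null(m)) {
      unmapped <<- union(unmapped, s)
      list(position = r, mapped = FALSE)
    } else {
      hit <- m$msa_position[match(r, m$author_number)]
      if (is.na(hit)) list(position = r, mapped = FALSE)
      else list(position = hit, mapped = TRUE)
    }
  })
  if (length(unmapped) > 0) {
    warning("no renumbering map for structure(s): ",
            paste(unmapped, collapse = ", "),
            "; original numbering kept and flagged", call. = FALSE)
  }
  rows$position <- vapply(pos, function(p) as.integer(p$position),
                          integer(1))
  rows$msa_mapped <- vapply(pos, function(p) p$mapped, logical(1))
  rows |>
    dplyr::distinct(.data$aars, .data$position, .data$msa_mapped,
                    .data$residue_type, .data$itype,
                    .data$structure_id) |>
    dplyr::count(.data$aars, .data$position, .data$msa_mapped,
                 .data$residue_type, .data$itype,
                 name = "n_structures") |>
    dplyr::arrange(.data$aars, .data$position)
}

#' Correlation of interacting-residue count with ligand size
#'
#' Pearson correlation between the per-aaRS mean number of distinct
#' interacting binding-site residues and the heavy-atom count of the
#' amino-acid ligand substructure.
#'
#' @param complexes a specificity-assigned [complex_set()] spanning at
#'   least 3 aaRSs.
#' @return tibble with one row: `r`, `p_value`, `n_groups`.
#' @export
residue_count_ligand_size_correlation <- function(complexes) {
  stopifnot(inherits(complexes, "complex_set"))
  assert_assigned(complexes, "residue_count_ligand_size_correlation()")
  per_structure <- purrr::map_dfr(seq_len(nrow(complexes)), function(i) {
    rec <- active_interactions(complexes$interactions[[i]])
    tibble::tibble(
      aars = complexes$aars[i],
      n_residues = nrow(dplyr::distinct(
        tibble::tibble(c = rec$chain_id, n = rec$protein_residue_number))))
  })
  groups <- per_structure |>
    dplyr::group_by(.data$aars) |>
    dplyr::summarise(mean_residues = mean(.data$n_residues),
                     .groups = "drop") |>
    dplyr::mutate(ligand_atoms = vapply(.data$aars, function(a) {
      nrow(build_scaffold(aars_ligand(a))$atoms)
    }, numeric(1)))
  if (nrow(groups) < 3) {
    stop("need >= 3 aaRS groups for the correlation, got ", nrow(groups),
         call. = FALSE)
  }
  if (stats::sd(groups$mean_residues) == 0 ||
      stats::sd(groups$ligand_atoms) == 0) {
    stop("correlation undefined: zero variance across groups",
         call. = FALSE)
  }
  ct <- stats::cor.test(groups$mean_residues, groups$ligand_atoms,
                        method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value,
                 n_groups = nrow(groups))
}
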