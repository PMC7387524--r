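#' Analysis configuration
#'
#' Bundles the tunable constants of the pipeline. The defaults reproduce the
#' reference analysis set-up: occupancy entries below 0.1 are discarded,
#' cavity volumes are one-hot binned over 30-270 A^3 in 20 A^3 steps (12
#' bins), the hashed interaction segment has 500 bits, embeddings use
#' n_neighbors = 60, min_dist = 0.1, n_components = 2, and sequence
#' clustering uses a 95% identity cutoff.
#'
#' @param occupancy_cutoff minimum relative occupancy retained in profiles.
#' @param volume_bin_start,volume_bin_stop,volume_bin_step volume binning grid
#'   in A^3; `(stop - start) / step` must be a positive integer.
#' @param hash_bits width of the hashed interaction segment.
#' @param n_neighbors,min_dist,n_components embedding parameters, passed to
#'   the embedding backend.
#' @param identity_threshold sequence identity cutoff for clustering.
#' @param random_seed default seed for stochastic steps.
#' @return a list with class `"aars_config"`.
#' @examples
#' cfg <- analysis_config()
#' cfg$hash_bits
#' @export
analysis_config <- function(occupancy_cutoff = 0.1,
                            volume_bin_start = 30,
                            volume_bin_stop = 270,
                            volume_bin_step = 20,
                            hash_bits = 500,
                            n_neighbors = 60,
                            min_dist = 0.1,
                            n_components = 2,
                            identity_threshold = 0.95,
                            random_seed = 42L) {
  n_bins <- (volume_bin_stop - volume_bin_start) / volume_bin_step
  if (!isTRUE(all.equal(n_bins, round(n_bins))) || n_bins <= 0) {
    stop("(volume_bin_stop - volume_bin_start) / volume_bin_step must be a ",
         "positive integer", call. = FALSE)
  }
  structure(
    list(occupancy_cutoff = occupancy_cutoff,
         volume_bin_start = volume_bin_start,
         volume_bin_stop = volume_bin_stop,
         volume_bin_step = volume_bin_step,
         n_volume_bins = as.integer(round(n_bins)),
         hash_bits = as.integer(hash_bits),
         n_neighbors = n_neighbors,
         min_dist = min_dist,
         n_components = n_components,
         identity_threshold = identity_threshold,
         random_seed = as.integer(random_seed)),
    class = "aars_config")
}

#' Editing-mechanism table
#'
#' Some aaRSs hydrolytically proofread ("edit") near-cognate amino acids,
#' either before or after transfer to the tRNA. The editing table maps each
#' editing aaRS to the set of ligand codes it edits against; it drives the
#' 22-bit editing segment of the fingerprint (e.g. for ThrRS structures the
#' serine bit is set).
#'
#' `load_editing_table()` reads a YAML or JSON mapping of aaRS label to a
#' vector of ligand codes. Unknown aaRS labels or ligand codes are fatal.
#' `default_editing_table()` loads the table shipped with the package, an
#' approximation of the editing survey of Perona & Gruic-Sovulj restricted to
#' targets within the 22-ligand vocabulary; it is a configuration default,
#' not ground truth, and users should supply their own table where accuracy
#' matters.
#'
#' @param path path to a YAML (`.yml`/`.yaml`) or JSON file.
#' @return a named list of character vectors with class `"editing_table"`;
#'   aaRSs absent from the table perform no editing.
#' @examples
#' tab <- default_editing_table()
#' tab$ThrRS
#' @export
load_editing_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  if (length(raw) == 0) return(new_editing_table(list()))
  bad <- setdiff(names(raw), aars_labels())
  if (length(bad) > 0) {
    stop("editing table contains unknown aaRS label(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  raw <- lapply(raw, function(v) as.character(unlist(v)))
  for (k in names(raw)) stop_unknown_ligand(raw[[k]])
  new_editing_table(raw)
}

#' @rdname load_editing_table
#' @export
default_editing_table <- function() {
  load_editing_table(system.file("extdata", "editing_table.yaml",
                                 package = "aarsfp", mustWork = TRUE))
}

new_editing_table <- function(x) structure(x, class = "editing_table")

#' @export
print.editing_table <- function(x, ...) {
  cat("<editing_table> ", length(x), " editing aaRS(s)\n", sep = "")
  for (k in names(x)) {
    cat("  ", k, " -> ", paste(x[[k]], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}
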