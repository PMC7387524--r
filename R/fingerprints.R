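#' Fingerprint segments
#'
#' Each complex is encoded as a structure-invariant binary fingerprint built
#' from up to four segments:
#'
#' * `fp_seq()` -- 20 bits, binding-site composition: bit *i* is active iff
#'   residue type *i* (fixed alphabetical order of the 20 standard residues)
#'   occurs among the interacting residues; multiplicity is ignored.
#' * `fp_int()` -- 500 bits (configurable), hashed interaction features: for
#'   every record, one feature per assigned scaffold atom combining the
#'   interaction type, the interacting ligand group (the atom's element
#'   symbol, or `"ring"` for pi-stacking) and the protein residue type; each
#'   canonical feature string is hashed (FNV-1a, 32-bit) to a bit index in
#'   `[1, hash_bits]`. Identical features are idempotent.
#' * `fp_editing()` -- 22 bits, one per ligand code: bit *j* is active iff
#'   this aaRS edits against ligand *j* per the editing table.
#' * `fp_volume()` -- 12 bits, one-hot binned cavity volume: half-open bins
#'   of 20 A^3 from 30 to 270 A^3; volumes below 30 clamp to bin 1, at or
#'   above 270 to bin 12. A 45 A^3 cavity sets bit 1, a 52 A^3 cavity bit 2.
#'
#' @param complex a specificity-assigned [structure_complex()] or one-row
#'   [complex_set()].
#' @param config an [analysis_config()].
#' @return an `aars_fingerprint`: list with sorted integer `bits` (active,
#'   1-based), `length`, and `segment` tag.
#' @name fingerprint-segments
NULL

new_fingerprint <- function(bits, length, segment) {
  structure(list(bits = sort(unique(as.integer(bits))),
                 length = as.integer(length), segment = segment),
            class = "aars_fingerprint")
}

#' @export
print.aars_fingerprint <- function(x, ...) {
  cat("<aars_fingerprint> [", x$segment, "] ", length(x$bits), "/",
      x$length, " bits active\n", sep = "")
  invisible(x)
}

one_complex <- function(complex) {
  if (inherits(complex, "complex_set")) {
    stopifnot(nrow(complex) == 1)
    complex <- set_to_complexes(complex)[[1]]
  }
  stopifnot(inherits(complex, "structure_complex"))
  if (!"scaffold_atoms" %in% names(complex$interactions)) {
    stop("fingerprints require specificity-assigned interactions; run ",
         "assign_specificity_interactions() first", call. = FALSE)
  }
  complex
}

#' @rdname fingerprint-segments
#' @export
fp_seq <- function(complex) {
  complex <- one_complex(complex)
  rec <- active_interactions(complex$interactions)
  res <- normalize_residue_type(rec$protein_residue_type)
  idx <- match(res[res %in% standard_residues()], standard_residues())
  new_fingerprint(idx, 20L, "seq")
}

#' @rdname fingerprint-segments
#' @export
fp_int <- function(complex, config = analysis_config()) {
  complex <- one_complex(complex)
  rec <- active_interactions(complex$interactions)
  feats <- interaction_features(rec, complex$ligand_graph)
  new_fingerprint(hash_feature(feats, config$hash_bits),
                  config$hash_bits, "int")
}

# Canonical feature strings for a record table: type|ligand group|residue,
# lower case. Pi-stacking contributes a single "ring" group; other types
# one feature per assigned scaffold atom's element.
interaction_features <- function(rec, ligand_graph) {
  if (nrow(rec) == 0) return(character(0))
  elem <- stats::setNames(tolower(ligand_graph$atoms$element),
                          ligand_graph$atoms$atom_id)
  scaf_elem <- scaffold_elements()
  unlist(purrr::map(seq_len(nrow(rec)), function(i) {
    res <- tolower(rec$protein_residue_type[i])
    if (rec$itype[i] == "pi_stacking") {
      groups <- "ring"
    } else {
      atoms <- rec$scaffold_atoms[[i]]
      groups <- unique(scaf_elem[atoms])
      groups <- groups[!is.na(groups)]
    }
    paste(rec$itype[i], groups, res, sep = "|")
  }), use.names = FALSE)
}

scaffold_elements <- function() {
  tabs <- scaffold_tables()
  e <- tolower(tabs$atoms$element)
  ids <- tabs$atoms$atom_id
  # scaffold atom names share elements across ligands (N is always nitrogen
  # etc.), so a single name -> element map is well defined
  stats::setNames(e, ids)[!duplicated(ids)]
}

# FNV-1a 32-bit of a character vector, mapped to bit indices 1..bits.
hash_feature <- function(x, bits) {
  if (length(x) == 0) return(integer(0))
  vapply(x, function(s) {
    h <- 2166136261
    for (b in utf8ToInt(s)) {
      h <- bitwXor32(h, b)
      h <- mul_mod32(h, 16777619)
    }
    as.integer(h %% bits) + 1L
  }, integer(1), USE.NAMES = FALSE)
}

bitwXor32 <- function(a, b) {
  # a < 2^32 stored as double; xor via 16-bit halves
  hi <- bitwXor(a %/% 65536, b %/% 65536)
  lo <- bitwXor(a %% 65536, b %% 65536)
  hi * 65536 + lo
}

mul_mod32 <- function(a, p) {
  # (a * p) mod 2^32 without exceeding double precision
  hi <- ((a %/% 65536) * p) %% 65536
  lo <- (a %% 65536) * p
  (hi * 65536 + lo) %% 4294967296
}

#' @rdname fingerprint-segments
#' @param aars aaRS label (for `fp_editing()`).
#' @param table an `editing_table`, see [load_editing_table()].
#' @export
fp_editing <- function(aars, table = default_editing_table()) {
  stop_unknown_aars(aars)
  edited <- table[[aars]]
  new_fingerprint(match(edited, ligand_codes()), 22L, "editing")
}

#' @rdname fingerprint-segments
#' @param volume binding-cavity volume in A^3 (> 0).
#' @export
fp_volume <- function(volume, config = analysis_config()) {
  if (is.na(volume) || volume <= 0) {
    stop("cavity volume must be > 0, got ", volume, call. = FALSE)
  }
  k <- floor((volume - config$volume_bin_start) / config$volume_bin_step) + 1
  k <- max(1, min(config$n_volume_bins, k))
  new_fingerprint(k, config$n_volume_bins, "volume")
}

#' Concatenate fingerprint segments into a design variant
#'
#' Supported designs mirror the standard design comparison: `"seq_sim"` (the
#' standalone 20-bit composition vector), `"seq_int"` (the 500-bit hashed
#' segment, which already encodes residue types in its features),
#' `"seq_int_ed"` (+22 editing bits), `"seq_int_ed_vol"` (+12 volume bits,
#' 534 bits total), and the baselines `"ed"` and `"vol"`.
#'
#' @param segments named list of `aars_fingerprint` segments (`seq`, `int`,
#'   `editing`, `volume` as required by the variant).
#' @param variant design name.
#' @return an `aars_fingerprint` with the variant as segment tag.
#' @export
fp_concat <- function(segments,
                      variant = c("seq_int_ed_vol", "seq_sim", "seq_int",
                                  "seq_int_ed", "ed", "vol")) {
  variant <- match.arg(variant)
  need <- switch(variant,
                 seq_sim = "seq",
                 seq_int = "int",
                 seq_int_ed = c("int", "editing"),
                 seq_int_ed_vol = c("int", "editing", "volume"),
                 ed = "editing",
                 vol = "volume")
  missing <- setdiff(need, names(segments))
  if (length(missing) > 0) {
    stop("variant '", variant, "' requires missing segment(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  offset <- 0L
  bits <- integer(0)
  for (seg in need) {
    s <- segments[[seg]]
    bits <- c(bits, s$bits + offset)
    offset <- offset + s$length
  }
  new_fingerprint(bits, offset, variant)
}

#' Fingerprint a whole complex set
#'
#' Builds one fingerprint per complex for a given design variant.
#'
#' @param complexes a specificity-assigned [complex_set()].
#' @param variant design name, see [fp_concat()].
#' @param editing_table an `editing_table`.
#' @param config an [analysis_config()].
#' @return tibble of class `"fingerprint_set"`: `structure_id`, `aars`,
#'   `variant`, list-column `fingerprint`.
#' @export
build_fingerprints <- function(complexes,
                               variant = "seq_int_ed_vol",
                               editing_table = default_editing_table(),
                               config = analysis_config()) {
  stopifnot(inherits(complexes, "complex_set"))
  assert_assigned(complexes, "build_fingerprints()")
  objs <- set_to_complexes(complexes)
  needs_vol <- variant %in% c("seq_int_ed_vol", "vol")
  if (needs_vol && any(is.na(complexes$cavity_volume))) {
    stop("design '", variant, "' requires cavity volumes for all complexes",
         call. = FALSE)
  }
  fps <- purrr::map(objs, function(cx) {
    segs <- list(seq = fp_seq(cx), int = fp_int(cx, config),
                 editing = fp_editing(cx$aars, editing_table))
    if (!is.na(cx$cavity_volume)) {
      segs$volume <- fp_volume(cx$cavity_volume, config)
    }
    fp_concat(segs, variant)
  })
  out <- tibble::tibble(structure_id = complexes$structure_id,
                        aars = complexes$aars,
                        aars_class = complexes$aars_class,
                        variant = variant,
                        fingerprint = fps)
  class(out) <- c("fingerprint_set", class(out))
  out
}

#' Jaccard distance between two fingerprints (and pairwise matrices)
#'
#' `jaccard_distance()` implements
#' `d(a, b) = 1 - n_ab / (n_a + n_b - n_ab)` where `n_a`, `n_b` are the
#' active-bit counts and `n_ab` the shared active bits. Two all-zero
#' fingerprints are indistinguishable and get distance 0.
#' `distance_matrix()` computes all pairwise distances of a fingerprint set
#' (symmetric, zero diagonal, entries in `[0, 1]`).
#'
#' @param a,b `aars_fingerprint` objects of the same variant and length.
#' @return `jaccard_distance()`: a number in `[0, 1]`;
#'   `distance_matrix()`: an n x n symmetric matrix with `structure_id`
#'   dimnames and the fingerprint labels as attributes.
#' @examples
#' a <- aarsfp:::new_fingerprint(c(1, 2, 3), 10, "demo")
#' b <- aarsfp:::new_fingerprint(c(2, 3, 4), 10, "demo")
#' jaccard_distance(a, b)   # 1 - 2/4 = 0.5
#' @export
jaccard_distance <- function(a, b) {
  if (a$length != b$length || a$segment != b$segment) {
    stop("fingerprints differ in variant or length", call. = FALSE)
  }
  na <- length(a$bits); nb <- length(b$bits)
  nab <- length(intersect(a$bits, b$bits))
  denom <- na + nb - nab
  if (denom == 0) return(0)
  1 - nab / denom
}

#' @rdname jaccard_distance
#' @param fps a `fingerprint_set` from [build_fingerprints()].
#' @export
distance_matrix <- function(fps) {
  stopifnot(inherits(fps, "fingerprint_set"))
  if (length(unique(fps$variant)) > 1 ||
      length(unique(vapply(fps$fingerprint, `[[`, integer(1), "length")))
      > 1) {
    stop("mixed fingerprint variants in distance_matrix()", call. = FALSE)
  }
  n <- nrow(fps)
  width <- fps$fingerprint[[1]]$length
  mat <- matrix(0L, n, width)
  for (i in seq_len(n)) mat[i, fps$fingerprint[[i]]$bits] <- 1L
  inter <- tcrossprod(mat)
  counts <- rowSums(mat)
  union <- outer(counts, counts, "+") - inter
  d <- 1 - inter / union
  d[union == 0] <- 0
  diag(d) <- 0
  dimnames(d) <- list(fps$structure_id, fps$structure_id)
  attr(d, "labels") <- fps$aars
  attr(d, "variant") <- fps$variant[1]
  d
}

#' Hash collision diagnostic for the interaction segment
#'
#' Enumerates the finite vocabulary of chemically realizable interaction
#' features and reports the collision rate: the fraction of features that
#' lose a dedicated bit, `(n_features - n_distinct_bits) / n_features`.
#' Realizable means type-compatible on both sides: hydrophobic contacts pair
#' a ligand carbon with any side-chain-bearing residue; hydrogen bonds pair
#' ligand O/N with any residue (backbone donors/acceptors included); salt
#' bridges pair ligand O/N with a charged residue; pi-stacking needs an
#' aromatic residue; metal complexes coordinate ligand O/N/S via zinc, the
#' metal observed in aaRS amino-acid binding sites.
#'
#' @param config an [analysis_config()].
#' @return tibble: `n_features`, `n_bits_used`, `collision_rate`.
#' @export
hash_collision_diagnostic <- function(config = analysis_config()) {
  res <- tolower(standard_residues())
  charged <- c("arg", "lys", "his", "asp", "glu")
  aromatic <- c("phe", "tyr", "trp", "his")
  vocab <- c(
    paste("hydrophobic", "c", setdiff(res, "gly"), sep = "|"),
    unlist(lapply(c("o", "n"),
                  function(g) paste("hydrogen_bond", g, res, sep = "|"))),
    unlist(lapply(c("o", "n"),
                  function(g) paste("salt_bridge", g, charged, sep = "|"))),
    paste("pi_stacking", "ring", aromatic, sep = "|"),
    paste("metal_complex", c("o", "n", "s"), "zn", sep = "|"))
  idx <- hash_feature(vocab, config$hash_bits)
  tibble::tibble(n_features = length(vocab),
                 n_bits_used = length(unique(idx)),
                 collision_rate = 1 - length(unique(idx)) / length(vocab))
}

#' Write fingerprints as bit strings
#'
#' Plain-text export: one line per fingerprint (`structure_id`, `aars`,
#' bit string of 0/1), preceded by a JSON header line with the layout.
#'
#' @param fps a `fingerprint_set`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_fingerprints <- function(fps, path) {
  stopifnot(inherits(fps, "fingerprint_set"))
  header <- jsonlite::toJSON(
    list(variant = fps$variant[1],
         length = fps$fingerprint[[1]]$length), auto_unbox = TRUE)
  lines <- vapply(seq_len(nrow(fps)), function(i) {
    f <- fps$fingerprint[[i]]
    bits <- rep("0", f$length)
    bits[f$bits] <- "1"
    paste(fps$structure_id[i], fps$aars[i], paste(bits, collapse = ""),
          sep = "\t")
  }, character(1))
  writeLines(c(as.character(header), lines), path)
  invisible(path)
}
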