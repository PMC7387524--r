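#' Controlled vocabularies for the aaRS recognition analysis
#'
#' The analysis covers the 20 standard amino acid ligands plus pyrrolysine
#' (Pyl, one-letter O) and phosphoserine (Sep, one-letter J), each handled by
#' its aminoacyl-tRNA synthetase (aaRS). All bit indices, template orders and
#' fingerprint segments derive from the fixed alphabetical order of the
#' three-letter ligand codes returned by [ligand_codes()], so indices are
#' stable across runs and machines.
#'
#' @return `ligand_codes()`: character vector of the 22 three-letter ligand
#'   codes in fixed alphabetical order. `aars_labels()`: the 22 aaRS labels in
#'   the matching order. `interaction_types()`: the seven recognised
#'   interaction type codes.
#' @examples
#' ligand_codes()
#' aars_class("ThrRS")
#' @export
ligand_codes <- function() {
  c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
    "Leu", "Lys", "Met", "Phe", "Pro", "Pyl", "Sep", "Ser", "Thr", "Trp",
    "Tyr", "Val")
}

#' @rdname ligand_codes
#' @export
aars_labels <- function() {
  paste0(sub("^(...).*", "\\1", ligand_codes()), "RS")
}

#' @rdname ligand_codes
#' @export
interaction_types <- function() {
  c("hydrogen_bond", "hydrophobic", "salt_bridge", "pi_stacking",
    "pi_cation", "metal_complex", "water_bridge")
}

# The five types entering class-level frequency tables; water bridges are
# excluded from all statistics by default and pi-cation contacts were never
# observed in amino-acid binding sites.
table_interaction_types <- function() {
  c("hydrogen_bond", "hydrophobic", "salt_bridge", "pi_stacking",
    "metal_complex")
}

#' @rdname ligand_codes
#' @export
standard_residues <- function() {
  c("Ala", "Arg", "Asn", "Asp", "Cys", "Gln", "Glu", "Gly", "His", "Ile",
    "Leu", "Lys", "Met", "Phe", "Pro", "Ser", "Thr", "Trp", "Tyr", "Val")
}

#' Map between aaRS labels, ligand codes and aaRS classes
#'
#' Class membership is fixed: ten Class I and ten Class II standard aaRSs,
#' with the non-standard PylRS and SepRS both belonging to Class II.
#'
#' @param aars aaRS label(s), e.g. `"ThrRS"`.
#' @return `aars_class()`: `"I"` or `"II"` per label. `aars_ligand()`: the
#'   cognate three-letter ligand code per label.
#' @examples
#' aars_class(c("GluRS", "AspRS"))
#' @export
aars_class <- function(aars) {
  class_i <- c("ArgRS", "CysRS", "GlnRS", "GluRS", "IleRS", "LeuRS",
               "MetRS", "TrpRS", "TyrRS", "ValRS")
  stop_unknown_aars(aars)
  ifelse(aars %in% class_i, "I", "II")
}

#' @rdname aars_class
#' @export
aars_ligand <- function(aars) {
  stop_unknown_aars(aars)
  ligand_codes()[match(aars, aars_labels())]
}

stop_unknown_aars <- function(aars) {
  bad <- setdiff(aars, aars_labels())
  if (length(bad) > 0) {
    stop("unknown aaRS label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(aars)
}

stop_unknown_ligand <- function(code) {
  bad <- setdiff(code, ligand_codes())
  if (length(bad) > 0) {
    stop("unknown ligand code(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(code)
}

# Three-letter residue codes (upper case, as found in structure files) to
# the package's title-case codes; nonstandard residues map to their parent
# standard residue where known, otherwise to "UNK".
normalize_residue_type <- function(x) {
  up <- toupper(x)
  std <- toupper(standard_residues())
  parents <- c(MSE = "Met", SEC = "Cys", PYL = "Lys", SEP = "Ser",
               TPO = "Thr", PTR = "Tyr", CSO = "Cys", MLY = "Lys",
               HYP = "Pro", KCX = "Lys")
  out <- ifelse(up %in% std, standard_residues()[match(up, std)],
                ifelse(up %in% names(parents), parents[up], "UNK"))
  unname(out)
}

# Metal element labels accepted on the protein side of metal_complex records.
metal_labels <- function() {
  c("ZN", "MG", "MN", "FE", "CO", "NI", "CU", "CA", "K", "NA")
}
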