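#' Signed dihedral angle of four points
#'
#' IUPAC sign convention: looking down the `p2 -> p3` axis, the angle from
#' the `p1` side to the `p4` side, positive clockwise, in `(-180, 180]`
#' degrees. Computed with the atan2 cross-product formula, so it is
#' invariant under rigid-body motion and symmetric under reversal of the
#' point order.
#'
#' @param p1,p2,p3,p4 numeric length-3 coordinates (A).
#' @return angle in degrees.
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1; b2 <- p3 - p2; b3 <- p4 - p3
  if (sqrt(sum(b1^2)) < 1e-12 || sqrt(sum(b2^2)) < 1e-12 ||
      sqrt(sum(b3^2)) < 1e-12) {
    stop("degenerate geometry: coincident consecutive points",
         call. = FALSE)
  }
  n1 <- cross3(b1, b2); n2 <- cross3(b2, b3)
  if (sqrt(sum(n1^2)) < 1e-12 || sqrt(sum(n2^2)) < 1e-12) {
    stop("degenerate geometry: collinear points", call. = FALSE)
  }
  ang <- atan2(sum(cross3(n1, n2) * b2) / sqrt(sum(b2^2)),
               sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

#' Torsion specification and ligand torsion angles
#'
#' The ligand orientation statistic is the torsion between the phosphate
#' and the amino-acid substructure of a post-activation ligand. A
#' `torsion_spec()` names the four atoms of the dihedral; the default
#' quadruple sits around the phosphoester bridge bond: ribose O5'
#' (equivalent), alpha-phosphorus (PA), bridging ester oxygen, carbonyl
#' carbon. The
#' exact choice is configurable and recorded in the output.
#'
#' @param atoms character vector of exactly four ligand atom ids/names.
#' @return `torsion_spec()`: a character vector of class `"torsion_spec"`.
#' @export
torsion_spec <- function(atoms = c("O5'", "PA", "O3A", "C")) {
  atoms <- as.character(atoms)
  if (length(atoms) != 4) {
    stop("a torsion spec needs exactly 4 atom selectors", call. = FALSE)
  }
  structure(atoms, class = "torsion_spec")
}

#' @rdname torsion_spec
#' @param complex a [structure_complex()] (or one-row [complex_set()]) with
#'   coordinates.
#' @param spec a `torsion_spec`.
#' @return `ligand_torsion()`: tibble `structure_id`, `angle` (degrees),
#'   `spec`.
#' @export
ligand_torsion <- function(complex, spec = torsion_spec()) {
  if (inherits(complex, "complex_set")) {
    return(purrr::map_dfr(set_to_complexes(complex), ligand_torsion,
                          spec = spec))
  }
  stopifnot(inherits(complex, "structure_complex"))
  co <- complex$coordinates
  if (is.null(co) || nrow(co) == 0) {
    stop("complex '", complex$structure_id, "' has no coordinates",
         call. = FALSE)
  }
  pts <- lapply(spec, function(sel) {
    hit <- which(co$atom_id == sel)
    if (length(hit) == 0) {
      stop("torsion selector '", sel, "' unresolvable in complex '",
           complex$structure_id, "'", call. = FALSE)
    }
    as.numeric(co[hit[length(hit)], c("x", "y", "z")])
  })
  tibble::tibble(structure_id = complex$structure_id,
                 angle = dihedral(pts[[1]], pts[[2]], pts[[3]], pts[[4]]),
                 spec = paste(unclass(spec), collapse = "-"))
}

#' Compare a numeric property between two groups
#'
#' Mann-Whitney U comparison (see [mann_whitney_u()]) of, e.g., binding
#' cavity volumes between Class I and Class II aaRSs, reporting group
#' medians alongside the test.
#'
#' @param values_by_group named list of exactly two numeric vectors.
#' @return tibble: group names, medians, `n`, `U`, `p_value`.
#' @export
group_compare <- function(values_by_group) {
  if (length(values_by_group) != 2) {
    stop("group_compare() expects exactly two groups", call. = FALSE)
  }
  nms <- names(values_by_group) %||% c("group1", "group2")
  x <- values_by_group[[1]]; y <- values_by_group[[2]]
  test <- mann_whitney_u(x, y)
  tibble::tibble(group1 = nms[1], group2 = nms[2],
                 median1 = stats::median(x), median2 = stats::median(y),
                 n1 = length(x), n2 = length(y),
                 U = test$U, p_value = test$p_value, method = test$method)
}
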