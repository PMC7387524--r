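#' Mann-Whitney U test
#'
#' Rank-sum test for a location difference between two independent samples.
#' The U statistic is reported in the x-over-y orientation (number of pairs
#' with `x > y`, ties counted 1/2). For small problems (`n + m <= 16`) the
#' two-sided p-value is computed by exhaustive enumeration of all
#' `choose(n + m, n)` group assignments of the pooled values, which remains
#' exact under ties; larger problems use the tie-corrected normal
#' approximation of the null distribution (no continuity correction).
#'
#' @param x,y numeric samples, both non-empty.
#' @param exact_max enumerate exactly when `length(x) + length(y)` is at
#'   most this; default 16.
#' @return tibble with one row: `U`, `p_value`, `method`.
#' @examples
#' mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
#' @export
mann_whitney_u <- function(x, y, exact_max = 16) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) == 0 || length(y) == 0) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  n <- length(x); m <- length(y)
  u <- u_statistic(x, y)
  if (n + m <= exact_max) {
    pooled <- c(x, y)
    combos <- utils::combn(n + m, n)
    us <- apply(combos, 2, function(idx) {
      u_statistic(pooled[idx], pooled[-idx])
    })
    center <- n * m / 2
    p <- mean(abs(us - center) >= abs(u - center) - 1e-9)
    method <- "exact enumeration"
  } else {
    pooled <- c(x, y)
    ties <- table(pooled)
    nn <- n + m
    sigma2 <- n * m / 12 *
      ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (u - n * m / 2) / sqrt(sigma2)
      p <- min(1, 2 * stats::pnorm(-abs(z)))
    }
    method <- "normal approximation, tie-corrected"
  }
  tibble::tibble(U = u, p_value = p, method = method)
}

u_statistic <- function(x, y) {
  # U for x-over-y: rank-sum formulation, ties share 1/2
  r <- rank(c(x, y))
  sum(r[seq_along(x)]) - length(x) * (length(x) + 1) / 2
}

#' Spearman rank correlation of two pairwise-distance lists
#'
#' Rank correlation with average ranks for ties, via [stats::cor.test()].
#' Used to relate recognition-space distances to physicochemical
#' (phase-transfer free energy) distances between amino acids.
#'
#' @param d1,d2 equal-length numeric vectors (length >= 3), typically the
#'   flattened lower triangles of two distance matrices.
#' @return tibble with one row: `rho`, `p_value`.
#' @export
spearman_rho <- function(d1, d2) {
  if (length(d1) != length(d2)) {
    stop("distance lists must have equal length", call. = FALSE)
  }
  if (length(d1) < 3) stop("need >= 3 pairs", call. = FALSE)
  ct <- suppressWarnings(
    stats::cor.test(d1, d2, method = "spearman", exact = FALSE))
  tibble::tibble(rho = unname(ct$estimate), p_value = ct$p.value)
}

#' Physicochemical side-chain distances
#'
#' Pairwise Euclidean distances between the 20 standard amino acids in the
#' space of experimental phase-transfer free energies of their side chains:
#' water-to-cyclohexane and vapor-to-cyclohexane (kcal/mol; bundled
#' reference table from the hydrophobicity-scale literature). These
#' descriptors capture side-chain size and polarity and serve as the
#' comparison space for [spearman_rho()] against recognition-space
#' distances.
#'
#' @return a symmetric 20 x 20 distance matrix with residue-code dimnames.
#' @export
physicochemical_distances <- function() {
  path <- system.file("extdata", "phase_transfer_energies.csv",
                      package = "aarsfp", mustWork = TRUE)
  tab <- utils::read.csv(path, comment.char = "#")
  m <- as.matrix(tab[, c("dG_water_cyclohexane", "dG_vapor_cyclohexane")])
  rownames(m) <- tab$residue
  as.matrix(stats::dist(m))
}
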