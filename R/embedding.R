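#' Embed a fingerprint distance matrix into two dimensions
#'
#' Projects the pairwise Jaccard distances into a low-dimensional
#' "recognition space". The backend is pluggable: any function taking
#' `(distance_matrix, config, seed)` and returning an n x 2 coordinate
#' matrix can be supplied. Two backends ship with the package:
#'
#' * `"umap"` (default) -- the UMAP algorithm on precomputed distances: a
#'   fuzzy k-nearest-neighbour graph is built (per-point bandwidths
#'   calibrated by bisection so each point's total membership is
#'   `log2(n_neighbors)`, connectivity anchored at the nearest-neighbour
#'   distance, memberships symmetrized by probabilistic union), initialized
#'   from principal coordinates, and optimized by negative-sampling
#'   stochastic gradient descent of the fuzzy-set cross-entropy with the
#'   standard low-dimensional kernel `1 / (1 + a d^(2b))` fitted from
#'   `min_dist`. Preserves local cluster structure rather than global
#'   distances; fixed seeds give identical coordinates.
#' * `"mds"` -- classical metric MDS (principal coordinates,
#'   [stats::cmdscale()]): fully deterministic, preserves global distance
#'   structure, but collapses many mutually equidistant clusters.
#'
#' `n_neighbors` is clamped with a warning when the dataset is smaller.
#'
#' @param dm square symmetric distance matrix (e.g. from
#'   [distance_matrix()]); `labels` attribute, if present, is carried along.
#' @param config an [analysis_config()].
#' @param seed integer seed forwarded to the backend; results are
#'   reproducible for a fixed seed.
#' @param backend `"umap"`, `"mds"`, or a backend function.
#' @return an `embedding_result`: list with `coordinates` (n x 2 matrix),
#'   `labels`, `parameters`, `seed`, `backend`.
#' @export
embed_fingerprints <- function(dm, config = analysis_config(),
                               seed = config$random_seed,
                               backend = "umap") {
  if (!is.matrix(dm) || nrow(dm) != ncol(dm)) {
    stop("distance matrix must be square", call. = FALSE)
  }
  if (max(abs(dm - t(dm))) > 1e-8) {
    stop("distance matrix must be symmetric", call. = FALSE)
  }
  fn <- if (is.function(backend)) backend else switch(
    backend,
    mds = backend_mds,
    umap = backend_umap,
    stop("unknown embedding backend '", backend, "'", call. = FALSE))
  coords <- fn(dm, config, seed)
  stopifnot(nrow(coords) == nrow(dm))
  rownames(coords) <- rownames(dm)
  structure(
    list(coordinates = coords,
         labels = attr(dm, "labels"),
         parameters = list(n_neighbors = config$n_neighbors,
                           min_dist = config$min_dist,
                           n_components = config$n_components),
         seed = seed,
         backend = if (is.function(backend)) "custom" else backend),
    class = "embedding_result")
}

backend_mds <- function(dm, config, seed) {
  n <- nrow(dm)
  k <- min(config$n_components, max(1L, n - 1L))
  coords <- suppressWarnings(stats::cmdscale(dm, k = k))
  if (is.null(dim(coords)) || ncol(coords) < config$n_components) {
    # degenerate inputs (e.g. all-identical points) can yield fewer axes
    pad <- matrix(0, n, config$n_components -
                    ifelse(is.null(dim(coords)), 0, ncol(coords)))
    coords <- cbind(coords, pad)[, seq_len(config$n_components),
                                 drop = FALSE]
  }
  if (nrow(coords) == 0) coords <- matrix(0, n, config$n_components)
  coords
}

backend_umap <- function(dm, config, seed, n_epochs = 300,
                         negative_samples = 5) {
  n <- nrow(dm)
  if (n <= 2) return(backend_mds(dm, config, seed))
  if (max(dm) == 0) {
    # zero-information input: every point is identical, place them together
    return(matrix(0, n, config$n_components))
  }
  k <- config$n_neighbors
  if (k >= n) {
    warning("n_neighbors = ", k, " clamped to n - 1 = ", n - 1,
            call. = FALSE)
    k <- n - 1
  }
  w <- fuzzy_knn_weights(dm, k)
  ut <- which(upper.tri(w) & w > 0, arr.ind = TRUE)
  ei <- ut[, 1]; ej <- ut[, 2]; ew <- w[ut]
  if (length(ei) == 0) return(backend_mds(dm, config, seed))
  ab <- umap_ab(config$min_dist)
  a <- ab[1]; b <- ab[2]

  # principal-coordinate initialization, scaled to the usual layout extent
  x <- backend_mds(dm, config, seed)
  spread0 <- max(abs(x))
  x <- if (spread0 > 0) x / spread0 * 10 else x

  old_seed <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  x <- x + matrix(stats::rnorm(length(x), sd = 1e-3), nrow = n)

  p_edge <- ew / max(ew)
  clip4 <- function(m) pmin(pmax(m, -4), 4)
  for (epoch in seq_len(n_epochs)) {
    alpha <- 1 - (epoch - 1) / n_epochs
    live <- which(stats::runif(length(ei)) < p_edge)
    if (length(live) == 0) next
    ii <- ei[live]; jj <- ej[live]
    diff <- x[ii, , drop = FALSE] - x[jj, , drop = FALSE]
    d2 <- rowSums(diff^2)
    co <- ifelse(d2 > 0, -2 * a * b * d2^(b - 1) / (1 + a * d2^b), 0)
    grad <- clip4(co * diff)
    # negative sampling: repulsion of edge heads from random points
    iin <- rep(ii, negative_samples)
    jn <- sample.int(n, length(iin), replace = TRUE)
    diffn <- x[iin, , drop = FALSE] - x[jn, , drop = FALSE]
    d2n <- rowSums(diffn^2)
    cr <- 2 * b / ((0.001 + d2n) * (1 + a * d2n^b))
    cr[iin == jn] <- 0
    gradn <- clip4(cr * diffn)
    upd_idx <- c(ii, jj, iin)
    upd <- alpha * rbind(grad, -grad, gradn)
    agg <- rowsum(upd, group = upd_idx)
    rows <- as.integer(rownames(agg))
    x[rows, ] <- x[rows, ] + agg
  }
  x[, seq_len(config$n_components), drop = FALSE]
}

# fit the low-dimensional kernel 1/(1 + a d^(2b)) to the ideal membership
# curve implied by min_dist (1 below min_dist, exponential decay above)
umap_ab <- function(min_dist, spread = 1) {
  d <- seq(0, 3 * spread, length.out = 300)
  target <- ifelse(d < min_dist, 1, exp(-(d - min_dist) / spread))
  fit <- stats::optim(c(1.5, 1), function(p) {
    sum((1 / (1 + p[1] * d^(2 * p[2])) - target)^2)
  }, method = "L-BFGS-B", lower = c(1e-3, 1e-3))
  fit$par
}

# Fuzzy k-nearest-neighbour membership weights from a distance matrix:
# per-point exponential kernel anchored at the nearest-neighbour distance,
# bandwidth calibrated by bisection so the total membership is log2(k);
# symmetrized by probabilistic union (w + w' - w w').
fuzzy_knn_weights <- function(dm, k) {
  n <- nrow(dm)
  w <- matrix(0, n, n)
  target <- log2(k)
  for (i in seq_len(n)) {
    d <- dm[i, -i]
    idx <- order(d)[seq_len(k)]
    dk <- d[idx]
    rho <- min(dk)
    memb <- function(sigma) sum(exp(-pmax(0, dk - rho) / sigma))
    lo <- 1e-6; hi <- 10
    for (it in 1:40) {
      mid <- (lo + hi) / 2
      if (memb(mid) < target) lo <- mid else hi <- mid
    }
    cols <- seq_len(n)[-i][idx]
    w[i, cols] <- exp(-pmax(0, dk - rho) / ((lo + hi) / 2))
  }
  w + t(w) - w * t(w)
}

#' @export
print.embedding_result <- function(x, ...) {
  cat("<embedding_result> ", nrow(x$coordinates), " points, backend '",
      x$backend, "', seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @method tidy embedding_result
#' @export
tidy.embedding_result <- function(x, ...) {
  tibble::tibble(
    structure_id = rownames(x$coordinates) %||%
      as.character(seq_len(nrow(x$coordinates))),
    aars = x$labels %||% NA_character_,
    dim1 = x$coordinates[, 1],
    dim2 = x$coordinates[, 2])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Mean silhouette coefficient
#'
#' Standard silhouette `s(i) = (b(i) - a(i)) / max(a(i), b(i))` with `a(i)`
#' the mean distance of point *i* to its own cluster (excluding itself) and
#' `b(i)` the smallest mean distance to another cluster; singleton clusters
#' and points with `a = b = 0` score 0. Perfect discrimination of every
#' aaRS approaches 1; negative values mean another aaRS's recognition looks
#' more similar than the point's own group.
#'
#' @param x either an n x d coordinate matrix (Euclidean mode, e.g. an
#'   embedding) or a precomputed symmetric distance matrix with
#'   `precomputed = TRUE`.
#' @param labels cluster label per point; at least two distinct labels.
#' @param precomputed interpret `x` as a distance matrix.
#' @return the mean silhouette over all points (in `[-1, 1]`).
#' @export
mean_silhouette <- function(x, labels, precomputed = FALSE) {
  mean(silhouette_values(x, labels, precomputed))
}

#' @rdname mean_silhouette
#' @export
silhouette_values <- function(x, labels, precomputed = FALSE) {
  labels <- as.character(labels)
  if (length(unique(labels)) < 2) {
    stop("silhouette requires >= 2 distinct labels", call. = FALSE)
  }
  d <- if (precomputed) as.matrix(x) else
    as.matrix(stats::dist(as.matrix(x)))
  stopifnot(nrow(d) == length(labels))
  groups <- sort(unique(labels))
  ind <- sapply(groups, function(g) as.numeric(labels == g))
  sums <- d %*% ind                      # n x k: sum of distances per group
  sizes <- colSums(ind)
  own <- match(labels, groups)
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    if (sizes[own[i]] == 1) { s[i] <- 0; next }
    a <- sums[i, own[i]] / (sizes[own[i]] - 1)
    b <- min(sums[i, -own[i]] / sizes[-own[i]])
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  s
}

#' Compare fingerprint designs by embedding silhouette
#'
#' For each design: build fingerprints, compute the Jaccard distance
#' matrix, embed once per seed, and score the mean silhouette of the aaRS
#' labels in the embedded space. Per-seed values and their dispersion are
#' reported; with the deterministic MDS backend the per-seed values
#' coincide, but the interface keeps seeds explicit for stochastic
#' backends.
#'
#' @param complexes a specificity-assigned [complex_set()] spanning >= 2
#'   aaRSs.
#' @param designs character vector of design variants (see [fp_concat()]).
#' @param seeds integer vector of embedding seeds.
#' @param editing_table,config,backend forwarded to the pipeline stages.
#' @param silhouette_on `"embedding"` (Euclidean in the embedded space,
#'   default) or `"jaccard"` (precomputed fingerprint distances; no
#'   embedding step).
#' @return a `design_comparison`: tibble `design`, `seed`, `silhouette`,
#'   with per-point silhouettes in `attr(, "points")`.
#' @export
compare_designs <- function(complexes,
                            designs = c("seq_sim", "seq_int", "seq_int_ed",
                                        "seq_int_ed_vol"),
                            seeds = 1L,
                            editing_table = default_editing_table(),
                            config = analysis_config(),
                            backend = "umap",
                            silhouette_on = c("embedding", "jaccard")) {
  silhouette_on <- match.arg(silhouette_on)
  stopifnot(inherits(complexes, "complex_set"), length(designs) >= 1)
  if (length(unique(complexes$aars)) < 2) {
    stop("compare_designs() needs complexes spanning >= 2 aaRSs",
         call. = FALSE)
  }
  # deterministic with respect to input ordering
  ord <- order(complexes$structure_id)
  complexes <- complexes[ord, ]
  points <- list()
  rows <- purrr::map_dfr(designs, function(design) {
    fps <- build_fingerprints(complexes, variant = design,
                              editing_table = editing_table,
                              config = config)
    dm <- distance_matrix(fps)
    purrr::map_dfr(seeds, function(sd) {
      if (silhouette_on == "jaccard") {
        sil <- silhouette_values(dm, fps$aars, precomputed = TRUE)
      } else {
        emb <- embed_fingerprints(dm, config, seed = sd, backend = backend)
        sil <- silhouette_values(emb$coordinates, fps$aars)
      }
      points[[paste(design, sd, sep = "@")]] <<-
        tibble::tibble(design = design, seed = sd, aars = fps$aars,
                       silhouette = sil)
      tibble::tibble(design = design, seed = as.integer(sd),
                     silhouette = mean(sil))
    })
  })
  out <- rows
  attr(out, "points") <- dplyr::bind_rows(points)
  class(out) <- c("design_comparison", class(out))
  out
}

#' @importFrom generics glance
#' @method glance design_comparison
#' @export
glance.design_comparison <- function(x, ...) {
  dplyr::group_by(tibble::as_tibble(x), .data$design) |>
    dplyr::summarise(mean_silhouette = mean(.data$silhouette),
                     sd_silhouette = stats::sd(.data$silhouette),
                     n_seeds = dplyr::n(), .groups = "drop")
}

#' @method tidy design_comparison
#' @export
tidy.design_comparison <- function(x, ...) {
  tibble::as_tibble(attr(x, "points"))
}
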