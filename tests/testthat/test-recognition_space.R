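test_that("silhouette matches the double-loop oracle to 1e-12", {
  set.seed(31)
  for (rep in 1:25) {
    n <- sample(6:30, 1)
    pts <- matrix(stats::rnorm(2 * n), ncol = 2)
    labels <- sample(letters[1:sample(2:4, 1)], n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    got <- silhouette_values(pts, labels)
    want <- silhouette_oracle(dist(pts), labels)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("silhouette agrees with cluster::silhouette on clean cases", {
  skip_if_not_installed("cluster")
  set.seed(8)
  pts <- rbind(matrix(stats::rnorm(20, 0), ncol = 2),
               matrix(stats::rnorm(20, 5), ncol = 2),
               matrix(stats::rnorm(20, -5), ncol = 2))
  labels <- rep(1:3, each = 10)
  ref <- cluster::silhouette(labels, dist(pts))
  expect_equal(mean(silhouette_values(pts, labels)),
               mean(ref[, "sil_width"]), tolerance = 1e-12)
})

test_that("silhouette edge conventions: perfect separation, identical points, singletons", {
  pts <- rbind(matrix(0, 4, 2), matrix(10, 4, 2))
  labels <- rep(c("a", "b"), each = 4)
  expect_equal(mean_silhouette(pts, labels), 1)

  # identical points with shuffled labels: a = b = 0 convention gives 0
  same <- matrix(1, 6, 2)
  expect_equal(mean_silhouette(same, rep(c("a", "b"), 3)), 0)

  # singleton cluster scores 0
  pts2 <- rbind(c(0, 0), c(0.1, 0), c(9, 9))
  expect_equal(silhouette_values(pts2, c("a", "a", "b"))[3], 0)

  expect_error(mean_silhouette(matrix(0, 3, 2), rep("a", 3)), ">= 2")

  # 5-point hand-computed configuration
  p <- rbind(c(0, 0), c(1, 0), c(0, 1), c(10, 0), c(10, 1))
  lab <- c("a", "a", "a", "b", "b")
  d <- as.matrix(dist(p))
  s1_a <- mean(d[1, 2:3]); s1_b <- mean(d[1, 4:5])
  expect_equal(silhouette_values(p, lab)[1],
               (s1_b - s1_a) / max(s1_a, s1_b), tolerance = 1e-12)
  expect_equal(mean_silhouette(p, lab), mean(silhouette_oracle(d, lab)),
               tolerance = 1e-12)
})

test_that("embedding handles degenerate input, separates blocks, and is seed-deterministic", {
  # three identical points: all pairwise embedded distances equal, no crash
  z <- matrix(0, 3, 3)
  emb <- embed_fingerprints(z, seed = 1)
  d <- dist(emb$coordinates)
  expect_equal(max(d) - min(d), 0, tolerance = 1e-6)

  # two well-separated fingerprint blocks stay separated
  dm <- rbind(cbind(matrix(0, 5, 5), matrix(1, 5, 5)),
              cbind(matrix(1, 5, 5), matrix(0, 5, 5)))
  cfg <- analysis_config(n_neighbors = 4)
  emb2 <- embed_fingerprints(dm, cfg, seed = 7)
  dd <- as.matrix(dist(emb2$coordinates))
  within <- c(dd[1:5, 1:5][upper.tri(diag(5))],
              dd[6:10, 6:10][upper.tri(diag(5))])
  between <- dd[1:5, 6:10]
  expect_gt(min(between), max(within))

  # fixed seed: identical coordinates on repeat runs
  emb3 <- embed_fingerprints(dm, cfg, seed = 7)
  expect_identical(emb2$coordinates, emb3$coordinates)
  emb4 <- embed_fingerprints(dm, cfg, seed = 8)
  expect_false(identical(emb2$coordinates, emb4$coordinates))

  expect_error(embed_fingerprints(matrix(0, 3, 4)), "square")
  expect_warning(embed_fingerprints(matrix(0.5, 4, 4) - diag(0.5, 4),
                                    analysis_config(n_neighbors = 60),
                                    seed = 1),
                 "clamped")
})

test_that("the MDS backend is available and deterministic", {
  dm <- as.matrix(dist(matrix(stats::rnorm(20), ncol = 2)))
  a <- embed_fingerprints(dm, seed = 1, backend = "mds")
  b <- embed_fingerprints(dm, seed = 99, backend = "mds")
  expect_identical(a$coordinates, b$coordinates)
  expect_error(embed_fingerprints(dm, backend = "nope"), "unknown")
})

test_that("compare_designs recovers perfect separation and validates inputs", {
  # two aaRSs with identical fingerprints within each aaRS (and distinct
  # ones across them): silhouette 1
  mk <- function(aars, rec, id) {
    aarsfp:::set_to_complexes(toy_assigned_complex(aars, rec,
                                                   id = id))[[1]]
  }
  g_rec <- rec1("hydrogen_bond", "Tyr", 10L, "N")
  t_rec <- rec1("hydrogen_bond", "Arg", 538L, "OG1")
  objs <- c(lapply(1:4, function(i) mk("GlyRS", g_rec, paste0("G", i))),
            lapply(1:4, function(i) mk("ThrRS", t_rec, paste0("W", i))))
  cx <- complex_set(objs)
  cx <- assign_specificity_interactions(cx)
  comp <- compare_designs(cx, designs = "seq_int_ed",
                          seeds = 1, config = analysis_config(n_neighbors = 4))
  expect_equal(comp$silhouette, 1, tolerance = 0.2)

  comp2 <- compare_designs(cx, designs = "seq_int_ed", seeds = 1,
                           config = analysis_config(n_neighbors = 4),
                           silhouette_on = "jaccard")
  expect_equal(comp2$silhouette, 1)

  cx$cavity_volume <- NA_real_
  expect_error(
    compare_designs(cx, designs = c("seq_int", "vol"), seeds = 1,
                    config = analysis_config(n_neighbors = 4)),
    "vol")

  one <- cx[cx$aars == "GlyRS", ]
  class(one) <- class(cx)
  expect_error(compare_designs(one, designs = "seq_int", seeds = 1),
               ">= 2 aaRSs")
})

test_that("compare_designs is invariant to the ordering of input complexes", {
  cx <- assign_specificity_interactions(
    generate_complexes(default_spec(), n_per_aars = 3, seed = 5))
  cfg <- analysis_config(n_neighbors = 10)
  a <- compare_designs(cx, designs = "seq_int", seeds = 2, config = cfg)
  shuffled <- cx[rev(seq_len(nrow(cx))), ]
  class(shuffled) <- class(cx)
  b <- compare_designs(shuffled, designs = "seq_int", seeds = 2,
                       config = cfg)
  expect_equal(a$silhouette, b$silhouette, tolerance = 1e-12)
})

test_that("tidy/glance/autoplot interfaces stay consistent", {
  cx <- assign_specificity_interactions(
    generate_complexes(default_spec(), n_per_aars = 2, seed = 4))
  fps <- build_fingerprints(cx, "seq_int_ed")
  dm <- distance_matrix(fps)
  emb <- embed_fingerprints(dm, analysis_config(n_neighbors = 10), seed = 1)
  td <- tidy(emb)
  expect_identical(nrow(td), nrow(cx))
  expect_named(td, c("structure_id", "aars", "dim1", "dim2"))
  expect_s3_class(autoplot(emb), "ggplot")

  comp <- compare_designs(cx, designs = c("seq_sim", "seq_int"), seeds = 1,
                          config = analysis_config(n_neighbors = 10))
  g <- glance(comp)
  expect_identical(nrow(g), 2L)
  expect_identical(nrow(tidy(comp)), 2L * nrow(cx))
  expect_s3_class(autoplot(comp), "ggplot")

  prof <- compute_occupancy(local({
    x <- cx[cx$aars == "GlyRS", ]; class(x) <- class(cx); x
  }))
  expect_s3_class(plot_occupancy(prof), "ggplot")
})
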