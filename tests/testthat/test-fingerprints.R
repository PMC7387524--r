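test_that("the sequence segment encodes residue occurrence, not multiplicity", {
  recs <- dplyr::bind_rows(
    rec1("hydrogen_bond", "Arg", 10L, "N"),
    rec1("salt_bridge", "Arg", 12L, "O"),
    rec1("hydrogen_bond", "Tyr", 14L, "O"))
  cx <- toy_assigned_complex("GlyRS", recs)
  fp <- fp_seq(cx[1, ])
  expect_identical(length(fp$bits), 2L)
  expect_identical(fp$length, 20L)
  expect_setequal(standard_residues()[fp$bits], c("Arg", "Tyr"))

  empty <- toy_assigned_complex("GlyRS")
  expect_identical(fp_seq(empty[1, ])$bits, integer(0))

  # all 20 residue types light all 20 bits; metals and UNK never do
  recs20 <- do.call(dplyr::bind_rows, lapply(seq_along(standard_residues()),
    function(i) rec1("hydrogen_bond", standard_residues()[i],
                     100L + i, "N")))
  recs20 <- dplyr::bind_rows(recs20, rec1("metal_complex", "ZN", 900L, "N"))
  full <- toy_assigned_complex("GlyRS", recs20)
  expect_identical(length(fp_seq(full[1, ])$bits), 20L)
})

test_that("the hashed interaction segment is idempotent and in range", {
  one <- toy_assigned_complex(
    "GlyRS", rec1("hydrogen_bond", "Tyr", 10L, "O"))
  fp <- fp_int(one[1, ])
  expect_identical(length(fp$bits), 1L)
  expect_true(fp$bits >= 1 && fp$bits <= 500)
  expect_identical(fp$length, 500L)

  dup <- toy_assigned_complex(
    "GlyRS", dplyr::bind_rows(rec1("hydrogen_bond", "Tyr", 10L, "O"),
                              rec1("hydrogen_bond", "Tyr", 44L, "O")))
  expect_identical(fp_int(dup[1, ])$bits, fp$bits)

  # record order never matters
  r <- dplyr::bind_rows(rec1("hydrogen_bond", "Tyr", 10L, "O"),
                        rec1("hydrophobic", "Leu", 11L, "CA"))
  a <- fp_int(toy_assigned_complex("GlyRS", r)[1, ])
  b <- fp_int(toy_assigned_complex("GlyRS", r[2:1, ])[1, ])
  expect_identical(a$bits, b$bits)
})

test_that("hash collisions over the realizable feature vocabulary stay below 10%", {
  diag <- hash_collision_diagnostic()
  expect_lt(diag$collision_rate, 0.10)
  expect_identical(diag$n_features, 76L)
})

test_that("the editing segment mirrors the editing table in fixed ligand order", {
  fp <- fp_editing("ThrRS")
  expect_identical(fp$length, 22L)
  expect_identical(ligand_codes()[fp$bits], "Ser")

  expect_identical(fp_editing("GlyRS")$bits, integer(0))

  tab <- aarsfp:::new_editing_table(list(ValRS = c("Thr", "Ala", "Cys")))
  expect_identical(length(fp_editing("ValRS", tab)$bits), 3L)
})

test_that("volume binning is one-hot over half-open 20 A^3 bins with clamping", {
  expect_identical(fp_volume(45)$bits, 1L)
  expect_identical(fp_volume(52)$bits, 2L)
  expect_identical(fp_volume(300)$bits, 12L)
  expect_identical(fp_volume(5)$bits, 1L)
  expect_identical(fp_volume(50 - 1e-9)$bits, 1L)
  expect_identical(fp_volume(50)$bits, 2L)
  expect_error(fp_volume(-1), "> 0")

  for (v in seq(11, 400, by = 7)) {
    fp <- fp_volume(v)
    expect_identical(length(fp$bits), 1L)
    expect_identical(fp$length, 12L)
  }
})

test_that("concatenation produces the documented design widths", {
  cx <- toy_assigned_complex("ThrRS",
                             rec1("hydrogen_bond", "Arg", 538L, "OG1"))
  obj <- aarsfp:::set_to_complexes(cx)[[1]]
  segs <- list(seq = fp_seq(obj), int = fp_int(obj),
               editing = fp_editing("ThrRS"), volume = fp_volume(100))
  expect_identical(fp_concat(segs, "seq_int_ed_vol")$length, 534L)
  expect_identical(fp_concat(segs, "seq_sim")$length, 20L)
  expect_identical(fp_concat(segs, "ed")$length, 22L)
  expect_identical(fp_concat(segs, "seq_int_ed")$length, 522L)
  expect_error(fp_concat(segs[c("seq", "int")], "seq_int_ed_vol"),
               "editing")
})

test_that("Jaccard distance follows the active-bit formula with the all-zero convention", {
  mk <- function(bits) aarsfp:::new_fingerprint(bits, 10L, "t")
  expect_equal(jaccard_distance(mk(1:3), mk(1:3)), 0)
  expect_equal(jaccard_distance(mk(1:3), mk(4:6)), 1)
  expect_equal(jaccard_distance(mk(1:3), mk(2:4)), 0.5)
  expect_equal(jaccard_distance(mk(integer(0)), mk(integer(0))), 0)
  expect_error(
    jaccard_distance(mk(1), aarsfp:::new_fingerprint(1, 8L, "t")),
    "length")
})

test_that("Jaccard distance is a metric on random fingerprint triples", {
  set.seed(77)
  for (i in 1:200) {
    a <- random_fp(60); b <- random_fp(60); c <- random_fp(60)
    dab <- jaccard_distance(a, b)
    dbc <- jaccard_distance(b, c)
    dac <- jaccard_distance(a, c)
    expect_gte(dab, 0); expect_lte(dab, 1)
    expect_equal(dab, jaccard_distance(b, a))
    expect_lte(dac, dab + dbc + 1e-12)
    if (identical(a$bits, b$bits)) expect_equal(dab, 0)
  }
})

test_that("distance matrices agree with pairwise calls and validate inputs", {
  cx <- assign_specificity_interactions(
    generate_complexes(default_spec(), n_per_aars = 2, seed = 9))
  fps <- build_fingerprints(cx, "seq_int_ed_vol")
  dm <- distance_matrix(fps)
  expect_true(isSymmetric(unname(dm)))
  expect_equal(unname(diag(dm)), rep(0, nrow(fps)))
  expect_true(all(dm >= 0 & dm <= 1))
  for (idx in list(c(1, 5), c(2, 40), c(13, 22))) {
    expect_equal(dm[idx[1], idx[2]],
                 jaccard_distance(fps$fingerprint[[idx[1]]],
                                  fps$fingerprint[[idx[2]]]))
  }

  mixed <- fps
  mixed$fingerprint[[1]] <- fp_volume(100)
  mixed$variant[1] <- "vol"
  expect_error(distance_matrix(mixed), "mixed")

  # identical fingerprints give a zero matrix; disjoint supports give 1
  same <- fps[c(1, 1, 1), ]
  class(same) <- class(fps)
  expect_equal(max(distance_matrix(same)), 0)
})

test_that("volume-requiring designs demand volumes", {
  cx <- generate_complexes(default_spec(), n_per_aars = 1, seed = 2)
  cx$cavity_volume[3] <- NA_real_
  cx <- assign_specificity_interactions(cx)
  expect_error(build_fingerprints(cx, "seq_int_ed_vol"), "cavity volumes")
  expect_silent(invisible(build_fingerprints(cx, "seq_int_ed")))
})
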