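make_aars_set <- function(aars, per_structure_records, volume = 100) {
  objs <- lapply(seq_along(per_structure_records), function(i) {
    structure_complex(
      structure_id = sprintf("OCC-%02d_A", i), aars = aars,
      ligand_graph = aarsfp:::synthetic_ligand_graph(aars_ligand(aars),
                                                     "pre_activation"),
      interactions = per_structure_records[[i]],
      reaction_state = "pre_activation", kingdom = "synthetic",
      cavity_volume = volume)
  })
  assign_specificity_interactions(complex_set(objs))
}

test_that("occupancy is per-structure presence with the cutoff applied at >=", {
  hbN <- rec1("hydrogen_bond", "Asp", 101L, "N")
  sbO <- rec1("salt_bridge", "Arg", 135L, "O")
  # 10 structures: 9 with the backbone hbond, 1 with a salt bridge at O
  recs <- c(replicate(9, hbN, simplify = FALSE),
            list(dplyr::bind_rows(hbN, sbO)[2, ]))
  cx <- make_aars_set("GlyRS", recs)
  prof <- compute_occupancy(cx, cutoff = 0.1)
  expect_equal(
    prof$occupancy[prof$scaffold_atom == "N" &
                     prof$itype == "hydrogen_bond"], 0.9)
  # 1/10 = 0.1 is exactly at the cutoff: retained ("below 0.1" is strict)
  expect_equal(
    prof$occupancy[prof$scaffold_atom == "O" &
                     prof$itype == "salt_bridge"], 0.1)

  # 1/20 = 0.05 falls below the cutoff: removed
  recs20 <- c(replicate(19, hbN, simplify = FALSE), list(sbO))
  prof20 <- compute_occupancy(make_aars_set("GlyRS", recs20), cutoff = 0.1)
  expect_false(any(prof20$itype == "salt_bridge"))
})

test_that("duplicate records within one structure do not inflate occupancy", {
  hbN <- rec1("hydrogen_bond", "Asp", 101L, "N")
  dup <- dplyr::bind_rows(hbN, hbN, hbN)
  cx <- make_aars_set("GlyRS", list(dup, hbN))
  prof <- compute_occupancy(cx)
  expect_equal(prof$occupancy[prof$scaffold_atom == "N"], 1)
  expect_equal(attr(prof, "n_structures"), 2L)
})

test_that("mixed aaRS labels are rejected", {
  a <- make_aars_set("GlyRS", list(rec1("hydrogen_bond", "Asp", 1L, "N")))
  b <- make_aars_set("AlaRS", list(rec1("hydrogen_bond", "Asp", 1L, "N")))
  both <- dplyr::bind_rows(a, b)
  class(both) <- class(a)
  expect_error(compute_occupancy(both), "single aaRS")
})

test_that("class frequency percentages reproduce printed-table arithmetic", {
  # Class I printed counts: percentages under half-up rounding
  expect_equal(interaction_percentages(c(468, 550, 153, 59, 3)),
               c(37.96, 44.61, 12.41, 4.79, 0.24))
  # Class II printed counts
  expect_equal(interaction_percentages(c(856, 193, 202, 144, 50)),
               c(59.24, 13.36, 13.98, 9.97, 3.46))
  expect_equal(interaction_percentages(c(0, 7, 0)), c(0, 100, 0))
})

test_that("class_frequency_table counts records, excludes water bridges, sums to 100", {
  hbN <- rec1("hydrogen_bond", "Asp", 101L, "N")
  wb <- interaction_records(itype = "water_bridge",
                            protein_residue_type = "Ser",
                            protein_residue_number = 9L, chain_id = "A",
                            ligand_atom_ids = list("N"))
  g <- make_aars_set("GlyRS", list(dplyr::bind_rows(hbN, hbN, wb)))
  a <- make_aars_set("ValRS", list(rec1("hydrophobic", "Trp", 456L, "CG1")))
  both <- dplyr::bind_rows(g, a)
  class(both) <- class(g)
  tab <- class_frequency_table(both)
  # duplicate records count twice (record counting, not structure presence)
  expect_equal(tab$count[tab$aars_class == "II" &
                           tab$itype == "hydrogen_bond"], 2L)
  expect_false("water_bridge" %in% tab$itype)
  sums <- tapply(tab$percent, tab$aars_class, sum)
  expect_true(all(abs(sums - 100) <= 0.02))
  totals <- attr(tab, "totals")
  expect_equal(sum(totals$total), sum(tab$count))
})

test_that("side-chain summaries exclude backbone contacts and use MSA numbering", {
  recs <- dplyr::bind_rows(
    rec1("hydrophobic", "Val", 293L, "CB"),
    rec1("hydrogen_bond", "Asp", 101L, "N"))
  cx <- make_aars_set("AlaRS", list(recs))
  map <- msa_renumber(paste(rep("A", 300), collapse = ""),
                      paste(rep("A", 300), collapse = ""), 1:300)
  out <- summarize_side_chain_recognition(
    cx, renumber_maps = stats::setNames(list(map), cx$structure_id))
  expect_identical(nrow(out), 1L)
  expect_identical(out$residue_type, "Val")
  expect_identical(out$position, 293L)
  expect_true(out$msa_mapped)
  expect_identical(out$itype, "hydrophobic")

  # backbone-only profile gives an empty summary
  bb <- make_aars_set("AlaRS", list(rec1("hydrogen_bond", "Asp", 101L,
                                         "N")))
  expect_identical(nrow(summarize_side_chain_recognition(bb)), 0L)

  # missing renumbering map: flagged, original numbering, warning
  expect_warning(
    out2 <- summarize_side_chain_recognition(cx, renumber_maps = list()),
    "no renumbering map")
  expect_false(out2$msa_mapped)
  expect_identical(out2$position, 293L)
})

test_that("residue-count/ligand-size correlation matches cor.test and guards degenerate input", {
  mk <- function(aars, n_res) {
    recs <- do.call(dplyr::bind_rows, lapply(seq_len(n_res), function(j) {
      rec1("hydrogen_bond", "Asp", 100L + j, "N")
    }))
    make_aars_set(aars, list(recs))
  }
  sizes <- vapply(c("GlyRS", "AlaRS", "SerRS", "ValRS", "TrpRS"),
                  function(a) nrow(build_scaffold(aars_ligand(a))$atoms),
                  numeric(1))
  # residue counts proportional to ligand size give r = 1
  sets <- purrr::map2(names(sizes), sizes, mk)
  all5 <- do.call(dplyr::bind_rows, sets)
  class(all5) <- class(sets[[1]])
  out <- residue_count_ligand_size_correlation(all5)
  expect_equal(out$r, 1, tolerance = 1e-12)

  # hand-checkable non-trivial counts: compare to the textbook formula
  counts <- c(3, 2, 6, 4, 9)
  sets2 <- purrr::map2(names(sizes), counts, mk)
  all52 <- do.call(dplyr::bind_rows, sets2)
  class(all52) <- class(sets2[[1]])
  out2 <- residue_count_ligand_size_correlation(all52)
  expect_equal(out2$r, unname(stats::cor(counts, sizes)),
               tolerance = 1e-12)

  # constant counts: zero variance is an error
  sets3 <- purrr::map2(names(sizes), rep(2, 5), mk)
  all53 <- do.call(dplyr::bind_rows, sets3)
  class(all53) <- class(sets3[[1]])
  expect_error(residue_count_ligand_size_correlation(all53),
               "zero variance")

  two <- do.call(dplyr::bind_rows, sets[1:2])
  class(two) <- class(sets[[1]])
  expect_error(residue_count_ligand_size_correlation(two), ">= 3")
})

test_that("Mann-Whitney U matches enumeration and wilcox.test where comparable", {
  out <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(out$U, 0)

  same <- mann_whitney_u(c(2, 2, 5), c(2, 2, 5))
  expect_equal(same$p_value, 1)

  # exhaustive check against an independent enumeration over all C(5,3)
  # arrangements of the pooled sample
  x <- c(1, 3, 5); y <- c(2, 4)
  got <- mann_whitney_u(x, y)
  pooled <- c(x, y)
  combos <- utils::combn(5, 3)
  u_of <- function(xx, yy) sum(outer(xx, yy, ">")) +
    0.5 * sum(outer(xx, yy, "=="))
  us <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  p_want <- mean(abs(us - 3) >= abs(got$U - 3))
  expect_equal(got$p_value, p_want)
  expect_equal(got$U, u_of(x, y))

  # tie-free large samples agree with wilcox.test's normal approximation
  set.seed(5)
  a <- stats::rnorm(25); b <- stats::rnorm(30, 0.7)
  got2 <- mann_whitney_u(a, b)
  ref <- stats::wilcox.test(a, b, exact = FALSE, correct = FALSE)
  expect_equal(got2$U, unname(ref$statistic))
  expect_equal(got2$p_value, ref$p.value, tolerance = 1e-10)

  expect_error(mann_whitney_u(numeric(0), 1), "non-empty")
})

test_that("Spearman correlation handles ties, direction, and length guards", {
  expect_equal(spearman_rho(1:6, 1:6)$rho, 1)
  expect_equal(spearman_rho(1:6, 6:1)$rho, -1)
  d1 <- c(1.2, 3.4, 2.2, 5.0, 4.1, 0.3)
  d2 <- c(0.8, 2.9, 3.1, 4.4, 4.0, 1.1)
  expect_equal(spearman_rho(d1, d2)$rho,
               unname(stats::cor(rank(d1), rank(d2))), tolerance = 1e-12)
  expect_error(spearman_rho(1:3, 1:4), "equal length")
})

test_that("physicochemical distance table covers the 20 standard residues", {
  m <- physicochemical_distances()
  expect_identical(dim(m), c(20L, 20L))
  expect_identical(rownames(m), standard_residues())
  expect_true(isSymmetric(m))
  # Ile and Leu side chains are nearly iso-hydrophobic
  expect_lt(m["Ile", "Leu"], m["Ile", "Arg"])
})
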