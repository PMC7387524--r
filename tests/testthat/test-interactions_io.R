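plip_fixture <- function(body) {
  f <- withr::local_tempfile(fileext = ".xml", .local_envir = parent.frame())
  writeLines(c("<report><bindingsite><interactions>", body,
               "</interactions></bindingsite></report>"), f)
  f
}

hb <- function(resnr, acceptor = "3") paste0(
  "<hydrogen_bond><restype>TYR</restype><resnr>", resnr,
  "</resnr><reschain>A</reschain><protisdon>True</protisdon>",
  "<donoridx>0</donoridx><acceptoridx>", acceptor,
  "</acceptoridx></hydrogen_bond>")

test_that("PLIP reports parse into typed interaction records", {
  f <- plip_fixture(c("<hydrogen_bonds>", hb(10), "</hydrogen_bonds>"))
  rec <- read_plip_report(f)
  expect_identical(nrow(rec), 1L)
  expect_identical(rec$itype, "hydrogen_bond")
  expect_identical(rec$protein_residue_number, 10L)
  expect_identical(rec$ligand_atom_ids[[1]], "3")
  expect_false(rec$excluded)
})

test_that("water bridges are parsed but flagged excluded", {
  f <- plip_fixture(c(
    "<hydrogen_bonds>", hb(10), hb(11), "</hydrogen_bonds>",
    "<water_bridges><water_bridge><restype>SER</restype><resnr>12</resnr>",
    "<reschain>A</reschain><protisdon>False</protisdon>",
    "<donor_idx>7</donor_idx><acceptor_idx>0</acceptor_idx>",
    "</water_bridge></water_bridges>"))
  rec <- read_plip_report(f)
  expect_identical(nrow(rec), 3L)
  expect_identical(sum(rec$excluded), 1L)
  expect_identical(rec$itype[rec$excluded], "water_bridge")
})

test_that("unknown interaction elements are skipped with a warning", {
  f <- plip_fixture(c(
    "<hydrogen_bonds>", hb(10), "</hydrogen_bonds>",
    "<halogen_bonds><halogen_bond><restype>MET</restype><resnr>9</resnr>",
    "<reschain>A</reschain></halogen_bond></halogen_bonds>"))
  expect_warning(rec <- read_plip_report(f), "halogen_bond")
  expect_identical(nrow(rec), 1L)
})

test_that("contacts without ligand serials are skipped with a warning", {
  f <- plip_fixture(
    paste0("<hydrophobic_interactions><hydrophobic_interaction>",
           "<restype>LEU</restype><resnr>4</resnr><reschain>A</reschain>",
           "</hydrophobic_interaction></hydrophobic_interactions>"))
  expect_warning(rec <- read_plip_report(f), "without ligand atom serial")
  expect_identical(nrow(rec), 0L)
})

test_that("the PLIP writer and reader round-trip every record type", {
  rec <- dplyr::bind_rows(
    rec1("hydrogen_bond", "TYR", 10L, "N"),
    rec1("hydrophobic", "LEU", 11L, "CB"),
    rec1("salt_bridge", "ARG", 12L, c("O", "OXT")),
    rec1("pi_stacking", "PHE", 13L, c("CG", "CD1", "CD2", "CE1", "CE2",
                                      "CZ")),
    rec1("metal_complex", "ZN", 14L, "SG"))
  f <- withr::local_tempfile(fileext = ".xml")
  write_plip_xml(rec, f)
  back <- read_plip_report(f)
  expect_identical(back$itype, rec$itype)
  expect_identical(back$protein_residue_number, rec$protein_residue_number)
  expect_identical(back$ligand_atom_ids, rec$ligand_atom_ids)
  expect_identical(back$protein_residue_type[5], "ZN")
})

test_that("MSA reading validates widths and preserves gaps", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">s1", "ACDEF", ">s2", "ACDEF"), f)
  aln <- read_msa(f)
  expect_identical(attr(aln, "width"), 5L)

  writeLines(c(">s1", "AC-EF", ">s2", "ACDEF"), f)
  aln <- read_msa(f)
  expect_identical(unname(aln["s1"]), "AC-EF")

  writeLines(c(">s1", "ACDEF", ">shorty", "ACD"), f)
  expect_error(read_msa(f), "shorty")
})

test_that("coordinate tables read with last-wins duplicate handling", {
  f <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(atom_id = c("N", "CA", "C", "O", "CB"),
                              x = 1:5, y = 1:5, z = 1:5),
                   f, row.names = FALSE)
  co <- read_coordinates(f)
  expect_identical(nrow(co), 5L)

  utils::write.csv(data.frame(atom_id = c("N", "N"), x = c(1, 9),
                              y = 0, z = 0), f, row.names = FALSE)
  expect_warning(co <- read_coordinates(f), "last occurrence wins")
  expect_equal(co$x, 9)

  utils::write.csv(data.frame(id = "N", x = 1), f, row.names = FALSE)
  expect_error(read_coordinates(f), "columns")
})

test_that("PDB coordinates resolve a named ligand or fail clearly", {
  skip_if_not_installed("bio3d")
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(c(
    sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            "HETATM", 1, "N", "ALA", "A", 1, 1.0, 2.0, 3.0, 1.0, 0.0),
    sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f",
            "HETATM", 2, "CA", "ALA", "A", 1, 2.5, 2.0, 3.0, 1.0, 0.0),
    "END"), f)
  co <- read_coordinates(f, ligand_resname = "ALA")
  expect_identical(nrow(co), 2L)
  expect_equal(co$x[co$atom_id == "CA"], 2.5)
  expect_error(read_coordinates(f, ligand_resname = "TRP"), "not found")
})
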