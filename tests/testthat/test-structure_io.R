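test_that("toy PDB parses into atoms, one polymer residue and one ligand", {
  tf <- tempfile(fileext = ".pdb")
  write_toy_pdb(tf, resolution = 1.10)
  s <- read_structure(tf)
  expect_s3_class(s, "shb_structure")
  expect_equal(nrow(s$atoms), 13)
  prot <- s$atoms[!s$atoms$het, ]
  expect_equal(unique(prot$resname), "SER")
  expect_length(s$ligands, 1)
  expect_equal(s$ligands[[1]]$code, "GOL")
  expect_equal(s$resolution, 1.10)
  # glycerol connectivity is a connected graph
  b <- s$ligands[[1]]$bonds
  expect_gte(nrow(b), 5)
})

test_that("mmCIF content gives identical atoms and coordinates as PDB", {
  tp <- tempfile(fileext = ".pdb"); tc <- tempfile(fileext = ".cif")
  write_toy_pdb(tp); write_toy_cif(tc)
  sp <- read_structure(tp); sc <- read_structure(tc)
  expect_equal(nrow(sp$atoms), nrow(sc$atoms))
  expect_equal(sp$atoms$name, sc$atoms$name)
  expect_equal(sp$atoms$x, sc$atoms$x, tolerance = 1e-6)
  expect_equal(sp$atoms$z, sc$atoms$z, tolerance = 1e-6)
})

test_that("files without atom records are rejected with a parse error", {
  tf <- tempfile(fileext = ".pdb")
  writeLines(c("HEADER    NOTHING", "END"), tf)
  expect_error(read_structure(tf), "no ATOM/HETATM")
  expect_error(read_structure(tempfile(fileext = ".pdb")), "not found")
})

test_that("PDB round trip preserves names and coordinates to 1e-3", {
  out <- synth_complex(list(plant_spec(2.5, 170),
                            plant_spec(3.0, 150, lig_group = "phenol")),
                       seed = 3)
  tf <- tempfile(fileext = ".pdb")
  write_structure(out$structure, tf)
  s2 <- read_structure(tf)
  expect_equal(nrow(s2$atoms), nrow(out$structure$atoms))
  expect_equal(s2$atoms$name, out$structure$atoms$name)
  expect_equal(s2$atoms$x, out$structure$atoms$x, tolerance = 1e-3)
  expect_equal(s2$atoms$y, out$structure$atoms$y, tolerance = 1e-3)
  expect_equal(s2$atoms$z, out$structure$atoms$z, tolerance = 1e-3)
})

test_that("ligand selection drops crystallization agents and O/N-free groups", {
  tf <- tempfile(fileext = ".pdb")
  lines <- c(
    pdb_atom_line(1, "N", "SER", "A", 1, c(0, 0, 0)),
    pdb_atom_line(2, "CA", "SER", "A", 1, c(1.46, 0, 0)),
    pdb_atom_line(3, "O1", "GOL", "B", 101, c(10, 0, 0), het = TRUE),
    pdb_atom_line(4, "C1", "GOL", "B", 101, c(11.4, 0, 0), het = TRUE),
    pdb_atom_line(5, "S", "SO4", "B", 102, c(20, 0, 0), het = TRUE),
    pdb_atom_line(6, "O1", "SO4", "B", 102, c(21.4, 0, 0), het = TRUE),
    pdb_atom_line(7, "O7N", "NAP", "B", 103, c(30, 0, 0), het = TRUE,
                  element = "O"),
    pdb_atom_line(8, "C7N", "NAP", "B", 103, c(31.2, 0, 0), het = TRUE),
    pdb_atom_line(9, "FE", "HEM", "B", 104, c(40, 0, 0), het = TRUE,
                  element = "FE"),
    pdb_atom_line(10, "O1A", "HEM", "B", 104, c(42, 0, 0), het = TRUE,
                  element = "O"),
    pdb_atom_line(11, "C1", "DCY", "B", 105, c(50, 0, 0), het = TRUE),
    "END")
  writeLines(lines, tf)
  s <- read_structure(tf)
  kept <- vapply(select_ligands(s), `[[`, character(1), "code")
  expect_setequal(kept, c("NAP", "HEM"))
  # idempotent and order-independent
  expect_identical(kept,
                   vapply(select_ligands(s), `[[`, character(1), "code"))
})

test_that("water is always excluded even from a custom policy", {
  pol <- ligand_exclusion_policy(extra = "XYZ")
  expect_true(all(c("HOH", "WAT", "XYZ") %in% pol))
  expect_false(any(duplicated(pol)))
})

test_that("sequence context matches chain order with terminus padding", {
  tf <- tempfile(fileext = ".pdb")
  write_chain_pdb(tf, c("GLY", "SER", "GLU", "ASP", "GLY", "THR", "ASP"))
  s <- read_structure(tf)
  expect_equal(sequence_context(s, "A", 4),
               c("GLY", "SER", "GLU", "GLY", "THR", "ASP"))
  # N-terminal residue of a 5-mer
  tf2 <- tempfile(fileext = ".pdb")
  write_chain_pdb(tf2, c("ALA", "VAL", "LEU", "ILE", "MET"))
  s2 <- read_structure(tf2)
  expect_equal(sequence_context(s2, "A", 1),
               c("XTR", "XTR", "XTR", "VAL", "LEU", "ILE"))
  expect_equal(sequence_context(s2, "A", 5),
               c("VAL", "LEU", "ILE", "XTR", "XTR", "XTR"))
  expect_length(sequence_context(s2, "A", 3, window = 0), 0)
  for (w in 1:4)
    expect_length(sequence_context(s2, "A", 2, window = w), 2 * w)
  expect_error(sequence_context(s2, "A", 99), "not found")
})

test_that("alternate conformers collapse to the highest-occupancy one", {
  tf <- tempfile(fileext = ".pdb")
  lines <- c(
    "ATOM      1  N  ASER A   1       0.000   0.000   0.000  0.40  0.00           N",
    "ATOM      2  N  BSER A   1       0.500   0.000   0.000  0.60  0.00           N",
    "ATOM      3  CA  SER A   1       1.460   0.000   0.000  1.00  0.00           C",
    "END")
  writeLines(lines, tf)
  s <- read_structure(tf)
  expect_equal(nrow(s$atoms), 2)
  expect_equal(s$atoms$x[s$atoms$name == "N"], 0.5)
})
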