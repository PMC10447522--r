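# One hand-built molecule per functional group, classified against
# hand-assigned truth.

test_that("the functional-group pattern deck classifies 11/11", {
  # phenol: OH on an aromatic ring
  g <- make_graph(c(rep("C", 6), "O"), rbind(ring6(), bonds_df(1, 7, 1)))
  expect_equal(detect_functional_group(g, 7), "phenol")

  # alkyl hydroxyl: ethanol C-C-O
  g <- make_graph(c("C", "C", "O"), bonds_df(1, 2, 1, 2, 3, 1))
  expect_equal(detect_functional_group(g, 3), "alkyl_hydroxyl")

  # sulfate: O on S
  g <- make_graph(c("S", "O", "O", "O", "O", "C"),
                  bonds_df(1, 2, 2, 1, 3, 2, 1, 4, 1, 1, 5, 1, 5, 6, 1))
  expect_equal(detect_functional_group(g, 4), "sulfate")

  # phosphate: O on P (bridging O also counts)
  g <- make_graph(c("P", "O", "O", "O", "O", "C"),
                  bonds_df(1, 2, 2, 1, 3, 1, 1, 4, 1, 1, 5, 1, 5, 6, 1))
  expect_equal(detect_functional_group(g, 3), "phosphate")
  expect_equal(detect_functional_group(g, 5), "phosphate")

  # carboxylate: deprotonated acid, both oxygens terminal, no H
  g <- make_graph(c("C", "C", "O", "O"),
                  bonds_df(1, 2, 1, 2, 3, 2, 2, 4, 1))
  expect_equal(detect_functional_group(g, 3), "carboxylate")
  expect_equal(detect_functional_group(g, 4), "carboxylate")

  # carboxyl: explicit H on one oxygen flips the protonation state
  g <- make_graph(c("C", "C", "O", "O", "H"),
                  bonds_df(1, 2, 1, 2, 3, 2, 2, 4, 1, 4, 5, 1))
  expect_equal(detect_functional_group(g, 4), "carboxyl")
  expect_equal(detect_functional_group(g, 3), "carboxyl")

  # ester: carbonyl O and bridging O
  g <- make_graph(c("C", "C", "O", "O", "C"),
                  bonds_df(1, 2, 1, 2, 3, 2, 2, 4, 1, 4, 5, 1))
  expect_equal(detect_functional_group(g, 3), "ester")
  expect_equal(detect_functional_group(g, 4), "ester")

  # amide: carbonyl C bonded to N
  g <- make_graph(c("C", "C", "O", "N"),
                  bonds_df(1, 2, 1, 2, 3, 2, 2, 4, 1))
  expect_equal(detect_functional_group(g, 3), "amide")
  expect_equal(detect_functional_group(g, 4), "amide")

  # alkyl amine
  g <- make_graph(c("C", "C", "N"), bonds_df(1, 2, 1, 2, 3, 1))
  expect_equal(detect_functional_group(g, 3), "alkyl_amine")

  # N-containing aromatic heterocycle: pyridine
  g <- make_graph(c(rep("C", 5), "N"), ring6())
  expect_equal(detect_functional_group(g, 6), "n_aromatic")

  # no pattern: plain ether oxygen
  g <- make_graph(c("C", "O", "C"), bonds_df(1, 2, 1, 2, 3, 1))
  expect_equal(detect_functional_group(g, 2), "OTHER")
})

test_that("non-heteroatom queries are rejected", {
  g <- make_graph(c("C", "O"), bonds_df(1, 2, 1))
  expect_error(detect_functional_group(g, 1), "O or N")
  expect_error(detect_functional_group(g, 99), "not part")
})

test_that("classification is coordinate-free: rotation changes nothing", {
  out <- synth_complex(list(plant_spec(2.5, 170, lig_group = "phenol"),
                            plant_spec(2.6, 160, lig_group = "phosphate")),
                       seed = 5)
  s <- out$structure
  ligs <- select_ligands(s)
  before <- lapply(ligs, function(lg) {
    g <- ligand_graph(s, lg)
    o <- lg$atoms[s$atoms$element[lg$atoms] == "O"]
    vapply(o, function(i) detect_functional_group(g, i), character(1))
  })
  th <- 1.2
  Ry <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3, 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(Ry)
  s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  s_rot <- structure_model(s$atoms)   # re-derives connectivity from scratch
  ligs_rot <- select_ligands(s_rot)
  after <- lapply(ligs_rot, function(lg) {
    g <- ligand_graph(s_rot, lg)
    o <- lg$atoms[s_rot$atoms$element[lg$atoms] == "O"]
    vapply(o, function(i) detect_functional_group(g, i), character(1))
  })
  expect_equal(before, after)
})

test_that("taxonomy maps each group to exactly one propensity type", {
  tax <- functional_group_taxonomy()
  expect_length(tax, 10)
  expect_equal(unname(tax["phenol"]), "L1")
  expect_equal(unname(tax["alkyl_hydroxyl"]), "L2")
  expect_setequal(names(tax)[tax == "L3"],
                  c("sulfate", "phosphate", "carboxyl", "carboxylate"))
  expect_setequal(names(tax)[tax == "L4"],
                  c("ester", "amide", "alkyl_amine", "n_aromatic"))
  aat <- amino_acid_typing()
  expect_setequal(names(aat)[aat == "A1"], c("TYR", "ASP", "GLU"))
  expect_setequal(names(aat)[aat == "A2"], c("SER", "THR", "HIS"))
  expect_setequal(names(aat)[aat == "A3"],
                  c("ARG", "LYS", "ASN", "GLN", "TRP"))
})
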