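test_that("amino-acid descriptors follow the pH-7 charge table", {
  expect_equal(amino_acid_descriptors("TYR", "OH"),
               list(aa_charge = 0, aa_residue = "TYR", aa_heteroatom = "OH"))
  expect_equal(amino_acid_descriptors("ASP", "OD1")$aa_charge, -1)
  expect_equal(amino_acid_descriptors("GLU", "OE2")$aa_charge, -1)
  expect_equal(amino_acid_descriptors("LYS", "NZ")$aa_charge, 1)
  expect_equal(amino_acid_descriptors("ARG", "NH1")$aa_charge, 1)
  expect_equal(amino_acid_descriptors("HIS", "NE2",
                                      charge_overrides = c(HIS = 1))$aa_charge,
               1)
  expect_error(amino_acid_descriptors("XXX", "O"), "unknown residue")
})

test_that("physchem table values pass through; fallback is controllable", {
  tf <- tempfile(fileext = ".csv")
  writeLines(c("code,pKa,pKb,logP", "NAP,3.9,10.5,-5.1"), tf)
  tb <- read_physchem_table(tf)
  d <- ligand_descriptors("NAP", "phosphate", table = tb)
  expect_equal(d$lig_pKa, 3.9)
  expect_equal(d$lig_pKb, 10.5)
  expect_equal(d$lig_logP, -5.1)
  expect_equal(d$provenance, "table")
  # absent from table, fallback disabled -> explicit missing
  d2 <- ligand_descriptors("ZZZ", "phenol", table = tb, fallback = FALSE)
  expect_true(is.na(d2$lig_pKa) && is.na(d2$lig_logP))
  expect_equal(d2$provenance, "missing")
  # malformed numeric cell
  tf2 <- tempfile(fileext = ".csv")
  writeLines(c("code,pKa,pKb,logP", "BAD,abc,1,2"), tf2)
  expect_error(read_physchem_table(tf2), "non-numeric")
})

test_that("fallback logP matches an independent Crippen computation", {
  # ethanol, hand-summed from the published atomic contributions:
  # CH3 0.1441 + CH2(-O) -0.2035 + OH -0.2893 + 5 H(C) 0.1230 + H(O) -0.2677
  ethanol_oracle <- 0.1441 - 0.2035 - 0.2893 + 5 * 0.1230 - 0.2677
  g <- make_graph(c("C", "C", "O"), bonds_df(1, 2, 1, 2, 3, 1))
  expect_equal(estimate_logp(g), ethanol_oracle, tolerance = 0.3)
  # phenol against the same scheme (reference value 1.39)
  gp <- make_graph(c(rep("C", 6), "O"), rbind(ring6(), bonds_df(1, 7, 1)))
  expect_equal(estimate_logp(gp), 1.39, tolerance = 0.3)
})

test_that("feature vectors carry all 14 predictors from the structure", {
  out <- synth_complex(list(plant_spec(2.64, 165, lig_group = "phosphate"),
                            plant_spec(2.56, 168,
                                       lig_group = "alkyl_hydroxyl",
                                       donor = "ligand")), seed = 2)
  s <- place_polar_hydrogens(out$structure)
  hb <- detect_hbonds(s)
  ft <- build_feature_table(hb, s)
  expect_true(all(shbligand:::FEATURE_COLUMNS %in% names(ft)))
  ser <- ft[ft$aa_residue == "SER", ]
  expect_equal(nrow(ser), 1)
  expect_equal(ser$lig_functional_group, "phosphate")
  expect_equal(ser$aa_heteroatom, "OG")
  asp <- ft[ft$aa_residue == "ASP", ]
  expect_equal(asp$lig_functional_group, "alkyl_hydroxyl")
  expect_equal(asp$aa_charge, -1)
  expect_equal(asp$label, "SHB")
  # site at residue 2: only one N-terminal neighbor exists
  expect_equal(ser$seq_m3, "XTR")
  expect_equal(ser$seq_m2, "XTR")
  expect_equal(ser$seq_m1, "GLY")
})

test_that("feature tables round-trip losslessly through TSV", {
  out <- synth_complex(list(plant_spec(2.5, 170)), seed = 4)
  s <- place_polar_hydrogens(out$structure)
  ft <- build_feature_table(detect_hbonds(s), s)
  tf <- tempfile(fileext = ".tsv")
  write_feature_table(ft, tf)
  ft2 <- read_feature_table(tf)
  for (col in shbligand:::FEATURE_COLUMNS) {
    if (is.numeric(ft[[col]]))
      expect_equal(ft2[[col]], ft[[col]], tolerance = 1e-9)
    else expect_equal(ft2[[col]], ft[[col]])
  }
  expect_equal(ft2$label, ft$label)
})

test_that("backbone protein partners are rejected", {
  out <- synth_complex(list(plant_spec(2.5, 170)), seed = 4)
  s <- place_polar_hydrogens(out$structure)
  hb <- detect_hbonds(s)
  hb$donor_atom[1] <- "N"   # simulate a backbone amide partner
  expect_error(build_feature_vector(hb[1, ], s), "backbone")
})
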