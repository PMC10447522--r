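test_that("distance classification follows the SHB/NHB windows", {
  expect_equal(classify_r(2.56), "SHB")
  expect_equal(classify_r(2.75), "AMBIGUOUS")
  expect_equal(classify_r(3.00), "NHB")
  expect_equal(classify_r(2.20), "OUT_OF_RANGE")
  expect_equal(classify_r(3.50), "OUT_OF_RANGE")
  expect_equal(classify_r(c(2.3, 2.7, 2.8, 3.2)),
               c("SHB", "SHB", "NHB", "NHB"))
  expect_error(classify_r(-1), "positive")
  expect_error(classify_r(0), "positive")
})

test_that("idealized hydrogens are placed on donors with correct geometry", {
  out <- synth_complex(list(plant_spec(2.5, 170)), seed = 1)
  s <- out$structure
  # strip the planted hydrogens to force placement
  s$atoms <- s$atoms[s$atoms$element != "H", ]
  s$atoms$serial <- seq_len(nrow(s$atoms))
  s2 <- place_polar_hydrogens(s)
  a <- s2$atoms
  og <- which(a$name == "OG")
  hs <- which(!is.na(a$h_parent) & a$h_parent == og)
  expect_length(hs, 1)
  d <- sqrt(sum((c(a$x[hs], a$y[hs], a$z[hs]) -
                   c(a$x[og], a$y[og], a$z[og]))^2))
  expect_equal(d, 0.96, tolerance = 0.01)
  # pre-existing hydrogens are preserved: atom count unchanged
  s3 <- place_polar_hydrogens(s2)
  expect_equal(nrow(s3$atoms), nrow(s2$atoms))
})

test_that("carboxylate side chains carry no protons", {
  out <- synth_complex(list(plant_spec(2.56, 168, lig_group = "alkyl_hydroxyl",
                                       donor = "ligand")), seed = 1)
  s <- place_polar_hydrogens(out$structure)
  a <- s$atoms
  for (nm in c("OD1", "OD2")) {
    i <- which(a$name == nm & a$resname == "ASP")
    expect_length(which(!is.na(a$h_parent) & a$h_parent == i), 0)
  }
})

test_that("planted contacts are detected iff the three criteria hold", {
  specs <- list(plant_spec(2.50, 170),                      # SHB
                plant_spec(3.00, 180),                      # NHB
                plant_spec(2.50, 120),                      # angle fails
                plant_spec(3.50, 180),                      # distance fails
                plant_spec(2.75, 170))                      # gap window
  out <- synth_complex(specs, seed = 11)
  s <- place_polar_hydrogens(out$structure)
  hb <- detect_hbonds(s)
  hb_pl <- hb[hb$partner_kind == "protein-ligand", ]
  expect_setequal(hb_pl$ligand_code, c("L01", "L02", "L05"))
  expect_equal(hb_pl$distance_class[hb_pl$ligand_code == "L01"], "SHB")
  expect_equal(hb_pl$distance_class[hb_pl$ligand_code == "L02"], "NHB")
  expect_equal(hb_pl$distance_class[hb_pl$ligand_code == "L05"], "AMBIGUOUS")
  expect_equal(hb_pl$R[hb_pl$ligand_code == "L01"], 2.50, tolerance = 0.01)
  expect_equal(hb_pl$theta[hb_pl$ligand_code == "L01"], 170, tolerance = 1)
})

test_that("detection matches the brute-force criteria oracle", {
  set.seed(421)
  for (rep in 1:8) {
    specs <- random_specs(sample(2:4, 1), NULL)
    out <- synth_complex(specs, seed = 500 + rep)
    s <- place_polar_hydrogens(out$structure)
    hb <- detect_hbonds(s)
    bf <- brute_force_hbonds(s, select_ligands(s))
    expect_setequal(hb_pair_key(hb$donor_idx, hb$acceptor_idx, hb$R),
                    hb_pair_key(bf$donor, bf$acceptor, bf$R))
  }
})

test_that("geometry is invariant under rigid rotation and translation", {
  out <- synth_complex(list(plant_spec(2.5, 165),
                            plant_spec(2.9, 150, lig_group = "phosphate")),
                       seed = 7)
  s <- place_polar_hydrogens(out$structure)
  hb0 <- detect_hbonds(s)
  th <- 0.83
  Rz <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  xyz <- as.matrix(s$atoms[, c("x", "y", "z")]) %*% t(Rz)
  s$atoms$x <- xyz[, 1] + 11.3
  s$atoms$y <- xyz[, 2] - 4.2
  s$atoms$z <- xyz[, 3] + 0.7
  hb1 <- detect_hbonds(s)
  expect_equal(nrow(hb1), nrow(hb0))
  o0 <- order(hb0$donor_idx, hb0$acceptor_idx)
  o1 <- order(hb1$donor_idx, hb1$acceptor_idx)
  expect_equal(hb1$R[o1], hb0$R[o0], tolerance = 1e-6)
  expect_equal(hb1$theta[o1], hb0$theta[o0], tolerance = 1e-6)
  expect_equal(hb1$distance_class[o1], hb0$distance_class[o0])
})

test_that("no record leaks across the SHB/NHB gap and roles are valid", {
  set.seed(99)
  for (rep in 1:5) {
    out <- synth_complex(random_specs(3, NULL), seed = 900 + rep)
    s <- place_polar_hydrogens(out$structure)
    hb <- detect_hbonds(s)
    if (nrow(hb) == 0) next
    expect_true(all(hb$R[hb$distance_class == "SHB"] <= 2.7))
    expect_true(all(hb$R[hb$distance_class == "NHB"] >= 2.8))
    expect_true(all(hb$theta >= 135))
    expect_true(all(hb$R >= 2.3 & hb$R <= 3.2))
    # every donor has attached hydrogens, every acceptor a lone pair
    a <- s$atoms
    for (k in seq_len(nrow(hb))) {
      expect_gte(sum(!is.na(a$h_parent) & a$h_parent == hb$donor_idx[k]), 1)
      expect_true(s$polar$lone_pair[s$polar$atom == hb$acceptor_idx[k]])
    }
  }
})
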