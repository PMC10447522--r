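# Synthetic fixtures with known ground truth.
#
# synth_complex() builds a minimal peptide plus small synthetic ligands in
# which each requested donor-acceptor contact is realized exactly at the
# requested R and donor-H-acceptor angle (hydrogens are written explicitly,
# so detection geometry is fully determined). synth_feature_table() draws
# labeled feature tables from a logistic generative model with controlled
# class imbalance and per-feature association strength.

#' Specify one planted hydrogen-bond contact
#'
#' @param R donor-acceptor heteroatom distance, Angstrom (> 0).
#' @param theta donor-H-acceptor angle, degrees (0 < theta <= 180).
#' @param aa protein residue at the site: `"SER"` (hydroxyl donor site) or
#'   `"ASP"` (carboxylate acceptor site; requires `donor = "ligand"`).
#' @param lig_group functional group of the participating ligand atom: one
#'   of `"alkyl_hydroxyl"`, `"phenol"`, `"phosphate"`, `"carboxylate"`,
#'   `"amide"`, `"n_aromatic"`.
#' @param donor which side donates the proton: `"protein"` or `"ligand"`.
#' @return `shb_plant_spec` list.
#' @export
plant_spec <- function(R, theta, aa = "SER", lig_group = "alkyl_hydroxyl",
                       donor = c("protein", "ligand")) {
  donor <- match.arg(donor)
  if (!is.numeric(R) || R <= 0) stop("R must be positive")
  if (!is.numeric(theta) || theta <= 0 || theta > 180)
    stop("theta must be in (0, 180]")
  if (donor == "protein" && !(aa %in% c("SER")))
    stop("protein-donor sites support aa = SER")
  if (donor == "ligand") {
    aa <- "ASP"
    if (!(lig_group %in% c("alkyl_hydroxyl", "phenol")))
      stop("ligand-donor planting needs a hydroxyl-bearing group")
  }
  acceptor_groups <- c("alkyl_hydroxyl", "phenol", "phosphate",
                       "carboxylate", "amide", "n_aromatic")
  if (!(lig_group %in% acceptor_groups))
    stop("unsupported ligand group: ", lig_group)
  structure(list(R = R, theta = theta, aa = aa, lig_group = lig_group,
                 donor = donor), class = "shb_plant_spec")
}

# Direction of the explicit H that realizes angle theta at H in the triangle
# donor - H - acceptor with |DH| = b, |DA| = R (law of sines).
planted_h_position <- function(D, A, b, theta) {
  R <- vec_norm(A - D)
  s <- b * sin(theta * pi / 180) / R
  if (s > 1) stop("infeasible geometry: R too short for requested angle")
  ang_A <- asin(s) * 180 / pi
  ang_D <- 180 - theta - ang_A
  e1 <- vec_unit(A - D)
  axis <- perp_unit(e1)
  D + b * rotate_about(e1, axis, ang_D)
}

#' Generate a synthetic protein-ligand complex with planted contacts
#'
#' Builds an extended glycine peptide carrying one donor/acceptor side chain
#' per planted contact, places a small ligand so that the contact geometry
#' matches the specification exactly (hydrogens written explicitly), and
#' optionally sprinkles carbon decoy atoms. Contacts that violate a
#' detection criterion by construction (theta < 135 degrees or R outside
#' [2.3, 3.2]) serve as decoy contacts; the truth table records what a
#' detector must and must not find.
#'
#' @param specs list of [plant_spec()] objects.
#' @param seed integer seed controlling decoy placement.
#' @param n_decoy_atoms number of isolated carbon decoy atoms (a carbon-only
#'   het group; also exercises ligand selection).
#' @param path optional output PDB path; written when non-`NULL`.
#' @return list with `structure` (`shb_structure`), `truth` (data.frame:
#'   site, residue, ligand code/group, planted R/theta, expected_detected,
#'   expected_class) and `path`.
#' @export
synth_complex <- function(specs, seed = 1, n_decoy_atoms = 0, path = NULL) {
  if (inherits(specs, "shb_plant_spec")) specs <- list(specs)
  stopifnot(length(specs) >= 1)
  set.seed(as.integer(seed) %% .Machine$integer.max)
  rows <- list()
  truth <- list()
  n_sites <- length(specs)
  nres <- 2 * n_sites + 1
  site_res <- 2 * seq_len(n_sites)   # residues 2, 4, ...
  add <- function(name, el, resname, chain, resno, pos, het) {
    rows[[length(rows) + 1]] <<- data.frame(
      name = name, element = el, resname = resname, chain = chain,
      resno = resno, insert = "", x = pos[1], y = pos[2], z = pos[3],
      occ = 1, het = het, stringsAsFactors = FALSE)
  }
  # extended backbone along x
  for (i in seq_len(nres)) {
    x0 <- 4.9 * (i - 1)
    resname <- "GLY"
    si <- match(i, site_res)
    if (!is.na(si)) resname <- specs[[si]]$aa
    add("N", "N", resname, "A", i, c(x0, 0.0, 0.0), FALSE)
    add("CA", "C", resname, "A", i, c(x0 + 1.46, 0.0, 0.0), FALSE)
    add("C", "C", resname, "A", i, c(x0 + 2.43, 1.16, 0.0), FALSE)
    add("O", "O", resname, "A", i, c(x0 + 2.43, 2.39, 0.0), FALSE)
  }
  lig_no <- 100
  for (si in seq_len(n_sites)) {
    sp <- specs[[si]]
    i <- site_res[si]
    x0 <- 4.9 * (i - 1)
    ca <- c(x0 + 1.46, 0.0, 0.0)
    cb <- ca + c(0, -0.76, 1.33)
    lig_no <- lig_no + 1
    code <- sprintf("L%02d", si)
    flip <- if (si %% 2 == 0) -1 else 1  # alternate ligand side
    zdir <- c(0, -0.35 * flip, 1.0 * flip)
    if (sp$donor == "protein") {
      og <- cb + 1.43 * vec_unit(c(0, -0.65, 1.30 * flip))
      add("CB", "C", sp$aa, "A", i, cb, FALSE)
      add("OG", "O", sp$aa, "A", i, og, FALSE)
      A <- og + sp$R * vec_unit(zdir)
      H <- planted_h_position(og, A, OH_BOND, sp$theta)
      add("HG", "H", sp$aa, "A", i, H, FALSE)
      build_synth_ligand(sp$lig_group, A, vec_unit(A - og), code, lig_no,
                         add, donor_side = FALSE)
      d_res <- sp$aa; d_atom <- "OG"
    } else {
      # carboxylate acceptor site: ligand hydroxyl donates
      cg <- cb + 1.52 * vec_unit(c(0, -0.65, 1.30 * flip))
      od1 <- cg + 1.25 * vec_unit(c(0, -0.30, 1.10 * flip))
      od2 <- cg + 1.25 * vec_unit(c(0.95, -0.85, -0.20 * flip))
      add("CB", "C", "ASP", "A", i, cb, FALSE)
      add("CG", "C", "ASP", "A", i, cg, FALSE)
      add("OD1", "O", "ASP", "A", i, od1, FALSE)
      add("OD2", "O", "ASP", "A", i, od2, FALSE)
      D <- od1 + sp$R * vec_unit(zdir)
      H <- planted_h_position(D, od1, OH_BOND, sp$theta)
      build_synth_ligand(sp$lig_group, D, vec_unit(D - od1), code, lig_no,
                         add, donor_side = TRUE, h_pos = H)
      d_res <- code; d_atom <- "O1"
    }
    expected <- sp$theta >= HB_THETA_MIN && sp$R >= HB_R_MIN &&
      sp$R <= HB_R_MAX
    truth[[si]] <- data.frame(
      site = si, resno = i, residue = sp$aa, ligand_code = code,
      lig_group = sp$lig_group, donor_side = sp$donor,
      R = sp$R, theta = sp$theta,
      expected_detected = expected,
      expected_class = if (expected) classify_r(sp$R) else NA_character_,
      stringsAsFactors = FALSE)
  }
  if (n_decoy_atoms > 0) {
    for (k in seq_len(n_decoy_atoms)) {
      pos <- c(stats::runif(1, -15, -8),
               stats::runif(1, 5, 12) * sample(c(-1, 1), 1),
               stats::runif(1, 6, 14))
      add(paste0("C", k), "C", "DCY", "D", 300 + k, pos, TRUE)
    }
  }
  atoms <- do.call(rbind, rows)
  s <- structure_model(atoms)
  check_no_clashes(s)
  if (!is.null(path)) write_structure(s, path)
  list(structure = s, truth = do.call(rbind, truth), path = path)
}

# Small synthetic ligand around the participating atom `A` (named "O1"/"N1"),
# grown away from the protein along `away`.
build_synth_ligand <- function(group, A, away, code, resno, add,
                               donor_side = FALSE, h_pos = NULL) {
  ax <- perp_unit(away)
  tilt <- function(deg) vec_unit(rotate_about(away, ax, deg))
  if (group == "alkyl_hydroxyl") {
    add("O1", "O", code, "B", resno, A, TRUE)
    c1 <- A + 1.43 * tilt(35)
    add("C1", "C", code, "B", resno, c1, TRUE)
    add("C2", "C", code, "B", resno, c1 + 1.52 * tilt(-15), TRUE)
    if (donor_side) add("HO1", "H", code, "B", resno, h_pos, TRUE)
    else add("HO1", "H", code, "B", resno, A + OH_BOND * tilt(-45), TRUE)
  } else if (group == "phenol") {
    add("O1", "O", code, "B", resno, A, TRUE)
    c1 <- A + 1.36 * tilt(25)
    ctr <- c1 + 1.39 * tilt(25)
    e1 <- vec_unit(c1 - ctr)
    e2 <- vec_unit(vec_cross(vec_cross(e1, away), e1))
    for (k in 0:5) {
      ang <- k * pi / 3
      p <- ctr + 1.39 * (cos(ang) * e1 + sin(ang) * e2)
      add(paste0("C", k + 1), "C", code, "B", resno, p, TRUE)
    }
    if (donor_side) add("HO1", "H", code, "B", resno, h_pos, TRUE)
    else add("HO1", "H", code, "B", resno, A + OH_BOND * tilt(-50), TRUE)
  } else if (group == "phosphate") {
    add("O1", "O", code, "B", resno, A, TRUE)
    p <- A + 1.52 * tilt(30)
    add("P1", "P", code, "B", resno, p, TRUE)
    # remaining substituents tetrahedral about P, leaning away from the
    # protein so they cannot form spurious contacts with the donor
    base <- vec_unit(A - p)
    w0 <- cone_direction_toward(base, 109.5, away)
    add("O2", "O", code, "B", resno, p + 1.49 * w0, TRUE)
    add("O3", "O", code, "B", resno,
        p + 1.49 * rotate_about(w0, base, 120), TRUE)
    w2 <- rotate_about(w0, base, 240)
    o4 <- p + 1.60 * w2
    add("O4", "O", code, "B", resno, o4, TRUE)
    add("C1", "C", code, "B", resno, o4 + 1.43 * w2, TRUE)
  } else if (group == "carboxylate") {
    add("O1", "O", code, "B", resno, A, TRUE)
    c1 <- A + 1.25 * tilt(30)
    add("C1", "C", code, "B", resno, c1, TRUE)
    add("O2", "O", code, "B", resno, c1 + 1.25 * tilt(95), TRUE)
    add("C2", "C", code, "B", resno, c1 + 1.50 * tilt(-45), TRUE)
  } else if (group == "amide") {
    add("O1", "O", code, "B", resno, A, TRUE)
    c1 <- A + 1.23 * tilt(30)
    add("C1", "C", code, "B", resno, c1, TRUE)
    add("N1", "N", code, "B", resno, c1 + 1.33 * tilt(95), TRUE)
    add("C2", "C", code, "B", resno, c1 + 1.50 * tilt(-45), TRUE)
  } else if (group == "n_aromatic") {
    # pyridine with N1 participating
    ctr <- A + 1.38 * tilt(15)
    e1 <- vec_unit(A - ctr)
    e2 <- vec_unit(vec_cross(vec_cross(e1, away), e1))
    add("N1", "N", code, "B", resno, A, TRUE)
    for (k in 1:5) {
      ang <- k * pi / 3
      p <- ctr + 1.38 * (cos(ang) * e1 + sin(ang) * e2)
      add(paste0("C", k), "C", code, "B", resno, p, TRUE)
    }
  } else stop("unsupported synthetic ligand group: ", group)
}

check_no_clashes <- function(s, min_dist = 0.7) {
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(xyz))
  diag(d) <- Inf
  # covalently bonded pairs are allowed to be close; only flag true overlaps
  if (any(d < min_dist))
    stop("synthetic structure generation produced overlapping atoms")
  invisible(TRUE)
}

# ---- labeled feature tables ------------------------------------------------

POLAR_AA <- c("TYR", "ASP", "GLU", "SER", "THR", "HIS",
              "ARG", "LYS", "ASN", "GLN", "TRP")

AA_HETEROATOMS <- list(
  TYR = "OH", ASP = c("OD1", "OD2"), GLU = c("OE1", "OE2"),
  SER = "OG", THR = "OG1", HIS = c("ND1", "NE2"),
  ARG = c("NE", "NH1", "NH2"), LYS = "NZ", ASN = c("OD1", "ND2"),
  GLN = c("OE1", "NE2"), TRP = "NE1")

# Ordinal class-association scores per categorical level: levels are ordered
# by their SHB propensity class and scored on an even grid in [-2.5, 2.5].
# A feature's log-odds contribution is log(odds_ratio) * score, so the
# stated odds ratio is the odds multiplier per unit of score; the grid span
# makes an odds ratio of 9 a strong association (near-separable classes),
# while an odds ratio of 1 carries no signal.
LEVEL_SCORE_SPAN <- 2.5

level_scores <- function(levels) {
  setNames(seq(LEVEL_SCORE_SPAN, -LEVEL_SCORE_SPAN,
               length.out = length(levels)), levels)
}

FG_ORDERED <- c("phenol", "alkyl_hydroxyl", "sulfate", "phosphate",
                "carboxyl", "carboxylate", "ester", "amide",
                "alkyl_amine", "n_aromatic")

#' Specify a synthetic labeled feature table
#'
#' @param n number of records.
#' @param shb_fraction target fraction of SHB labels, in (0, 1).
#' @param odds_ratios named list/vector of per-feature association
#'   strengths; names among the 14 predictor columns. A feature's log-odds
#'   contribution is `log(OR)` per unit of its level score (categorical
#'   levels are scored on an even grid in [-2.5, 2.5] ordered by propensity
#'   class; numeric features use their clipped z-score). Unlisted features
#'   get OR 1 (no association).
#' @param missing_rate fraction of pKa/pKb/logP values set to missing.
#' @param mode `"exact"` allocates exactly `round(n * shb_fraction)` SHB
#'   labels (weighted sampling without replacement); `"bernoulli"` draws
#'   labels independently.
#' @param seed RNG seed.
#' @return `shb_table_spec` list.
#' @export
table_spec <- function(n, shb_fraction = 1019 / 3219, odds_ratios = list(),
                       missing_rate = 0, mode = c("exact", "bernoulli"),
                       seed = 1) {
  mode <- match.arg(mode)
  stopifnot(n >= 2, shb_fraction > 0, shb_fraction < 1,
            all(unlist(odds_ratios) > 0), missing_rate >= 0,
            missing_rate <= 1)
  structure(list(n = n, shb_fraction = shb_fraction,
                 odds_ratios = odds_ratios, missing_rate = missing_rate,
                 mode = mode, seed = seed), class = "shb_table_spec")
}

#' Draw a labeled synthetic feature table
#'
#' Samples the 14 predictors from fixed marginals (uniform over the 11 polar
#' residues and the 10 functional groups; heteroatom, charges and group
#' constants derived from them; sequence neighbors uniform over the 20
#' amino acids) and assigns SHB/NHB labels from a logistic model whose
#' coefficients encode the requested odds ratios. Generator settings are
#' attached as the `"generator"` attribute.
#'
#' @param spec from [table_spec()].
#' @return data.frame in feature-table layout with a `label` column.
#' @export
synth_feature_table <- function(spec) {
  stopifnot(inherits(spec, "shb_table_spec"))
  set.seed(as.integer(spec$seed) %% .Machine$integer.max)
  n <- spec$n
  aa <- sample(POLAR_AA, n, replace = TRUE)
  het <- vapply(aa, function(r) {
    hs <- AA_HETEROATOMS[[r]]
    hs[sample.int(length(hs), 1)]
  }, character(1))
  fg <- sample(FG_ORDERED, n, replace = TRUE)
  # pKa/pKb/logP are drawn independently of the functional group so that
  # each feature's class association is attributable to its own odds ratio
  tb <- data.frame(
    aa_charge = unname(AA_CHARGE[aa]),
    aa_residue = aa,
    aa_heteroatom = unname(het),
    lig_charge = unname(GROUP_CHARGE[fg]),
    lig_functional_group = fg,
    lig_pKa = stats::rnorm(n, 8, 3),
    lig_pKb = stats::rnorm(n, 10, 3),
    lig_logP = stats::rnorm(n, 0, 1.5),
    seq_m3 = sample(STANDARD_AA, n, TRUE),
    seq_m2 = sample(STANDARD_AA, n, TRUE),
    seq_m1 = sample(STANDARD_AA, n, TRUE),
    seq_p1 = sample(STANDARD_AA, n, TRUE),
    seq_p2 = sample(STANDARD_AA, n, TRUE),
    seq_p3 = sample(STANDARD_AA, n, TRUE),
    stringsAsFactors = FALSE)

  lp <- rep(0, n)
  ors <- spec$odds_ratios
  score_of <- function(col) {
    x <- tb[[col]]
    if (is.numeric(x)) {
      s <- stats::sd(x)
      z <- if (s > 0) (x - mean(x)) / s else rep(0, n)
      pmax(-LEVEL_SCORE_SPAN, pmin(LEVEL_SCORE_SPAN, z))
    } else {
      lv <- switch(col,
                   aa_residue = POLAR_AA,
                   lig_functional_group = FG_ORDERED,
                   aa_heteroatom = sort(unique(unlist(AA_HETEROATOMS))),
                   STANDARD_AA)
      unname(level_scores(lv)[x])
    }
  }
  for (f in names(ors)) {
    if (!(f %in% names(tb))) stop("unknown feature in odds_ratios: ", f)
    lp <- lp + log(ors[[f]]) * score_of(f)
  }
  a0 <- uniroot(function(a) mean(stats::plogis(a + lp)) - spec$shb_fraction,
                c(-30, 30))$root
  p <- stats::plogis(a0 + lp)
  if (spec$mode == "exact") {
    n_shb <- round(n * spec$shb_fraction)
    pos <- sample.int(n, n_shb, prob = p)
    lab <- rep("NHB", n)
    lab[pos] <- "SHB"
  } else {
    lab <- ifelse(stats::runif(n) < p, "SHB", "NHB")
  }
  tb$label <- lab
  if (spec$missing_rate > 0) {
    for (col in c("lig_pKa", "lig_pKb", "lig_logP")) {
      drop <- stats::runif(n) < spec$missing_rate
      tb[[col]][drop] <- NA_real_
    }
  }
  attr(tb, "generator") <- list(spec = unclass(spec), intercept = a0)
  tb
}
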