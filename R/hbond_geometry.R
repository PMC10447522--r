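# Polar-hydrogen placement and geometric hydrogen-bond detection.
#
# A hydrogen bond requires: O or N heteroatoms on both sides; a
# donor-acceptor distance R in [2.3, 3.2] Angstrom; a donor-H-acceptor
# angle of at least 135 degrees. Bonds with R <= 2.7 are short hydrogen
# bonds (SHBs), R >= 2.8 normal (NHBs); the 2.7-2.8 gap is AMBIGUOUS.

HB_R_MIN <- 2.3
HB_R_MAX <- 3.2
HB_SHB_MAX <- 2.7
HB_NHB_MIN <- 2.8
HB_THETA_MIN <- 135
OH_BOND <- 0.96
NH_BOND <- 1.01

# Side-chain polar atom templates for the 11 polar amino acids. n_h is the
# idealized proton count at pH 7 (His neutral, proton on NE2); lone_pair
# marks acceptor capability; geom drives hydrogen placement.
PROTEIN_POLAR <- list(
  SER = list(list(name = "OG",  n_h = 1, lp = TRUE,  geom = "hydroxyl", nb = "CB")),
  THR = list(list(name = "OG1", n_h = 1, lp = TRUE,  geom = "hydroxyl", nb = "CB")),
  TYR = list(list(name = "OH",  n_h = 1, lp = TRUE,  geom = "hydroxyl", nb = "CZ")),
  ASP = list(list(name = "OD1", n_h = 0, lp = TRUE),
             list(name = "OD2", n_h = 0, lp = TRUE)),
  GLU = list(list(name = "OE1", n_h = 0, lp = TRUE),
             list(name = "OE2", n_h = 0, lp = TRUE)),
  ASN = list(list(name = "OD1", n_h = 0, lp = TRUE),
             list(name = "ND2", n_h = 2, lp = FALSE, geom = "planar1",
                  nb = "CG", ref = "OD1")),
  GLN = list(list(name = "OE1", n_h = 0, lp = TRUE),
             list(name = "NE2", n_h = 2, lp = FALSE, geom = "planar1",
                  nb = "CD", ref = "OE1")),
  HIS = list(list(name = "ND1", n_h = 0, lp = TRUE),
             list(name = "NE2", n_h = 1, lp = FALSE, geom = "planar2",
                  nb = c("CD2", "CE1"))),
  LYS = list(list(name = "NZ",  n_h = 3, lp = FALSE, geom = "sp3",
                  nb = "CE")),
  ARG = list(list(name = "NE",  n_h = 1, lp = FALSE, geom = "planar2",
                  nb = c("CD", "CZ")),
             list(name = "NH1", n_h = 2, lp = FALSE, geom = "planar1",
                  nb = "CZ", ref = "NE"),
             list(name = "NH2", n_h = 2, lp = FALSE, geom = "planar1",
                  nb = "CZ", ref = "NE")),
  TRP = list(list(name = "NE1", n_h = 1, lp = FALSE, geom = "planar2",
                  nb = c("CD1", "CE2"))))

atom_xyz <- function(atoms, i) c(atoms$x[i], atoms$y[i], atoms$z[i])

find_residue_atom <- function(atoms, chain, resno, insert, name) {
  which(atoms$chain == chain & atoms$resno == resno &
          atoms$insert == insert & atoms$name %in% name)
}

#' Place idealized polar hydrogens
#'
#' Adds hydrogens to hydrogen-bond-capable O/N atoms: side-chain donors of
#' the 11 polar amino acids and ligand donors identified from each ligand's
#' connectivity graph. Bond lengths are 0.96 Angstrom for O-H and 1.01 for
#' N-H; rotatable hydroxyl/amine hydrogens are oriented toward the nearest
#' candidate acceptor within 3.5 Angstrom, other hydrogens take standard
#' planar or tetrahedral positions. Pre-existing hydrogens (within 1.25
#' Angstrom of their heavy atom) are preserved and counted.
#'
#' Charged side chains follow fixed pH-7 states: Asp/Glu carboxylates carry
#' no proton, Lys/Arg are fully protonated, His is the neutral NE2-H
#' tautomer unless `his_cationic` is set.
#'
#' @param s `shb_structure`.
#' @param ligands ligand instances to protonate (default: all non-excluded,
#'   via [select_ligands()]).
#' @param his_cationic if `TRUE`, His carries protons on both ring nitrogens
#'   and loses its acceptor lone pair.
#' @return `shb_structure` with hydrogens appended and a `polar` table
#'   (atom index, donor/acceptor capability, ligand membership) attached.
#' @export
place_polar_hydrogens <- function(s, ligands = NULL, his_cationic = FALSE) {
  if (is.null(ligands)) ligands <- select_ligands(s)
  a <- s$atoms
  # map pre-existing hydrogens to their parent heavy atoms
  h_parent <- rep(NA_integer_, nrow(a))
  h_idx <- which(a$element == "H")
  heavy <- which(a$element != "H")
  for (h in h_idx) {
    d2 <- (a$x[heavy] - a$x[h])^2 + (a$y[heavy] - a$y[h])^2 +
      (a$z[heavy] - a$z[h])^2
    j <- heavy[which.min(d2)]
    if (min(d2) < 1.25^2) h_parent[h] <- j
  }

  polar <- collect_polar_atoms(s, ligands, his_cationic)
  if (nrow(polar) == 0) {
    s$atoms$h_parent <- h_parent
    s$polar <- polar
    return(s)
  }

  # acceptor candidates for orienting rotatable hydrogens
  acc_idx <- polar$atom[polar$lone_pair]
  new_rows <- list()
  next_serial <- nrow(a)
  for (r in seq_len(nrow(polar))) {
    i <- polar$atom[r]
    have <- sum(h_parent == i, na.rm = TRUE)
    need <- polar$n_h[r] - have
    if (need <= 0) next
    nb <- polar$neighbor[r]
    if (is.na(nb)) {
      warning("no heavy neighbor for donor ", a$name[i], " in ",
              a$resname[i], a$resno[i], "; skipped as donor")
      polar$n_h[r] <- have
      next
    }
    o <- atom_xyz(a, i)
    blen <- if (a$element[i] == "O") OH_BOND else NH_BOND
    target <- nearest_acceptor_dir(a, i, setdiff(acc_idx, c(i, nb)))
    dirs <- hydrogen_directions(a, polar[r, ], o, target)
    if (is.null(dirs)) {
      warning("unresolvable geometry for donor ", a$name[i], "; skipped")
      polar$n_h[r] <- have
      next
    }
    for (k in seq_len(min(need, nrow(dirs)))) {
      pos <- o + blen * dirs[k, ]
      next_serial <- next_serial + 1
      new_rows[[length(new_rows) + 1]] <- data.frame(
        name = paste0("H", substring(a$name[i], 2), if (k > 1) k else ""),
        element = "H", resname = a$resname[i], chain = a$chain[i],
        resno = a$resno[i], insert = a$insert[i],
        x = pos[1], y = pos[2], z = pos[3], occ = 1, het = a$het[i],
        serial = next_serial, stringsAsFactors = FALSE)
      h_parent <- c(h_parent, i)
    }
  }
  if (length(new_rows) > 0)
    s$atoms <- rbind(a, do.call(rbind, new_rows))
  s$atoms$h_parent <- h_parent
  s$polar <- polar
  s
}

nearest_acceptor_dir <- function(a, i, acc_idx) {
  if (length(acc_idx) == 0) return(NULL)
  d2 <- (a$x[acc_idx] - a$x[i])^2 + (a$y[acc_idx] - a$y[i])^2 +
    (a$z[acc_idx] - a$z[i])^2
  j <- acc_idx[which.min(d2)]
  if (min(d2) > 3.5^2) return(NULL)
  atom_xyz(a, j) - atom_xyz(a, i)
}

# Unit direction(s) for the hydrogens of one polar atom, as rows of a matrix.
hydrogen_directions <- function(a, p, origin, target) {
  geom <- p$geom
  ch <- a$chain[p$atom]; rn <- a$resno[p$atom]; ins <- a$insert[p$atom]
  get1 <- function(nm) {
    k <- find_residue_atom(a, ch, rn, ins, nm)
    if (length(k) == 0) NULL else atom_xyz(a, k[1])
  }
  nbp <- if (!is.na(p$neighbor)) atom_xyz(a, p$neighbor) else NULL
  if (geom %in% c("hydroxyl", "sp3", "sp3_n")) {
    if (is.null(nbp)) return(NULL)
    u <- vec_unit(origin - nbp)
    h0 <- cone_direction_toward(u, 70.5, target)
    if (geom == "hydroxyl") return(matrix(h0, nrow = 1))
    rbind(h0,
          rotate_about(h0, u, 120),
          rotate_about(h0, u, 240))
  } else if (geom == "planar2") {
    nms <- strsplit(p$nb_names, ",")[[1]]
    p1 <- get1(nms[1]); p2 <- get1(nms[2])
    if (is.null(p1) || is.null(p2)) return(NULL)
    matrix(-vec_unit(vec_unit(p1 - origin) + vec_unit(p2 - origin)),
           nrow = 1)
  } else if (geom %in% c("planar1", "planar_n")) {
    if (is.null(nbp)) return(NULL)
    refp <- if (!is.na(p$ref_name) && nzchar(p$ref_name)) get1(p$ref_name) else NULL
    u <- vec_unit(origin - nbp)
    nrm <- if (!is.null(refp)) vec_cross(u, refp - nbp) else NULL
    if (is.null(nrm) || vec_norm(nrm) < 1e-8) nrm <- vec_cross(u, perp_unit(u))
    pp <- vec_unit(vec_cross(vec_unit(nrm), u))
    rbind(u * cos(pi / 3) + pp * sin(pi / 3),
          u * cos(pi / 3) - pp * sin(pi / 3))
  } else NULL
}

# One row per hydrogen-bond-capable atom: protein side chains + ligand O/N.
collect_polar_atoms <- function(s, ligands, his_cationic = FALSE) {
  a <- s$atoms
  rows <- list()
  prot <- which(!a$het & a$resname %in% names(PROTEIN_POLAR) &
                  a$element %in% c("O", "N"))
  for (i in prot) {
    tmpl <- PROTEIN_POLAR[[a$resname[i]]]
    hit <- Filter(function(t) t$name == a$name[i], tmpl)
    if (length(hit) == 0) next
    t <- hit[[1]]
    n_h <- t$n_h; lp <- t$lp
    if (his_cationic && a$resname[i] == "HIS" && a$name[i] == "ND1") {
      n_h <- 1; lp <- FALSE
      t$geom <- "planar2"; t$nb <- c("CG", "CE1")
    }
    nb_idx <- NA_integer_
    if (!is.null(t$nb)) {
      k <- find_residue_atom(a, a$chain[i], a$resno[i], a$insert[i],
                             t$nb[1])
      if (length(k) > 0) nb_idx <- k[1]
    }
    rows[[length(rows) + 1]] <- data.frame(
      atom = i, kind = "protein", ligand = NA_integer_,
      group = NA_character_, n_h = n_h, lone_pair = lp,
      neighbor = nb_idx,
      geom = if (is.null(t$geom)) "none" else t$geom,
      nb_names = if (is.null(t$nb)) "" else paste(t$nb, collapse = ","),
      ref_name = if (is.null(t$ref)) "" else t$ref,
      stringsAsFactors = FALSE)
  }
  for (li in seq_along(ligands)) {
    g <- ligand_graph(s, ligands[[li]])
    typing <- ligand_polar_typing(g)
    if (nrow(typing) == 0) next
    for (r in seq_len(nrow(typing))) {
      geom <- switch(typing$geom[r], hydroxyl = "hydroxyl",
                     sp3_n = "sp3_n", planar_n = "planar_n", "none")
      rows[[length(rows) + 1]] <- data.frame(
        atom = typing$atom[r], kind = "ligand", ligand = li,
        group = typing$group[r], n_h = typing$n_h[r],
        lone_pair = typing$lone_pair[r], neighbor = typing$neighbor[r],
        geom = geom, nb_names = "", ref_name = "",
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0)
    return(data.frame(atom = integer(), kind = character(),
                      ligand = integer(), group = character(),
                      n_h = integer(), lone_pair = logical(),
                      neighbor = integer(), geom = character(),
                      nb_names = character(), ref_name = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Classify a donor-acceptor distance
#'
#' @param R donor-acceptor heteroatom distance(s), Angstrom; must be > 0.
#' @return `"SHB"` for 2.3 <= R <= 2.7, `"AMBIGUOUS"` for 2.7 < R < 2.8,
#'   `"NHB"` for 2.8 <= R <= 3.2, `"OUT_OF_RANGE"` otherwise.
#' @export
classify_r <- function(R) {
  if (any(!is.finite(R) | R <= 0))
    stop("R must be positive and finite")
  ifelse(R >= HB_R_MIN & R <= HB_SHB_MAX, "SHB",
         ifelse(R > HB_SHB_MAX & R < HB_NHB_MIN, "AMBIGUOUS",
                ifelse(R >= HB_NHB_MIN & R <= HB_R_MAX, "NHB",
                       "OUT_OF_RANGE")))
}

#' Detect hydrogen bonds between side chains and ligands
#'
#' Enumerates donor-acceptor pairs among side-chain heteroatoms of the 11
#' polar amino acids and ligand O/N atoms, applying the three geometric
#' criteria (O/N heteroatoms; 2.3 <= R <= 3.2 Angstrom; donor-H-acceptor
#' angle >= 135 degrees). When both atoms could donate, both role
#' assignments are evaluated and the one with the larger angle kept.
#' Ligand-ligand contacts are not reported.
#'
#' @param s `shb_structure`, ideally from [place_polar_hydrogens()] (it is
#'   called automatically otherwise).
#' @param ligands ligand instances (default [select_ligands()]).
#' @param include_protein_protein also report side-chain/side-chain bonds
#'   between different residues (default `TRUE`).
#' @return data.frame of hydrogen-bond records: donor and acceptor identity,
#'   `R`, `theta`, `distance_class`, `partner_kind`.
#' @export
detect_hbonds <- function(s, ligands = NULL, include_protein_protein = TRUE) {
  if (is.null(ligands)) ligands <- select_ligands(s)
  if (is.null(s$polar)) s <- place_polar_hydrogens(s, ligands)
  a <- s$atoms
  polar <- s$polar
  empty <- hbond_record_frame()
  if (nrow(polar) < 2) return(empty)
  n_h_attached <- tabulate(a$h_parent[!is.na(a$h_parent)], nbins = nrow(a))
  res_key <- residue_key(a)
  xyz <- as.matrix(a[polar$atom, c("x", "y", "z")])
  recs <- list()
  np <- nrow(polar)
  for (p in seq_len(np - 1)) {
    for (q in (p + 1):np) {
      i <- polar$atom[p]; j <- polar$atom[q]
      if (polar$kind[p] == "ligand" && polar$kind[q] == "ligand") next
      if (res_key[i] == res_key[j]) next
      R <- sqrt(sum((xyz[p, ] - xyz[q, ])^2))
      if (R < HB_R_MIN || R > HB_R_MAX) next
      cand <- list()
      for (dir in 1:2) {
        d <- if (dir == 1) i else j
        acc <- if (dir == 1) j else i
        d_row <- if (dir == 1) p else q
        a_row <- if (dir == 1) q else p
        if (n_h_attached[d] == 0) next
        if (!polar$lone_pair[a_row]) next
        hs <- which(!is.na(a$h_parent) & a$h_parent == d)
        theta <- max(vapply(hs, function(h)
          angle_deg(atom_xyz(a, d), atom_xyz(a, h), atom_xyz(a, acc)),
          numeric(1)))
        if (theta < HB_THETA_MIN) next
        cand[[length(cand) + 1]] <- list(d = d, acc = acc, d_row = d_row,
                                         a_row = a_row, theta = theta)
      }
      if (length(cand) == 0) next
      best <- cand[[1]]
      if (length(cand) == 2) {
        if (cand[[2]]$theta > cand[[1]]$theta + 1e-9) best <- cand[[2]]
        else if (abs(cand[[2]]$theta - cand[[1]]$theta) <= 1e-9 &&
                 cand[[2]]$d < cand[[1]]$d) best <- cand[[2]]
      }
      kinds <- c(polar$kind[p], polar$kind[q])
      pk <- if (all(kinds == "protein")) "protein-protein" else "protein-ligand"
      if (pk == "protein-protein" && !include_protein_protein) next
      d <- best$d; acc <- best$acc
      lig_code <- function(row) {
        if (polar$kind[row] == "ligand")
          ligands[[polar$ligand[row]]]$code else NA_character_
      }
      recs[[length(recs) + 1]] <- data.frame(
        donor_resname = a$resname[d], donor_chain = a$chain[d],
        donor_resno = a$resno[d], donor_insert = a$insert[d],
        donor_atom = a$name[d],
        donor_is_ligand = polar$kind[best$d_row] == "ligand",
        donor_group = polar$group[best$d_row],
        acceptor_resname = a$resname[acc], acceptor_chain = a$chain[acc],
        acceptor_resno = a$resno[acc], acceptor_insert = a$insert[acc],
        acceptor_atom = a$name[acc],
        acceptor_is_ligand = polar$kind[best$a_row] == "ligand",
        acceptor_group = polar$group[best$a_row],
        ligand_code = if (!is.na(lig_code(best$d_row))) lig_code(best$d_row)
                      else lig_code(best$a_row),
        R = R, theta = best$theta,
        distance_class = classify_r(R), partner_kind = pk,
        donor_idx = d, acceptor_idx = acc,
        stringsAsFactors = FALSE)
    }
  }
  if (length(recs) == 0) return(empty)
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}

hbond_record_frame <- function() {
  data.frame(donor_resname = character(), donor_chain = character(),
             donor_resno = integer(), donor_insert = character(),
             donor_atom = character(), donor_is_ligand = logical(),
             donor_group = character(),
             acceptor_resname = character(), acceptor_chain = character(),
             acceptor_resno = integer(), acceptor_insert = character(),
             acceptor_atom = character(), acceptor_is_ligand = logical(),
             acceptor_group = character(), ligand_code = character(),
             R = numeric(), theta = numeric(),
             distance_class = character(), partner_kind = character(),
             donor_idx = integer(), acceptor_idx = integer(),
             stringsAsFactors = FALSE)
}

#' Write hydrogen-bond records to TSV
#' @param records from [detect_hbonds()].
#' @param path output file.
#' @export
write_hbonds <- function(records, path) {
  write.table(records, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
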