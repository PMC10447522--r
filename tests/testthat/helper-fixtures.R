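# Shared fixtures and independent oracles, all built in code.

# ---- toy structure files ---------------------------------------------------

pdb_atom_line <- function(serial, name, resname, chain, resno, xyz,
                          het = FALSE, element = substr(name, 1, 1)) {
  sprintf("%-6s%5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          if (het) "HETATM" else "ATOM", serial,
          if (nchar(name) < 4) paste0(" ", name) else name,
          resname, chain, resno, xyz[1], xyz[2], xyz[3], 1, 0, element)
}

# One serine residue plus a glycerol molecule (13 heavy atoms).
write_toy_pdb <- function(path, resolution = NULL) {
  lines <- character()
  if (!is.null(resolution))
    lines <- c(lines, sprintf(
      "REMARK   2 RESOLUTION.    %4.2f ANGSTROMS.", resolution))
  ser <- list(N = c(0, 0, 0), CA = c(1.46, 0, 0), C = c(2.43, 1.16, 0),
              O = c(2.43, 2.39, 0), OXT = c(3.64, 0.62, 0),
              CB = c(1.46, -0.76, 1.33), OG = c(1.46, -1.41, 2.63))
  gol <- list(C1 = c(5.0, -1.0, 3.2), O1 = c(4.2, -2.0, 3.7),
              C2 = c(6.4, -1.5, 3.0), O2 = c(7.2, -0.5, 2.4),
              C3 = c(7.0, -2.0, 4.3), O3 = c(8.3, -2.4, 4.1))
  k <- 0
  for (nm in names(ser)) {
    k <- k + 1
    lines <- c(lines, pdb_atom_line(k, nm, "SER", "A", 1, ser[[nm]]))
  }
  for (nm in names(gol)) {
    k <- k + 1
    lines <- c(lines, pdb_atom_line(k, nm, "GOL", "B", 101, gol[[nm]],
                                    het = TRUE))
  }
  writeLines(c(lines, "END"), path)
  path
}

write_toy_cif <- function(path) {
  header <- c("data_TOY", "loop_",
              paste0("_atom_site.",
                     c("group_PDB", "id", "type_symbol", "label_atom_id",
                       "label_alt_id", "label_comp_id", "label_asym_id",
                       "label_entity_id", "label_seq_id",
                       "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y", "Cartn_z",
                       "occupancy", "B_iso_or_equiv", "pdbx_formal_charge",
                       "auth_seq_id", "auth_comp_id", "auth_asym_id",
                       "auth_atom_id", "pdbx_PDB_model_num")))
  tmp <- tempfile(fileext = ".pdb")
  on.exit(unlink(tmp))
  write_toy_pdb(tmp)
  s <- read_structure(tmp)
  a <- s$atoms
  rows <- sprintf(
    "%s %d %s %s . %s %s 1 %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
    ifelse(a$het, "HETATM", "ATOM"), seq_len(nrow(a)), a$element, a$name,
    a$resname, a$chain, a$resno, a$x, a$y, a$z, a$resno, a$resname,
    a$chain, a$name)
  writeLines(c(header, rows), path)
  path
}

# Minimal polymer chain (N/CA/C/O per residue) for sequence-context tests.
write_chain_pdb <- function(path, codes, chain = "A") {
  lines <- character(); k <- 0
  for (i in seq_along(codes)) {
    x0 <- 4.9 * (i - 1)
    for (at in list(c("N", 0, 0), c("CA", 1.46, 0), c("C", 2.43, 1.16),
                    c("O", 2.43, 2.39))) {
      k <- k + 1
      lines <- c(lines, pdb_atom_line(
        k, at[1], codes[i], chain, i,
        c(x0 + as.numeric(at[2]), as.numeric(at[3]), 0)))
    }
  }
  writeLines(c(lines, "END"), path)
  path
}

# ---- hand-built ligand graphs ----------------------------------------------

# elements: character vector; bonds: data.frame(i, j, order) in local indices.
make_graph <- function(elements, bonds, names = NULL) {
  n <- length(elements)
  if (is.null(names)) names <- paste0(elements, seq_len(n))
  adj <- rep(list(integer(0)), n)
  ord <- rep(list(character(0)), n)
  for (k in seq_len(nrow(bonds))) {
    i <- bonds$i[k]; j <- bonds$j[k]; o <- as.character(bonds$order[k])
    adj[[i]] <- c(adj[[i]], j); ord[[i]] <- c(ord[[i]], o)
    adj[[j]] <- c(adj[[j]], i); ord[[j]] <- c(ord[[j]], o)
  }
  g <- list(idx = seq_len(n), element = toupper(elements), name = names,
            adj = adj, ord = ord)
  g$aromatic <- shbligand:::aromatic_atoms(g)
  g
}

bonds_df <- function(...) {
  m <- matrix(c(...), ncol = 3, byrow = TRUE)
  data.frame(i = as.integer(m[, 1]), j = as.integer(m[, 2]),
             order = as.character(m[, 3]), stringsAsFactors = FALSE)
}

# benzene ring bonds 1..6 aromatic
ring6 <- function(offset = 0, order = "ar") {
  b <- cbind(offset + 1:6, offset + c(2:6, 1))
  data.frame(i = as.integer(b[, 1]), j = as.integer(b[, 2]),
             order = order, stringsAsFactors = FALSE)
}

# ---- brute-force hydrogen-bond oracle --------------------------------------

# Literal double loop over all polar O/N pairs applying the three criteria,
# written independently of detect_hbonds.
brute_force_hbonds <- function(s, ligands) {
  a <- s$atoms
  polar <- s$polar
  key <- paste(a$chain, a$resno, a$insert, a$resname)
  out <- list()
  for (p in seq_len(nrow(polar))) {
    for (q in seq_len(nrow(polar))) {
      if (p == q) next
      i <- polar$atom[p]; j <- polar$atom[q]
      if (polar$kind[p] == "ligand" && polar$kind[q] == "ligand") next
      if (key[i] == key[j]) next
      D <- c(a$x[i], a$y[i], a$z[i]); A <- c(a$x[j], a$y[j], a$z[j])
      R <- sqrt(sum((D - A)^2))
      if (R < 2.3 || R > 3.2) next                      # criterion 2
      if (!(a$element[i] %in% c("O", "N"))) next        # criterion 1
      if (!(a$element[j] %in% c("O", "N"))) next
      hs <- which(!is.na(a$h_parent) & a$h_parent == i)
      if (length(hs) == 0) next                         # donor needs H
      if (!polar$lone_pair[q]) next                     # acceptor lone pair
      theta <- -Inf
      for (h in hs) {
        H <- c(a$x[h], a$y[h], a$z[h])
        v1 <- D - H; v2 <- A - H
        cosv <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        theta <- max(theta, acos(max(-1, min(1, cosv))) * 180 / pi)
      }
      if (theta < 135) next                             # criterion 3
      out[[length(out) + 1]] <- data.frame(donor = i, acceptor = j,
                                           R = R, theta = theta)
    }
  }
  if (length(out) == 0)
    return(data.frame(donor = integer(), acceptor = integer(),
                      R = numeric(), theta = numeric()))
  cand <- do.call(rbind, out)
  # resolve roles per unordered pair: larger angle wins, tie -> lower index
  pk <- paste(pmin(cand$donor, cand$acceptor),
              pmax(cand$donor, cand$acceptor))
  keep <- logical(nrow(cand))
  for (u in unique(pk)) {
    rows <- which(pk == u)
    if (length(rows) == 1) keep[rows] <- TRUE
    else {
      best <- rows[order(-cand$theta[rows], cand$donor[rows])][1]
      keep[best] <- TRUE
    }
  }
  cand[keep, , drop = FALSE]
}

hb_pair_key <- function(donor, acceptor, R) {
  paste(donor, acceptor, round(R, 6), sep = "|")
}

# random mixed planting specification for property tests
random_specs <- function(n_sites, rng) {
  groups <- c("alkyl_hydroxyl", "phenol", "phosphate", "carboxylate",
              "amide", "n_aromatic")
  lapply(seq_len(n_sites), function(i) {
    kind <- sample(c("shb", "nhb", "bad_angle", "far"), 1)
    R <- switch(kind, shb = runif(1, 2.35, 2.7), nhb = runif(1, 2.8, 3.15),
                bad_angle = runif(1, 2.4, 3.1), far = runif(1, 3.35, 3.8))
    theta <- if (kind == "bad_angle") runif(1, 95, 130) else runif(1, 140, 178)
    donor <- sample(c("protein", "ligand"), 1, prob = c(0.7, 0.3))
    grp <- if (donor == "ligand") sample(c("alkyl_hydroxyl", "phenol"), 1)
           else sample(groups, 1)
    plant_spec(R, theta, lig_group = grp, donor = donor)
  })
}

# Records of exactly the planted donor/acceptor pair of one truth row
# (other criteria-satisfying contacts of the same ligand are legitimate
# detections and are validated by the brute-force oracle instead).
planted_records <- function(hb, tr) {
  lig_atom <- if (tr$lig_group == "n_aromatic") "N1" else "O1"
  prot_atom <- if (tr$donor_side == "protein") "OG" else "OD1"
  hb[hb$ligand_code == tr$ligand_code &
       ((hb$donor_atom == lig_atom & hb$acceptor_atom == prot_atom) |
          (hb$donor_atom == prot_atom & hb$acceptor_atom == lig_atom)), ,
     drop = FALSE]
}

# brute-force AUC: concordance over all positive-negative pairs, ties = 1/2
pairwise_auc <- function(p, y) {
  pos <- p[y == 1]; neg <- p[y == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

small_config <- function(n_members = 2, ...) {
  shb_config(n_members = n_members, n_trees = 60, shrinkage = 0.1,
             depth_candidates = 2, cv_folds = 3, ...)
}
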