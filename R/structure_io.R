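#' @importFrom stats setNames uniroot runif rnorm plogis sd dist predict
#' @importFrom utils read.table write.table head
#' @importFrom graphics hist
NULL

STANDARD_AA <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                 "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                 "THR", "TRP", "TYR", "VAL")

WATER_CODES <- c("HOH", "DOD", "WAT", "H2O")

# Single-bond covalent radii (Angstrom); tolerance added when inferring bonds.
COVALENT_RADII <- c(H = 0.31, C = 0.76, N = 0.71, O = 0.66, P = 1.07,
                    S = 1.05, F = 0.57, CL = 1.02, BR = 1.20, I = 1.39,
                    FE = 1.32, ZN = 1.22, MG = 1.41, MN = 1.39, CA = 1.71,
                    "NA" = 1.66, K = 2.03, SE = 1.20, B = 0.84)

#' Construct a structure model from an atom table
#'
#' The central container for one protein-ligand complex. Atoms are stored in
#' a single data frame; het-group residues (everything that is not a standard
#' amino acid read from ATOM records) are treated as ligand instances and get
#' distance-inferred covalent bonds unless a component dictionary is supplied.
#'
#' @param atoms data.frame with columns `name`, `element`, `resname`, `chain`,
#'   `resno`, `insert`, `x`, `y`, `z`, `occ`, `het` (logical: HETATM record).
#' @param resolution crystallographic resolution in Angstrom, or `NA`.
#' @param ccd optional path to a chemical-component-dictionary CIF providing
#'   ligand bond lists; falls back to covalent-radius distance bonding.
#' @return object of class `shb_structure` with elements `atoms`, `ligands`
#'   (list of ligand instances, each with `code`, `chain`, `resno`, `insert`,
#'   `atoms` (row indices) and `bonds`), and `resolution`.
#' @export
structure_model <- function(atoms, resolution = NA_real_, ccd = NULL) {
  need <- c("name", "element", "resname", "chain", "resno", "insert",
            "x", "y", "z", "occ", "het")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0)
    stop("atom table is missing columns: ", paste(miss, collapse = ", "))
  if (nrow(atoms) == 0) stop("structure contains no atoms")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("non-finite atom coordinates")
  atoms$element <- toupper(atoms$element)
  atoms$serial <- seq_len(nrow(atoms))
  rownames(atoms) <- NULL
  ccd_bonds <- if (!is.null(ccd)) read_ccd_bonds(ccd) else NULL
  s <- structure(list(atoms = atoms, ligands = list(),
                      resolution = resolution),
                 class = "shb_structure")
  s$ligands <- find_ligand_instances(s, ccd_bonds)
  s
}

#' @export
print.shb_structure <- function(x, ...) {
  np <- length(unique(residue_key(x$atoms[!x$atoms$het &
                                            x$atoms$resname %in% STANDARD_AA, ])))
  cat(sprintf("shb_structure: %d atoms, %d polymer residues, %d ligand instance(s)\n",
              nrow(x$atoms), np, length(x$ligands)))
  if (!is.na(x$resolution))
    cat(sprintf("resolution: %.2f Angstrom\n", x$resolution))
  invisible(x)
}

residue_key <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$insert, atoms$resname, sep = "|")
}

#' Read a protein-ligand complex from PDB or mmCIF
#'
#' Parses all atoms of the first model. Alternate conformers are reduced to
#' the highest-occupancy one. Ligand connectivity comes from a
#' chemical-component dictionary CIF when given, otherwise from
#' covalent-radius distance bonding.
#'
#' @param path file path.
#' @param format `"pdb"`, `"mmcif"` or `"auto"` (by file extension).
#' @param ccd optional component-dictionary CIF path.
#' @return `shb_structure`.
#' @export
read_structure <- function(path, format = c("auto", "pdb", "mmcif"),
                           ccd = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("cif", "mmcif")) "mmcif" else "pdb"
  }
  lines <- readLines(path, warn = FALSE)
  if (format == "pdb") {
    n_models <- sum(startsWith(lines, "MODEL "))
    if (n_models > 1)
      warning("multi-model file: using the first model only")
    if (!any(startsWith(lines, "ATOM") | startsWith(lines, "HETATM")))
      stop("no ATOM/HETATM records found in ", path)
    # rm.alt = FALSE: alternate conformers are resolved here by occupancy,
    # not by the reader's keep-A rule
    pdb <- tryCatch(
      suppressWarnings(invisible(bio3d::read.pdb(
        path, multi = FALSE, rm.alt = FALSE, verbose = FALSE))),
      error = function(e)
        stop("PDB parse error in ", path, ": ", conditionMessage(e)))
  } else {
    pdb <- withCallingHandlers(
      tryCatch(bio3d::read.cif(path, verbose = FALSE),
               error = function(e)
                 stop("mmCIF parse error in ", path, ": ",
                      conditionMessage(e))),
      warning = function(w) {
        # silence the reader's beta-status and secondary-structure notes
        if (grepl("beta version|helix/sheet", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    if (is.null(pdb$atom) || nrow(pdb$atom) == 0)
      stop("no atom records found in ", path)
  }
  at <- pdb$atom
  element <- toupper(trimws(at$elesy))
  bad <- is.na(element) | element == ""
  if (any(bad)) element[bad] <- guess_element(at$elety[bad])
  atoms <- data.frame(
    name = trimws(at$elety),
    element = element,
    resname = trimws(at$resid),
    chain = ifelse(is.na(at$chain) | at$chain == "", "A", at$chain),
    resno = at$resno,
    insert = ifelse(is.na(at$insert), "", at$insert),
    x = at$x, y = at$y, z = at$z,
    occ = ifelse(is.na(at$o), 1, at$o),
    het = at$type == "HETATM",
    alt = ifelse(is.na(at$alt), "", at$alt),
    stringsAsFactors = FALSE)
  atoms <- resolve_altloc(atoms)
  atoms$alt <- NULL
  structure_model(atoms, resolution = scan_resolution(lines, format),
                  ccd = ccd)
}

# Keep the highest-occupancy conformer of each alternate-location group.
resolve_altloc <- function(atoms) {
  has_alt <- atoms$alt != "" & atoms$alt != " "
  if (!any(has_alt)) return(atoms)
  key <- paste(residue_key(atoms), atoms$name, sep = "|")
  keep <- rep(TRUE, nrow(atoms))
  for (k in unique(key[has_alt])) {
    idx <- which(key == k)
    if (length(idx) > 1) {
      best <- idx[which.max(atoms$occ[idx])]
      keep[setdiff(idx, best)] <- FALSE
    }
  }
  atoms[keep, , drop = FALSE]
}

guess_element <- function(name) {
  nm <- gsub("[0-9'\"]", "", toupper(trimws(name)))
  two <- substr(nm, 1, 2)
  one <- substr(nm, 1, 1)
  ifelse(two %in% names(COVALENT_RADII) & !(one %in% c("C", "N", "O", "H", "P", "S")),
         two, one)
}

scan_resolution <- function(lines, format) {
  if (format == "pdb") {
    hit <- grep("^REMARK   2 RESOLUTION\\.", lines, value = TRUE)
    if (length(hit) > 0) {
      m <- regmatches(hit[1], regexpr("[0-9]+\\.[0-9]+", hit[1]))
      if (length(m) > 0) return(as.numeric(m))
    }
  } else {
    hit <- grep("_refine\\.ls_d_res_high", lines, value = TRUE)
    if (length(hit) > 0) {
      m <- regmatches(hit[1], regexpr("[0-9]+\\.?[0-9]*\\s*$", hit[1]))
      if (length(m) > 0) return(as.numeric(trimws(m)))
    }
  }
  NA_real_
}

#' Write a structure model to a PDB file
#'
#' @param s `shb_structure`.
#' @param path output path.
#' @export
write_structure <- function(s, path) {
  a <- s$atoms
  bio3d::write.pdb(file = path,
                   type = ifelse(a$het, "HETATM", "ATOM"),
                   eleno = a$serial, elety = a$name, resid = a$resname,
                   chain = a$chain, resno = a$resno, insert = a$insert,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   o = a$occ, b = rep(0, nrow(a)), elesy = a$element)
  invisible(path)
}

# ---- ligand instances and connectivity ------------------------------------

find_ligand_instances <- function(s, ccd_bonds = NULL) {
  a <- s$atoms
  is_lig_atom <- a$het & !(a$resname %in% STANDARD_AA)
  if (!any(is_lig_atom)) return(list())
  key <- residue_key(a)
  out <- list()
  for (k in unique(key[is_lig_atom])) {
    idx <- which(key == k & is_lig_atom)
    parts <- strsplit(k, "|", fixed = TRUE)[[1]]
    code <- parts[4]
    bonds <- NULL
    if (!is.null(ccd_bonds) && code %in% names(ccd_bonds))
      bonds <- match_ccd_bonds(a, idx, ccd_bonds[[code]])
    if (is.null(bonds)) bonds <- infer_bonds(a, idx)
    out[[length(out) + 1]] <- list(code = code, chain = parts[1],
                                   resno = as.integer(parts[2]),
                                   insert = parts[3],
                                   atoms = idx, bonds = bonds)
  }
  out
}

#' Infer covalent bonds among a set of atoms from interatomic distances
#'
#' Two atoms are bonded when their distance is below the sum of single-bond
#' covalent radii plus 0.4 Angstrom. Approximate bond orders are assigned
#' from distance: short C-C / C-N contacts are flagged conjugated/aromatic
#' ("ar"), short C-O / P-O / S-O contacts double ("2"), the rest single.
#'
#' @return data.frame with columns `i`, `j` (atom row indices) and `order`.
#' @noRd
infer_bonds <- function(atoms, idx) {
  n <- length(idx)
  out <- data.frame(i = integer(), j = integer(), order = character(),
                    stringsAsFactors = FALSE)
  if (n < 2) return(out)
  xyz <- as.matrix(atoms[idx, c("x", "y", "z")])
  el <- atoms$element[idx]
  rad <- unname(COVALENT_RADII[el])
  rad[is.na(rad)] <- 0.77
  for (p in seq_len(n - 1)) {
    for (q in (p + 1):n) {
      d <- sqrt(sum((xyz[p, ] - xyz[q, ])^2))
      if (d > rad[p] + rad[q] + 0.4 || d < 0.4) next
      ord <- bond_order_from_length(el[p], el[q], d)
      out <- rbind(out, data.frame(i = idx[p], j = idx[q], order = ord,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}

bond_order_from_length <- function(e1, e2, d) {
  pair <- paste(sort(c(e1, e2)), collapse = "-")
  if (pair == "C-C" && d <= 1.45) return("ar")
  if (pair == "C-N" && d <= 1.38) return("ar")
  if (pair == "C-O" && d <= 1.28) return("2")
  if (pair == "O-P" && d <= 1.55) return("2")
  if (pair == "O-S" && d <= 1.50) return("2")
  "1"
}

# Parse _chem_comp_bond loops from a component-dictionary CIF. Returns a
# named list (component code -> data.frame atom1, atom2, order).
read_ccd_bonds <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_starts <- which(trimws(lines) == "loop_")
  out <- list()
  for (ls in loop_starts) {
    i <- ls + 1
    tags <- character()
    while (i <= length(lines) && startsWith(trimws(lines[i]), "_")) {
      tags <- c(tags, trimws(lines[i])); i <- i + 1
    }
    if (!any(grepl("^_chem_comp_bond\\.", tags))) next
    cols <- sub("^_chem_comp_bond\\.", "", tags)
    rows <- list()
    while (i <= length(lines)) {
      ln <- trimws(lines[i])
      if (ln == "" || startsWith(ln, "_") || ln %in% c("loop_", "#") ||
          startsWith(ln, "data_")) break
      rows[[length(rows) + 1]] <- scan(text = ln, what = character(),
                                       quiet = TRUE)
      i <- i + 1
    }
    if (length(rows) == 0) next
    m <- do.call(rbind, rows)
    colnames(m) <- cols[seq_len(ncol(m))]
    comp <- m[, "comp_id"]
    ord <- toupper(m[, "value_order"])
    ord <- ifelse(ord %in% c("DOUB", "2"), "2",
                  ifelse(ord %in% c("AROM", "AR"), "ar", "1"))
    for (code in unique(comp)) {
      sel <- comp == code
      out[[code]] <- data.frame(atom1 = m[sel, "atom_id_1"],
                                atom2 = m[sel, "atom_id_2"],
                                order = ord[sel], stringsAsFactors = FALSE)
    }
  }
  out
}

match_ccd_bonds <- function(atoms, idx, tmpl) {
  nm <- atoms$name[idx]
  i <- idx[match(tmpl$atom1, nm)]
  j <- idx[match(tmpl$atom2, nm)]
  ok <- !is.na(i) & !is.na(j)
  if (!any(ok)) return(NULL)
  data.frame(i = i[ok], j = j[ok], order = tmpl$order[ok],
             stringsAsFactors = FALSE)
}

# ---- ligand selection ------------------------------------------------------

#' Default ligand exclusion policy
#'
#' Waters, crystallization polyols (glycerol, ethylene glycol, PEG fragments,
#' MPD and friends) and inorganic anions (sulfate, phosphate ion, halides,
#' nitrate) are dropped from analysis: they come from the crystallization
#' buffer rather than biology. The list ships as a plain-text file of
#' component codes that users can replace or extend.
#'
#' @param extra character vector of additional component codes to exclude.
#' @param file path to a custom exclusion file (one code per line, `#`
#'   comments allowed); defaults to the packaged list.
#' @return object of class `shb_exclusion_policy` (a character set).
#' @export
ligand_exclusion_policy <- function(extra = character(), file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "excluded_components.txt",
                        package = "shbligand")
  codes <- readLines(file, warn = FALSE)
  codes <- toupper(trimws(sub("#.*", "", codes)))
  codes <- unique(c(codes[codes != ""], toupper(extra), WATER_CODES))
  structure(sort(codes), class = "shb_exclusion_policy")
}

#' Select ligands eligible for hydrogen-bond analysis
#'
#' Drops ligand instances whose component code is in the exclusion policy and
#' instances with no O or N atom (they cannot hydrogen bond).
#'
#' @param s `shb_structure`.
#' @param policy from [ligand_exclusion_policy()]; `NULL` uses the default.
#' @return list of ligand instances (possibly empty).
#' @export
select_ligands <- function(s, policy = NULL) {
  if (is.null(policy)) policy <- ligand_exclusion_policy()
  keep <- vapply(s$ligands, function(lg) {
    if (toupper(lg$code) %in% policy) return(FALSE)
    any(s$atoms$element[lg$atoms] %in% c("O", "N"))
  }, logical(1))
  s$ligands[keep]
}

# ---- sequence context ------------------------------------------------------

# Ordered polymer residue table for one chain (author numbering; insertion
# codes sort after their base number).
chain_residues <- function(s, chain) {
  a <- s$atoms
  sel <- !a$het & a$resname %in% STANDARD_AA & a$chain == chain
  if (!any(sel)) return(NULL)
  r <- unique(a[sel, c("resname", "chain", "resno", "insert")])
  r[order(r$resno, r$insert), , drop = FALSE]
}

#' Sequence context of a polymer residue
#'
#' Returns the residue codes of the `window` neighbors on each side of the
#' given residue along its chain, ordered N-terminal to C-terminal
#' (positions -window..-1 then +1..+window). Positions beyond a chain
#' terminus are filled with the token `"XTR"`.
#'
#' @param s `shb_structure`.
#' @param chain chain identifier.
#' @param resno author residue number.
#' @param insert insertion code (default none).
#' @param window number of residues on each side (default 3).
#' @return character vector of length `2 * window`.
#' @export
sequence_context <- function(s, chain, resno, insert = "", window = 3) {
  if (window == 0) return(character(0))
  res <- chain_residues(s, chain)
  if (is.null(res))
    stop("no polymer residues in chain ", chain)
  pos <- which(res$resno == resno & res$insert == insert)
  if (length(pos) != 1)
    stop("residue ", chain, ":", resno, insert, " not found in polymer chain")
  n <- nrow(res)
  take <- function(i) if (i >= 1 && i <= n) res$resname[i] else "XTR"
  vapply(c(pos - window:1, pos + 1:window), take, character(1))
}
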