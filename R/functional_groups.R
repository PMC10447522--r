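# Ligand functional-group perception from atomic connectivity.
#
# Groups follow the four propensity types used throughout the package:
#   L1: phenol
#   L2: alkyl hydroxyl
#   L3: sulfate, phosphate, carboxyl, carboxylate
#   L4: ester, amide, alkyl amine, N-containing aromatic heterocycle
# Anything else is OTHER. Matching is purely graph-based (elements + bonds),
# never coordinate-based, with the most specific pattern winning: S/P-bound
# oxygens first, then carboxylate before carboxyl (protonation state), then
# ester/amide, then phenol before alkyl hydroxyl.

FUNCTIONAL_GROUPS <- c("phenol", "alkyl_hydroxyl", "sulfate", "phosphate",
                       "carboxyl", "carboxylate", "ester", "amide",
                       "alkyl_amine", "n_aromatic", "OTHER")

#' Functional-group taxonomy
#'
#' Maps each named ligand functional group to its SHB-propensity type
#' (L1 highest to L4 lowest).
#'
#' @return named character vector: group -> type.
#' @export
functional_group_taxonomy <- function() {
  c(phenol = "L1",
    alkyl_hydroxyl = "L2",
    sulfate = "L3", phosphate = "L3", carboxyl = "L3", carboxylate = "L3",
    ester = "L4", amide = "L4", alkyl_amine = "L4", n_aromatic = "L4")
}

#' Amino-acid SHB-propensity typing
#'
#' The 11 polar amino acids fall into three propensity classes: A1 (high:
#' Tyr, Asp, Glu), A2 (intermediate: Ser, Thr, His) and A3 (low: Arg, Lys,
#' Asn, Gln, Trp).
#'
#' @return named character vector: residue code -> type.
#' @export
amino_acid_typing <- function() {
  c(TYR = "A1", ASP = "A1", GLU = "A1",
    SER = "A2", THR = "A2", HIS = "A2",
    ARG = "A3", LYS = "A3", ASN = "A3", GLN = "A3", TRP = "A3")
}

#' Build the connectivity graph of one ligand instance
#'
#' @param s `shb_structure`.
#' @param lig one element of `s$ligands` / [select_ligands()].
#' @return list with `idx` (global atom row indices), `element`, `name`,
#'   `adj`/`ord` (per-atom neighbor lists, local indices), and `aromatic`
#'   (logical per atom).
#' @export
ligand_graph <- function(s, lig) {
  idx <- lig$atoms
  n <- length(idx)
  loc <- match(seq_len(nrow(s$atoms)), idx)
  adj <- rep(list(integer(0)), n)
  ord <- rep(list(character(0)), n)
  b <- lig$bonds
  if (!is.null(b) && nrow(b) > 0) {
    for (k in seq_len(nrow(b))) {
      i <- loc[b$i[k]]; j <- loc[b$j[k]]
      if (is.na(i) || is.na(j)) next
      adj[[i]] <- c(adj[[i]], j); ord[[i]] <- c(ord[[i]], b$order[k])
      adj[[j]] <- c(adj[[j]], i); ord[[j]] <- c(ord[[j]], b$order[k])
    }
  }
  g <- list(idx = idx, element = s$atoms$element[idx],
            name = s$atoms$name[idx], adj = adj, ord = ord)
  g$aromatic <- aromatic_atoms(g)
  g
}

# Enumerate simple rings of size 5 or 6 and flag members aromatic when at
# least half of the ring bonds are non-single (covers both explicit aromatic
# flags and Kekule alternation from dictionaries or bond-length inference).
aromatic_atoms <- function(g) {
  n <- length(g$element)
  arom <- rep(FALSE, n)
  rings <- find_rings(g$adj, max_size = 6)
  for (r in rings) {
    if (length(r) < 5) next
    k <- length(r)
    nonsingle <- 0
    for (i in seq_len(k)) {
      a <- r[i]; b <- r[if (i == k) 1 else i + 1]
      pos <- which(g$adj[[a]] == b)[1]
      if (!is.na(pos) && g$ord[[a]][pos] != "1") nonsingle <- nonsingle + 1
    }
    if (nonsingle >= floor(k / 2)) arom[r] <- TRUE
  }
  arom
}

# All simple cycles up to max_size, deduplicated by membership set.
find_rings <- function(adj, max_size = 6) {
  n <- length(adj)
  seen <- character(0)
  rings <- list()
  dfs <- function(start, path) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb == start && length(path) >= 3) {
        key <- paste(sort(path), collapse = ",")
        if (!(key %in% seen)) {
          seen <<- c(seen, key)
          rings[[length(rings) + 1]] <<- path
        }
      } else if (!(nb %in% path) && nb > start && length(path) < max_size) {
        dfs(start, c(path, nb))
      }
    }
  }
  for (v in seq_len(n)) dfs(v, v)
  rings
}

heavy_neighbors <- function(g, i) {
  nb <- g$adj[[i]]
  nb[g$element[nb] != "H"]
}

h_count <- function(g, i) sum(g$element[g$adj[[i]]] == "H")

# Terminal oxygens (heavy degree 1) attached to a carbon.
terminal_oxygens <- function(g, c_local) {
  nb <- heavy_neighbors(g, c_local)
  o <- nb[g$element[nb] == "O"]
  o[vapply(o, function(j) length(heavy_neighbors(g, j)) == 1, logical(1))]
}

# Carbonyl oxygens: terminal O double-bonded to the carbon.
carbonyl_oxygens <- function(g, c_local) {
  term <- terminal_oxygens(g, c_local)
  term[vapply(term, function(j) {
    pos <- which(g$adj[[c_local]] == j)[1]
    !is.na(pos) && g$ord[[c_local]][pos] == "2"
  }, logical(1))]
}

#' Classify the functional group of a ligand heteroatom
#'
#' Determines which hydrogen-bonding functional group the participating O or
#' N atom of a ligand belongs to, by matching connectivity patterns in a
#' fixed most-specific-first order. The result depends only on the ligand
#' graph, not on coordinates.
#'
#' @param g from [ligand_graph()].
#' @param atom participating heteroatom, as a global atom row index.
#' @return one of "phenol", "alkyl_hydroxyl", "sulfate", "phosphate",
#'   "carboxyl", "carboxylate", "ester", "amide", "alkyl_amine",
#'   "n_aromatic" or "OTHER".
#' @export
detect_functional_group <- function(g, atom) {
  i <- match(atom, g$idx)
  if (is.na(i)) stop("atom ", atom, " is not part of the ligand")
  el <- g$element[i]
  if (!(el %in% c("O", "N")))
    stop("functional-group classification requires an O or N atom, got ", el)
  nb <- heavy_neighbors(g, i)
  if (el == "O") {
    if (any(g$element[nb] == "P")) return("phosphate")
    if (any(g$element[nb] == "S")) return("sulfate")
    cnb <- nb[g$element[nb] == "C"]
    if (length(nb) == 1 && length(cnb) == 1) {
      cc <- cnb[1]
      term_o <- terminal_oxygens(g, cc)
      carb_o <- carbonyl_oxygens(g, cc)
      if (length(term_o) >= 2 && length(carb_o) >= 1) {
        # carboxyl(ate): both terminal oxygens share the classification
        any_h <- any(vapply(term_o, function(j) h_count(g, j) > 0,
                            logical(1)))
        return(if (any_h) "carboxyl" else "carboxylate")
      }
      bridge_o <- setdiff(which_bridging_o(g, cc), i)
      if (i %in% carb_o && length(bridge_o) >= 1)
        return("ester")
      if (i %in% carb_o &&
          any(g$element[heavy_neighbors(g, cc)] == "N"))
        return("amide")
      if (i %in% carb_o)
        return("OTHER")  # bare carbonyl (ketone/aldehyde)
      if (g$aromatic[cc]) return("phenol")
      return("alkyl_hydroxyl")
    }
    if (length(nb) == 2 && length(cnb) == 2) {
      # bridging C-O-C: ester linkage if either carbon is carbonyl-like
      if (any(vapply(cnb, function(cc) length(carbonyl_oxygens(g, cc)) > 0,
                     logical(1))))
        return("ester")
      return("OTHER")  # plain ether
    }
    return("OTHER")
  }
  # nitrogen
  amide_c <- nb[g$element[nb] == "C" &
                  vapply(nb, function(cc)
                    g$element[cc] == "C" &&
                      length(carbonyl_oxygens(g, cc)) > 0, logical(1))]
  if (length(amide_c) > 0 && !g$aromatic[i]) return("amide")
  if (g$aromatic[i]) return("n_aromatic")
  if (length(nb) > 0 && all(g$element[nb] == "C") &&
      !any(g$aromatic[nb]))
    return("alkyl_amine")
  "OTHER"
}

which_bridging_o <- function(g, c_local) {
  nb <- heavy_neighbors(g, c_local)
  o <- nb[g$element[nb] == "O"]
  o[vapply(o, function(j) {
    hn <- heavy_neighbors(g, j)
    length(hn) == 2 && all(g$element[hn] %in% c("C", "P", "S"))
  }, logical(1))]
}

# Polar-atom typing for a ligand: how many hydrogens each O/N should carry
# and whether it keeps an available lone pair. Protonation states follow a
# fixed pH-7 convention: sulfate/phosphate/carboxylate oxygens deprotonated,
# hydroxyls protonated, amide N fills its valence, aromatic N without
# explicit H is a pyridine-like acceptor, alkyl amines neutral.
ligand_polar_typing <- function(g) {
  out <- data.frame(atom = integer(), group = character(),
                    n_h = integer(), lone_pair = logical(),
                    neighbor = integer(), geom = character(),
                    stringsAsFactors = FALSE)
  for (i in seq_along(g$element)) {
    el <- g$element[i]
    if (!(el %in% c("O", "N"))) next
    grp <- detect_functional_group(g, g$idx[i])
    nb <- heavy_neighbors(g, i)
    nbh <- if (length(nb) > 0) g$idx[nb[1]] else NA_integer_
    exp_h <- h_count(g, i)
    if (el == "O") {
      n_h <- if (grp %in% c("phenol", "alkyl_hydroxyl") &&
                 length(nb) == 1) 1L else 0L
      if (exp_h > 0) n_h <- exp_h  # explicit hydrogens win
      out <- rbind(out, data.frame(
        atom = g$idx[i], group = grp, n_h = n_h, lone_pair = TRUE,
        neighbor = nbh, geom = "hydroxyl", stringsAsFactors = FALSE))
    } else {
      deg <- length(nb)
      if (grp == "amide") {
        n_h <- max(0L, 3L - deg); geom <- "planar_n"; lp <- FALSE
      } else if (grp == "n_aromatic") {
        n_h <- 0L; geom <- "none"; lp <- (exp_h == 0)
      } else if (grp == "alkyl_amine") {
        n_h <- max(0L, 3L - deg); geom <- "sp3_n"; lp <- TRUE
      } else {
        n_h <- max(0L, 3L - deg); geom <- if (deg >= 2) "planar_n" else "sp3_n"
        lp <- (n_h + deg) <= 3
      }
      if (exp_h > 0) n_h <- exp_h
      out <- rbind(out, data.frame(
        atom = g$idx[i], group = grp, n_h = n_h, lone_pair = lp,
        neighbor = nbh, geom = geom, stringsAsFactors = FALSE))
    }
  }
  out
}
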