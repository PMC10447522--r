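# Ligand physicochemical descriptors: pKa, pKb and logP.
#
# Preferred source is a user-supplied table keyed by component code (as
# computed by any external property engine). When a ligand is absent and the
# fallback is enabled, logP is estimated with a Wildman-Crippen style
# atom-contribution sum over the ligand graph, and pKa/pKb from canonical
# per-functional-group constants. Provenance ("table" vs "estimated") is
# recorded so downstream users can tell the sources apart.

# Wildman & Crippen (1999) atomic contributions, reduced to the atom classes
# this fallback can discriminate from element + connectivity.
CRIPPEN_CONTRIB <- c(
  H_C = 0.1230, H_O = -0.2677, H_O_acid = 0.2980, H_N = 0.2142,
  C_sp3 = 0.1441, C_sp3_tert = 0.0000, C_sp3_het = -0.2035,
  C_sp3_het_tert = -0.2051, C_carbonyl = -0.2783,
  C_ar_H = 0.1581, C_ar_sub = 0.1360, C_ar_het = 0.5437,
  O_alcohol = -0.2893, O_carbonyl = -0.1526, O_ether = -0.0684,
  N_amine = -1.0190, N_ar = -0.3239, N_amide = -0.6027,
  P = 0.8612, S = 0.6482, F = -0.0031, CL = 0.6445,
  BR = 0.8456, I = 0.8857, OTHER = 0.0)

# Canonical per-group acidity/basicity constants used by the fallback
# estimator (pKa of the most acidic proton of the group; pKb = 14 minus the
# conjugate-acid pKa of the basic site).
GROUP_PKA_PKB <- list(
  phenol         = c(pKa = 10.0, pKb = 13.0),
  alkyl_hydroxyl = c(pKa = 15.5, pKb = 12.5),
  carboxyl       = c(pKa = 4.0,  pKb = 12.0),
  carboxylate    = c(pKa = 4.0,  pKb = 12.0),
  phosphate      = c(pKa = 6.8,  pKb = 13.0),
  sulfate        = c(pKa = 1.9,  pKb = 13.5),
  ester          = c(pKa = 25.0, pKb = 13.5),
  amide          = c(pKa = 16.5, pKb = 13.9),
  alkyl_amine    = c(pKa = 10.6, pKb = 3.4),
  n_aromatic     = c(pKa = 15.0, pKb = 8.8))

# Formal charge of the participating group at pH 7.
GROUP_CHARGE <- c(phenol = 0, alkyl_hydroxyl = 0, sulfate = -1,
                  phosphate = -1, carboxyl = 0, carboxylate = -1,
                  ester = 0, amide = 0, alkyl_amine = 1, n_aromatic = 0,
                  OTHER = 0)

#' Estimate logP by atom contributions
#'
#' Sums Wildman-Crippen style atomic contributions over the ligand graph.
#' Implicit hydrogens are inferred from standard valences and the bond
#' orders stored in the graph.
#'
#' @param g from [ligand_graph()].
#' @return estimated octanol-water logP.
#' @export
estimate_logp <- function(g) {
  total <- 0
  for (i in seq_along(g$element)) {
    el <- g$element[i]
    if (el == "H") next
    nb <- g$adj[[i]]
    heavy <- nb[g$element[nb] != "H"]
    exp_h <- sum(g$element[nb] == "H")
    # bond_order_sum already counts explicit H bonds, so implicit_h returns
    # only the hydrogens still unaccounted for
    n_h <- exp_h + implicit_h(g, i)
    total <- total + atom_contrib(g, i, heavy, n_h) +
      n_h * h_contrib(g, i, heavy)
  }
  total
}

bond_order_sum <- function(g, i) {
  o <- g$ord[[i]]
  sum(vapply(o, function(x) switch(x, "2" = 2, "ar" = 1.5, 1), numeric(1)))
}

implicit_h <- function(g, i) {
  val <- switch(g$element[i], C = 4, N = 3, O = 2, S = 2, P = 5, 0)
  max(0, round(val - bond_order_sum(g, i)))
}

atom_contrib <- function(g, i, heavy, n_h) {
  el <- g$element[i]
  het <- any(g$element[heavy] %in% c("N", "O", "P", "S", "F", "CL", "BR", "I"))
  cc <- CRIPPEN_CONTRIB
  if (el == "C") {
    if (isTRUE(g$aromatic[i])) {
      if (n_h > 0) return(cc[["C_ar_H"]])
      if (any(g$element[heavy] %in% c("O", "N"))) return(cc[["C_ar_het"]])
      return(cc[["C_ar_sub"]])
    }
    if (length(carbonyl_oxygens(g, i)) > 0) return(cc[["C_carbonyl"]])
    nC <- sum(g$element[heavy] == "C")
    if (het) {
      if (length(heavy) >= 3) return(cc[["C_sp3_het_tert"]])
      return(cc[["C_sp3_het"]])
    }
    if (nC >= 3) return(cc[["C_sp3_tert"]])
    return(cc[["C_sp3"]])
  }
  if (el == "O") {
    if (length(heavy) == 1 && g$element[heavy[1]] == "C" &&
        i %in% carbonyl_oxygens(g, heavy[1]))
      return(cc[["O_carbonyl"]])
    if (length(heavy) == 2) return(cc[["O_ether"]])
    return(cc[["O_alcohol"]])
  }
  if (el == "N") {
    if (isTRUE(g$aromatic[i])) return(cc[["N_ar"]])
    amide <- any(vapply(heavy, function(j)
      g$element[j] == "C" && length(carbonyl_oxygens(g, j)) > 0,
      logical(1)))
    if (amide) return(cc[["N_amide"]])
    return(cc[["N_amine"]])
  }
  if (el %in% names(cc)) return(cc[[el]])
  cc[["OTHER"]]
}

h_contrib <- function(g, i, heavy) {
  el <- g$element[i]
  cc <- CRIPPEN_CONTRIB
  if (el == "C") return(cc[["H_C"]])
  if (el == "O") {
    if (length(heavy) == 1 && g$element[heavy[1]] == "C" &&
        length(carbonyl_oxygens(g, heavy[1])) > 0)
      return(cc[["H_O_acid"]])
    return(cc[["H_O"]])
  }
  if (el == "N") return(cc[["H_N"]])
  0
}

#' Read a ligand physicochemical table
#'
#' CSV/TSV with columns `code`, `pKa`, `pKb`, `logP` (extra columns are
#' ignored), one row per component code.
#'
#' @param path file path; separator sniffed from the extension.
#' @return data.frame keyed by `code`.
#' @export
read_physchem_table <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) %in% c("tsv", "txt")) "\t" else ","
  tb <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE,
                   strip.white = TRUE)
  need <- c("code", "pKa", "pKb", "logP")
  miss <- setdiff(tolower(need), tolower(names(tb)))
  if (length(miss) > 0)
    stop("physchem table is missing columns: ", paste(miss, collapse = ", "))
  names(tb)[match(tolower(need), tolower(names(tb)))] <- need
  for (col in c("pKa", "pKb", "logP")) {
    v <- tb[[col]]
    if (!is.numeric(v)) {
      suppressWarnings(num <- as.numeric(v))
      if (any(is.na(num) & !is.na(v) & v != "" & toupper(v) != "NA"))
        stop("non-numeric value in physchem column ", col)
      tb[[col]] <- num
    }
  }
  tb
}

#' Ligand physicochemical descriptors for one hydrogen bond
#'
#' @param code ligand component code.
#' @param group functional group of the participating heteroatom.
#' @param graph ligand graph (needed by the fallback logP estimator).
#' @param table optional data.frame from [read_physchem_table()].
#' @param fallback use the built-in estimators when the code is absent from
#'   the table (default `TRUE`); when disabled, missing values stay `NA`.
#' @return list with `lig_charge`, `lig_pKa`, `lig_pKb`, `lig_logP`,
#'   `provenance`.
#' @export
ligand_descriptors <- function(code, group, graph = NULL, table = NULL,
                               fallback = TRUE) {
  charge <- unname(GROUP_CHARGE[group])
  if (is.na(charge)) charge <- 0
  if (!is.null(table)) {
    hit <- which(toupper(table$code) == toupper(code))
    if (length(hit) >= 1) {
      r <- table[hit[1], ]
      return(list(lig_charge = charge, lig_pKa = r$pKa, lig_pKb = r$pKb,
                  lig_logP = r$logP, provenance = "table"))
    }
  }
  if (!fallback)
    return(list(lig_charge = charge, lig_pKa = NA_real_, lig_pKb = NA_real_,
                lig_logP = NA_real_, provenance = "missing"))
  pk <- GROUP_PKA_PKB[[group]]
  if (is.null(pk)) pk <- c(pKa = NA_real_, pKb = NA_real_)
  logp <- if (!is.null(graph)) estimate_logp(graph) else NA_real_
  list(lig_charge = charge, lig_pKa = unname(pk["pKa"]),
       lig_pKb = unname(pk["pKb"]), lig_logP = logp,
       provenance = "estimated")
}
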