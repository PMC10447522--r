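# Assembly of the 14 model inputs for each protein-ligand hydrogen bond:
# amino-acid charge, residue type and side-chain heteroatom; ligand group
# charge, functional group, pKa, pKb and logP; and the residue codes of the
# three sequence neighbors on each side of the hydrogen-bonded amino acid.

FEATURE_COLUMNS <- c("aa_charge", "aa_residue", "aa_heteroatom",
                     "lig_charge", "lig_functional_group",
                     "lig_pKa", "lig_pKb", "lig_logP",
                     "seq_m3", "seq_m2", "seq_m1",
                     "seq_p1", "seq_p2", "seq_p3")

# Fixed pH-7 side-chain charge assignment.
AA_CHARGE <- c(ASP = -1, GLU = -1, LYS = 1, ARG = 1,
               SER = 0, THR = 0, TYR = 0, HIS = 0, ASN = 0, GLN = 0,
               TRP = 0, ALA = 0, CYS = 0, GLY = 0, ILE = 0, LEU = 0,
               MET = 0, PHE = 0, PRO = 0, VAL = 0)

#' Amino-acid descriptors of a hydrogen bond
#'
#' @param resname 3-letter residue code.
#' @param heteroatom participating side-chain atom name (e.g. `"OD1"`).
#' @param charge_overrides optional named vector overriding the pH-7 charge
#'   table (e.g. `c(HIS = 1)`).
#' @return list with `aa_charge`, `aa_residue`, `aa_heteroatom`.
#' @export
amino_acid_descriptors <- function(resname, heteroatom,
                                   charge_overrides = NULL) {
  resname <- toupper(resname)
  if (!(resname %in% names(AA_CHARGE)))
    stop("unknown residue code: ", resname)
  charge <- unname(AA_CHARGE[resname])
  if (!is.null(charge_overrides) && resname %in% names(charge_overrides))
    charge <- unname(charge_overrides[resname])
  list(aa_charge = charge, aa_residue = resname,
       aa_heteroatom = toupper(heteroatom))
}

#' Build the feature vector of one detected hydrogen bond
#'
#' The protein partner must participate through its side chain (backbone
#' partners are not modeled).
#'
#' @param hb one row of the record table from [detect_hbonds()], restricted
#'   to `partner_kind == "protein-ligand"`.
#' @param s the `shb_structure` the record came from.
#' @param ligands ligand list used during detection.
#' @param physchem optional table from [read_physchem_table()].
#' @param fallback enable built-in pKa/pKb/logP estimation for ligands
#'   absent from the table.
#' @param charge_overrides see [amino_acid_descriptors()].
#' @return one-row data.frame with the 14 predictor columns plus `R`,
#'   `theta`, `label` (from `distance_class`, `NA` for AMBIGUOUS bonds) and
#'   identifying columns.
#' @export
build_feature_vector <- function(hb, s, ligands = NULL, physchem = NULL,
                                 fallback = TRUE, charge_overrides = NULL) {
  if (hb$partner_kind != "protein-ligand")
    stop("feature vectors are defined for protein-ligand bonds only")
  if (is.null(ligands)) ligands <- select_ligands(s)
  on_ligand <- hb$donor_is_ligand
  if (on_ligand) {
    aa <- list(resname = hb$acceptor_resname, atom = hb$acceptor_atom,
               chain = hb$acceptor_chain, resno = hb$acceptor_resno,
               insert = hb$acceptor_insert)
    lig_atom <- hb$donor_idx; lig_group <- hb$donor_group
  } else {
    aa <- list(resname = hb$donor_resname, atom = hb$donor_atom,
               chain = hb$donor_chain, resno = hb$donor_resno,
               insert = hb$donor_insert)
    lig_atom <- hb$acceptor_idx; lig_group <- hb$acceptor_group
  }
  if (aa$atom %in% c("N", "O", "C", "CA", "OXT"))
    stop("backbone protein partner is not modeled")
  aad <- amino_acid_descriptors(aa$resname, aa$atom, charge_overrides)
  # locate the ligand instance containing the participating atom
  li <- which(vapply(ligands, function(lg) lig_atom %in% lg$atoms,
                     logical(1)))
  if (length(li) == 0)
    stop("participating ligand atom not found in the supplied ligand list")
  lg <- ligands[[li[1]]]
  g <- ligand_graph(s, lg)
  if (is.na(lig_group) || !nzchar(lig_group))
    lig_group <- detect_functional_group(g, lig_atom)
  ld <- ligand_descriptors(lg$code, lig_group, graph = g, table = physchem,
                           fallback = fallback)
  ctx <- sequence_context(s, aa$chain, aa$resno, aa$insert, window = 3)
  label <- switch(hb$distance_class, SHB = "SHB", NHB = "NHB",
                  NA_character_)
  data.frame(aa_charge = aad$aa_charge, aa_residue = aad$aa_residue,
             aa_heteroatom = aad$aa_heteroatom,
             lig_charge = ld$lig_charge,
             lig_functional_group = lig_group,
             lig_pKa = ld$lig_pKa, lig_pKb = ld$lig_pKb,
             lig_logP = ld$lig_logP,
             seq_m3 = ctx[1], seq_m2 = ctx[2], seq_m1 = ctx[3],
             seq_p1 = ctx[4], seq_p2 = ctx[5], seq_p3 = ctx[6],
             label = label, R = hb$R, theta = hb$theta,
             ligand_code = lg$code,
             aa_chain = aa$chain, aa_resno = aa$resno,
             physchem_provenance = ld$provenance,
             stringsAsFactors = FALSE)
}

#' Featurize all protein-ligand hydrogen bonds of a structure
#'
#' @param records data.frame from [detect_hbonds()].
#' @inheritParams build_feature_vector
#' @return data.frame, one row per protein-ligand record.
#' @export
build_feature_table <- function(records, s, ligands = NULL, physchem = NULL,
                                fallback = TRUE, charge_overrides = NULL) {
  if (is.null(ligands)) ligands <- select_ligands(s)
  pl <- records[records$partner_kind == "protein-ligand", , drop = FALSE]
  if (nrow(pl) == 0) return(NULL)
  rows <- lapply(seq_len(nrow(pl)), function(k)
    build_feature_vector(pl[k, ], s, ligands, physchem, fallback,
                         charge_overrides))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read / write feature tables
#'
#' Feature tables are TSV (or CSV) files with the 14 predictor columns, an
#' optional `label` column (`SHB`/`NHB`) and any extra bond-geometry or
#' identification columns.
#'
#' @param path file path; separator sniffed from the extension.
#' @return data.frame.
#' @export
read_feature_table <- function(path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  tb <- read.table(path, header = TRUE, sep = sep, stringsAsFactors = FALSE)
  miss <- setdiff(FEATURE_COLUMNS, names(tb))
  if (length(miss) > 0)
    stop("feature table is missing predictor columns: ",
         paste(miss, collapse = ", "))
  tb
}

#' @rdname read_feature_table
#' @param tb feature table.
#' @export
write_feature_table <- function(tb, path) {
  sep <- if (tolower(tools::file_ext(path)) == "csv") "," else "\t"
  write.table(tb, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
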