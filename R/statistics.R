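# Descriptive statistics of detected hydrogen bonds: per-group SHB
# propensities, ligand-category distributions and R histograms.

#' SHB propensity table
#'
#' Counts SHBs and NHBs per group (residue code or ligand functional group)
#' and computes the propensity P_SHB = N_SHB / (N_SHB + N_NHB). AMBIGUOUS
#' records (2.7 < R < 2.8) are excluded.
#'
#' @param records hydrogen-bond record table with `distance_class`; for
#'   `group_by = "residue"` the protein residue is used, for
#'   `"functional_group"` the participating ligand group.
#' @param group_by `"residue"` or `"functional_group"`.
#' @return data.frame with columns `group`, `N_SHB`, `N_NHB`, `P_SHB`
#'   (fraction) and `P_SHB_pct` (rounded to whole percent), sorted by
#'   decreasing propensity.
#' @export
pshb_table <- function(records, group_by = c("residue", "functional_group")) {
  group_by <- match.arg(group_by)
  if (nrow(records) == 0)
    return(data.frame(group = character(), N_SHB = integer(),
                      N_NHB = integer(), P_SHB = numeric(),
                      P_SHB_pct = numeric(), stringsAsFactors = FALSE))
  rec <- records[records$distance_class %in% c("SHB", "NHB"), , drop = FALSE]
  key <- if (group_by == "residue") {
    ifelse(rec$donor_is_ligand, rec$acceptor_resname, rec$donor_resname)
  } else {
    ifelse(rec$donor_is_ligand, rec$donor_group, rec$acceptor_group)
  }
  tab <- table(key, factor(rec$distance_class, levels = c("SHB", "NHB")))
  out <- data.frame(group = rownames(tab),
                    N_SHB = as.integer(tab[, "SHB"]),
                    N_NHB = as.integer(tab[, "NHB"]),
                    stringsAsFactors = FALSE)
  tot <- out$N_SHB + out$N_NHB
  out$P_SHB <- ifelse(tot > 0, out$N_SHB / tot, NA_real_)
  out$P_SHB_pct <- round(100 * out$P_SHB)
  out <- out[order(-out$P_SHB), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Propensity from explicit counts
#'
#' Convenience constructor for propensity rows given known SHB/NHB counts
#' per group.
#'
#' @param group group labels.
#' @param n_shb,n_nhb counts.
#' @return same layout as [pshb_table()].
#' @export
pshb_from_counts <- function(group, n_shb, n_nhb) {
  stopifnot(length(group) == length(n_shb), length(n_shb) == length(n_nhb),
            all(n_shb >= 0), all(n_nhb >= 0))
  tot <- n_shb + n_nhb
  out <- data.frame(group = as.character(group), N_SHB = as.integer(n_shb),
                    N_NHB = as.integer(n_nhb),
                    P_SHB = ifelse(tot > 0, n_shb / tot, NA_real_),
                    stringsAsFactors = FALSE)
  out$P_SHB_pct <- round(100 * out$P_SHB)
  out
}

#' Distribution of ligand categories among SHBs
#'
#' Maps each SHB record's ligand to a category (carbohydrates, nucleotides,
#' acids/anions, hemes, non-proteinogenic amino acids, Other) through a
#' user-editable component-code map and reports the percentage of SHBs per
#' category.
#'
#' @param records hydrogen-bond records (only rows with
#'   `distance_class == "SHB"` and a ligand partner are used).
#' @param category_map data.frame with columns `code`, `category`; `NULL`
#'   loads the packaged default map.
#' @return data.frame with `category`, `n`, `percent` (sums to 100).
#' @export
category_distribution <- function(records, category_map = NULL) {
  if (is.null(category_map)) {
    category_map <- read.table(
      system.file("extdata", "ligand_categories.tsv", package = "shbligand"),
      header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  }
  shb <- records[records$distance_class == "SHB" &
                   records$partner_kind == "protein-ligand", , drop = FALSE]
  if (nrow(shb) == 0)
    return(data.frame(category = character(), n = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  cat_of <- category_map$category[match(toupper(shb$ligand_code),
                                        toupper(category_map$code))]
  if (any(is.na(cat_of))) {
    warning("unmapped ligand code(s) assigned to Other: ",
            paste(unique(shb$ligand_code[is.na(cat_of)]), collapse = ", "))
    cat_of[is.na(cat_of)] <- "Other"
  }
  tab <- table(cat_of)
  out <- data.frame(category = names(tab), n = as.integer(tab),
                    stringsAsFactors = FALSE)
  out$percent <- 100 * out$n / sum(out$n)
  out[order(-out$n), , drop = FALSE]
}

#' Histogram of donor-acceptor distances
#'
#' Bins R over the detection window [2.3, 3.2] and normalizes counts to
#' probabilities within each partner kind (protein-protein vs
#' protein-ligand), for distribution plots.
#'
#' @param records hydrogen-bond records.
#' @param bin_width bin width in Angstrom (default 0.05; must be > 0).
#' @return data.frame with `partner_kind`, `bin_mid`, `count`,
#'   `probability` (sums to 1 within each partner kind).
#' @export
r_histogram <- function(records, bin_width = 0.05) {
  if (!is.numeric(bin_width) || bin_width <= 0)
    stop("bin_width must be positive")
  if (nrow(records) == 0) stop("no records to bin")
  k <- ceiling((HB_R_MAX - HB_R_MIN) / bin_width - 1e-9)
  breaks <- HB_R_MIN + bin_width * (0:k)
  nb <- length(breaks)
  if (abs(breaks[nb] - HB_R_MAX) < 1e-9) breaks[nb] <- HB_R_MAX
  else if (breaks[nb] < HB_R_MAX) breaks <- c(breaks, breaks[nb] + bin_width)
  out <- list()
  for (pk in unique(records$partner_kind)) {
    r <- records$R[records$partner_kind == pk]
    h <- hist(r, breaks = breaks, plot = FALSE, include.lowest = TRUE,
              right = FALSE)
    out[[pk]] <- data.frame(partner_kind = pk, bin_mid = h$mids,
                            count = h$counts,
                            probability = h$counts / sum(h$counts),
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Charged vs neutral SHB breakdown
#'
#' Splits protein-ligand SHBs by whether at least one participant (the
#' amino-acid side chain or the ligand functional group) carries a formal
#' charge at pH 7.
#'
#' @param features feature table from [build_feature_table()] with labels.
#' @return data.frame with `kind` ("charged"/"neutral"), `n`, `percent`.
#' @export
charge_distribution <- function(features) {
  shb <- features[!is.na(features$label) & features$label == "SHB", ,
                  drop = FALSE]
  if (nrow(shb) == 0)
    return(data.frame(kind = character(), n = integer(),
                      percent = numeric(), stringsAsFactors = FALSE))
  charged <- shb$aa_charge != 0 | shb$lig_charge != 0
  tab <- c(charged = sum(charged), neutral = sum(!charged))
  data.frame(kind = names(tab), n = as.integer(tab),
             percent = 100 * as.integer(tab) / sum(tab),
             stringsAsFactors = FALSE)
}
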