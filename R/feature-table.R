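# The frozen 97-feature registry and the feature-table operations:
# assembly, z-score standardization, hotspot labelling and CORE_RIM.

#' The frozen 97-feature registry
#'
#' The ordered names and family assignment of the 97 per-residue
#' features: 10 amino-acid physicochemical properties, 16 depth and
#' protrusion index features, 54 solvent-accessibility features, 5
#' electrostatic-potential summaries, 2 interface hydrogen-bond counts,
#' 5 secondary-structure indicator features and 5 conservation features.
#' Published anchor positions pin part of the ordering (Na = 1,
#' Nphb = 3, Hdrpo = 4, PItu = 13, PIsu = 14, DItb = 15, DIsb = 16,
#' dDIt = 19, dDIs = 20, dPIs = 22, SAStau = 29, SASbau = 33,
#' SASpau = 37, SAStab = 39, dSASta_p0.5 = 49, dSASsa_p0.5 = 50,
#' dSASnr_p0.5 = 68, esp1 = 81, esp3 = 83, Helix = 88, CNSV = 93); the
#' remaining order is frozen here and is authoritative for this package.
#'
#' Naming: \code{SAS<c><r><s>} with atom class \code{c} in t (total),
#' s (side chain), b (backbone), n (nonpolar), p (polar); representation
#' \code{r} in a (absolute) or r (relative); state \code{s} in u
#' (unbound) or b (bound).  \code{dSAS*} are buried (unbound - bound)
#' values and \code{_p<e>} marks the power \code{e}.
#'
#' @return data.frame with columns index, name, family.
#' @export
feature_registry <- function() {
  if (!is.null(.pnhot_env$registry)) return(.pnhot_env$registry)
  physchem <- c("Na", "Nelc", "Nphb", "Hdrpo", "Hdrpi", "Pol", "Viso",
                "Mass", "Vol", "Asa")
  dipi <- c("DItu", "DIsu", "PItu", "PIsu", "DItb", "DIsb", "PItb",
            "PIsb", "dDIt", "dDIs", "dPIt", "dPIs", "relDIt", "relDIs",
            "relPIt", "relPIs")
  cats <- c("t", "s", "b", "n", "p")
  cats_rel <- c("t", "s", "b", "p", "n")
  sasa <- c(
    "dSASta", "dSAStr",
    as.vector(rbind(paste0("SAS", cats, "au"),
                    paste0("SAS", cats, "ru"))),
    as.vector(rbind(paste0("SAS", cats, "ab"),
                    paste0("SAS", cats, "rb"))),
    paste0("dSAS", cats, "a_p0.5"),
    paste0("dSAS", cats, "a_p1.5"),
    paste0("dSAS", cats, "a_p2"),
    paste0("dSAS", cats_rel, "r_p0.5"),
    paste0("dSAS", cats_rel, "r_p1.5"),
    paste0("dSAS", cats_rel, "r_p2"),
    "dSASsa", "dSASsr")
  esp <- paste0("esp", 1:5)
  hbond <- c("Nhb", "Nhbs")
  ss <- c("Helix", "Strand", "Turn", "Helix1", "Loop")
  cons <- c("CNSV", "CNSV_REL1_wop", "CNSV_REL2_wop", "CNSV_REL1_pps",
            "CNSV_REL2_pps")
  name <- c(physchem, dipi, sasa, esp, hbond, ss, cons)
  family <- rep(c("physchem", "dipi", "sasa", "esp", "hbond", "ss",
                  "conservation"),
                c(length(physchem), length(dipi), length(sasa),
                  length(esp), length(hbond), length(ss), length(cons)))
  stopifnot(length(name) == 97L, !anyDuplicated(name))
  reg <- data.frame(index = seq_along(name), name = name,
                    family = family, stringsAsFactors = FALSE)
  .pnhot_env$registry <- reg
  reg
}

#' Assemble the 97-feature vector of one interface residue
#'
#' Concatenates the per-family feature blocks in registry order.  Every
#' block must be present and complete; a missing block is a typed error
#' naming the family.
#'
#' @param physchem,dipi,sasa,esp,hbond,ss,conservation named numeric
#'   vectors as produced by the corresponding feature functions
#'   (\code{\link{physchem_features}}, \code{\link{dipi_feature_block}},
#'   \code{\link{sasa_feature_block}}, \code{\link{esp_features}},
#'   \code{\link{interface_hbond_counts}},
#'   \code{\link{secondary_structure}},
#'   \code{\link{conservation_features}}).
#' @return named numeric vector of length 97 in registry order.
#' @export
assemble_features <- function(physchem, dipi, sasa, esp, hbond, ss,
                              conservation) {
  blocks <- list(physchem = physchem, dipi = dipi, sasa = sasa,
                 esp = esp, hbond = hbond, ss = ss,
                 conservation = conservation)
  reg <- feature_registry()
  out <- numeric(0)
  for (fam in unique(reg$family)) {
    b <- blocks[[fam]]
    if (is.null(b)) stop(fam, " block absent")
    b <- unlist(b)
    want <- reg$name[reg$family == fam]
    if (is.null(names(b)) || !all(want %in% names(b))) {
      if (length(b) == length(want)) names(b) <- want
      else stop(fam, " block incomplete")
    }
    out <- c(out, b[want])
  }
  if (any(!is.finite(out))) stop("non-finite feature values")
  stopifnot(length(out) == 97L)
  out
}

#' Z-score standardization with training-derived parameters
#'
#' Fits per-feature mean and standard deviation on \code{fit_rows} and
#' applies the transform to all rows; constant features (sd 0) map to 0.
#' Test rows are always standardized with the training parameters.
#'
#' @param x numeric matrix (rows = residues, columns = features).
#' @param fit_rows indices of rows used to fit the parameters (default
#'   all rows).
#' @param params optional precomputed list with \code{mean} and
#'   \code{sd}; when given, \code{fit_rows} is ignored.
#' @return list with \code{x} (standardized matrix), \code{mean},
#'   \code{sd}.
#' @export
standardize <- function(x, fit_rows = seq_len(nrow(x)), params = NULL) {
  x <- as.matrix(x)
  if (is.null(params)) {
    if (length(fit_rows) == 0L) stop("fit_rows is empty")
    mu <- colMeans(x[fit_rows, , drop = FALSE])
    sd <- apply(x[fit_rows, , drop = FALSE], 2, stats::sd)
    sd[is.na(sd)] <- 0
  } else {
    mu <- params$mean
    sd <- params$sd
  }
  z <- sweep(x, 2, mu, `-`)
  z <- sweep(z, 2, ifelse(sd > 0, sd, 1), `/`)
  z[, sd == 0] <- 0
  list(x = z, mean = mu, sd = sd)
}

#' Hotspot label from an alanine-mutation ddG
#'
#' A residue is a hot spot when its alanine-mutation binding free energy
#' change reaches the cutoff (ties count as hot spots: the rule is
#' \code{ddG >= cutoff}).
#'
#' @param ddG binding free energy change(s) in kcal/mol.
#' @param cutoff hotspot cutoff in kcal/mol (default 2.0).
#' @return logical vector, \code{TRUE} for hot spots.
#' @export
label_hotspot <- function(ddG, cutoff = 2.0) {
  if (any(!is.finite(ddG))) stop("non-finite ddG")
  ddG >= cutoff
}

#' Read an alanine-scanning ddG table
#'
#' Tab-separated table with columns pdb_id, chain, res_num, wild_res and
#' ddG (kcal/mol); extra columns are kept.  An alanine wild-type row is
#' reported with a warning (alanine cannot be alanine-scanned) but not
#' dropped.
#'
#' @param path TSV file.
#' @return data.frame with a \code{key} column
#'   (\code{"chain_resno_"}) matching \code{\link{residue_table}} keys.
#' @export
load_ddg_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("pdb_id", "chain", "res_num", "wild_res", "ddG")
  if (!all(need %in% names(d))) {
    stop("ddG table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(toupper(d$wild_res) %in% c("A", "ALA"))) {
    warning("ddG table contains alanine wild-type rows")
  }
  d$key <- residue_key(d$chain, d$res_num)
  d
}

#' Interface core/rim position of a residue
#'
#' The fraction of the residue's unbound total SASA buried on binding:
#' \code{(SAStau - SAStab) / SAStau}.  High values mark interface-core
#' residues, low values rim residues.
#'
#' @param SAStau unbound total absolute SASA (squared Angstrom).
#' @param SAStab bound total absolute SASA (squared Angstrom).
#' @return ratio in [0, 1] (0 with a warning when \code{SAStau} is 0).
#' @export
core_rim <- function(SAStau, SAStab) {
  out <- numeric(length(SAStau))
  zero <- SAStau == 0
  if (any(zero)) warning("SAStau = 0: CORE_RIM defined as 0")
  out[!zero] <- (SAStau[!zero] - SAStab[!zero]) / SAStau[!zero]
  out
}
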