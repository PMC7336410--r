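# End-to-end feature extraction: from a parsed complex (plus optional
# PSSM profiles and a ddG table) to the labelled 97-feature table.

#' Full 97-feature table of a complex's interface residues
#'
#' Runs the complete per-residue characterization: interface detection
#' by buried SASA, bound/unbound SASA records, depth and protrusion
#' indices, electrostatic summaries, interface hydrogen bonds,
#' secondary structure, physicochemical constants and (when PSSM
#' profiles are supplied) conservation features.  Without a profile for
#' a chain the conservation block cannot be assembled and the call
#' fails, mirroring the assembly contract.
#'
#' @param cx bound \code{pnhot_complex}.
#' @param pssms named list of \code{pnhot_pssm} objects keyed by protein
#'   chain id; positions are matched to residues by rank order within
#'   the chain.
#' @param ddg optional ddG table from \code{\link{load_ddg_table}};
#'   when given, rows are restricted to residues present in the table
#'   and a \code{ddG}/\code{hotspot} column pair is attached.
#' @param cutoff hotspot cutoff in kcal/mol.
#' @param probe,n_points SASA engine settings.
#' @return list with \code{features} (matrix n x 97), \code{residues}
#'   (data.frame with keys, names, buried SASA, CORE_RIM and, with a
#'   ddG table, labels).
#' @export
interface_feature_table <- function(cx, pssms = NULL, ddg = NULL,
                                    cutoff = 2.0, probe = 1.4,
                                    n_points = 960) {
  stopifnot(inherits(cx, "pnhot_complex"))
  iface <- identify_interface_residues(cx, probe = probe,
                                       n_points = n_points)
  if (nrow(iface) == 0L) stop("no interface residues found")
  ub <- extract_unbound_protein(cx)
  sasa_b <- atom_sasa(cx$atoms, probe = probe, n_points = n_points)
  sasa_u <- atom_sasa(ub$atoms, probe = probe, n_points = n_points)
  di_b <- depth_index(cx, sasa = sasa_b)
  di_u <- depth_index(ub, sasa = sasa_u)
  pi_b <- protrusion_index(cx)
  pi_u <- protrusion_index(ub)
  ss <- secondary_structure(ub)

  # residue rank within chain, for PSSM position lookup
  rt <- residue_table(cx)
  pos_in_chain <- stats::ave(seq_len(nrow(rt)), rt$chain,
                             FUN = seq_along)
  names(pos_in_chain) <- rt$key

  rows <- vector("list", nrow(iface))
  for (i in seq_len(nrow(iface))) {
    key <- iface$key[i]
    rec_u <- residue_sasa_record(ub, key, sasa = sasa_u, probe = probe,
                                 n_points = n_points)
    rec_b <- residue_sasa_record(cx, key, sasa = sasa_b, probe = probe,
                                 n_points = n_points)
    g <- list(
      DItu = di_u$residue$entire[di_u$residue$key == key],
      DIsu = di_u$residue$side[di_u$residue$key == key],
      DItb = di_b$residue$entire[di_b$residue$key == key],
      DIsb = di_b$residue$side[di_b$residue$key == key],
      PItu = pi_u$residue$entire[pi_u$residue$key == key],
      PIsu = pi_u$residue$side[pi_u$residue$key == key],
      PItb = pi_b$residue$entire[pi_b$residue$key == key],
      PIsb = pi_b$residue$side[pi_b$residue$key == key])
    cons <- if (!is.null(pssms)) {
      ch <- iface$chain[i]
      prof <- pssms[[ch]]
      if (is.null(prof)) stop("conservation block absent for chain ",
                              ch)
      conservation_features(prof, pos_in_chain[[key]],
                            iface$resname[i])
    } else {
      stop("conservation block absent: no PSSM profiles supplied")
    }
    ssrow <- ss[ss$key == key, c("Helix", "Strand", "Turn", "Helix1",
                                 "Loop")]
    rows[[i]] <- assemble_features(
      physchem = physchem_features(iface$resname[i]),
      dipi = dipi_feature_block(g),
      sasa = sasa_feature_block(rec_u, rec_b),
      esp = esp_features(ub, key, sasa = sasa_u),
      hbond = interface_hbond_counts(cx, key),
      ss = unlist(ssrow),
      conservation = cons)
  }
  feats <- do.call(rbind, rows)
  rownames(feats) <- iface$key
  res <- iface
  res$core_rim <- core_rim(feats[, "SAStau"], feats[, "SAStab"])
  if (!is.null(ddg)) {
    m <- match(res$key, ddg$key)
    res$ddG <- ddg$ddG[m]
    keep <- !is.na(res$ddG)
    res <- res[keep, , drop = FALSE]
    feats <- feats[keep, , drop = FALSE]
    res$hotspot <- label_hotspot(res$ddG, cutoff = cutoff)
  }
  list(features = feats, residues = res)
}
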