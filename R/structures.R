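#' Load a protein-nucleic-acid complex from a PDB file
#'
#' Reads standard PDB ATOM records (via \pkg{bio3d}), resolves alternate
#' locations to the highest-occupancy copy, drops waters and (by default)
#' all other heteroatoms, classifies every chain as protein, DNA or RNA
#' from its residue-name vocabulary, and assigns van der Waals radii,
#' partial charges and backbone/polar flags from the embedded atom-typing
#' tables.  Only the first model of a multi-model file is used and
#' hydrogens are discarded: all descriptors in this package are
#' heavy-atom based.
#'
#' @param path path to a PDB file.
#' @param pdb_id four-character identifier stored with the structure;
#'   defaults to the file name stem.
#' @param strict if \code{TRUE}, an unknown residue name raises an error;
#'   otherwise unknown residues are skipped with a warning and common
#'   modified residues (e.g. MSE) are mapped to their parent.
#' @return an object of class \code{pnhot_complex}: a list with the atom
#'   table (\code{atoms}), per-chain molecule kinds (\code{chain_kinds}),
#'   the \code{pdb_id} and the \code{state} ("bound").
#' @examples
#' tc <- make_toy_complex(n_res = 8, na_len = 3, gap = 4, seed = 1,
#'                        path = tempfile(fileext = ".pdb"))
#' cx <- load_complex(tc$path, "TOYC")
#' table(cx$chain_kinds)
#' @export
load_complex <- function(path, pdb_id = NULL, strict = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE,
                         verbose = FALSE)
  at <- pdb$atom
  if (nrow(at) == 0L) stop("no ATOM records in ", path)
  at <- at[at$type == "ATOM" | at$type == "HETATM", , drop = FALSE]
  at <- at[!(at$resid %in% c("HOH", "WAT", "DOD")), , drop = FALSE]

  # map modified residues (HETATM in real files) before dropping HETATM
  if (!strict) {
    m <- match(at$resid, names(MODIFIED_AA))
    mapped <- !is.na(m)
    at$resid[mapped] <- MODIFIED_AA[m[mapped]]
    at$type[mapped] <- "ATOM"
  }
  at <- at[at$type == "ATOM", , drop = FALSE]
  if (nrow(at) == 0L) stop("no ATOM records in ", path)

  elem <- at$elesy
  bad <- is.na(elem) | elem == ""
  elem[bad] <- element_from_name(at$elety[bad])
  elem <- toupper(elem)
  keep <- elem != "H" & elem != "D"
  at <- at[keep, , drop = FALSE]
  elem <- elem[keep]
  elem[elem == "SE"] <- "S"   # selenium treated as sulfur (MSE -> MET)

  # resolve alternate locations: highest occupancy, then earliest altloc
  at$insert[is.na(at$insert)] <- ""
  at$alt[is.na(at$alt)] <- ""
  at$o[is.na(at$o)] <- 1
  akey <- paste(at$chain, at$resno, at$insert, at$elety, sep = "|")
  ord <- order(akey, -at$o, at$alt)
  at <- at[ord, , drop = FALSE]
  elem <- elem[ord]
  dup <- duplicated(paste(at$chain, at$resno, at$insert, at$elety,
                          sep = "|"))
  at <- at[!dup, , drop = FALSE]
  elem <- elem[!dup]

  known_prot <- at$resid %in% AA3
  known_na <- at$resid %in% NA_RES
  unknown <- !known_prot & !known_na
  if (any(unknown)) {
    if (strict) {
      stop("unknown residue(s): ",
           paste(unique(at$resid[unknown]), collapse = ", "))
    }
    warning("skipping ", sum(unknown), " atoms in unknown residues: ",
            paste(unique(at$resid[unknown]), collapse = ", "))
    at <- at[!unknown, , drop = FALSE]
    elem <- elem[!unknown]
    known_prot <- at$resid %in% AA3
  }
  if (nrow(at) == 0L) stop("no usable atoms in ", path)

  # classify chains by majority residue vocabulary
  chains <- unique(at$chain)
  chain_kinds <- vapply(chains, function(ch) {
    res <- unique(paste(at$resno, at$insert, at$resid)[at$chain == ch])
    rn <- vapply(strsplit(res, " "), function(p) p[length(p)], "")
    n_p <- sum(rn %in% AA3)
    n_d <- sum(rn %in% DNA_RES)
    n_r <- sum(rn %in% RNA_RES)
    c("protein", "DNA", "RNA")[which.max(c(n_p, n_d, n_r))]
  }, character(1))
  names(chain_kinds) <- chains

  is_prot <- chain_kinds[at$chain] == "protein"
  atoms <- data.frame(
    serial = at$eleno,
    name = at$elety,
    element = elem,
    x = at$x, y = at$y, z = at$z,
    chain = at$chain,
    resno = at$resno,
    icode = at$insert,
    resname = at$resid,
    is_protein = unname(is_prot),
    stringsAsFactors = FALSE
  )
  atoms$radius <- element_radius(atoms$element)
  atoms$is_backbone <- atoms$is_protein & atoms$name %in% PROTEIN_BACKBONE
  atoms$is_polar <- is_polar_element(atoms$element)
  atoms$charge <- atom_partial_charge(atoms$resname, atoms$name,
                                      atoms$is_protein)

  if (!any(chain_kinds == "protein") ||
      !any(chain_kinds %in% c("DNA", "RNA"))) {
    stop("not a protein-NA complex")
  }

  structure(list(
    pdb_id = pdb_id %||% toupper(sub("\\.pdb$", "", basename(path))),
    atoms = atoms,
    chain_kinds = chain_kinds,
    state = "bound"
  ), class = "pnhot_complex")
}

#' @export
print.pnhot_complex <- function(x, ...) {
  cat("<pnhot_complex>", x$pdb_id, "(", x$state, "state )\n")
  cat("  chains:",
      paste(sprintf("%s[%s]", names(x$chain_kinds), x$chain_kinds),
            collapse = " "), "\n")
  cat("  atoms:", nrow(x$atoms), " residues:",
      nrow(residue_table(x)), "\n")
  invisible(x)
}

#' Residue table of a structure
#'
#' One row per residue (chain, author number, insertion code, name),
#' sorted by chain then sequence number.
#'
#' @param cx a \code{pnhot_complex}.
#' @param protein_only restrict to protein residues.
#' @return data.frame with columns chain, resno, icode, resname, key.
#' @export
residue_table <- function(cx, protein_only = TRUE) {
  a <- cx$atoms
  if (protein_only) a <- a[a$is_protein, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$icode, sep = "_")
  first <- !duplicated(key)
  out <- data.frame(chain = a$chain[first], resno = a$resno[first],
                    icode = a$icode[first], resname = a$resname[first],
                    key = key[first], stringsAsFactors = FALSE)
  out[order(out$chain, out$resno, out$icode), , drop = FALSE]
}

residue_key <- function(chain, resno, icode = "") {
  paste(chain, resno, icode, sep = "_")
}

atom_res_keys <- function(atoms) {
  paste(atoms$chain, atoms$resno, atoms$icode, sep = "_")
}

#' Unbound-protein view of a complex
#'
#' Returns the protein chains of a complex with coordinates unchanged:
#' the unbound state is obtained by deleting the nucleic-acid chains,
#' not by re-modelling.  All per-state descriptors (SASA, depth and
#' protrusion indices, electrostatic summaries) accept either the bound
#' complex or this view.
#'
#' @param cx a \code{pnhot_complex}.
#' @return a \code{pnhot_complex} with \code{state = "unbound"} and no
#'   nucleic-acid chains.
#' @export
extract_unbound_protein <- function(cx) {
  stopifnot(inherits(cx, "pnhot_complex"))
  out <- cx
  out$atoms <- cx$atoms[cx$atoms$is_protein, , drop = FALSE]
  out$chain_kinds <- cx$chain_kinds[cx$chain_kinds == "protein"]
  out$state <- "unbound"
  out
}

#' Identify interface residues by buried solvent accessible surface area
#'
#' A protein residue is an interface residue when its total absolute
#' SASA buried on binding (unbound minus bound, unbound = all protein
#' chains jointly with the nucleic acid deleted) exceeds a small
#' tolerance that makes the strict "larger than 0" rule numerically
#' meaningful.
#'
#' @param cx a bound \code{pnhot_complex}.
#' @param tol buried-SASA tolerance in squared Angstrom (default 1e-6).
#' @param probe,n_points solvent-probe radius and sphere sample size
#'   passed to \code{\link{atom_sasa}}.
#' @return data.frame with columns chain, resno, icode, resname, key and
#'   buried_sasa, sorted by chain then residue number.
#' @export
identify_interface_residues <- function(cx, tol = 1e-6, probe = 1.4,
                                        n_points = 960) {
  stopifnot(inherits(cx, "pnhot_complex"))
  ub <- extract_unbound_protein(cx)
  sasa_b <- atom_sasa(cx$atoms, probe = probe, n_points = n_points)
  sasa_u <- atom_sasa(ub$atoms, probe = probe, n_points = n_points)
  keys_b <- atom_res_keys(cx$atoms)
  keys_u <- atom_res_keys(ub$atoms)
  prot <- cx$atoms$is_protein
  tot_b <- tapply(sasa_b[prot], keys_b[prot], sum)
  tot_u <- tapply(sasa_u, keys_u, sum)
  buried <- tot_u - tot_b[names(tot_u)]
  rt <- residue_table(cx)
  rt$buried_sasa <- unname(buried[rt$key])
  out <- rt[rt$buried_sasa > tol, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a structure back to PDB format
#'
#' Minimal fixed-width ATOM-record writer used by the fixture generators
#' and for round-trip checks.  Coordinates are written to 3 decimals.
#'
#' @param cx a \code{pnhot_complex} (or a bare atom data.frame).
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
write_complex <- function(cx, path) {
  a <- if (inherits(cx, "pnhot_complex")) cx$atoms else cx
  lines <- sprintf(
    "ATOM  %5d %-4s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    a$serial %% 100000,
    sprintf("%-4s", ifelse(nchar(a$name) < 4, paste0(" ", a$name),
                           a$name)),
    a$resname, a$chain, a$resno,
    ifelse(a$icode == "", " ", a$icode),
    a$x, a$y, a$z, 1.00, 0.00, a$element)
  writeLines(c(lines, "END"), path)
  invisible(path)
}
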