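# Solvent accessible surface area by Shrake-Rupley sphere sampling with
# a deterministic golden-angle point lattice (no RNG; results are
# bit-stable for a fixed point count).

#' Per-atom solvent accessible surface area (Shrake-Rupley)
#'
#' Each atom is expanded by the probe radius and sampled with a
#' deterministic quasi-uniform spherical lattice; a sample point is
#' accessible when it lies outside every other expanded atom.  The SASA
#' of the atom is the accessible fraction of its expanded-sphere area.
#'
#' @param atoms data.frame with columns x, y, z, radius (a
#'   \code{pnhot_complex} is also accepted).
#' @param probe probe radius in Angstrom (water, 1.4).
#' @param n_points sample points per atom (>= 60; default 960).
#' @return numeric vector of per-atom SASA in squared Angstrom.
#' @examples
#' a <- data.frame(x = 0, y = 0, z = 0, radius = 1.8)
#' atom_sasa(a)                     # 4*pi*(1.8+1.4)^2
#' @export
atom_sasa <- function(atoms, probe = 1.4, n_points = 960) {
  if (inherits(atoms, "pnhot_complex")) atoms <- atoms$atoms
  n <- nrow(atoms)
  if (is.null(n) || n == 0L) stop("empty atom list")
  stopifnot(n_points >= 60, all(atoms$radius > 0))
  xyz <- cbind(atoms$x, atoms$y, atoms$z)
  if (any(!is.finite(xyz))) stop("non-finite coordinates")
  rext <- atoms$radius + probe
  pts <- sphere_points(n_points)
  out <- numeric(n)

  if (n == 1L) return(4 * pi * rext^2)

  # neighbour lists from the pairwise distance matrix; fixture- and
  # single-chain-scale structures keep this comfortably in memory
  d2 <- as.matrix(stats::dist(xyz))^2
  for (i in seq_len(n)) {
    cut <- (rext[i] + rext)^2
    nb <- which(d2[, i] < cut & seq_len(n) != i)
    if (length(nb) == 0L) {
      out[i] <- 4 * pi * rext[i]^2
      next
    }
    p <- pts * rext[i]
    p <- sweep(p, 2, xyz[i, ], `+`)
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dx <- p[acc, 1] - xyz[j, 1]
      dy <- p[acc, 2] - xyz[j, 2]
      dz <- p[acc, 3] - xyz[j, 3]
      acc[acc] <- dx * dx + dy * dy + dz * dz >= rext[j]^2
    }
    out[i] <- 4 * pi * rext[i]^2 * sum(acc) / n_points
  }
  out
}

# Per-atom SASA for a structure view, cached on the object's atom table.
structure_sasa <- function(cx, probe = 1.4, n_points = 960) {
  atom_sasa(cx$atoms, probe = probe, n_points = n_points)
}

.pnhot_env <- new.env(parent = emptyenv())

# Reference exposures of residue X in an extended Gly-X-Gly tripeptide,
# computed with this package's own surface engine and atom model
# (simplified side chains) and memoised per (probe, n_points).  Used to
# express residue SASA as a percentage of its extended-state exposure.
reference_sasa <- function(probe = 1.4, n_points = 960) {
  key <- sprintf("ref_%g_%d", probe, n_points)
  if (!is.null(.pnhot_env[[key]])) return(.pnhot_env[[key]])
  cats <- c("total", "side", "backbone", "nonpolar", "polar")
  ref <- matrix(0, nrow = length(AA3), ncol = length(cats),
                dimnames = list(AA3, cats))
  for (aa in AA3) {
    atoms <- build_peptide(c("GLY", aa, "GLY"), phi = -120, psi = 120,
                           chain = "A")
    sasa <- atom_sasa(atoms, probe = probe, n_points = n_points)
    mid <- atoms$resno == 2
    ref[aa, "total"] <- sum(sasa[mid])
    ref[aa, "side"] <- sum(sasa[mid & !atoms$is_backbone])
    ref[aa, "backbone"] <- sum(sasa[mid & atoms$is_backbone])
    ref[aa, "nonpolar"] <- sum(sasa[mid & !atoms$is_polar])
    ref[aa, "polar"] <- sum(sasa[mid & atoms$is_polar])
  }
  .pnhot_env[[key]] <- ref
  ref
}

#' Residue SASA record (absolute and relative, five atom classes)
#'
#' Sums the member-atom SASA of one residue over the five atom
#' categories (all atoms, side chain, backbone, polar, nonpolar) and
#' expresses each as a percentage of the residue's reference exposure in
#' an extended Gly-X-Gly tripeptide.  Glycine has no side chain: its
#' side-chain categories are 0 by convention.
#'
#' @param cx a \code{pnhot_complex} view (bound or unbound).
#' @param key residue key \code{"chain_resno_icode"} (see
#'   \code{\link{residue_table}}).
#' @param sasa optional precomputed per-atom SASA for \code{cx} (saves
#'   recomputation when looping over residues).
#' @param probe,n_points passed to \code{\link{atom_sasa}}.
#' @return named numeric vector: abs_total, abs_side, abs_backbone,
#'   abs_nonpolar, abs_polar, rel_total, rel_side, rel_backbone,
#'   rel_nonpolar, rel_polar.
#' @export
residue_sasa_record <- function(cx, key, sasa = NULL, probe = 1.4,
                                n_points = 960) {
  a <- cx$atoms
  if (is.null(sasa)) sasa <- atom_sasa(a, probe = probe,
                                       n_points = n_points)
  sel <- atom_res_keys(a) == key & a$is_protein
  if (!any(sel)) stop("residue not present in view: ", key)
  resname <- a$resname[sel][1]
  abs_v <- c(
    total = sum(sasa[sel]),
    side = sum(sasa[sel & !a$is_backbone]),
    backbone = sum(sasa[sel & a$is_backbone]),
    nonpolar = sum(sasa[sel & !a$is_polar]),
    polar = sum(sasa[sel & a$is_polar])
  )
  ref <- reference_sasa(probe = probe, n_points = n_points)[resname, ]
  rel_v <- ifelse(ref > 0, 100 * abs_v / ref, 0)
  names(rel_v) <- names(abs_v)
  c(stats::setNames(abs_v, paste0("abs_", names(abs_v))),
    stats::setNames(rel_v, paste0("rel_", names(rel_v))))
}

#' SASA feature block of one interface residue (54 features)
#'
#' Combines the unbound- and bound-state SASA records into the frozen
#' 54-member registry: plain buried total/side values, the twenty state
#' SASAs (absolute and relative for five atom classes in each state),
#' and the buried absolute and relative values raised to the powers
#' 0.5, 1.5 and 2.0.  Buried values are clamped at zero before the
#' fractional power.
#'
#' @param unbound,bound residue SASA records from
#'   \code{\link{residue_sasa_record}} on the unbound and bound views.
#' @return named numeric vector of length 54 in registry order.
#' @export
sasa_feature_block <- function(unbound, bound) {
  cats <- c("total", "side", "backbone", "nonpolar", "polar")
  dabs <- pmax(0, unbound[paste0("abs_", cats)] -
                 bound[paste0("abs_", cats)])
  drel <- pmax(0, unbound[paste0("rel_", cats)] -
                 bound[paste0("rel_", cats)])
  names(dabs) <- cats
  names(drel) <- cats
  state <- unlist(lapply(cats, function(cc) {
    c(unbound[[paste0("abs_", cc)]], unbound[[paste0("rel_", cc)]])
  }))
  stateb <- unlist(lapply(cats, function(cc) {
    c(bound[[paste0("abs_", cc)]], bound[[paste0("rel_", cc)]])
  }))
  # frozen category order for the powered relative block: the registry
  # places the nonpolar relative term last (see feature_registry())
  cats_rel <- c("total", "side", "backbone", "polar", "nonpolar")
  vals <- c(
    dabs[["total"]], drel[["total"]],
    state, stateb,
    dabs[cats]^0.5, dabs[cats]^1.5, dabs[cats]^2.0,
    drel[cats_rel]^0.5, drel[cats_rel]^1.5, drel[cats_rel]^2.0,
    dabs[["side"]], drel[["side"]]
  )
  reg <- feature_registry()
  stats::setNames(as.numeric(vals), reg$name[reg$family == "sasa"])
}

#' Depth index (distance to the solvent-accessible surface)
#'
#' An atom with SASA above \code{threshold_sasa} is solvent accessible
#' and has depth 0; a buried atom's depth is its distance to the nearest
#' accessible atom.  Per-residue summaries are the mean over all residue
#' atoms (entire) and over side-chain atoms (side); for glycine the
#' side-chain mean falls back to the entire-residue mean.
#'
#' @param cx a \code{pnhot_complex} view.
#' @param threshold_sasa accessibility threshold in squared Angstrom.
#' @param sasa optional precomputed per-atom SASA.
#' @param probe,n_points passed to \code{\link{atom_sasa}}.
#' @return list with \code{atom} (per-atom depth) and \code{residue}
#'   (data.frame key, entire, side).
#' @export
depth_index <- function(cx, threshold_sasa = 1.0, sasa = NULL,
                        probe = 1.4, n_points = 960) {
  a <- cx$atoms
  if (is.null(sasa)) sasa <- atom_sasa(a, probe = probe,
                                       n_points = n_points)
  exposed <- sasa > threshold_sasa
  if (!any(exposed)) stop("no accessible surface")
  dpx <- numeric(nrow(a))
  if (any(!exposed)) {
    xyz_e <- cbind(a$x, a$y, a$z)[exposed, , drop = FALSE]
    idx <- which(!exposed)
    vals <- vapply(seq_along(idx), function(k) {
      i <- idx[k]
      d2 <- (xyz_e[, 1] - a$x[i])^2 + (xyz_e[, 2] - a$y[i])^2 +
        (xyz_e[, 3] - a$z[i])^2
      sqrt(min(d2))
    }, numeric(1))
    dpx[idx] <- vals
  }
  residue_mean_record(a, dpx)
}

#' Protrusion index (empty-to-occupied volume ratio)
#'
#' For each heavy atom, the occupied volume inside a sphere of radius
#' \code{sphere_radius} is the count of heavy atoms within the sphere
#' (including the atom itself) times the mean atom volume, capped at the
#' sphere volume and floored at one atom volume; the index is the ratio
#' of the remaining (empty) volume to the occupied volume.  Residue
#' summaries as in \code{\link{depth_index}}.
#'
#' @param cx a \code{pnhot_complex} view.
#' @param sphere_radius neighbourhood radius in Angstrom (default 10).
#' @param atom_volume mean heavy-atom volume in cubic Angstrom
#'   (default 20.1).
#' @return list with \code{atom} and \code{residue} components.
#' @export
protrusion_index <- function(cx, sphere_radius = 10.0,
                             atom_volume = 20.1) {
  a <- cx$atoms
  xyz <- cbind(a$x, a$y, a$z)
  v_sph <- 4 / 3 * pi * sphere_radius^3
  d2 <- as.matrix(stats::dist(xyz))^2
  counts <- rowSums(d2 <= sphere_radius^2)   # includes self (d = 0)
  v_int <- pmin(pmax(counts * atom_volume, atom_volume), v_sph)
  cx_atom <- (v_sph - v_int) / v_int
  residue_mean_record(a, cx_atom)
}

residue_mean_record <- function(a, values) {
  keys <- atom_res_keys(a)
  prot <- a$is_protein
  uk <- unique(keys[prot])
  entire <- vapply(uk, function(k) mean(values[keys == k & prot]),
                   numeric(1))
  side <- vapply(uk, function(k) {
    sel <- keys == k & prot & !a$is_backbone
    if (!any(sel)) NA_real_ else mean(values[sel])
  }, numeric(1))
  side[is.na(side)] <- entire[is.na(side)]   # GLY fallback
  list(atom = unname(values),
       residue = data.frame(key = uk, entire = unname(entire),
                            side = unname(side),
                            stringsAsFactors = FALSE))
}

#' Depth/protrusion feature block of one residue (16 features)
#'
#' Emits the eight state values (entire and side-chain depth and
#' protrusion in unbound and bound states), the four unbound-minus-bound
#' differences and the four relative differences (difference divided by
#' the unbound value, defined as 0 when the unbound value is 0).
#'
#' @param g named list or vector with elements DItu, DIsu, PItu, PIsu,
#'   DItb, DIsb, PItb, PIsb.
#' @return named numeric vector of length 16 in registry order.
#' @export
dipi_feature_block <- function(g) {
  g <- as.list(g)
  need <- c("DItu", "DIsu", "PItu", "PIsu", "DItb", "DIsb", "PItb",
            "PIsb")
  if (!all(need %in% names(g))) {
    stop("missing state values: ",
         paste(setdiff(need, names(g)), collapse = ", "))
  }
  d <- function(u, b) g[[u]] - g[[b]]
  rel <- function(delta, u) if (g[[u]] == 0) 0 else delta / g[[u]]
  dDIt <- d("DItu", "DItb"); dDIs <- d("DIsu", "DIsb")
  dPIt <- d("PItu", "PItb"); dPIs <- d("PIsu", "PIsb")
  vals <- c(g$DItu, g$DIsu, g$PItu, g$PIsu, g$DItb, g$DIsb, g$PItb,
            g$PIsb, dDIt, dDIs, dPIt, dPIs,
            rel(dDIt, "DItu"), rel(dDIs, "DIsu"),
            rel(dPIt, "PItu"), rel(dPIs, "PIsu"))
  reg <- feature_registry()
  stats::setNames(vals, reg$name[reg$family == "dipi"])
}
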