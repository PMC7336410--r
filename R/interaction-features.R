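# Electrostatic-potential summaries, interface hydrogen-bond counts and
# secondary-structure assignment.

KCAL_COULOMB <- 332.0637   # kcal*Angstrom/(mol*e^2)
KT_KCAL <- 0.593           # kT at 298 K in kcal/mol

#' Electrostatic-potential summaries of an interface residue (esp1-esp5)
#'
#' Screened-Coulomb (Debye-Hueckel) potential of the unbound protein,
#' evaluated at the positions of solvent-exposed atoms and summarised
#' around the target residue:
#' \describe{
#'   \item{esp1}{mean potential over the target residue's exposed atoms}
#'   \item{esp2}{mean over the target's exposed side-chain atoms}
#'   \item{esp3}{mean over the surface patch formed by the target plus
#'     every residue with an atom within \code{neighbor_cutoff}}
#'   \item{esp4}{mean over the neighbour residues only}
#'   \item{esp5}{maximum point potential on the target residue}
#' }
#' Potentials are in kT/e at 298 K.  A residue with no exposed atoms
#' returns all zeros with a warning.
#'
#' @param view unbound-protein \code{pnhot_complex} view with partial
#'   charges assigned.
#' @param key target residue key.
#' @param neighbor_cutoff patch radius in Angstrom (default 10).
#' @param kappa inverse Debye screening length in 1/Angstrom (default
#'   0.1274, physiological 150 mM; 0 disables screening).
#' @param epsilon relative dielectric constant (default 78.5).
#' @param exposed_threshold SASA (squared Angstrom) above which an atom
#'   counts as solvent exposed.
#' @param sasa optional precomputed per-atom SASA for the view.
#' @return named numeric vector esp1..esp5.
#' @export
esp_features <- function(view, key, neighbor_cutoff = 10.0,
                         kappa = 0.1274, epsilon = 78.5,
                         exposed_threshold = 1.0, sasa = NULL) {
  a <- view$atoms
  if (is.null(sasa)) sasa <- atom_sasa(a)
  keys <- atom_res_keys(a)
  if (!any(keys == key)) stop("residue not present in view: ", key)
  exposed <- sasa > exposed_threshold
  xyz <- cbind(a$x, a$y, a$z)
  q <- a$charge
  src <- which(q != 0)

  phi_at <- function(idx) {
    vapply(idx, function(k) {
      use <- src[src != k]
      if (length(use) == 0L) return(0)
      dx <- xyz[use, 1] - xyz[k, 1]
      dy <- xyz[use, 2] - xyz[k, 2]
      dz <- xyz[use, 3] - xyz[k, 3]
      r <- pmax(sqrt(dx * dx + dy * dy + dz * dz), 0.1)
      sum(KCAL_COULOMB * q[use] * exp(-kappa * r) / (epsilon * r)) /
        KT_KCAL
    }, numeric(1))
  }

  tgt <- which(keys == key)
  tgt_exp <- tgt[exposed[tgt]]
  reg <- feature_registry()
  nm <- reg$name[reg$family == "esp"]
  if (length(tgt_exp) == 0L) {
    warning("residue ", key, " has no solvent-exposed atoms")
    out <- stats::setNames(numeric(5), nm)
    attr(out, "no_exposed") <- TRUE
    return(out)
  }

  # neighbour residues: any atom within the cutoff of any target atom
  d2min <- rep(Inf, nrow(a))
  for (k in tgt) {
    d2 <- (xyz[, 1] - xyz[k, 1])^2 + (xyz[, 2] - xyz[k, 2])^2 +
      (xyz[, 3] - xyz[k, 3])^2
    d2min <- pmin(d2min, d2)
  }
  nb_keys <- setdiff(unique(keys[d2min <= neighbor_cutoff^2]), key)
  nb_exp <- which(keys %in% nb_keys & exposed)

  phi_t <- phi_at(tgt_exp)
  phi_n <- if (length(nb_exp)) phi_at(nb_exp) else numeric(0)
  side <- tgt_exp[!a$is_backbone[tgt_exp]]
  esp1 <- mean(phi_t)
  esp2 <- if (length(side)) mean(phi_at(side)) else 0
  esp3 <- mean(c(phi_t, phi_n))
  esp4 <- if (length(phi_n)) mean(phi_n) else 0
  esp5 <- max(phi_t)
  stats::setNames(c(esp1, esp2, esp3, esp4, esp5), nm)
}

# Base-aware nucleic-acid donor/acceptor typing (heavy atoms), keyed by
# the base letter (DNA "D" prefix stripped).
NA_BASE_DONORS <- list(A = "N6", G = c("N1", "N2"), C = "N4",
                       T = "N3", U = "N3", I = "N1")
NA_BASE_ACCEPTORS <- list(A = c("N1", "N3", "N7"),
                          G = c("N3", "N7", "O6"),
                          C = c("N3", "O2"),
                          T = c("O2", "O4"), U = c("O2", "O4"),
                          I = c("N3", "N7", "O6"))
NA_BACKBONE_ACCEPTORS <- c("OP1", "OP2", "O1P", "O2P", "O5'", "O3'",
                           "O4'", "O2'")

na_base_letter <- function(resname) sub("^D", "", resname)

#' Interface hydrogen-bond counts of a residue
#'
#' Counts donor-acceptor pairs between one protein residue and the
#' nucleic-acid chains with heavy-atom (donor-acceptor) distance at most
#' \code{d_max}; when the donor hydrogen can be placed from idealized
#' geometry (backbone amides), the D-H...A angle must also reach
#' \code{angle_min}, otherwise the pair is kept on distance alone.  Two
#' counts are returned: all residue atoms and side-chain atoms only.
#'
#' @param cx bound \code{pnhot_complex}.
#' @param key residue key.
#' @param d_max donor-acceptor distance cutoff in Angstrom (default
#'   3.5).
#' @param angle_min minimum D-H...A angle in degrees (default 120).
#' @return named integer vector c(Nhb, Nhbs).
#' @export
interface_hbond_counts <- function(cx, key, d_max = 3.5,
                                   angle_min = 120) {
  a <- cx$atoms
  keys <- atom_res_keys(a)
  sel <- which(keys == key & a$is_protein)
  if (length(sel) == 0L) stop("residue not present in complex: ", key)
  na_idx <- which(!a$is_protein)
  if (length(na_idx) == 0L) stop("no nucleic-acid atoms in view")

  res_donor <- is_protein_donor(a$resname[sel], a$name[sel])
  res_accep <- is_protein_acceptor(a$resname[sel], a$name[sel])
  base <- na_base_letter(a$resname[na_idx])
  na_name <- a$name[na_idx]
  na_donor <- mapply(function(b, nm) {
    nm %in% (NA_BASE_DONORS[[b]] %||% character(0))
  }, base, na_name)
  na_accep <- na_name %in% NA_BACKBONE_ACCEPTORS |
    mapply(function(b, nm) {
      nm %in% (NA_BASE_ACCEPTORS[[b]] %||% character(0))
    }, base, na_name)

  # idealized backbone amide hydrogen (along the preceding C=O bond)
  h_pos <- function(i) {
    if (a$name[i] != "N" || a$resname[i] == "PRO") return(NULL)
    prev <- which(a$chain == a$chain[i] & a$resno == a$resno[i] - 1L &
                    a$is_protein)
    cprev <- prev[a$name[prev] == "C"]
    oprev <- prev[a$name[prev] == "O"]
    if (length(cprev) != 1L || length(oprev) != 1L) return(NULL)
    n <- c(a$x[i], a$y[i], a$z[i])
    co <- c(a$x[cprev] - a$x[oprev], a$y[cprev] - a$y[oprev],
            a$z[cprev] - a$z[oprev])
    n + unitv(co) * 1.0
  }

  n_total <- 0L
  n_side <- 0L
  for (ii in seq_along(sel)) {
    i <- sel[ii]
    pi_ <- c(a$x[i], a$y[i], a$z[i])
    for (jj in seq_along(na_idx)) {
      j <- na_idx[jj]
      ok <- (res_donor[ii] && na_accep[jj]) ||
        (res_accep[ii] && na_donor[jj])
      if (!ok) next
      pj <- c(a$x[j], a$y[j], a$z[j])
      if (vnorm(pi_ - pj) > d_max) next
      if (res_donor[ii] && !res_accep[ii]) {
        h <- h_pos(i)
        if (!is.null(h)) {
          ang <- acos(max(-1, min(1, sum(unitv(pi_ - h) *
                                           unitv(pj - h))))) * 180 / pi
          if (ang < angle_min) next
        }
      }
      n_total <- n_total + 1L
      if (!a$is_backbone[i]) n_side <- n_side + 1L
    }
  }
  c(Nhb = n_total, Nhbs = n_side)
}

#' Secondary-structure assignment (Kabsch-Sander)
#'
#' Re-implementation of the hydrogen-bond-energy based assignment:
#' backbone amide hydrogens are placed from idealized geometry, the
#' electrostatic bond energy
#' \eqn{E = 0.084 \cdot 332 (1/r_{ON} + 1/r_{CH} - 1/r_{OH} - 1/r_{CN})}
#' (kcal/mol) defines an H-bond when \eqn{E < -0.5}, and the canonical
#' n-turn and bridge patterns yield the eight structure classes H, G, I,
#' E, B, T, S and blank (pi-helix priority below alpha).  The eight
#' classes are recoded to five (B, T, S as "turn"; G, I as "helix1";
#' blank as "loop") and one-hot encoded.
#'
#' @param view a \code{pnhot_complex} (protein chains are used).
#' @return data.frame with one row per protein residue: key, dssp8,
#'   class5 and the five indicator columns Helix, Strand, Turn, Helix1,
#'   Loop.  Chains shorter than 4 residues are all loop.
#' @export
secondary_structure <- function(view) {
  a <- view$atoms[view$atoms$is_protein, , drop = FALSE]
  rt <- residue_table(view)
  out8 <- stats::setNames(rep(" ", nrow(rt)), rt$key)
  for (ch in unique(rt$chain)) {
    rch <- rt[rt$chain == ch, , drop = FALSE]
    n <- nrow(rch)
    if (n < 4L) next
    get_atom <- function(k, nm) {
      i <- which(atom_res_keys(a) == k & a$name == nm)
      if (length(i) != 1L) return(c(NA, NA, NA))
      c(a$x[i], a$y[i], a$z[i])
    }
    Nc <- t(vapply(rch$key, get_atom, numeric(3), nm = "N"))
    CAc <- t(vapply(rch$key, get_atom, numeric(3), nm = "CA"))
    Cc <- t(vapply(rch$key, get_atom, numeric(3), nm = "C"))
    Oc <- t(vapply(rch$key, get_atom, numeric(3), nm = "O"))
    if (any(is.na(Nc)) || any(is.na(CAc)) || any(is.na(Cc)) ||
        any(is.na(Oc))) next
    Hc <- matrix(NA_real_, n, 3)
    for (i in 2:n) {
      if (rch$resname[i] == "PRO") next
      Hc[i, ] <- Nc[i, ] + unitv(Cc[i - 1, ] - Oc[i - 1, ])
    }
    hb <- matrix(FALSE, n, n)   # hb[i, j]: CO(i) ... HN(j)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (abs(i - j) <= 1L || any(is.na(Hc[j, ]))) next
        rON <- vnorm(Oc[i, ] - Nc[j, ])
        rCH <- vnorm(Cc[i, ] - Hc[j, ])
        rOH <- vnorm(Oc[i, ] - Hc[j, ])
        rCN <- vnorm(Cc[i, ] - Nc[j, ])
        if (min(rON, rCH, rOH, rCN) < 0.5) { e <- -9.9 } else {
          e <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
        }
        if (e < -0.5) hb[i, j] <- TRUE
      }
    }
    turn <- function(nn) {
      t_ <- rep(FALSE, n)
      idx <- seq_len(max(0, n - nn))
      t_[idx] <- hb[cbind(idx, idx + nn)]
      t_
    }
    t3 <- turn(3); t4 <- turn(4); t5 <- turn(5)
    mark_helix <- function(tn, nn) {
      flag <- rep(FALSE, n)
      for (i in 2:max(2, n)) {
        if (i > n || i - 1 < 1) next
        if (i + nn - 1 <= n && tn[i - 1] && tn[i]) {
          flag[i:(i + nn - 1)] <- TRUE
        }
      }
      flag
    }
    h4 <- mark_helix(t4, 4)
    g3 <- mark_helix(t3, 3)
    i5 <- mark_helix(t5, 5)
    bridge <- matrix(FALSE, n, n)
    for (i in 2:(n - 1)) {
      for (j in 2:(n - 1)) {
        if (abs(i - j) < 3L) next
        par <- (hb[i - 1, j] && hb[j, i + 1]) ||
          (hb[j - 1, i] && hb[i, j + 1])
        anti <- (hb[i, j] && hb[j, i]) ||
          (hb[i - 1, j + 1] && hb[j - 1, i + 1])
        if (par || anti) bridge[i, j] <- TRUE
      }
    }
    has_bridge <- apply(bridge, 1, any)
    ladder <- rep(FALSE, n)
    for (i in which(has_bridge)) {
      js <- which(bridge[i, ])
      for (j in js) {
        nb <- FALSE
        for (di in c(-1L, 1L)) {
          ii <- i + di
          if (ii >= 1 && ii <= n &&
              any(bridge[ii, pmax(1, pmin(n, j + c(-1L, 0L, 1L)))])) {
            nb <- TRUE
          }
        }
        if (nb) ladder[i] <- TRUE
      }
    }
    tflag <- rep(FALSE, n)
    for (nn in 3:5) {
      tn <- turn(nn)
      for (i in which(tn)) {
        span <- (i + 1):(i + nn - 1)
        span <- span[span <= n]
        tflag[span] <- TRUE
      }
    }
    sflag <- rep(FALSE, n)
    for (i in 3:(n - 2)) {
      v1 <- CAc[i, ] - CAc[i - 2, ]
      v2 <- CAc[i + 2, ] - CAc[i, ]
      ang <- acos(max(-1, min(1, sum(unitv(v1) * unitv(v2))))) * 180 / pi
      if (ang > 70) sflag[i] <- TRUE
    }
    code <- rep(" ", n)
    code[sflag] <- "S"
    code[tflag] <- "T"
    code[i5 & !h4] <- "I"
    code[g3 & !h4 & !i5] <- "G"
    code[has_bridge & !ladder] <- "B"
    code[ladder] <- "E"
    code[h4] <- "H"
    out8[rch$key] <- code
  }
  class5 <- vapply(out8, function(cc) {
    switch(cc, H = "H", E = "E", B = "turn", T = "turn", S = "turn",
           G = "helix1", I = "helix1", "loop")
  }, character(1))
  onehot <- t(vapply(class5, function(cl) {
    as.numeric(cl == c("H", "E", "turn", "helix1", "loop"))
  }, numeric(5)))
  colnames(onehot) <- c("Helix", "Strand", "Turn", "Helix1", "Loop")
  cbind(data.frame(key = rt$key, dssp8 = unname(out8),
                   class5 = unname(class5), stringsAsFactors = FALSE),
        as.data.frame(onehot, row.names = FALSE))
}
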