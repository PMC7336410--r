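# Deterministic generators of synthetic structures, PSSM profiles and
# planted benchmark datasets.  Every generator is a pure function of its
# seed and arguments; the global RNG state is saved and restored.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(),
                    inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# One pseudo side-chain atom per residue type: enough for the
# side-chain/backbone partition, charges and donor/acceptor typing
# without a rotamer library.
PSEUDO_SIDECHAIN <- c(ARG = "NH1", LYS = "NZ", ASP = "OD1", GLU = "OE1",
                      ASN = "OD1", GLN = "OE1", SER = "OG", THR = "OG1",
                      TYR = "OH", CYS = "SG", HIS = "ND1", TRP = "NE1",
                      MET = "SD", PHE = "CG", LEU = "CG", ILE = "CG1",
                      VAL = "CG1", PRO = "CG")

# Build a peptide chain atom table with ideal covalent geometry and the
# given backbone torsions.  Side chains are CB plus one pseudo-atom.
build_peptide <- function(resnames, phi = -57, psi = -47, chain = "A",
                          start_resno = 1L) {
  n <- length(resnames)
  stopifnot(n >= 1, all(resnames %in% AA3))
  phi <- rep_len(phi, n)
  psi <- rep_len(psi, n)
  Nc <- CAc <- Cc <- Oc <- matrix(NA_real_, n, 3)
  Nc[1, ] <- c(0, 0, 0)
  CAc[1, ] <- c(1.458, 0, 0)
  Cc[1, ] <- CAc[1, ] + 1.525 *
    c(cos(pi * (180 - 111.2) / 180), sin(pi * (180 - 111.2) / 180), 0)
  if (n > 1) {
    for (i in 2:n) {
      Nc[i, ] <- place_atom(Nc[i - 1, ], CAc[i - 1, ], Cc[i - 1, ],
                            1.329, 116.2, psi[i - 1])
      CAc[i, ] <- place_atom(CAc[i - 1, ], Cc[i - 1, ], Nc[i, ],
                             1.458, 121.7, 180)
      Cc[i, ] <- place_atom(Cc[i - 1, ], Nc[i, ], CAc[i, ],
                            1.525, 111.2, phi[i])
      Oc[i - 1, ] <- place_atom(Nc[i, ], CAc[i - 1, ], Cc[i - 1, ],
                                1.231, 120.8, 180)
    }
  }
  Oc[n, ] <- place_atom(Nc[n, ], CAc[n, ], Cc[n, ], 1.231, 120.8,
                        psi[n] + 180)

  rows <- list()
  serial <- 0L
  add <- function(nm, pos, resno, resname) {
    serial <<- serial + 1L
    rows[[length(rows) + 1L]] <<- data.frame(
      serial = serial, name = nm, element = element_from_name(nm),
      x = pos[1], y = pos[2], z = pos[3], chain = chain,
      resno = resno, icode = "", resname = resname,
      is_protein = TRUE, stringsAsFactors = FALSE)
  }
  for (i in seq_len(n)) {
    rn <- resnames[i]
    resno <- start_resno + i - 1L
    add("N", Nc[i, ], resno, rn)
    add("CA", CAc[i, ], resno, rn)
    add("C", Cc[i, ], resno, rn)
    add("O", Oc[i, ], resno, rn)
    if (rn != "GLY") {
      cb <- place_atom(Nc[i, ], Cc[i, ], CAc[i, ], 1.53, 110.5, 122.6)
      add("CB", cb, resno, rn)
      if (rn != "ALA") {
        px <- cb + 1.5 * unitv(cb - CAc[i, ])
        add(PSEUDO_SIDECHAIN[[rn]], px, resno, rn)
      }
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$radius <- element_radius(atoms$element)
  atoms$is_backbone <- atoms$name %in% PROTEIN_BACKBONE
  atoms$is_polar <- is_polar_element(atoms$element)
  atoms$charge <- atom_partial_charge(atoms$resname, atoms$name,
                                      atoms$is_protein)
  atoms
}

na_fragment <- function(na_len, origin, axis, perp, spacing = 6.0,
                        kind = "DNA", chain = "B") {
  third <- unitv(pracma_cross(axis, perp))
  resnames <- if (kind == "DNA") {
    rep(c("DA", "DT"), length.out = na_len)
  } else {
    rep(c("A", "U"), length.out = na_len)
  }
  offs <- list(P = c(0, 0, 0), OP1 = c(0.8, 0, 1.25),
               OP2 = c(0.8, 0, -1.25), "O5'" = c(-0.9, 1.2, 0),
               "C1'" = c(1.2, 2.6, 0), N1 = c(2.2, 3.9, 0))
  rows <- list()
  serial <- 9000L
  for (k in seq_len(na_len)) {
    t_k <- (k - (na_len + 1) / 2) * spacing
    for (nm in names(offs)) {
      o <- offs[[nm]]   # components along (perp, third, axis)
      pos <- origin + t_k * axis + o[1] * perp + o[2] * third +
        o[3] * axis
      serial <- serial + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        serial = serial, name = nm, element = element_from_name(nm),
        x = pos[1], y = pos[2], z = pos[3], chain = chain,
        resno = k, icode = "", resname = resnames[k],
        is_protein = FALSE, stringsAsFactors = FALSE)
    }
  }
  atoms <- do.call(rbind, rows)
  atoms$radius <- element_radius(atoms$element)
  atoms$is_backbone <- FALSE
  atoms$is_polar <- is_polar_element(atoms$element)
  atoms$charge <- atom_partial_charge(atoms$resname, atoms$name,
                                      atoms$is_protein)
  atoms
}

#' Generate a toy protein-nucleic-acid complex
#'
#' Writes a standard-PDB toy complex: an ideal alpha-helix
#' (phi = -57, psi = -47) or extended strand (phi = -120, psi = 120)
#' with seeded mixed side chains (simplified to CB plus one pseudo-atom
#' per residue type), and a phosphate-backbone nucleic-acid fragment
#' placed parallel to the chain's principal axis at the given gap from
#' the protein face.  Ground-truth annotations (contact residues within
#' gap + 2 Angstrom of the fragment; helical residues) are returned for
#' cross-module consistency tests.
#'
#' @param n_res protein length (>= 6).
#' @param geometry "helix" or "strand".
#' @param na_len number of nucleotides (>= 1).
#' @param gap distance in Angstrom between the protein face and the
#'   nucleic-acid backbone (> 0).
#' @param seed integer seed driving the residue sequence.
#' @param kind "DNA" or "RNA".
#' @param path output PDB path (default a tempfile).
#' @return list with \code{path}, \code{atoms}, ground-truth
#'   \code{contacts} (residue keys), \code{helical} (residue keys) and
#'   \code{sequence} (3-letter codes).
#' @export
make_toy_complex <- function(n_res = 12, geometry = c("helix", "strand"),
                             na_len = 4, gap = 4, seed = 1,
                             kind = c("DNA", "RNA"),
                             path = tempfile(fileext = ".pdb")) {
  geometry <- match.arg(geometry)
  kind <- match.arg(kind)
  stopifnot(n_res >= 6, na_len >= 1)
  if (gap <= 0) stop("impossible geometry: gap must be positive")
  pool <- c("ALA", "ARG", "LYS", "SER", "LEU", "GLU", "ASN", "PHE",
            "VAL", "THR", "GLY", "TYR")
  resnames <- with_seed(seed, sample(pool, n_res, replace = TRUE))
  if (geometry == "helix") {
    prot <- build_peptide(resnames, phi = -57, psi = -47)
  } else {
    prot <- build_peptide(resnames, phi = -120, psi = 120)
  }
  xyz <- cbind(prot$x, prot$y, prot$z)
  ctr <- colMeans(xyz)
  pc <- stats::prcomp(xyz, center = TRUE)
  axis <- unitv(pc$rotation[, 1])
  perp <- unitv(pc$rotation[, 2])
  proj <- as.matrix(sweep(xyz, 2, ctr)) %*% perp
  if (max(proj) < abs(min(proj))) perp <- -perp
  dmax <- max(as.matrix(sweep(xyz, 2, ctr)) %*% perp)
  origin <- ctr + (dmax + gap) * perp
  na <- na_fragment(na_len, origin, axis, perp, kind = kind)
  atoms <- rbind(prot, na)
  atoms$serial <- seq_len(nrow(atoms))
  write_complex(atoms, path)

  # ground truth from the actual coordinates
  na_xyz <- cbind(na$x, na$y, na$z)
  keys <- atom_res_keys(prot)
  mind <- vapply(seq_len(nrow(prot)), function(i) {
    sqrt(min((na_xyz[, 1] - prot$x[i])^2 + (na_xyz[, 2] - prot$y[i])^2 +
               (na_xyz[, 3] - prot$z[i])^2))
  }, numeric(1))
  # contact radius gap + 2, capped at the maximum distance over which
  # two heavy atoms can still occlude each other's probe-expanded
  # surface (~8 A); beyond that no SASA can be buried
  contacts <- unique(keys[mind <= min(gap + 2, 8)])
  helical <- if (geometry == "helix" && n_res >= 5) {
    unique(keys)[3:(n_res - 2)]
  } else {
    character(0)
  }
  list(path = path, atoms = atoms, contacts = contacts,
       helical = helical, sequence = resnames)
}

#' Generate a synthetic PSI-BLAST ASCII PSSM file
#'
#' Conserved positions get a near one-hot weighted-observed-percentage
#' row (>= 90 percent on the query residue) and high scores; all other
#' positions are near uniform.  Scores are a monotone log-odds transform
#' of the percentages, so the file round-trips through
#' \code{\link{parse_pssm}} and behaves like a real profile.
#'
#' @param length number of query positions.
#' @param conserved_positions integer positions to conserve.
#' @param seed integer seed.
#' @param query_seq optional 1-letter query sequence (generated when
#'   missing).
#' @param path output file (default a tempfile).
#' @return \code{path}, invisibly annotated with the query sequence.
#' @export
make_synthetic_pssm <- function(length, conserved_positions = integer(0),
                                seed = 1, query_seq = NULL,
                                path = tempfile(fileext = ".pssm")) {
  stopifnot(all(conserved_positions >= 1),
            all(conserved_positions <= length))
  with_seed(seed, {
    if (is.null(query_seq)) {
      query_seq <- paste(sample(PSSM_AA, length, replace = TRUE),
                         collapse = "")
    }
    qs <- strsplit(query_seq, "")[[1]]
    stopifnot(base::length(qs) == length)
    wop <- matrix(0L, length, 20, dimnames = list(NULL, PSSM_AA))
    for (i in seq_len(length)) {
      if (i %in% conserved_positions) {
        wop[i, ] <- 0L
        wop[i, qs[i]] <- 92L
        other <- sample(setdiff(PSSM_AA, qs[i]), 2)
        wop[i, other] <- 4L
      } else {
        wop[i, ] <- pmax(0L, as.integer(round(stats::rnorm(20, 5, 1))))
      }
    }
    scores <- round(2 * log2((wop / 100 + 1e-3) / 0.05))
    scores <- pmin(pmax(scores, -5), 12)
    header <- paste0(
      "\nLast position-specific scoring matrix computed, weighted ",
      "observed percentages rounded down, information per position, ",
      "and relative weight of gapless real matches to pseudocounts\n")
    colhdr <- paste0("            ",
                     paste(sprintf("%2s", PSSM_AA), collapse = " "), "  ",
                     paste(sprintf("%3s", PSSM_AA), collapse = " "))
    body <- vapply(seq_len(length), function(i) {
      paste0(sprintf("%5d %s  ", i, qs[i]),
             paste(sprintf("%2d", scores[i, ]), collapse = " "), "  ",
             paste(sprintf("%3d", wop[i, ]), collapse = " "),
             sprintf("  %4.2f %8.2f", 0.5, 1.0))
    }, character(1))
    writeLines(c(header, colhdr, body, ""), path)
  })
  invisible(structure(path, query_seq = query_seq))
}

#' Generate a planted labelled benchmark dataset
#'
#' Class-conditional Gaussian informative features (hot spots shifted by
#' \code{shift} standard deviations), class-independent noise features,
#' rows assigned to complexes (groups) with optional group-level offsets
#' on the informative features, and labels at the configured class
#' ratio.  The default ratio 86:207 mirrors the class imbalance of
#' alanine-scanning hotspot datasets.
#'
#' @param n number of rows (residues).
#' @param n_informative,n_noise feature counts (sum at most 97).
#' @param shift class separation in units of the feature standard
#'   deviation.
#' @param class_ratio length-2 integer vector c(hotspots,
#'   non-hotspots); scaled to \code{n}.
#' @param group_count number of complexes.
#' @param group_sd standard deviation of per-group offsets added to the
#'   informative features (0 disables group structure).
#' @param seed integer seed.
#' @return list with \code{x} (matrix, named columns), \code{y}
#'   (logical hotspot labels), \code{groups} (complex ids),
#'   \code{informative} (column names carrying signal).
#' @export
make_planted_dataset <- function(n = 293, n_informative = 5,
                                 n_noise = 45, shift = 1.5,
                                 class_ratio = c(86, 207),
                                 group_count = 20, group_sd = 0,
                                 seed = 1) {
  stopifnot(n_informative + n_noise <= 97, shift >= 0, group_count >= 1)
  with_seed(seed, {
    n_pos <- round(n * class_ratio[1] / sum(class_ratio))
    y <- sample(c(rep(TRUE, n_pos), rep(FALSE, n - n_pos)))
    groups <- sprintf("CPLX%03d", sample(rep_len(seq_len(group_count),
                                                 n)))
    p <- n_informative + n_noise
    x <- matrix(stats::rnorm(n * p), n, p)
    if (n_informative > 0) {
      x[y, seq_len(n_informative)] <-
        x[y, seq_len(n_informative)] + shift
      if (group_sd > 0) {
        for (g in unique(groups)) {
          off <- stats::rnorm(n_informative, 0, group_sd)
          rows <- groups == g
          x[rows, seq_len(n_informative)] <-
            sweep(x[rows, seq_len(n_informative), drop = FALSE], 2,
                  off, `+`)
        }
      }
    }
    colnames(x) <- c(sprintf("INF%02d", seq_len(n_informative)),
                     sprintf("NOI%02d", seq_len(n_noise)))
    list(x = x, y = y, groups = groups,
         informative = colnames(x)[seq_len(n_informative)])
  })
}

#' Generate a synthetic alanine-scanning ddG table
#'
#' Stand-in for a curated per-residue ddG table: fake complex/residue
#' keys with ddG values drawn on either side of the hotspot cutoff,
#' including boundary values exactly at the cutoff among the hot spots
#' (the labelling rule is ddG >= cutoff).  Purely synthetic; the values
#' carry no experimental meaning.
#'
#' @param n_hot,n_non numbers of hotspot and non-hotspot rows.
#' @param cutoff hotspot cutoff in kcal/mol.
#' @param n_complexes number of fake complexes the rows are spread over.
#' @param seed integer seed.
#' @return data.frame with columns pdb_id, chain, res_num, wild_res,
#'   ddG.
#' @export
make_synthetic_ddg <- function(n_hot, n_non, cutoff = 2.0,
                               n_complexes = max(2, (n_hot + n_non) %/% 3),
                               seed = 1) {
  with_seed(seed, {
    n <- n_hot + n_non
    ddg_hot <- if (n_hot > 0) {
      v <- round(cutoff + stats::rexp(n_hot, 1 / 1.5), 2)
      if (n_hot >= 2) v[2] <- cutoff   # boundary case pins the >= rule
      v
    } else numeric(0)
    ddg_non <- if (n_non > 0) {
      v <- round(cutoff - 0.01 - stats::rexp(n_non, 1 / 1.0), 2)
      pmin(v, cutoff - 0.01)
    } else numeric(0)
    pdb_ids <- sprintf("%1d%s", sample(1:6, n_complexes, replace = TRUE),
                       toupper(substr(sprintf("%03x",
                                              sample(0:4095,
                                                     n_complexes)),
                                      1, 3)))
    data.frame(
      pdb_id = sample(rep_len(pdb_ids, n)),
      chain = "A",
      res_num = sample(1:400, n, replace = TRUE),
      wild_res = sample(setdiff(unname(AA1), "A"), n, replace = TRUE),
      ddG = sample(c(ddg_hot, ddg_non)),
      stringsAsFactors = FALSE
    )
  })
}
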