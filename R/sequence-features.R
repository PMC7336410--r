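# Sequence-level features: the embedded 10 x 20 physicochemical property
# table, the PSI-BLAST ASCII PSSM reader, and the five conservation
# features (entropy plus relative-conservation ratios/differences).

# Standard PSI-BLAST amino-acid column order.
PSSM_AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
             "M", "F", "P", "S", "T", "W", "Y", "V")

# Ten physicochemical properties of the 20 amino acids, frozen from
# standard published scales (one row per property):
#   Na    heavy-atom count of the residue
#   Nelc  net formal side-chain charge at pH 7 (His counted 0.5)
#   Nphb  number of potential hydrogen bonds the residue can form
#   Hdrpo hydropathy (Kyte & Doolittle)
#   Hdrpi hydrophilicity (Hopp & Woods)
#   Pol   polarity (Grantham)
#   Viso  isoelectric point (Zimmerman)
#   Mass  residue mass (Da)
#   Vol   residue volume (Zamyatnin)
#   Asa   exposed surface in an extended tripeptide (Chothia-type)
PHYSCHEM_TABLE <- local({
  aa <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  m <- rbind(
    Na    = c(5, 11, 8, 8, 6, 9, 9, 4, 10, 8,
              8, 9, 8, 11, 7, 6, 7, 14, 12, 7),
    Nelc  = c(0, 1, 0, -1, 0, 0, -1, 0, 0.5, 0,
              0, 1, 0, 0, 0, 0, 0, 0, 0, 0),
    Nphb  = c(2, 7, 4, 4, 3, 4, 4, 2, 4, 2,
              2, 5, 3, 2, 1, 4, 4, 3, 4, 2),
    Hdrpo = c(1.8, -4.5, -3.5, -3.5, 2.5, -3.5, -3.5, -0.4, -3.2, 4.5,
              3.8, -3.9, 1.9, 2.8, -1.6, -0.8, -0.7, -0.9, -1.3, 4.2),
    Hdrpi = c(-0.5, 3.0, 0.2, 3.0, -1.0, 0.2, 3.0, 0.0, -0.5, -1.8,
              -1.8, 3.0, -1.3, -2.5, 0.0, 0.3, -0.4, -3.4, -2.3, -1.5),
    Pol   = c(8.1, 10.5, 11.6, 13.0, 5.5, 10.5, 12.3, 9.0, 10.4, 5.2,
              4.9, 11.3, 5.7, 5.2, 8.0, 9.2, 8.6, 5.4, 6.2, 5.9),
    Viso  = c(6.00, 10.76, 5.41, 2.77, 5.05, 5.65, 3.22, 5.97, 7.59,
              6.02, 5.98, 9.74, 5.74, 5.48, 6.30, 5.68, 5.66, 5.89,
              5.66, 5.96),
    Mass  = c(71.08, 156.19, 114.10, 115.09, 103.14, 128.13, 129.12,
              57.05, 137.14, 113.16, 113.16, 128.17, 131.19, 147.18,
              97.12, 87.08, 101.10, 186.21, 163.18, 99.13),
    Vol   = c(88.6, 173.4, 114.1, 111.1, 108.5, 143.8, 138.4, 60.1,
              153.2, 166.7, 166.7, 168.6, 162.9, 189.9, 112.7, 89.0,
              116.1, 227.8, 193.6, 140.0),
    Asa   = c(115, 225, 160, 150, 135, 180, 190, 75, 195, 175,
              170, 200, 185, 210, 145, 115, 140, 255, 230, 155)
  )
  colnames(m) <- aa
  m
})

#' Physicochemical feature block of one residue (10 features)
#'
#' Returns the frozen constants of the ten embedded amino-acid property
#' scales in registry order (heavy-atom count, formal charge, potential
#' hydrogen bonds, hydropathy, hydrophilicity, polarity, isoelectric
#' point, mass, volume, extended-state exposure).
#'
#' @param res_name residue as a 3-letter (e.g. "ARG") or 1-letter code.
#' @return named numeric vector of length 10.
#' @export
physchem_features <- function(res_name) {
  aa <- toupper(res_name)
  if (nchar(aa) == 3) aa <- unname(AA1[aa])
  if (is.na(aa) || !aa %in% colnames(PHYSCHEM_TABLE)) {
    stop("unknown amino acid: ", res_name)
  }
  v <- PHYSCHEM_TABLE[, aa]
  reg <- feature_registry()
  stats::setNames(as.numeric(v), reg$name[reg$family == "physchem"])
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the standard 40-column layout: per position, 20 position
#' specific (log-odds) scores followed by 20 weighted observed
#' percentages.  Positions are 1-based query positions.
#'
#' @param path PSSM file produced by PSI-BLAST (\code{-out_ascii_pssm})
#'   or by \code{\link{make_synthetic_pssm}}.
#' @return object of class \code{pnhot_pssm}: list with \code{length},
#'   \code{query_seq} (1-letter), \code{scores} and \code{wop}
#'   (position x 20 matrices, columns in PSI-BLAST order).
#' @export
parse_pssm <- function(path) {
  lines <- readLines(path)
  rows <- list()
  seq_chars <- character(0)
  expect <- 1L
  for (ln in seq_along(lines)) {
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 2L) next
    pos <- suppressWarnings(as.integer(tok[1]))
    if (is.na(pos) || pos != expect || !(tok[2] %in% PSSM_AA)) next
    vals <- suppressWarnings(as.numeric(tok[-(1:2)]))
    if (length(vals) < 40L || any(is.na(vals[1:40]))) {
      stop("malformed PSSM row at line ", ln)
    }
    rows[[pos]] <- vals[1:40]
    seq_chars[pos] <- tok[2]
    expect <- expect + 1L
  }
  if (length(rows) == 0L) stop("no PSSM rows found in ", path)
  m <- do.call(rbind, rows)
  scores <- m[, 1:20, drop = FALSE]
  wop <- m[, 21:40, drop = FALSE]
  colnames(scores) <- PSSM_AA
  colnames(wop) <- PSSM_AA
  structure(list(length = nrow(m), query_seq = paste(seq_chars,
                                                     collapse = ""),
                 scores = scores, wop = wop),
            class = "pnhot_pssm")
}

#' Conservation feature block of one sequence position (5 features)
#'
#' The information entropy of the position's weighted observed
#' percentages (renormalized per position; natural log by default), two
#' relative-conservation ratios on the +1-smoothed percentages
#' (actual-residue / alanine and maximum-residue / alanine), and two
#' relative-conservation differences on the raw position-specific scores
#' (actual minus alanine and maximum-percentage residue minus alanine).
#'
#' @param pssm a \code{pnhot_pssm}.
#' @param pos 1-based query position.
#' @param actual_res the residue actually observed at the position
#'   (1-letter or 3-letter code).
#' @param base logarithm base for the entropy: "nat" (default) or "2".
#' @return named numeric vector of length 5.
#' @export
conservation_features <- function(pssm, pos, actual_res,
                                  base = c("nat", "2")) {
  base <- match.arg(base)
  stopifnot(inherits(pssm, "pnhot_pssm"), pos >= 1, pos <= pssm$length)
  aa <- toupper(actual_res)
  if (nchar(aa) == 3) aa <- unname(AA1[aa])
  if (is.na(aa) || !aa %in% PSSM_AA) {
    stop("unknown amino acid: ", actual_res)
  }
  w <- pssm$wop[pos, ]
  s <- pssm$scores[pos, ]
  tot <- sum(w)
  if (tot > 0) {
    p <- w / tot
    p <- p[p > 0]
    ent <- -sum(p * log(p))
    if (base == "2") ent <- ent / log(2)
  } else {
    ent <- 0
  }
  rm_aa <- PSSM_AA[which.max(w)]   # ties: first in PSI-BLAST order
  rel1_wop <- (w[[aa]] + 1) / (w[["A"]] + 1)
  rel2_wop <- (w[[rm_aa]] + 1) / (w[["A"]] + 1)
  rel1_pps <- s[[aa]] - s[["A"]]
  rel2_pps <- s[[rm_aa]] - s[["A"]]
  reg <- feature_registry()
  stats::setNames(c(ent, rel1_wop, rel2_wop, rel1_pps, rel2_pps),
                  reg$name[reg$family == "conservation"])
}
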