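# Shared fixtures, built once per test run.

.fixture_env <- new.env()

toy_complex <- function() {
  if (is.null(.fixture_env$tc)) {
    tc <- make_toy_complex(n_res = 12, na_len = 4, gap = 4, seed = 1,
                           path = file.path(tempdir(), "toy1.pdb"))
    tc$cx <- load_complex(tc$path, "TOYC")
    .fixture_env$tc <- tc
  }
  .fixture_env$tc
}

toy_pssm <- function() {
  if (is.null(.fixture_env$pssm)) {
    tc <- toy_complex()
    q <- paste(unname(pnhot:::AA1[tc$sequence]), collapse = "")
    p <- make_synthetic_pssm(nchar(q), conserved_positions = c(3L),
                             seed = 2, query_seq = q,
                             path = file.path(tempdir(), "toy1.pssm"))
    .fixture_env$pssm <- parse_pssm(p)
  }
  .fixture_env$pssm
}

# Minimal pnhot_complex wrapper around a bare atom table (for views
# constructed directly in tests).
as_view <- function(atoms, kinds = c(A = "protein"), state = "unbound") {
  structure(list(pdb_id = "TEST", atoms = atoms, chain_kinds = kinds,
                 state = state), class = "pnhot_complex")
}

# A bare one-chain atom table row.
atom_row <- function(name, x, y, z, resno = 1L, resname = "GLY",
                     chain = "A", is_protein = TRUE, charge = 0) {
  elem <- pnhot:::element_from_name(name)
  data.frame(serial = 0L, name = name, element = elem, x = x, y = y,
             z = z, chain = chain, resno = resno, icode = "",
             resname = resname, is_protein = is_protein,
             radius = pnhot:::element_radius(elem),
             is_backbone = is_protein &
               name %in% pnhot:::PROTEIN_BACKBONE,
             is_polar = pnhot:::is_polar_element(elem),
             charge = charge, stringsAsFactors = FALSE)
}

rigid_transform <- function(atoms, angle = 37, shift = c(5, -3, 11)) {
  th <- angle * pi / 180
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1),
              3, 3, byrow = TRUE)
  xyz <- as.matrix(atoms[, c("x", "y", "z")]) %*% t(R)
  atoms$x <- xyz[, 1] + shift[1]
  atoms$y <- xyz[, 2] + shift[2]
  atoms$z <- xyz[, 3] + shift[3]
  atoms
}
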