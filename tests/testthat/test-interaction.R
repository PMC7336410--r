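test_that("zero charges give an all-zero potential record", {
  atoms <- pnhot:::build_peptide(c("ALA", "ALA", "ALA"))
  atoms$charge <- 0
  v <- as_view(atoms)
  esp <- esp_features(v, "A_2_")
  expect_length(esp, 5L)
  expect_true(all(esp == 0))
})

test_that("a single point charge reproduces the closed-form Coulomb value", {
  tgt <- atom_row("CA", 0, 0, 0, resno = 1)
  src <- atom_row("NZ", 5, 0, 0, resno = 2, resname = "LYS",
                  charge = 1)
  v <- as_view(rbind(tgt, src))
  esp <- esp_features(v, "A_1_", kappa = 0)
  phi_hand <- 332.0637 * 1 / (78.5 * 5) / 0.593
  expect_equal(esp[["esp1"]], phi_hand, tolerance = 1e-9)
  expect_equal(esp[["esp5"]], phi_hand, tolerance = 1e-9)
  # with screening the potential is strictly smaller
  esp_s <- esp_features(v, "A_1_", kappa = 0.1274)
  expect_lt(esp_s[["esp1"]], esp[["esp1"]])
})

test_that("potential summaries are additive in the charges", {
  tc <- toy_complex()
  ub <- extract_unbound_protein(tc$cx)
  key <- tc$contacts[1]
  e1 <- esp_features(ub, key)
  ub2 <- ub
  ub2$atoms$charge <- 2 * ub$atoms$charge
  e2 <- esp_features(ub2, key)
  expect_equal(unname(e2), unname(2 * e1), tolerance = 1e-9)
})

test_that("basic patches are more positive than acidic patches", {
  arg <- as_view(pnhot:::build_peptide(rep("ARG", 8)))
  glu <- as_view(pnhot:::build_peptide(rep("GLU", 8)))
  e_arg <- esp_features(arg, "A_4_")
  e_glu <- esp_features(glu, "A_4_")
  expect_gt(e_arg[["esp3"]], e_glu[["esp3"]])
  expect_gt(e_arg[["esp3"]], 0)
  expect_lt(e_glu[["esp3"]], 0)
})

# A hand-built serine + mononucleotide geometry for the H-bond counter.
hbond_fixture <- function(d_og = 2.9) {
  ser <- rbind(
    atom_row("N", 0, 0, 0, resno = 1, resname = "SER"),
    atom_row("CA", 1.46, 0, 0, resno = 1, resname = "SER"),
    atom_row("C", 2.0, 1.4, 0, resno = 1, resname = "SER"),
    atom_row("O", 1.4, 2.45, 0, resno = 1, resname = "SER"),
    atom_row("CB", 2.0, -0.7, 1.2, resno = 1, resname = "SER"),
    atom_row("OG", 2.0, -0.7, 2.6, resno = 1, resname = "SER"))
  phos <- atom_row("OP1", 2.0, -0.7, 2.6 + d_og, resno = 1,
                   resname = "DA", is_protein = FALSE)
  atoms <- rbind(ser, phos)
  atoms$chain[!atoms$is_protein] <- "B"
  as_view(atoms, kinds = c(A = "protein", B = "DNA"), state = "bound")
}

test_that("hydrogen bonds are counted with distance and partition rules", {
  cx <- hbond_fixture(2.9)
  hb <- interface_hbond_counts(cx, "A_1_")
  expect_equal(unname(hb), c(1L, 1L))   # OG -> phosphate, side chain

  # stretched beyond the cutoff
  hb_far <- interface_hbond_counts(hbond_fixture(4.5), "A_1_")
  expect_equal(unname(hb_far), c(0L, 0L))
})

test_that("backbone-only hydrogen bonds count in total but not side chain", {
  # dipeptide whose residue-2 amide points at a base oxygen with
  # near-linear geometry
  pep <- pnhot:::build_peptide(c("ALA", "ALA"), phi = -120, psi = 120)
  n2 <- pep[pep$resno == 2 & pep$name == "N", c("x", "y", "z")]
  cpr <- pep[pep$resno == 1 & pep$name == "C", c("x", "y", "z")]
  opr <- pep[pep$resno == 1 & pep$name == "O", c("x", "y", "z")]
  h <- as.numeric(n2) + pnhot:::unitv(as.numeric(cpr) - as.numeric(opr))
  acc_pos <- as.numeric(n2) +
    pnhot:::unitv(h - as.numeric(n2)) * 2.9
  acc <- atom_row("O2", acc_pos[1], acc_pos[2], acc_pos[3], resno = 1,
                  resname = "DT", is_protein = FALSE)
  acc$chain <- "B"
  cx <- as_view(rbind(pep, acc), kinds = c(A = "protein", B = "DNA"),
                state = "bound")
  hb <- interface_hbond_counts(cx, "A_2_")
  expect_equal(unname(hb), c(1L, 0L))
  # same acceptor but behind the amide: angle filter rejects it
  bad_pos <- as.numeric(n2) - pnhot:::unitv(h - as.numeric(n2)) * 2.9
  acc2 <- acc
  acc2$x <- bad_pos[1]; acc2$y <- bad_pos[2]; acc2$z <- bad_pos[3]
  cx2 <- as_view(rbind(pep, acc2), kinds = c(A = "protein", B = "DNA"),
                 state = "bound")
  hb2 <- interface_hbond_counts(cx2, "A_2_")
  expect_equal(unname(hb2), c(0L, 0L))
})

test_that("ideal helix interiors are H and the one-hot block is valid", {
  tc <- toy_complex()
  ub <- extract_unbound_protein(tc$cx)
  ss <- secondary_structure(ub)
  onehot <- as.matrix(ss[, c("Helix", "Strand", "Turn", "Helix1",
                             "Loop")])
  expect_true(all(rowSums(onehot) == 1))
  interior <- ss$key %in% tc$helical
  expect_true(all(ss$class5[interior] == "H"))
  expect_equal(unname(onehot[which(interior)[1], ]),
               c(1, 0, 0, 0, 0))
})

test_that("an isolated extended strand is never helical", {
  atoms <- pnhot:::build_peptide(rep("VAL", 8), phi = -120, psi = 120)
  v <- as_view(atoms)
  ss <- secondary_structure(v)
  expect_true(all(ss$class5 %in% c("E", "loop", "turn")))
  expect_false(any(ss$class5 %in% c("H", "helix1")))
})

test_that("chains shorter than four residues are all loop", {
  atoms <- pnhot:::build_peptide(c("ALA", "GLY", "SER"))
  ss <- secondary_structure(as_view(atoms))
  expect_true(all(ss$class5 == "loop"))
  expect_true(all(ss$Loop == 1))
})
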