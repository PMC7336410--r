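test_that("single and well-separated atoms match the analytic sphere", {
  a1 <- data.frame(x = 0, y = 0, z = 0, radius = 1.8)
  expect_equal(atom_sasa(a1), 4 * pi * (1.8 + 1.4)^2, tolerance = 1e-9)
  a2 <- data.frame(x = c(0, 50), y = 0, z = 0, radius = c(1.8, 1.5))
  expect_equal(atom_sasa(a2),
               4 * pi * (c(1.8, 1.5) + 1.4)^2, tolerance = 1e-9)
  expect_error(atom_sasa(a1[0, ]), "empty")
})

test_that("overlapping pair matches a high-density numerical oracle", {
  a2 <- data.frame(x = c(0, 2), y = 0, z = 0, radius = 1.8)
  ref <- atom_sasa(a2, n_points = 100000)
  got <- atom_sasa(a2, n_points = 960)
  expect_lt(max(abs(got - ref) / ref), 0.01)
})

test_that("sphere sampling is converged at the default density", {
  tc <- toy_complex()
  s1 <- sum(atom_sasa(tc$cx$atoms, n_points = 960))
  s2 <- sum(atom_sasa(tc$cx$atoms, n_points = 3840))
  expect_lt(abs(s1 - s2) / s2, 0.005)
})

test_that("residue SASA record partitions and references behave", {
  atoms <- pnhot:::build_peptide(c("ALA", "GLY", "ALA"),
                                 phi = -120, psi = 120)
  v <- as_view(atoms)
  s <- atom_sasa(atoms)
  gly <- residue_sasa_record(v, "A_2_", sasa = s)
  expect_equal(gly[["abs_side"]], 0)
  expect_equal(gly[["rel_side"]], 0)
  # abs values are an independent per-atom summation
  sel <- atoms$resno == 2
  expect_equal(gly[["abs_total"]], sum(s[sel]))
  expect_equal(gly[["abs_backbone"]],
               sum(s[sel & atoms$is_backbone]))
  expect_equal(gly[["abs_total"]],
               gly[["abs_side"]] + gly[["abs_backbone"]],
               tolerance = 1e-3)
  # relative = 100 * abs / reference exposure
  ref <- pnhot:::reference_sasa()["GLY", "total"]
  expect_equal(gly[["rel_total"]], 100 * gly[["abs_total"]] / ref)
})

test_that("a shell-buried residue has zero exposure", {
  # central atom surrounded by a tight shell
  core <- atom_row("CA", 0, 0, 0, resno = 1)
  sp <- pnhot:::sphere_points(40) * 3.0
  shell <- do.call(rbind, lapply(seq_len(nrow(sp)), function(i) {
    atom_row("CA", sp[i, 1], sp[i, 2], sp[i, 3], resno = 2)
  }))
  atoms <- rbind(core, shell)
  s <- atom_sasa(atoms)
  expect_equal(s[1], 0)
})

test_that("SASA feature block follows the registry arithmetic", {
  cats <- c("total", "side", "backbone", "nonpolar", "polar")
  mk <- function(abs, rel) {
    stats::setNames(c(abs, rel),
                    c(paste0("abs_", cats), paste0("rel_", cats)))
  }
  u <- mk(c(100, 60, 40, 70, 30), c(50, 55, 45, 52, 48))
  b <- mk(c(40, 20, 20, 30, 10), c(20, 18, 22, 21, 16))
  blk <- sasa_feature_block(u, b)
  expect_length(blk, 54L)
  expect_equal(blk[["SAStau"]], 100)
  expect_equal(blk[["SAStab"]], 40)
  expect_equal(blk[["dSASta"]], 60)
  expect_equal(blk[["dSASta_p0.5"]], sqrt(60), tolerance = 1e-6)
  expect_equal(round(blk[["dSASta_p0.5"]], 4), 7.746)
  expect_equal(blk[["dSASnr_p0.5"]], sqrt(52 - 21))
  # bound == unbound: every buried and powered value 0
  blk0 <- sasa_feature_block(u, u)
  expect_true(all(blk0[grep("^dSAS", names(blk0))] == 0))
  # numerical noise (bound > unbound) clamps at 0
  b2 <- u
  b2["abs_side"] <- u[["abs_side"]] + 1e-9
  blk2 <- sasa_feature_block(u, b2)
  expect_equal(blk2[["dSASsa"]], 0)
  expect_equal(blk2[["dSASsa_p0.5"]], 0)
})

test_that("depth index is zero for exposed atoms and exact for buried", {
  atoms <- pnhot:::build_peptide(c("ALA", "ALA"), phi = -120, psi = 120)
  v <- as_view(atoms)
  di <- depth_index(v)
  expect_true(all(di$atom == 0))

  # three-shell synthetic cluster: buried atoms against brute force
  core <- atom_row("CA", 0, 0, 0, resno = 1)
  shells <- do.call(rbind, lapply(c(3, 5.5, 8), function(r) {
    sp <- pnhot:::sphere_points(60) * r
    do.call(rbind, lapply(seq_len(nrow(sp)), function(i) {
      atom_row("CA", sp[i, 1], sp[i, 2], sp[i, 3], resno = 2)
    }))
  }))
  atoms2 <- rbind(core, shells)
  v2 <- as_view(atoms2)
  s <- atom_sasa(atoms2)
  di2 <- depth_index(v2, sasa = s)
  exposed <- s > 1.0
  expect_false(exposed[1])
  xyz <- as.matrix(atoms2[, c("x", "y", "z")])
  brute <- sqrt(min(rowSums(sweep(xyz[exposed, , drop = FALSE], 2,
                                  xyz[1, ])^2)))
  expect_equal(di2$atom[1], brute, tolerance = 1e-9)

  # a fully buried structure has no accessible reference surface
  one <- as_view(atom_row("CA", 0, 0, 0))
  expect_error(depth_index(one, threshold_sasa = 1e9),
               "no accessible surface")
})

test_that("glycine side-chain means fall back to the entire residue", {
  atoms <- pnhot:::build_peptide(c("ALA", "GLY", "ALA"))
  v <- as_view(atoms)
  di <- depth_index(v)
  g <- di$residue[di$residue$key == "A_2_", ]
  expect_equal(g$side, g$entire)
})

test_that("protrusion index matches the analytic isolated-atom value", {
  v <- as_view(atom_row("CA", 0, 0, 0))
  pi1 <- protrusion_index(v)
  vs <- 4 / 3 * pi * 10^3
  expect_equal(pi1$atom, (vs - 20.1) / 20.1, tolerance = 1e-9)
  expect_equal(round(pi1$atom, 2), 207.4)
})

test_that("buried atoms protrude less than surface atoms", {
  sp <- pnhot:::sphere_points(80)
  cluster <- do.call(rbind, lapply(c(2, 4, 6, 8), function(r) {
    s <- sp * r
    do.call(rbind, lapply(seq_len(nrow(s)), function(i) {
      atom_row("CA", s[i, 1], s[i, 2], s[i, 3], resno = 2)
    }))
  }))
  atoms <- rbind(atom_row("CA", 0, 0, 0, resno = 1), cluster)
  v <- as_view(atoms)
  px <- protrusion_index(v)
  expect_true(all(px$atom >= 0))
  # centre atom vs the outermost shell
  outer <- which(sqrt(atoms$x^2 + atoms$y^2 + atoms$z^2) > 7.5)
  expect_lt(px$atom[1], min(px$atom[outer]))
  # brute-force count for the centre atom
  d <- sqrt(atoms$x^2 + atoms$y^2 + atoms$z^2)
  cnt <- sum(d <= 10)
  v_int <- min(max(cnt * 20.1, 20.1), 4 / 3 * pi * 1000)
  expect_equal(px$atom[1], (4 / 3 * pi * 1000 - v_int) / v_int,
               tolerance = 1e-9)
})

test_that("depth/protrusion are invariant under rigid-body motion", {
  tc <- toy_complex()
  ub <- extract_unbound_protein(tc$cx)
  ub2 <- ub
  ub2$atoms <- rigid_transform(ub$atoms)
  d1 <- depth_index(ub)$residue
  d2 <- depth_index(ub2)$residue
  expect_equal(d1$entire, d2$entire, tolerance = 0.05)
  p1 <- protrusion_index(ub)$residue
  p2 <- protrusion_index(ub2)$residue
  expect_equal(p1$entire, p2$entire, tolerance = 1e-9)
})

test_that("progressive burial raises depth and lowers protrusion/SASA", {
  # add shells outward one by one: the centre atom gets deeper, less
  # protruding and no more exposed at every step
  atoms <- atom_row("CA", 0, 0, 0, resno = 1)
  sasa_seq <- di_seq <- pi_seq <- numeric(0)
  for (radius in c(4, 6.5, 9)) {
    sp <- pnhot:::sphere_points(70) * radius
    shell <- do.call(rbind, lapply(seq_len(nrow(sp)), function(i) {
      atom_row("CA", sp[i, 1], sp[i, 2], sp[i, 3], resno = 2)
    }))
    atoms <- rbind(atoms, shell)
    v <- as_view(atoms)
    s <- atom_sasa(atoms)
    sasa_seq <- c(sasa_seq, s[1])
    di_seq <- c(di_seq, depth_index(v, sasa = s)$atom[1])
    pi_seq <- c(pi_seq, protrusion_index(v)$atom[1])
  }
  expect_true(all(diff(sasa_seq) <= 1e-9))
  expect_true(all(diff(pi_seq) < 0))
  expect_true(all(diff(di_seq) > 0))
})

test_that("depth/protrusion block reproduces the defining arithmetic", {
  g <- c(DItu = 2, DIsu = 2, PItu = 4, PIsu = 5, DItb = 3, DIsb = 2.5,
         PItb = 3, PIsb = 4)
  blk <- dipi_feature_block(g)
  expect_length(blk, 16L)
  expect_equal(blk[["dDIt"]], -1)
  expect_equal(blk[["relDIt"]], -0.5)
  expect_equal(blk[["dDIs"]], -0.5)
  expect_equal(blk[["relPIt"]], (4 - 3) / 4)
  # no-change case
  g0 <- c(DItu = 2, DIsu = 2, PItu = 2, PIsu = 2, DItb = 2, DIsb = 2,
          PItb = 2, PIsb = 2)
  blk0 <- dipi_feature_block(g0)
  expect_equal(blk0[["dDIt"]], 0)
  expect_equal(blk0[["relDIt"]], 0)
  # division guard
  gz <- c(DItu = 0, DIsu = 0, PItu = 0, PIsu = 0, DItb = 1, DIsb = 1,
          PItb = 1, PIsb = 1)
  expect_equal(dipi_feature_block(gz)[["relDIt"]], 0)
  expect_error(dipi_feature_block(g[1:5]), "missing state values")
})

test_that("toy-complex depth/protrusion block equals hand recomputation", {
  tc <- toy_complex()
  cx <- tc$cx
  ub <- extract_unbound_protein(cx)
  key <- tc$contacts[1]
  di_u <- depth_index(ub)$residue
  di_b <- depth_index(cx)$residue
  pi_u <- protrusion_index(ub)$residue
  pi_b <- protrusion_index(cx)$residue
  g <- list(DItu = di_u$entire[di_u$key == key],
            DIsu = di_u$side[di_u$key == key],
            DItb = di_b$entire[di_b$key == key],
            DIsb = di_b$side[di_b$key == key],
            PItu = pi_u$entire[pi_u$key == key],
            PIsu = pi_u$side[pi_u$key == key],
            PItb = pi_b$entire[pi_b$key == key],
            PIsb = pi_b$side[pi_b$key == key])
  blk <- dipi_feature_block(g)
  expect_equal(blk[["dPIt"]], g$PItu - g$PItb)
  expect_equal(blk[["relPIs"]],
               if (g$PIsu == 0) 0 else (g$PIsu - g$PIsb) / g$PIsu)
  expect_equal(blk[["dDIs"]], g$DIsu - g$DIsb)
})
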