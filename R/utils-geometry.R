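# Small 3D helpers shared by the structure builders and descriptors.

vnorm <- function(v) sqrt(sum(v * v))

unitv <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("zero-length vector")
  v / n
}

# Place atom D given positions of A, B, C and the internal coordinates
# |CD| = bond, angle(B,C,D) = angle (degrees), torsion(A,B,C,D) = tors
# (degrees).  Standard natural-extension (NeRF) construction.
place_atom <- function(a, b, c, bond, angle, tors) {
  angle <- angle * pi / 180
  tors <- tors * pi / 180
  bc <- unitv(c - b)
  n <- unitv(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d2 <- c(-bond * cos(angle),
          bond * sin(angle) * cos(tors),
          bond * sin(angle) * sin(tors))
  c + d2[1] * bc + d2[2] * m + d2[3] * n
}

pracma_cross <- function(u, v) {
  c(u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1])
}

dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unitv(b2))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

# Deterministic quasi-uniform points on the unit sphere (generalized
# spiral / golden-angle lattice).  No RNG: results are bit-stable.
sphere_points <- function(n) {
  stopifnot(n >= 1)
  k <- seq_len(n)
  z <- 1 - (2 * k - 1) / n
  phi <- k * pi * (3 - sqrt(5))
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
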