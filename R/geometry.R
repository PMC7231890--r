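# Internal 3-D geometry helpers: rotations, internal-coordinate atom placement
# (natural extension reference frames), and Kabsch superposition. All lengths
# in Angstrom, all angles in degrees at the interfaces.

deg2rad <- function(x) x * pi / 180

rot_x <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(1, 0, 0, 0, cos(t), -sin(t), 0, sin(t), cos(t)), 3, 3, byrow = TRUE)
}

rot_y <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), 0, sin(t), 0, 1, 0, -sin(t), 0, cos(t)), 3, 3, byrow = TRUE)
}

rot_z <- function(theta_deg) {
  t <- deg2rad(theta_deg)
  matrix(c(cos(t), -sin(t), 0, sin(t), cos(t), 0, 0, 0, 1), 3, 3, byrow = TRUE)
}

vnorm <- function(v) sqrt(sum(v^2))

unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) abort("cannot normalize a zero vector")
  v / n
}

# Place atom D given positions of A, B, C so that |C-D| = bond,
# angle(B, C, D) = angle_deg and dihedral(A, B, C, D) = torsion_deg.
place_atom <- function(a, b, c, bond, angle_deg, torsion_deg) {
  ang <- deg2rad(angle_deg)
  tor <- -deg2rad(torsion_deg) # right-hand-rule dihedral convention
  bc <- unit(c - b)
  n <- unit(pracma_cross(b - a, bc))
  m <- pracma_cross(n, bc)
  d_local <- c(
    -bond * cos(ang),
    bond * sin(ang) * cos(tor),
    bond * sin(ang) * sin(tor)
  )
  c + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}

pracma_cross <- function(u, v) {
  c(
    u[2] * v[3] - u[3] * v[2],
    u[3] * v[1] - u[1] * v[3],
    u[1] * v[2] - u[2] * v[1]
  )
}

dihedral_deg <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- pracma_cross(b1, b2)
  n2 <- pracma_cross(b2, b3)
  m1 <- pracma_cross(n1, unit(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  atan2(y, x) * 180 / pi
}

# Kabsch: proper rotation R and translation t minimizing RMSD of
# R %*% t(x) + t onto y (both n x 3 matrices).
kabsch <- function(x, y) {
  stopifnot(nrow(x) == nrow(y), ncol(x) == 3, ncol(y) == 3)
  cx <- colMeans(x)
  cy <- colMeans(y)
  x0 <- sweep(x, 2, cx)
  y0 <- sweep(y, 2, cy)
  h <- t(x0) %*% y0
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  dd <- diag(c(1, 1, d))
  r <- s$v %*% dd %*% t(s$u)
  trans <- cy - as.vector(r %*% cx)
  moved <- sweep(x %*% t(r), 2, trans, "+")
  rmsd <- sqrt(mean(rowSums((moved - y)^2)))
  list(rotation = r, translation = trans, rmsd = rmsd, transformed = moved)
}
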