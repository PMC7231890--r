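# Independent oracles used across the suite. These deliberately reimplement
# small pieces of geometry with different algorithms than the package so
# that agreement is evidence, not tautology.

# Chain construction oracle: places atom D from A, B, C and internal
# coordinates by explicit Gram-Schmidt construction of the local frame.
oracle_place <- function(a, c2, c3, bond, ang_deg, tor_deg) {
  # place the new atom cis to A first, then rotate about the B-C axis by
  # the requested dihedral (Rodrigues formula)
  ang <- ang_deg * pi / 180
  e1 <- (c3 - c2) / sqrt(sum((c3 - c2)^2))
  ab <- a - c2
  perp <- ab - sum(ab * e1) * e1
  u <- perp / sqrt(sum(perp^2)) # toward A: dihedral 0 (cis)
  d_cis <- c3 + bond * (-cos(ang) * e1 + sin(ang) * u)
  t <- -tor_deg * pi / 180 # right-hand rule about e1 measures -t here
  k <- matrix(c(
    0, -e1[3], e1[2],
    e1[3], 0, -e1[1],
    -e1[2], e1[1], 0
  ), 3, 3, byrow = TRUE)
  rot <- diag(3) + sin(t) * k + (1 - cos(t)) * k %*% k
  as.vector(rot %*% (d_cis - c3)) + c3
}

oracle_dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  cr <- function(u, v) {
    c(
      u[2] * v[3] - u[3] * v[2],
      u[3] * v[1] - u[1] * v[3],
      u[1] * v[2] - u[2] * v[1]
    )
  }
  n1 <- cr(b1, b2)
  n2 <- cr(b2, b3)
  m1 <- cr(n1, b2 / sqrt(sum(b2^2)))
  atan2(sum(m1 * n2), sum(n1 * n2)) * 180 / pi
}

oracle_angle <- function(p1, p2, p3) {
  u <- p1 - p2
  v <- p3 - p2
  acos(sum(u * v) / sqrt(sum(u^2) * sum(v^2))) * 180 / pi
}

# Backbone CA-trace oracle: rebuilds the full backbone independently with
# oracle_place and returns the CA coordinates.
oracle_backbone_cas <- function(n_res, phi, psi) {
  g <- list(
    n_ca = 1.458, ca_c = 1.525, c_n = 1.329,
    ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2
  )
  n <- c(0, 0, 0)
  ca <- c(g$n_ca, 0, 0)
  th <- (180 - g$ang_n_ca_c) * pi / 180
  cc <- ca + g$ca_c * c(cos(th), sin(th), 0)
  cas <- list(ca)
  for (i in seq_len(n_res - 1)) {
    n2 <- oracle_place(n, ca, cc, g$c_n, g$ang_ca_c_n, psi)
    ca2 <- oracle_place(ca, cc, n2, g$n_ca, g$ang_c_n_ca, 180)
    c2 <- oracle_place(cc, n2, ca2, g$ca_c, g$ang_n_ca_c, phi)
    cas[[length(cas) + 1]] <- ca2
    n <- n2
    ca <- ca2
    cc <- c2
  }
  do.call(rbind, cas)
}

# Debye two-point closed form
oracle_two_point <- function(f, q, d) 2 * f^2 * (1 + sin(q * d) / (q * d))

# Uniform solid sphere form factor (amplitude)
oracle_sphere_profile <- function(q, radius) {
  x <- q * radius
  amp <- ifelse(x < 1e-8, 1, 3 * (sin(x) - x * cos(x)) / x^3)
  amp^2
}

rigid_motion <- function(df, axis = c(1, 2, 2), angle = 37, shift = c(5, -3, 11)) {
  a <- axis / sqrt(sum(axis^2))
  t <- angle * pi / 180
  k <- matrix(c(0, -a[3], a[2], a[3], 0, -a[1], -a[2], a[1], 0), 3, 3, byrow = TRUE)
  r <- diag(3) + sin(t) * k + (1 - cos(t)) * k %*% k
  m <- as.matrix(df[, c("x", "y", "z")]) %*% t(r)
  df$x <- m[, 1] + shift[1]
  df$y <- m[, 2] + shift[2]
  df$z <- m[, 3] + shift[3]
  df
}
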