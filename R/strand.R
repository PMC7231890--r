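# Idealized extended beta-strand construction.
#
# Atoms live in a tidy table (class "zipper_atoms"): one row per atom with
# peptide / residue bookkeeping and Cartesian coordinates in Angstrom. A
# single strand is the degenerate one-peptide case; nanocrystal blocks add
# lattice index columns (i_a, i_b, i_c) and a sense column.

AA3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

# Engh-Huber-style ideal backbone geometry (Angstrom, degrees)
BB_GEOM <- list(
  n_ca = 1.458, ca_c = 1.525, c_n = 1.329, c_o = 1.231, n_h = 1.010,
  ca_cb = 1.521, c_oxt = 1.250,
  ang_c_n_ca = 121.7, ang_n_ca_c = 111.2, ang_ca_c_n = 116.2,
  ang_ca_c_o = 120.8, ang_ca_n_h = 118.2, ang_n_ca_cb = 110.4,
  omega = 180
)

new_zipper_atoms <- function(df) {
  structure(df, class = c("zipper_atoms", class(tibble())))
}

#' Build an idealized extended beta-strand
#'
#' Generates a peptide in an extended, pleated conformation by forward
#' kinematics from ideal bond lengths and angles. Backbone atoms
#' (N, H, CA, C, O) are placed exactly; the C-terminal carboxylate is
#' represented by its single carbonyl oxygen, and side chains are
#' represented at the Cbeta level with a single idealized geometry. The strand is centered on its Calpha centroid, its N-to-C
#' axis aligned with +x (the terminus-terminus lattice axis), and rolled so
#' that backbone carbonyls point along +/- z (the hydrogen-bonding axis),
#' leaving side chains along +/- y (the sheet-stacking axis). Termini carry
#' formal unit charges (protonated amine, deprotonated carboxylate).
#'
#' @param sequence One-letter amino-acid string, e.g. `"ILQINS"`.
#' @param dihedrals Numeric `(phi, psi)` pair in degrees; the default
#'   `c(-120, 115)` is an idealized pleated beta conformation compatible
#'   with parallel in-register sheets.
#' @return A tibble of class `zipper_atoms` with columns `peptide`, `res_id`,
#'   `res_name`, `atom`, `element`, `x`, `y`, `z`, `charge`, `i_a`, `i_b`,
#'   `i_c`, `sense`, and attributes `sequence`, `direction` (unit N-to-C
#'   vector) and `termini_charges`.
#' @examples
#' strand <- build_extended_strand("ILQINS")
#' nrow(dplyr::filter(strand, atom == "CA"))
#' @export
build_extended_strand <- function(sequence, dihedrals = c(-120, 115)) {
  if (!is.character(sequence) || length(sequence) != 1 || nchar(sequence) == 0) {
    abort("`sequence` must be a nonempty one-letter amino-acid string")
  }
  letters1 <- strsplit(toupper(sequence), "")[[1]]
  bad <- which(!letters1 %in% names(AA3))
  if (length(bad) > 0) {
    abort(sprintf(
      "unknown residue letter '%s' at position %d", letters1[bad[1]], bad[1]
    ))
  }
  stopifnot(is.numeric(dihedrals), length(dihedrals) == 2)
  phi <- dihedrals[1]
  psi <- dihedrals[2]
  g <- BB_GEOM
  nres <- length(letters1)

  coords <- list()
  add <- function(res, name, xyz) {
    coords[[length(coords) + 1]] <<- list(res = res, name = name, xyz = xyz)
  }

  # seed residue 1 backbone in the xy-plane
  n1 <- c(0, 0, 0)
  ca1 <- c(g$n_ca, 0, 0)
  ang <- deg2rad(180 - g$ang_n_ca_c)
  c1 <- ca1 + g$ca_c * c(cos(ang), sin(ang), 0)
  add(1, "N", n1)
  add(1, "CA", ca1)
  add(1, "C", c1)
  prev <- list(n = n1, ca = ca1, c = c1)
  add(1, "H", place_atom(c1, ca1, n1, g$n_h, g$ang_ca_n_h, 180))

  for (i in seq_len(nres)[-1]) {
    ni <- place_atom(prev$n, prev$ca, prev$c, g$c_n, g$ang_ca_c_n, psi)
    cai <- place_atom(prev$ca, prev$c, ni, g$n_ca, g$ang_c_n_ca, g$omega)
    ci <- place_atom(prev$c, ni, cai, g$ca_c, g$ang_n_ca_c, phi)
    add(i, "N", ni)
    add(i, "H", place_atom(prev$c, cai, ni, g$n_h, g$ang_ca_n_h, 180))
    add(i, "CA", cai)
    add(i, "C", ci)
    # carbonyl O of the previous residue, anti to the new N
    add(i - 1, "O", place_atom(prev$n, prev$ca, prev$c, g$c_o, g$ang_ca_c_o, psi + 180))
    prev <- list(n = ni, ca = cai, c = ci)
  }
  # terminal carbonyl O (carries the carboxylate charge; no OXT placed)
  add(nres, "O", place_atom(prev$n, prev$ca, prev$c, g$c_o, g$ang_ca_c_o, psi + 180))

  # Cbeta for non-glycine residues
  per_res <- split(coords, vapply(coords, function(a) a$res, numeric(1)))
  for (i in seq_len(nres)) {
    if (letters1[i] == "G") next
    res_atoms <- per_res[[as.character(i)]]
    get <- function(nm) res_atoms[[which(vapply(res_atoms, `[[`, "", "name") == nm)]]$xyz
    add(i, "CB", place_atom(get("N"), get("C"), get("CA"), g$ca_cb, g$ang_n_ca_cb, 122.6))
  }

  df <- tibble(
    peptide = 1L,
    res_id = vapply(coords, function(a) as.integer(a$res), integer(1)),
    res_name = unname(AA3[letters1[vapply(coords, function(a) a$res, numeric(1))]]),
    atom = vapply(coords, `[[`, "", "name"),
    element = substr(vapply(coords, `[[`, "", "name"), 1, 1),
    x = vapply(coords, function(a) a$xyz[1], numeric(1)),
    y = vapply(coords, function(a) a$xyz[2], numeric(1)),
    z = vapply(coords, function(a) a$xyz[3], numeric(1))
  ) %>%
    arrange(.data$res_id, factor(.data$atom,
      levels = c("N", "H", "CA", "CB", "C", "O")
    ))

  # formal terminal charges: NH3+ on N of residue 1, COO- on OXT
  df$charge <- 0
  df$charge[df$res_id == 1 & df$atom == "N"] <- 1
  df$charge[df$res_id == nres & df$atom == "O"] <- -1

  df <- orient_strand(df)
  df$i_a <- 0L
  df$i_b <- 0L
  df$i_c <- 0L
  df$sense <- 1L

  out <- new_zipper_atoms(df)
  attr(out, "sequence") <- paste(letters1, collapse = "")
  attr(out, "direction") <- c(1, 0, 0)
  attr(out, "termini_charges") <- c(1, -1)
  out
}

# Center on the Calpha centroid, align the N->C Calpha axis with +x and
# roll about x so the first carbonyl's y-z projection points along +z.
orient_strand <- function(df) {
  ca <- df[df$atom == "CA", c("x", "y", "z")]
  xyz <- as.matrix(df[, c("x", "y", "z")])
  xyz <- sweep(xyz, 2, colMeans(as.matrix(ca)))

  ca_m <- as.matrix(ca) - matrix(colMeans(as.matrix(ca)), nrow(ca), 3, byrow = TRUE)
  pc <- svd(ca_m)$v[, 1]
  if (sum(pc * (as.numeric(ca_m[nrow(ca_m), ]) - as.numeric(ca_m[1, ]))) < 0) pc <- -pc
  # rotation taking pc -> +x
  r1 <- rotation_between(pc, c(1, 0, 0))
  xyz <- xyz %*% t(r1)

  co <- xyz[df$atom == "O", , drop = FALSE][1, ] -
    xyz[df$atom == "C", , drop = FALSE][1, ]
  roll <- atan2(co[2], co[3]) * 180 / pi
  xyz <- xyz %*% t(rot_x(roll))

  df$x <- xyz[, 1]
  df$y <- xyz[, 2]
  df$z <- xyz[, 3]
  df
}

# Minimal rotation taking unit vector u onto unit vector v.
rotation_between <- function(u, v) {
  u <- unit(u)
  v <- unit(v)
  w <- pracma_cross(u, v)
  s <- vnorm(w)
  c_ <- sum(u * v)
  if (s < 1e-12) {
    if (c_ > 0) return(diag(3))
    # antiparallel: rotate 180 deg about any perpendicular axis
    p <- if (abs(u[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    ax <- unit(pracma_cross(u, p))
    return(2 * outer(ax, ax) - diag(3))
  }
  wx <- matrix(c(0, -w[3], w[2], w[3], 0, -w[1], -w[2], w[1], 0), 3, 3, byrow = TRUE)
  diag(3) + wx + wx %*% wx * ((1 - c_) / s^2)
}

#' @export
print.zipper_atoms <- function(x, ...) {
  seqs <- attr(x, "sequence")
  cat(sprintf(
    "<zipper_atoms> %d atoms, %d peptide(s)%s\n",
    nrow(x), length(unique(x$peptide)),
    if (!is.null(seqs)) paste0(", sequence ", seqs) else ""
  ))
  NextMethod()
}

coords_matrix <- function(atoms) {
  as.matrix(atoms[, c("x", "y", "z")])
}

set_coords <- function(atoms, m) {
  atoms$x <- m[, 1]
  atoms$y <- m[, 2]
  atoms$z <- m[, 3]
  atoms
}
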