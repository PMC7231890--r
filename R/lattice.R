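# Steric-zipper symmetry classes and nanocrystal lattice assembly.
#
# Axis semantics: a = terminus-terminus axis (x), b = side-chain stacking
# axis (in the x-y plane at angle gamma from a), c = hydrogen-bonding axis
# (z). A unit cell holds two sheets separated by b/2 along the b direction;
# block dimensions (n_a, n_b, n_c) count peptides per axis, so n_b counts
# sheets and n_c counts strands.

#' Steric-zipper symmetry classes
#'
#' The eight canonical steric-zipper arrangements as three binary choices:
#' strand sense within a sheet (parallel for classes 1-4, antiparallel for
#' 5-8), sheet face packing (face-to-face vs face-to-back) and sheet
#' orientation (up-up vs up-down). The parallel/antiparallel split is fixed
#' by the cross-beta literature; the within-group ordering used here is a
#' documented convention. The `flip_axis` column records the rotation axis
#' used to reverse strands in antiparallel sheets: about b preserves the
#' side-chain face registry, about c flips it.
#'
#' @return A tibble with columns `class`, `strand_sense` (`"P"`/`"AP"`),
#'   `face_packing`, `orientation`, `flip_axis`.
#' @examples
#' symmetry_classes()
#' @export
symmetry_classes <- function() {
  tibble(
    class = 1:8,
    strand_sense = rep(c("P", "AP"), each = 4),
    face_packing = rep(c("face-to-face", "face-to-back"), 4),
    orientation = rep(rep(c("up-up", "up-down"), each = 2), 2),
    flip_axis = c(rep(NA_character_, 4), "b", "c", "b", "c")
  )
}

#' Construct a symmetry-class descriptor
#'
#' @param index Integer 1-8.
#' @return A one-row tibble (class `symmetry_class`) from
#'   [symmetry_classes()].
#' @examples
#' symmetry_class(5)
#' @export
symmetry_class <- function(index) {
  if (!is.numeric(index) || length(index) != 1 || is.na(index) ||
    index != as.integer(index) || index < 1 || index > 8) {
    abort("symmetry class index must be an integer in 1..8")
  }
  out <- symmetry_classes()[as.integer(index), ]
  class(out) <- c("symmetry_class", class(out))
  out
}

#' Lattice parameters for a steric-zipper nanocrystal
#'
#' Defaults follow the ILQINS nanocrystal geometry: a = 20.6 Angstrom
#' (terminus-terminus), b = 19.1 Angstrom (side-chain stacking, two sheets
#' per b repeat), gamma = 82 degrees between a and b. The per-strand rise
#' along the hydrogen-bonding axis defaults to 4.8 Angstrom for parallel
#' sheets and 4.85 for antiparallel ones, so that the translated-equivalent
#' repeat in an antiparallel sheet is 9.7 Angstrom.
#'
#' @param a,b Lattice lengths in Angstrom.
#' @param gamma Angle between the a and b axes, degrees.
#' @param c_rise Per-strand rise along c in Angstrom, or `NULL` to choose
#'   4.8 (P) / 4.85 (AP) from the symmetry class at assembly time.
#' @return A list of class `lattice_params`.
#' @export
lattice_params <- function(a = 20.6, b = 19.1, gamma = 82, c_rise = NULL) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(gamma))
  if (a <= 0 || b <= 0) abort("lattice lengths must be positive")
  if (gamma <= 0 || gamma >= 180) abort("gamma must lie in (0, 180) degrees")
  if (!is.null(c_rise) && c_rise <= 0) abort("c_rise must be positive")
  structure(list(a = a, b = b, gamma = gamma, c_rise = c_rise),
    class = "lattice_params"
  )
}

default_c_rise <- function(lattice, sense) {
  if (!is.null(lattice$c_rise)) {
    return(lattice$c_rise)
  }
  if (sense == "P") 4.8 else 4.85
}

# 3x3 pose matrices for strand placement
R_FLIP_B <- diag(c(-1, 1, -1)) # 180 deg about b (sheet normal): reverses sense
R_FLIP_C <- diag(c(-1, -1, 1)) # 180 deg about c: reverses sense, flips face
R_FACE <- diag(c(1, -1, -1)) # 180 deg about a: turns a sheet's face around

#' Build the minimal repeating motif of a steric-zipper unit cell
#'
#' Returns the smallest set of posed strands that tiles the lattice: two
#' strands (one per sheet) for parallel classes, four (two per sheet, of
#' opposite sense) for antiparallel classes. Sheet 2 sits at b/2 along the
#' b direction and is turned around (180 degrees about a) for face-to-face
#' classes; up-down classes stagger sheet 2 by half the c rise.
#'
#' @param strand A `zipper_atoms` strand from [build_extended_strand()].
#' @param symmetry A class index 1-8 or a [symmetry_class()] descriptor.
#' @param lattice A [lattice_params()] object.
#' @return A `zipper_atoms` tibble of 2 or 4 posed peptides with lattice
#'   labels `(i_a, i_b, i_c)` and `sense` (+1/-1); attributes `lattice`,
#'   `symmetry`, `c_rise` and `base_strand`.
#' @examples
#' cell <- build_extended_strand("ILQINS") |> make_unit_cell(5)
#' dplyr::count(cell, peptide, sense)
#' @export
make_unit_cell <- function(strand, symmetry, lattice = lattice_params()) {
  if (!inherits(strand, "zipper_atoms")) abort("`strand` must be a zipper_atoms object")
  if (!inherits(symmetry, "symmetry_class")) symmetry <- symmetry_class(symmetry)
  if (!inherits(lattice, "lattice_params")) abort("`lattice` must be lattice_params()")

  sense_lbl <- symmetry$strand_sense
  c_rise <- default_c_rise(lattice, sense_lbl)
  flip_r <- if (identical(symmetry$flip_axis, "c")) R_FLIP_C else R_FLIP_B
  face_r <- if (symmetry$face_packing == "face-to-face") R_FACE else diag(3)
  stagger <- if (symmetry$orientation == "up-down") c_rise / 2 else 0

  b_dir <- c(cos(deg2rad(lattice$gamma)), sin(deg2rad(lattice$gamma)), 0)
  xyz0 <- coords_matrix(strand)

  pose <- function(sheet, slot) {
    r <- diag(3)
    # AP sheets alternate strand sense along c; the two sheets of a zipper
    # meet anti-phase (flip on odd slots in sheet 0, even slots in sheet 1),
    # so strand pairs facing each other across the zipper are antiparallel.
    flip_slot <- if (sheet == 0) 1L else 0L
    off <- c(0, 0, slot * c_rise)
    if (sense_lbl == "AP" && slot == flip_slot) {
      r <- flip_r
      # reversed strands related by the in-sheet (b-axis) two-fold take a
      # registry shift along a, as antiparallel strand pairs do; 2.0 A
      # clears the termini and restores the inter-strand hydrogen bonds
      if (identical(flip_r, R_FLIP_B)) off <- off + c(2.0, 0, 0)
    }
    if (sheet == 1) {
      r <- face_r %*% r
      off <- off + (lattice$b / 2) * b_dir + c(0, 0, stagger)
    }
    m <- xyz0 %*% t(r)
    m <- sweep(m, 2, off, "+")
    p <- set_coords(strand, m)
    p$i_a <- 0L
    p$i_b <- as.integer(sheet)
    p$i_c <- as.integer(slot)
    p$sense <- if (sum((r %*% c(1, 0, 0))[1]) > 0) 1L else -1L
    p
  }

  slots <- if (sense_lbl == "AP") 0:1 else 0L
  cells <- list()
  for (sheet in 0:1) {
    for (slot in slots) {
      cells[[length(cells) + 1]] <- pose(sheet, slot)
    }
  }
  out <- bind_rows(cells)
  out$peptide <- as.integer(interaction(out$i_b, out$i_c, drop = TRUE))
  out <- new_zipper_atoms(as_tibble(out))
  attr(out, "sequence") <- attr(strand, "sequence")
  attr(out, "lattice") <- lattice
  attr(out, "symmetry") <- symmetry
  attr(out, "c_rise") <- c_rise
  attr(out, "base_strand") <- strand
  out
}

#' Replicate a unit-cell motif into a nanocrystal block
#'
#' Tiles the motif from [make_unit_cell()] on the oblique lattice. Block
#' dimensions count peptides: `n_a` along the terminus-terminus axis, `n_b`
#' sheets along the side-chain stacking axis, `n_c` strands along the
#' hydrogen-bonding axis. Odd `n_b`/`n_c` are honoured by trimming the last
#' replicated cell, so single sheets (e.g. 1 x 1 x 14) are expressible.
#'
#' @param cell Output of [make_unit_cell()].
#' @param n_a,n_b,n_c Positive integers; peptide counts per axis.
#' @return A `zipper_atoms` tibble with `n_a * n_b * n_c` peptides; carries
#'   the cell's attributes plus `dims`.
#' @examples
#' blk <- build_extended_strand("ILQINS") |>
#'   make_unit_cell(1) |>
#'   build_block(2, 2, 4)
#' length(unique(blk$peptide))
#' @export
build_block <- function(cell, n_a, n_b, n_c) {
  for (d in c(n_a, n_b, n_c)) {
    if (!is.numeric(d) || length(d) != 1 || is.na(d) || d < 1 || d != as.integer(d)) {
      abort("block dimensions must be positive integers")
    }
  }
  lattice <- attr(cell, "lattice")
  symmetry <- attr(cell, "symmetry")
  c_rise <- attr(cell, "c_rise")
  if (is.null(lattice) || is.null(symmetry)) {
    abort("`cell` must come from make_unit_cell()")
  }
  strands_per_cell_c <- if (symmetry$strand_sense == "AP") 2L else 1L
  c_period <- strands_per_cell_c * c_rise
  b_dir <- c(cos(deg2rad(lattice$gamma)), sin(deg2rad(lattice$gamma)), 0)

  grid <- tidyr::crossing(
    ka = seq_len(n_a) - 1L,
    kb = seq_len(ceiling(n_b / 2)) - 1L,
    kc = seq_len(ceiling(n_c / strands_per_cell_c)) - 1L
  )

  base <- as_tibble(cell)
  reps <- purrr::pmap(grid, function(ka, kb, kc) {
    p <- base
    off <- ka * c(lattice$a, 0, 0) + kb * lattice$b * b_dir + c(0, 0, kc * c_period)
    p$x <- p$x + off[1]
    p$y <- p$y + off[2]
    p$z <- p$z + off[3]
    p$i_a <- p$i_a + as.integer(ka)
    p$i_b <- p$i_b + 2L * as.integer(kb)
    p$i_c <- p$i_c + strands_per_cell_c * as.integer(kc)
    p
  })
  out <- bind_rows(reps) %>%
    filter(.data$i_b < n_b, .data$i_c < n_c) %>%
    arrange(.data$i_a, .data$i_b, .data$i_c, .data$res_id)
  out$peptide <- as.integer(factor(
    paste(out$i_a, out$i_b, out$i_c),
    levels = unique(paste(out$i_a, out$i_b, out$i_c))
  ))
  out <- new_zipper_atoms(out)
  attr(out, "sequence") <- attr(cell, "sequence")
  attr(out, "lattice") <- lattice
  attr(out, "symmetry") <- symmetry
  attr(out, "c_rise") <- c_rise
  attr(out, "dims") <- c(n_a = n_a, n_b = n_b, n_c = n_c)
  out
}

#' Count peptides in an atom table
#' @param atoms A `zipper_atoms` tibble.
#' @return Integer peptide count.
#' @export
n_peptides <- function(atoms) length(unique(atoms$peptide))

#' Check for steric clashes between non-bonded atoms
#'
#' Reports the minimum distance between heavy atoms of different peptides
#' using a voxel hash, and whether it falls below a clash cutoff.
#'
#' @param atoms A `zipper_atoms` tibble.
#' @param cutoff Clash distance in Angstrom (default 1.8).
#' @return A list with `min_distance` and `clashed`.
#' @export
check_clashes <- function(atoms, cutoff = 1.8) {
  heavy <- atoms[atoms$element != "H", ]
  xyz <- coords_matrix(heavy)
  pep <- heavy$peptide
  cell <- 4
  key <- paste(floor(xyz[, 1] / cell), floor(xyz[, 2] / cell), floor(xyz[, 3] / cell))
  idx_by_key <- split(seq_len(nrow(xyz)), key)
  keys <- do.call(rbind, strsplit(names(idx_by_key), " "))
  storage.mode(keys) <- "integer"
  keymap <- stats::setNames(seq_along(idx_by_key), names(idx_by_key))
  mind <- Inf
  for (k in seq_along(idx_by_key)) {
    i0 <- idx_by_key[[k]]
    neigh <- i0
    for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
      if (dx == 0 && dy == 0 && dz == 0) next
      nk <- paste(keys[k, 1] + dx, keys[k, 2] + dy, keys[k, 3] + dz)
      j <- keymap[nk]
      if (!is.na(j)) neigh <- c(neigh, idx_by_key[[j]])
    }
    if (length(neigh) < 2) next
    d2 <- as.matrix(stats::dist(xyz[neigh, , drop = FALSE]))^2
    samepep <- outer(pep[neigh], pep[neigh], "==")
    d2[samepep] <- Inf
    m <- min(d2)
    if (m < mind) mind <- m
  }
  list(min_distance = sqrt(mind), clashed = sqrt(mind) < cutoff)
}
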