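# Block-cutting interface free-energy decomposition.
#
# Reference block free energies G are estimated as averages of the
# minimized coarse-grained energy of blocks cut from trajectory snapshots.
# The sheet-elongation free energy dG_c splits a 1 x 1 x n_c single sheet
# in half along the hydrogen-bonding axis; the zipper-formation free
# energy dG_zip splits a 1 x 2 x n_c two-sheet zipper into its sheets.
# Values are normalized per peptide buried by the interface and reported
# in kcal/mol.

#' Cut a sub-block out of a frame by lattice indices
#'
#' Selects exactly the peptides whose `(i_a, i_b, i_c)` labels fall inside
#' the given window; coordinates are untouched.
#'
#' @param frame A `zipper_atoms` (or labeled bead) table with lattice
#'   index columns.
#' @param dims `(n_a, n_b, n_c)` extents of the sub-block.
#' @param origin `(i_a, i_b, i_c)` lower corner (default `c(0, 0, 0)`).
#' @return The sub-block rows, same class as the input.
#' @export
cut_block <- function(frame, dims, origin = c(0L, 0L, 0L)) {
  stopifnot(length(dims) == 3, length(origin) == 3)
  if (any(dims < 1)) abort("sub-block dims must be >= 1")
  if (any(is.na(frame$i_a))) abort("frame has no lattice labels")
  parent_max <- c(max(frame$i_a), max(frame$i_b), max(frame$i_c))
  if (any(origin + dims - 1 > parent_max)) {
    abort("sub-block exceeds parent dimensions")
  }
  out <- frame %>%
    filter(
      .data$i_a >= origin[1], .data$i_a < origin[1] + dims[1],
      .data$i_b >= origin[2], .data$i_b < origin[2] + dims[2],
      .data$i_c >= origin[3], .data$i_c < origin[3] + dims[3]
    )
  out
}

#' Reference block free energy from sampled snapshots
#'
#' Relaxes each cut block in the continuum-solvent toy model (rigid-body
#' relaxation per peptide by default, preserving sampled intrachain
#' conformations) and averages the minimized energies. Refuses fewer than `min_blocks`
#' samples (default 50) unless `allow_few = TRUE`; the override is
#' recorded in the output.
#'
#' @param blocks List of cut blocks (atom or bead tables), all of the same
#'   dimensions.
#' @param model An [energy_model()].
#' @param tolerance,max_iterations,mode,max_displacement Minimizer
#'   settings (see [minimize_configuration()]); the 0.15 Angstrom trust
#'   region keeps each block's relaxation local to the sampled crystal
#'   basin, so the estimate regularizes snapshot noise without letting the
#'   coarse-grained model rearrange the lattice.
#' @param min_blocks Minimum sample count (default 50).
#' @param allow_few Override the sample-count check.
#' @return A list with `g` (mean minimized energy, kcal/mol), `stderr`,
#'   `n`, `undersampled` (TRUE when the override was used).
#' @export
block_free_energy <- function(blocks, model = energy_model(), tolerance = 0.05,
                              max_iterations = 200, min_blocks = 50,
                              allow_few = FALSE, mode = "rigid",
                              max_displacement = 0.15) {
  if (length(blocks) == 0) abort("no blocks supplied")
  npep <- vapply(blocks, n_peptides, integer(1))
  if (length(unique(npep)) != 1) abort("heterogeneous block dimensions")
  if (length(blocks) < min_blocks && !allow_few) {
    abort(sprintf(
      "only %d blocks (< %d); pass allow_few = TRUE to override",
      length(blocks), min_blocks
    ))
  }
  energies <- vapply(blocks, function(b) {
    minimize_configuration(b, model,
      tolerance = tolerance, max_iterations = max_iterations,
      mode = mode, max_displacement = max_displacement
    )$report$total
  }, numeric(1))
  list(
    g = mean(energies),
    stderr = if (length(energies) > 1) sd(energies) / sqrt(length(energies)) else 0,
    n = length(energies),
    undersampled = length(blocks) < min_blocks
  )
}

#' Interface formation free energy per buried peptide
#'
#' `[G_joined - (G_A + G_B)] / n_buried`; attractive interfaces give
#' negative values.
#'
#' @param g_joined,g_part_a,g_part_b Block free energies, kcal/mol.
#' @param n_buried Number of peptides buried by the interface (>= 1).
#' @return dG in kcal/mol per buried peptide.
#' @examples
#' interface_dG(-10, -4, -4, 2)
#' @export
interface_dG <- function(g_joined, g_part_a, g_part_b, n_buried) {
  if (n_buried < 1) abort("n_buried must be >= 1")
  (g_joined - (g_part_a + g_part_b)) / n_buried
}

# Shared machinery for the two split protocols.
split_dg <- function(trajectory, model, dims_full, cut_axis, min_blocks,
                     allow_few, tolerance, max_iterations, seed) {
  frames <- if (inherits(trajectory, "zipper_trajectory")) {
    production_frames(trajectory)
  } else {
    trajectory
  }
  if (length(frames) < 1) abort("no production frames in trajectory")
  if (!is.null(seed)) set.seed(seed)
  take <- if (length(frames) >= min_blocks || allow_few) {
    sample(seq_along(frames), min(length(frames), max(min_blocks, 1)),
      replace = FALSE
    )
  } else {
    abort(sprintf(
      "only %d frames (< %d); pass allow_few = TRUE", length(frames), min_blocks
    ))
  }
  frames <- frames[take]
  half <- dims_full
  half[cut_axis] <- dims_full[cut_axis] / 2
  origin_b <- c(0L, 0L, 0L)
  origin_b[cut_axis] <- half[cut_axis]
  joined <- lapply(frames, cut_block, dims = dims_full)
  part_a <- lapply(frames, cut_block, dims = half)
  part_b <- lapply(frames, cut_block, dims = half, origin = origin_b)
  gj <- block_free_energy(joined, model,
    min_blocks = min_blocks, allow_few = TRUE,
    tolerance = tolerance, max_iterations = max_iterations
  )
  ga <- block_free_energy(part_a, model,
    min_blocks = min_blocks, allow_few = TRUE,
    tolerance = tolerance, max_iterations = max_iterations
  )
  gb <- block_free_energy(part_b, model,
    min_blocks = min_blocks, allow_few = TRUE,
    tolerance = tolerance, max_iterations = max_iterations
  )
  list(gj = gj, ga = ga, gb = gb, n = gj$n, undersampled = length(frames) < min_blocks)
}

#' Sheet-elongation free energy along the hydrogen-bonding axis
#'
#' Splits a single sheet (1 x 1 x n_c, n_c even) in half along c and
#' applies [interface_dG()] with 2 buried peptides (one face on each side
#' of the cut). Sheet elongation along c is evaluated on single sheets
#' because aggregation in c precedes assembly in the other directions.
#'
#' @param trajectory A `zipper_trajectory` of the sheet (or list of
#'   frames).
#' @param model An [energy_model()].
#' @param dims Full sheet dims, default `c(1, 1, 14)`.
#' @param min_blocks,allow_few,tolerance,max_iterations,seed Sampling and
#'   minimizer settings (see [block_free_energy()]).
#' @return A list with `dg` (kcal/mol per buried peptide), `stderr`, `n`,
#'   `undersampled`.
#' @export
dg_c <- function(trajectory, model = energy_model(), dims = c(1, 1, 14),
                 min_blocks = 50, allow_few = FALSE, tolerance = 0.05,
                 max_iterations = 200, seed = NULL) {
  if (dims[3] %% 2 != 0) abort("n_c must be even to split in half")
  s <- split_dg(
    trajectory, model, dims, 3L, min_blocks, allow_few,
    tolerance, max_iterations, seed
  )
  n_buried <- 2
  list(
    dg = interface_dG(s$gj$g, s$ga$g, s$gb$g, n_buried),
    stderr = sqrt(s$gj$stderr^2 + s$ga$stderr^2 + s$gb$stderr^2) / n_buried,
    n = s$n, undersampled = s$undersampled
  )
}

#' Zipper-formation free energy across the sheet-stacking axis
#'
#' Splits a two-sheet zipper (1 x 2 x n_c) into its two sheets and applies
#' [interface_dG()]; every peptide of the zipper touches the steric-zipper
#' interface, so `n_buried = 2 * n_c`.
#'
#' @inheritParams dg_c
#' @param dims Full zipper dims, default `c(1, 2, 14)`.
#' @return As [dg_c()].
#' @export
dg_zip <- function(trajectory, model = energy_model(), dims = c(1, 2, 14),
                   min_blocks = 50, allow_few = FALSE, tolerance = 0.05,
                   max_iterations = 200, seed = NULL) {
  if (dims[2] != 2) abort("zipper split needs n_b = 2")
  s <- split_dg(
    trajectory, model, dims, 2L, min_blocks, allow_few,
    tolerance, max_iterations, seed
  )
  n_buried <- 2 * dims[3]
  list(
    dg = interface_dG(s$gj$g, s$ga$g, s$gb$g, n_buried),
    stderr = sqrt(s$gj$stderr^2 + s$ga$stderr^2 + s$gb$stderr^2) / n_buried,
    n = s$n, undersampled = s$undersampled
  )
}

#' Assemble an interface free-energy comparison table
#'
#' Takes per-sequence, per-class sheet-elongation and zipper free energies
#' and appends the class-1-minus-class-5 differences. Positive
#' `ddg = dG(class 1) - dG(class 5)` means the antiparallel arrangement is
#' stronger (more negative dG); negative means the parallel one is.
#'
#' @param results A tibble with columns `sequence`, `class` (1 or 5),
#'   `dg_c`, `dg_zip` and optionally `se_c`, `se_zip`.
#' @param sequence_order Optional ordering used for the monotonic-trend
#'   flag across sequences (e.g. increasing amyloidogenicity).
#' @return A tibble of class `interface_energy_table` with one row per
#'   sequence: per-class values plus `ddg_c` and `ddg_zip`; attribute
#'   `trend_monotonic` records whether both ddg columns are monotonic in
#'   `sequence_order`.
#' @examples
#' ddg_table(reference_interface_table())
#' @export
ddg_table <- function(results, sequence_order = NULL) {
  need <- c("sequence", "class", "dg_c", "dg_zip")
  if (!all(need %in% names(results))) {
    abort("results need columns sequence, class, dg_c, dg_zip")
  }
  wide <- results %>%
    filter(.data$class %in% c(1, 5)) %>%
    tidyr::pivot_wider(
      id_cols = "sequence", names_from = "class",
      values_from = dplyr::any_of(c("dg_c", "dg_zip", "se_c", "se_zip"))
    )
  if (!all(c("dg_c_1", "dg_c_5", "dg_zip_1", "dg_zip_5") %in% names(wide))) {
    abort("both classes 1 and 5 must be present for every sequence")
  }
  wide <- wide %>%
    mutate(
      ddg_c = .data$dg_c_1 - .data$dg_c_5,
      ddg_zip = .data$dg_zip_1 - .data$dg_zip_5
    )
  if (!is.null(sequence_order)) {
    w <- wide[match(sequence_order, wide$sequence), ]
    mono <- function(v) all(diff(v) >= 0) || all(diff(v) <= 0)
    attr(wide, "trend_monotonic") <- mono(w$ddg_c) && mono(w$ddg_zip)
  }
  structure(wide, class = c("interface_energy_table", class(tibble())))
}

#' Published per-class interface free energies (reference input)
#'
#' The per-sequence, per-class sheet-elongation and zipper free energies
#' (kcal/mol per buried peptide, with standard errors in the last printed
#' digit) used as printed inputs for the difference arithmetic.
#'
#' @return A tibble with columns `sequence`, `class`, `dg_c`, `se_c`,
#'   `dg_zip`, `se_zip`.
#' @export
reference_interface_table <- function() {
  path <- system.file("extdata", "reference_interface_energies.csv",
    package = "stericzipper"
  )
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  as_tibble(df)
}

#' Plot an interface free-energy comparison table
#'
#' @param object An `interface_energy_table`.
#' @param ... Ignored.
#' @return A ggplot bar chart of ddg_c and ddg_zip per sequence.
#' @export
autoplot.interface_energy_table <- function(object, ...) {
  df <- as_tibble(object) %>%
    select("sequence", "ddg_c", "ddg_zip") %>%
    tidyr::pivot_longer(-"sequence", names_to = "interface", values_to = "ddg")
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$sequence, y = .data$ddg,
    fill = .data$interface
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(y = expression(Delta * Delta * G ~ (kcal / mol)), x = NULL)
}
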