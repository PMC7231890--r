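# Coarse-grained toy energy backend: screened electrostatics between the
# charged termini, a backbone hydrogen-bond surrogate well, side-chain
# packing with a facing-gated homotypic stacking bonus, soft excluded
# volume, and an exposure-based implicit-solvent penalty. Units are
# kcal/mol, Angstrom, Kelvin throughout.

#' Parameters of the coarse-grained peptide energy model
#'
#' One bead per backbone unit (at Calpha) plus one side-chain bead per
#' non-glycine residue (at Cbeta); the terminal backbone beads carry the
#' +1/-1 formal charges of the protonated amine and the carboxylate.
#'
#' @param eps_r Relative dielectric constant (default 80, water-like).
#' @param debye_len Debye screening length in Angstrom (default 7; `Inf`
#'   disables screening).
#' @param e_hb Depth (kcal/mol) of the backbone hydrogen-bond surrogate
#'   well between backbone beads of different peptides.
#' @param hb_r0,hb_w Center and width of the hydrogen-bond well, Angstrom.
#' @param e_pack Depth of the generic side-chain packing well.
#' @param e_same Extra depth for mutually facing side chains of the same
#'   residue index (in-register homotypic stacking across a zipper
#'   interface).
#' @param pack_r0,pack_w Center and width of the packing well, Angstrom.
#' @param k_rep,rep_sigma Soft excluded-volume half-harmonic (kcal/mol/A^2)
#'   and onset distance.
#' @param solv_gamma,solv_c0,solv_rs Exposure penalty scale, target
#'   coordination and coordination range for the implicit-solvent term.
#' @param k_bond,k_angle,theta0 Bonded force constants and backbone angle
#'   (degrees) holding chains near-extended.
#' @param cutoff Nonbonded cutoff, Angstrom.
#' @param temperature Temperature in Kelvin.
#' @param w_bonded,w_elec,w_hbond,w_pack,w_solv Term weights; setting a
#'   weight to 0 switches the term off.
#' @return A list of class `energy_model`.
#' @examples
#' m <- energy_model()
#' m$eps_r
#' @export
energy_model <- function(eps_r = 80, debye_len = 7,
                         e_hb = 1.0, hb_r0 = 4.8, hb_w = 0.7,
                         e_pack = 0.2, e_same = 1.0, pack_r0 = 5.5, pack_w = 1.5,
                         k_rep = 10, rep_sigma = 4.0,
                         solv_gamma = 0.05, solv_c0 = 4, solv_rs = 6,
                         k_bond = 20, k_angle = 5, theta0 = 139,
                         cutoff = 15, temperature = 300,
                         w_bonded = 1, w_elec = 1, w_hbond = 1,
                         w_pack = 1, w_solv = 1) {
  if (eps_r <= 0) abort("eps_r must be positive")
  if (temperature <= 0) abort("temperature must be positive")
  m <- as.list(environment())
  if (!all(vapply(m, function(v) is.numeric(v) && length(v) == 1 && !is.na(v), logical(1)))) {
    abort("all energy_model parameters must be finite scalars")
  }
  structure(m, class = "energy_model")
}

#' Switch off all nonbonded interactions of a model
#'
#' Convenience for null-model checks: bonded terms stay, every interaction
#' between peptides is zeroed.
#' @param model An [energy_model()].
#' @return The model with interaction weights and repulsion set to 0.
#' @export
interactions_off <- function(model = energy_model()) {
  model$w_elec <- 0
  model$w_hbond <- 0
  model$w_pack <- 0
  model$w_solv <- 0
  model$k_rep <- 0
  model
}

#' Map an atomic structure onto coarse-grained beads
#'
#' Backbone beads at Calpha positions, side-chain beads at Cbeta; atom
#' formal charges are transferred to the backbone bead of the carrying
#' residue.
#'
#' @param atoms A `zipper_atoms` table with a `charge` column.
#' @return A tibble of class `zipper_beads` with columns `peptide`,
#'   `res_id`, `bead` ("BB"/"SC"), `x`, `y`, `z`, `charge`.
#' @export
coarse_grain <- function(atoms) {
  if (!"charge" %in% names(atoms) || all(is.na(atoms$charge))) {
    abort("missing charge assignment: atoms need a `charge` column")
  }
  chg <- atoms %>%
    group_by(.data$peptide, .data$res_id) %>%
    summarise(charge = sum(.data$charge, na.rm = TRUE), .groups = "drop")
  bb <- atoms %>%
    filter(.data$atom == "CA") %>%
    mutate(bead = "BB") %>%
    select("peptide", "res_id", "bead", "x", "y", "z") %>%
    left_join(chg, by = c("peptide", "res_id"))
  sc <- atoms %>%
    filter(.data$atom == "CB") %>%
    mutate(bead = "SC", charge = 0) %>%
    select("peptide", "res_id", "bead", "x", "y", "z", "charge")
  out <- bind_rows(bb, sc) %>%
    arrange(.data$peptide, .data$res_id, .data$bead)
  structure(out, class = c("zipper_beads", class(tibble())))
}

# Internal: bead table -> matrices/topology for the C++ backend.
bead_system <- function(beads, model) {
  beads <- as_tibble(beads)
  pep_levels <- unique(beads$peptide)
  pep0 <- as.integer(factor(beads$peptide, levels = pep_levels)) - 1L
  type0 <- ifelse(beads$bead == "SC", 1L, 0L)
  n <- nrow(beads)
  partner <- rep(-1L, n)
  bonds <- list()
  angles <- list()
  th0 <- model$theta0 * pi / 180
  for (p in unique(pep0)) {
    idx <- which(pep0 == p)
    bb <- idx[type0[idx] == 0L][order(beads$res_id[idx][type0[idx] == 0L])]
    sc <- idx[type0[idx] == 1L]
    for (k in seq_along(bb)[-1]) {
      bonds[[length(bonds) + 1]] <- c(bb[k - 1] - 1L, bb[k] - 1L, 3.80, model$k_bond)
    }
    if (length(bb) > 2) {
      for (k in 2:(length(bb) - 1)) {
        angles[[length(angles) + 1]] <- c(
          bb[k - 1] - 1L, bb[k] - 1L, bb[k + 1] - 1L, th0, model$k_angle
        )
      }
    }
    for (s in sc) {
      ca <- bb[match(beads$res_id[s], beads$res_id[bb])]
      partner[s] <- ca - 1L
      bonds[[length(bonds) + 1]] <- c(ca - 1L, s - 1L, 1.53, model$k_bond)
    }
  }
  list(
    coords = as.matrix(beads[, c("x", "y", "z")]),
    pep = pep0,
    type = type0,
    resid = as.integer(beads$res_id),
    partner = partner,
    charge = as.numeric(beads$charge),
    bonds = if (length(bonds)) do.call(rbind, bonds) else matrix(0, 0, 4),
    angles = if (length(angles)) do.call(rbind, angles) else matrix(0, 0, 5),
    pep_levels = pep_levels,
    beads = beads
  )
}

is_bead_table <- function(x) {
  inherits(x, "zipper_beads") || ("bead" %in% names(x) && !"atom" %in% names(x))
}

model_params <- function(model) {
  model[c(
    "eps_r", "debye_len", "e_hb", "hb_r0", "hb_w", "e_pack", "e_same",
    "pack_r0", "pack_w", "k_rep", "rep_sigma", "solv_gamma", "solv_c0",
    "solv_rs", "cutoff", "w_bonded", "w_elec", "w_hbond", "w_pack", "w_solv"
  )]
}

#' Total energy of a configuration
#'
#' Evaluates the coarse-grained energy of an atomic structure (coarse
#' grained on the fly) or of a bead table, returning the per-term breakdown
#' and a per-peptide decomposition.
#'
#' @param configuration A `zipper_atoms` or `zipper_beads` table.
#' @param model An [energy_model()].
#' @return A list of class `energy_report`: `total` (kcal/mol), `terms`
#'   (named vector: bonded, packing, electrostatic, hbond, solvation,
#'   repulsion), `per_peptide` (tibble).
#' @examples
#' dimer <- make_ideal_assembly("ILQINS", 5, sheet_n(2))
#' total_energy(dimer, energy_model())$terms
#' @export
total_energy <- function(configuration, model = energy_model()) {
  beads <- if (is_bead_table(configuration)) {
    configuration
  } else {
    coarse_grain(configuration)
  }
  sys <- bead_system(beads, model)
  res <- toy_energy_cpp(
    sys$coords, sys$pep, sys$type, sys$resid, sys$partner, sys$charge,
    sys$bonds, sys$angles, model_params(model), FALSE
  )
  structure(
    list(
      total = res$total,
      terms = res$terms,
      per_peptide = tibble(peptide = sys$pep_levels, energy = res$per_peptide)
    ),
    class = "energy_report"
  )
}

#' @export
print.energy_report <- function(x, ...) {
  cat(sprintf("<energy_report> total %.4f kcal/mol\n", x$total))
  print(round(x$terms, 4))
  invisible(x)
}

#' @export
tidy.energy_report <- function(x, ...) {
  tibble(term = names(x$terms), energy = as.numeric(x$terms))
}

#' @export
glance.energy_report <- function(x, ...) {
  tibble(total = x$total, n_peptides = nrow(x$per_peptide))
}

#' Locally minimize a configuration
#'
#' Gradient descent with backtracking line search on the coarse-grained
#' energy surface. Accepted steps never increase the energy; iteration
#' stops when the gradient norm falls below `tolerance` or at
#' `max_iterations`. In `"rigid"` mode each peptide moves as a rigid body
#' (net force and torque only), keeping intrachain geometry fixed --- the
#' mode used when regularizing cut nanocrystal blocks, where internal
#' strand conformations come from the sampled snapshot and only packing
#' artifacts of the cut should relax.
#'
#' @param configuration A `zipper_atoms` or `zipper_beads` table.
#' @param model An [energy_model()].
#' @param tolerance Gradient max-norm convergence threshold
#'   (kcal/mol/Angstrom).
#' @param max_iterations Iteration cap.
#' @param mode `"cartesian"` (all bead coordinates free) or `"rigid"`
#'   (per-peptide rigid-body relaxation).
#' @param max_displacement Optional trust region, Angstrom: iteration also
#'   stops once any bead has moved this far from its starting position,
#'   keeping the relaxation local to the sampled basin (used by the
#'   block-cutting protocol).
#' @return A list of class `minimized_configuration`: `beads` (minimized
#'   bead table), `report` (final [total_energy()] report), `initial_energy`,
#'   `converged`, `iterations`, `grad_norm`.
#' @export
minimize_configuration <- function(configuration, model = energy_model(),
                                   tolerance = 0.01, max_iterations = 500,
                                   mode = c("cartesian", "rigid"),
                                   max_displacement = Inf) {
  mode <- match.arg(mode)
  beads <- if (is_bead_table(configuration)) {
    configuration
  } else {
    coarse_grain(configuration)
  }
  sys <- bead_system(beads, model)
  pars <- model_params(model)
  x <- sys$coords
  evalE <- function(xx) {
    toy_energy_cpp(
      xx, sys$pep, sys$type, sys$resid, sys$partner, sys$charge,
      sys$bonds, sys$angles, pars, TRUE
    )
  }
  pep_split <- split(seq_len(nrow(x)), sys$pep)
  rigid_step <- function(xx, g, step) {
    # rigid-body descent: net force moves the centroid, net torque
    # rotates about it (Rodrigues), per peptide
    out <- xx
    for (idx in pep_split) {
      cen <- colMeans(xx[idx, , drop = FALSE])
      rel <- sweep(xx[idx, , drop = FALSE], 2, cen)
      f <- colSums(g[idx, , drop = FALSE])
      tq <- c(
        sum(rel[, 2] * g[idx, 3] - rel[, 3] * g[idx, 2]),
        sum(rel[, 3] * g[idx, 1] - rel[, 1] * g[idx, 3]),
        sum(rel[, 1] * g[idx, 2] - rel[, 2] * g[idx, 1])
      )
      r2 <- mean(rowSums(rel^2))
      ang <- -step * tq / max(r2 * length(idx), 1e-8)
      th <- sqrt(sum(ang^2))
      rotm <- if (th > 1e-12) rotation_about_axis(ang / th, th * 180 / pi) else diag(3)
      out[idx, ] <- sweep(rel %*% t(rotm), 2, cen - step * f / length(idx), "+")
    }
    out
  }
  gnorm_of <- function(g) {
    if (mode == "cartesian") {
      return(max(abs(g)))
    }
    # rigid mode: largest per-peptide net force / torque component
    max(vapply(pep_split, function(idx) {
      cen <- colMeans(x[idx, , drop = FALSE])
      rel <- sweep(x[idx, , drop = FALSE], 2, cen)
      f <- colSums(g[idx, , drop = FALSE]) / length(idx)
      tq <- c(
        sum(rel[, 2] * g[idx, 3] - rel[, 3] * g[idx, 2]),
        sum(rel[, 3] * g[idx, 1] - rel[, 1] * g[idx, 3]),
        sum(rel[, 1] * g[idx, 2] - rel[, 2] * g[idx, 1])
      ) / max(mean(rowSums(rel^2)) * length(idx), 1e-8)
      max(abs(c(f, tq)))
    }, numeric(1)))
  }
  x_start <- x
  cur <- evalE(x)
  e0 <- cur$total
  step <- 0.05
  it <- 0
  gnorm <- gnorm_of(cur$gradient)
  while (it < max_iterations && gnorm > tolerance) {
    if (is.finite(max_displacement) &&
      max(abs(x - x_start)) >= max_displacement) {
      break
    }
    it <- it + 1
    g <- cur$gradient
    accepted <- FALSE
    for (bt in 1:25) {
      xn <- if (mode == "rigid") rigid_step(x, g, step) else x - step * g
      nxt <- evalE(xn)
      if (is.finite(nxt$total) && nxt$total <= cur$total) {
        x <- xn
        cur <- nxt
        step <- step * 1.5
        accepted <- TRUE
        break
      }
      step <- step / 2
    }
    if (!accepted) break
    gnorm <- gnorm_of(cur$gradient)
    if (cur$total < -1e8) abort("energy diverging: model error")
  }
  out_beads <- sys$beads
  out_beads$x <- x[, 1]
  out_beads$y <- x[, 2]
  out_beads$z <- x[, 3]
  out_beads <- structure(out_beads, class = c("zipper_beads", class(tibble())))
  structure(
    list(
      beads = out_beads,
      report = total_energy(out_beads, model),
      initial_energy = e0,
      converged = gnorm <= tolerance,
      iterations = it,
      grad_norm = gnorm
    ),
    class = "minimized_configuration"
  )
}

#' Bjerrum length
#'
#' Separation at which two unit charges interact with thermal energy k_B T
#' in a medium of relative dielectric `epsilon_r`:
#' `l_B = e^2 / (4 pi eps0 eps_r k_B T)`.
#'
#' @param epsilon_r Relative dielectric constant (> 0).
#' @param temperature_K Temperature in Kelvin (> 0).
#' @return Length in Angstrom.
#' @examples
#' bjerrum_length(80, 300) # about 7 Angstrom through water
#' bjerrum_length(15, 300) # about 37 Angstrom through a peptide assembly
#' @export
bjerrum_length <- function(epsilon_r, temperature_K = 300) {
  if (!is.numeric(epsilon_r) || epsilon_r <= 0) abort("epsilon_r must be > 0")
  if (!is.numeric(temperature_K) || temperature_K <= 0) abort("temperature_K must be > 0")
  332.0637 / (epsilon_r * KB_KCAL * temperature_K)
}

#' Effective molar concentration of molecules in a sphere
#'
#' @param n_molecules Number of molecules.
#' @param radius_A Sphere radius in Angstrom.
#' @return Concentration in mol/L.
#' @examples
#' effective_concentration(64, 50) # about 0.2 M
#' @export
effective_concentration <- function(n_molecules, radius_A) {
  if (n_molecules <= 0 || radius_A <= 0) abort("inputs must be positive")
  vol_L <- 4 / 3 * pi * (radius_A * 1e-9)^3 # A^3 -> dm^3 via (1e-9 dm)^3
  n_molecules / (6.02214076e23 * vol_L)
}
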