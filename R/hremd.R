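# Hamiltonian replica exchange over the coarse-grained energy backend.
#
# Replica i feels the unmodified Hamiltonian plus a harmonic restraint
# U(x, lambda_i) = (1/2) lambda_i |x|^2, where x is the vector of bead
# displacements from an extended reference conformation rigidly
# superimposed on each peptide. lambda_0 = 0, so the replica-0 stream
# samples the unbiased ensemble. Dynamics between exchange attempts are
# overdamped Langevin; exchanges alternate between even and odd adjacent
# pairs with the Metropolis criterion.

#' Replica schedule for Hamiltonian replica exchange
#'
#' The restraint strengths follow the quadratic ladder
#' `lambda_i = lambda_max * (i / (M - 1))^2` for `i` in `0..M-1`, so
#' `lambda_0 = 0` exactly and `lambda_{M-1} = lambda_max`.
#'
#' @param n_replicas Replica count M (default 64).
#' @param lambda_max Strongest restraint, kcal/mol/A^2 (default 0.032).
#' @param exchange_interval_ps Time between exchange attempts, ps
#'   (default 5).
#' @param temperature Temperature in Kelvin (default 300).
#' @return A list of class `replica_schedule` with `lambda` (length M),
#'   `beta` (1/kcal/mol) and the inputs.
#' @examples
#' sched <- replica_schedule()
#' c(sched$lambda[1], sched$lambda[64])
#' @export
replica_schedule <- function(n_replicas = 64, lambda_max = 0.032,
                             exchange_interval_ps = 5, temperature = 300) {
  if (n_replicas < 1) abort("need at least one replica")
  lambda <- if (n_replicas == 1) {
    0
  } else {
    lambda_max * ((seq_len(n_replicas) - 1) / (n_replicas - 1))^2
  }
  structure(
    list(
      n_replicas = as.integer(n_replicas), lambda_max = lambda_max,
      lambda = lambda, exchange_interval_ps = exchange_interval_ps,
      temperature = temperature, beta = 1 / (KB_KCAL * temperature)
    ),
    class = "replica_schedule"
  )
}

#' Optimal rigid superposition (Kabsch)
#'
#' Proper rotation (determinant +1) and translation minimizing the RMSD of
#' `reference` onto `target`.
#'
#' @param reference,target n x 3 coordinate matrices (or bead/atom tables),
#'   equal row counts, at least 3 non-collinear points.
#' @return A list with `rotation`, `translation`, `rmsd` and `transformed`
#'   (the fitted reference).
#' @export
superimpose <- function(reference, target) {
  ref <- to_coords(reference)
  tgt <- to_coords(target)
  if (nrow(ref) != nrow(tgt)) abort("coordinate sets differ in atom count")
  if (nrow(ref) < 3) abort("need at least 3 points")
  for (m in list(ref, tgt)) {
    s <- svd(sweep(m, 2, colMeans(m)))$d
    if (s[2] < 1e-8 * max(s[1], 1)) abort("degenerate (collinear) geometry")
  }
  kabsch(ref, tgt)
}

to_coords <- function(x) {
  if (is.matrix(x)) {
    return(x)
  }
  as.matrix(x[, c("x", "y", "z")])
}

#' Harmonic reference-restraint energy of one peptide
#'
#' Superimposes the rigid reference onto the peptide and returns
#' `(1/2) * lambda * sum(|displacement|^2)`.
#'
#' @param peptide Bead/atom table or coordinate matrix of one peptide.
#' @param reference Matching reference coordinates.
#' @param lambda Restraint strength, kcal/mol/A^2 (>= 0).
#' @return Energy in kcal/mol.
#' @export
restraint_energy <- function(peptide, reference, lambda) {
  if (lambda < 0) abort("lambda must be >= 0")
  if (lambda == 0) {
    return(0)
  }
  fit <- superimpose(reference, peptide)
  0.5 * lambda * sum((to_coords(peptide) - fit$transformed)^2)
}

#' Replica-exchange energy difference
#'
#' `DeltaU_ij = [U(lambda_i, x_j) + U(lambda_j, x_i)] -
#'  [U(lambda_j, x_j) + U(lambda_i, x_i)]`, evaluated with the shared
#' reference; symmetric under jointly swapping (lambda_i, x_i) with
#' (lambda_j, x_j) (the cost of an exchange does not depend on which
#' partner proposes it) and zero when the lambdas are equal.
#'
#' @param lambda_i,lambda_j Restraint strengths.
#' @param coords_i,coords_j Multi-peptide bead tables (with `peptide`
#'   column) or single-peptide coordinate matrices.
#' @param reference Per-peptide reference coordinates.
#' @return DeltaU in kcal/mol.
#' @export
exchange_delta <- function(lambda_i, lambda_j, coords_i, coords_j, reference) {
  ri <- restraint_sum(coords_i, reference)
  rj <- restraint_sum(coords_j, reference)
  (lambda_i * rj + lambda_j * ri) - (lambda_j * rj + lambda_i * ri)
}

# Sum over peptides of the per-unit-lambda restraint (1/2)|x - T(ref)|^2.
restraint_sum <- function(coords, reference) {
  ref <- to_coords(reference)
  if (is.matrix(coords)) {
    return(restraint_sum_cpp(coords, rep(0L, nrow(coords)), ref, 1L))
  }
  pep0 <- as.integer(factor(coords$peptide)) - 1L
  restraint_sum_cpp(to_coords(coords), pep0, ref, max(pep0) + 1L)
}

#' Metropolis acceptance for a replica exchange
#'
#' Deterministic accept for `delta_u <= 0`; otherwise accept when the
#' uniform draw is below `exp(-beta * delta_u)`.
#'
#' @param delta_u Exchange energy difference, kcal/mol.
#' @param beta Inverse temperature, 1/(kcal/mol).
#' @param random_draw Uniform(0,1) draw; generated if missing.
#' @return Logical.
#' @examples
#' metropolis_accept(-1, 1.69) # always TRUE
#' @export
metropolis_accept <- function(delta_u, beta, random_draw = runif(1)) {
  if (beta <= 0) abort("beta must be positive")
  if (delta_u <= 0) {
    return(TRUE)
  }
  random_draw < exp(-beta * delta_u)
}

#' Run Hamiltonian replica-exchange dynamics
#'
#' Propagates every replica with overdamped Langevin dynamics on the toy
#' energy model plus its restraint, attempting adjacent-pair exchanges
#' (alternating even/odd pairings) every `exchange_interval_ps`. Peptide
#' centroids are confined to a sphere. Fully reproducible for a given
#' seed.
#'
#' @param system A `zipper_beads` table: the starting configuration of all
#'   peptides (see [initial_gas()]).
#' @param schedule A [replica_schedule()].
#' @param reference Bead coordinates of the extended reference peptide
#'   (matrix or single-peptide bead table), internally rigid.
#' @param model An [energy_model()].
#' @param n_steps Total Langevin steps per replica.
#' @param seed Integer RNG seed (mandatory).
#' @param dt_ps Langevin step, ps (nominal time axis).
#' @param friction Friction coefficient (kcal/mol ps / A^2 scale).
#' @param confinement_radius Sphere radius in Angstrom (default 50).
#' @param confinement_k Wall stiffness, kcal/mol/A^2.
#' @param stride Steps between stored frames (default: one frame per
#'   exchange segment).
#' @return A list of class `hremd_run`: `exchange_log` (tibble: attempt,
#'   step, i, j, delta_u, accepted), `trajectories` (per replica list of
#'   bead tables), `time_ns`, `schedule`, `replica_of_walker`.
#' @export
run_hremd <- function(system, schedule, reference, model = energy_model(),
                      n_steps = 1000, seed, dt_ps = 0.002, friction = 1,
                      confinement_radius = 50, confinement_k = 10,
                      stride = NULL) {
  if (missing(seed)) abort("`seed` is mandatory for reproducibility")
  set.seed(seed)
  ref <- to_coords(reference)
  sys <- bead_system(system, model)
  m <- schedule$n_replicas
  if (nrow(ref) * length(sys$pep_levels) != nrow(sys$coords)) {
    abort("reference bead count inconsistent with system")
  }
  pars <- model_params(model)
  steps_per_seg <- max(1L, round(schedule$exchange_interval_ps / dt_ps))
  n_seg <- max(1L, ceiling(n_steps / steps_per_seg))

  coords <- replicate(m, sys$coords, simplify = FALSE)
  restr <- rep(NA_real_, m)
  log_rows <- list()
  trajs <- replicate(m, list(), simplify = FALSE)
  walker <- seq_len(m) # replica_of_walker bookkeeping for round trips
  walker_trace <- matrix(NA_integer_, n_seg, m)
  times <- numeric(0)

  for (seg in seq_len(n_seg)) {
    for (i in seq_len(m)) {
      out <- langevin_segment_cpp(
        coords[[i]], sys$pep, sys$type, sys$resid, sys$partner, sys$charge,
        sys$bonds, sys$angles, pars, ref, schedule$lambda[i],
        steps_per_seg, dt_ps, schedule$temperature, friction,
        confinement_radius, confinement_k
      )
      coords[[i]] <- out$coords
      restr[i] <- out$restraint_sum
    }
    step_now <- seg * steps_per_seg
    if (m > 1) {
      start <- if (seg %% 2 == 1) 1L else 2L
      pairs <- if (start > m - 1) integer(0) else seq(start, m - 1L, by = 2L)
      for (i in pairs) {
        j <- i + 1L
        du <- (schedule$lambda[i] * restr[j] + schedule$lambda[j] * restr[i]) -
          (schedule$lambda[j] * restr[j] + schedule$lambda[i] * restr[i])
        acc <- metropolis_accept(du, schedule$beta)
        if (acc) {
          tmp <- coords[[i]]
          coords[[i]] <- coords[[j]]
          coords[[j]] <- tmp
          tr <- restr[i]
          restr[i] <- restr[j]
          restr[j] <- tr
          tw <- walker[i]
          walker[i] <- walker[j]
          walker[j] <- tw
        }
        log_rows[[length(log_rows) + 1]] <- tibble(
          attempt = seg, step = step_now, i = i - 1L, j = j - 1L,
          delta_u = du, accepted = acc
        )
      }
    }
    walker_trace[seg, ] <- walker
    if (is.null(stride) || (step_now %% stride) == 0) {
      for (i in seq_len(m)) {
        b <- sys$beads
        b$x <- coords[[i]][, 1]
        b$y <- coords[[i]][, 2]
        b$z <- coords[[i]][, 3]
        trajs[[i]][[length(trajs[[i]]) + 1]] <- b
      }
      times <- c(times, step_now * dt_ps / 1000)
    }
  }
  structure(
    list(
      exchange_log = if (length(log_rows)) bind_rows(log_rows) else
        tibble(attempt = integer(0), step = integer(0), i = integer(0),
               j = integer(0), delta_u = numeric(0), accepted = logical(0)),
      trajectories = trajs,
      time_ns = times,
      schedule = schedule,
      replica_of_walker = walker,
      walker_trace = walker_trace
    ),
    class = "hremd_run"
  )
}

#' @export
tidy.hremd_run <- function(x, ...) as_tibble(x$exchange_log)

#' @export
glance.hremd_run <- function(x, ...) {
  lg <- x$exchange_log
  tibble(
    n_replicas = x$schedule$n_replicas,
    n_attempts = nrow(lg),
    acceptance = if (nrow(lg)) mean(lg$accepted) else NA_real_,
    n_frames = length(x$time_ns)
  )
}

#' Exchange-mixing diagnostics
#'
#' Per-adjacent-pair acceptance rates and a lower-bound round-trip count
#' from the walker permutation.
#'
#' @param exchange_log Tibble from [run_hremd()] (or an `hremd_run`).
#' @return A list with `pair_rates` (tibble: i, j, attempts, accepted,
#'   rate; pairs never attempted are flagged with `NA` rate),
#'   `n_accepted_total` and `round_trips` (total walker traversals from
#'   replica 0 to the top and back; `NA` when only a bare log is given).
#' @export
mixing_diagnostics <- function(exchange_log) {
  trace <- NULL
  if (inherits(exchange_log, "hremd_run")) {
    trace <- exchange_log$walker_trace
    exchange_log <- exchange_log$exchange_log
  }
  if (nrow(exchange_log) == 0) abort("exchange log is empty")
  rates <- exchange_log %>%
    group_by(.data$i, .data$j) %>%
    summarise(
      attempts = n(),
      rate = mean(.data$accepted),
      accepted = sum(.data$accepted),
      .groups = "drop"
    )
  round_trips <- NA_integer_
  if (!is.null(trace) && ncol(trace) > 1) {
    m <- ncol(trace)
    round_trips <- 0L
    for (w in seq_len(m)) {
      # replica index occupied by walker w over time
      pos <- apply(trace, 1, function(row) which(row == w))
      state <- 0L # 1 after touching bottom, 2 after then touching top
      for (p in pos) {
        if (state == 0L && p == 1L) state <- 1L
        if (state == 1L && p == m) state <- 2L
        if (state == 2L && p == 1L) {
          round_trips <- round_trips + 1L
          state <- 1L
        }
      }
    }
  }
  list(
    pair_rates = rates,
    n_accepted_total = sum(exchange_log$accepted),
    round_trips = round_trips
  )
}
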