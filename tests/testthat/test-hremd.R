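# Replica-exchange machinery: superposition, restraint, exchange rule,
# Metropolis acceptance, schedules and reproducibility.

ref_beads <- coarse_grain(build_extended_strand("ILQINS"))
ref <- as.matrix(ref_beads[, c("x", "y", "z")])

test_that("lambda schedule endpoints are exact and the ladder increases", {
  sched <- replica_schedule()
  expect_equal(sched$n_replicas, 64L)
  expect_identical(sched$lambda[1], 0)
  expect_identical(sched$lambda[64], 0.032)
  expect_true(all(diff(sched$lambda) > 0))
  expect_equal(sched$lambda[33], 0.032 * (32 / 63)^2)
  s1 <- replica_schedule(n_replicas = 1)
  expect_equal(s1$lambda, 0)
})

test_that("superposition recovers identity, known rotations and stays proper", {
  fit0 <- superimpose(ref, ref)
  expect_equal(fit0$rmsd, 0, tolerance = 1e-9)
  expect_equal(fit0$rotation, diag(3), tolerance = 1e-9)
  set.seed(4)
  ax <- c(1, 2, 3) / sqrt(14)
  th <- 50 * pi / 180
  k <- matrix(c(0, -ax[3], ax[2], ax[3], 0, -ax[1], -ax[2], ax[1], 0), 3, 3, byrow = TRUE)
  rot <- diag(3) + sin(th) * k + (1 - cos(th)) * k %*% k
  target <- sweep(ref %*% t(rot), 2, c(3, -2, 8), "+")
  fit <- superimpose(ref, target)
  expect_equal(fit$rotation, rot, tolerance = 1e-8)
  expect_equal(fit$rmsd, 0, tolerance = 1e-8)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  # mirror image: still a proper rotation, nonzero residual
  mirror <- ref %*% diag(c(-1, 1, 1))
  fitm <- superimpose(ref, mirror)
  expect_equal(det(fitm$rotation), 1, tolerance = 1e-9)
  expect_gt(fitm$rmsd, 0.1)
  # cross-check against the bio3d least-squares fit
  n3 <- 3 * nrow(ref)
  b3 <- bio3d::fit.xyz(
    fixed = as.vector(t(target)), mobile = as.vector(t(ref)),
    fixed.inds = seq_len(n3), mobile.inds = seq_len(n3)
  )
  expect_equal(
    fit$transformed,
    matrix(b3, ncol = 3, byrow = TRUE),
    tolerance = 1e-6, ignore_attr = TRUE
  )
  expect_error(superimpose(ref, ref[-1, ]), "count")
  line <- cbind(1:5, 0, 0)
  expect_error(superimpose(line, line), "degenerate")
})

test_that("restraint energy vanishes at lambda 0 and under rigid motion", {
  expect_identical(restraint_energy(ref, ref, 0), 0)
  moved <- rigid_motion(ref_beads)
  expect_equal(restraint_energy(moved, ref, 0.032), 0, tolerance = 1e-8)
  # displacing one bead by delta along the residual costs 1/2 lambda delta^2
  # (numeric oracle: brute-force evaluation after superposition)
  pert <- ref
  pert[5, ] <- pert[5, ] + c(0, 0, 0.4)
  lam <- 0.02
  fit <- superimpose(ref, pert)
  brute <- 0.5 * lam * sum((pert - fit$transformed)^2)
  expect_equal(restraint_energy(pert, ref, lam), brute, tolerance = 1e-10)
  expect_gt(brute, 0)
  expect_error(restraint_energy(ref, ref, -1), ">= 0")
})

test_that("exchange delta is pair-symmetric and recomputable from restraints", {
  set.seed(8)
  conf_i <- ref + matrix(rnorm(length(ref), sd = 0.3), ncol = 3)
  conf_j <- ref + matrix(rnorm(length(ref), sd = 0.6), ncol = 3)
  li <- 0.01
  lj <- 0.03
  du <- exchange_delta(li, lj, conf_i, conf_j, ref)
  # the exchange cost is the same whichever replica proposes it
  expect_equal(exchange_delta(lj, li, conf_j, conf_i, ref), du, tolerance = 1e-10)
  expect_equal(exchange_delta(li, li, conf_i, conf_j, ref), 0, tolerance = 1e-12)
  # direct recomputation from four restraint evaluations
  u <- function(l, x) restraint_energy(x, ref, l)
  du_direct <- (u(li, conf_j) + u(lj, conf_i)) - (u(lj, conf_j) + u(li, conf_i))
  expect_equal(du, du_direct, tolerance = 1e-10)
})

test_that("Metropolis rule accepts downhill always and uphill at exp(-beta dU)", {
  beta <- replica_schedule()$beta
  expect_true(metropolis_accept(-1, beta))
  expect_true(metropolis_accept(0, beta))
  # empirical acceptance over 1e5 draws within 3 sigma binomial
  du <- 0.7
  p_theory <- exp(-beta * du)
  set.seed(123)
  n <- 1e5
  acc <- mean(vapply(runif(n), function(u) metropolis_accept(du, beta, u), logical(1)))
  se <- sqrt(p_theory * (1 - p_theory) / n)
  expect_lt(abs(acc - p_theory), 3 * se)
  expect_error(metropolis_accept(1, -2), "positive")
})

test_that("a single-replica run is plain dynamics without exchanges", {
  gas <- initial_gas("ILQINS", 3, radius = 15, seed = 21)
  run <- run_hremd(gas, replica_schedule(n_replicas = 1, exchange_interval_ps = 0.2),
    attr(gas, "reference"),
    energy_model(),
    n_steps = 100, seed = 1, dt_ps = 0.01, confinement_radius = 15
  )
  expect_equal(nrow(run$exchange_log), 0)
  expect_gt(length(run$trajectories[[1]]), 0)
})

test_that("two replicas with equal lambdas always exchange", {
  gas <- initial_gas("ILQINS", 3, radius = 15, seed = 22)
  sched <- replica_schedule(n_replicas = 2, lambda_max = 0, exchange_interval_ps = 0.1)
  run <- run_hremd(gas, sched, attr(gas, "reference"), energy_model(),
    n_steps = 200, seed = 2, dt_ps = 0.01, confinement_radius = 15
  )
  expect_true(all(run$exchange_log$accepted))
  expect_true(all(abs(run$exchange_log$delta_u) < 1e-12))
})

test_that("identical seeds give bit-identical exchange logs", {
  gas <- initial_gas("ILQINS", 4, radius = 15, seed = 23)
  sched <- replica_schedule(n_replicas = 3, exchange_interval_ps = 0.1)
  go <- function() {
    run_hremd(gas, sched, attr(gas, "reference"), energy_model(),
      n_steps = 300, seed = 77, dt_ps = 0.01, confinement_radius = 15
    )
  }
  a <- go()
  b <- go()
  expect_identical(a$exchange_log, b$exchange_log)
  expect_identical(
    a$trajectories[[1]][[length(a$trajectories[[1]])]],
    b$trajectories[[1]][[length(b$trajectories[[1]])]]
  )
})

test_that("confinement keeps peptide centroids near the sphere", {
  gas <- initial_gas("ILQINS", 4, radius = 12, seed = 31)
  run <- run_hremd(gas, replica_schedule(n_replicas = 2, exchange_interval_ps = 0.5),
    attr(gas, "reference"), energy_model(),
    n_steps = 1000, seed = 3, dt_ps = 0.01, confinement_radius = 12
  )
  end <- run$trajectories[[1]][[length(run$trajectories[[1]])]]
  cen <- end |>
    dplyr::group_by(peptide) |>
    dplyr::summarise(r = sqrt(mean(x)^2 + mean(y)^2 + mean(z)^2))
  expect_true(all(cen$r < 12 + 5))
})

test_that("mixing diagnostics count rates and round trips from known logs", {
  log <- tibble::tibble(
    attempt = c(1, 1, 2, 2, 3),
    step = c(10, 10, 20, 20, 30),
    i = c(0L, 2L, 1L, 0L, 0L),
    j = c(1L, 3L, 2L, 1L, 1L),
    delta_u = 0,
    accepted = c(TRUE, FALSE, TRUE, TRUE, FALSE)
  )
  md <- mixing_diagnostics(log)
  r01 <- md$pair_rates[md$pair_rates$i == 0 & md$pair_rates$j == 1, ]
  expect_equal(r01$rate, 2 / 3)
  expect_equal(r01$attempts, 3L)
  r23 <- md$pair_rates[md$pair_rates$i == 2 & md$pair_rates$j == 3, ]
  expect_equal(r23$rate, 0)
  expect_true(is.na(md$round_trips)) # bare log: walker trace unknown
  expect_error(mixing_diagnostics(log[0, ]), "empty")
  # all-accepted log has rate 1 everywhere
  log2 <- log
  log2$accepted <- TRUE
  expect_true(all(mixing_diagnostics(log2)$pair_rates$rate == 1))
  # walker trace with a known single round trip (2 replicas)
  fake_run <- structure(
    list(
      exchange_log = log2,
      walker_trace = matrix(
        c(
          1L, 2L, # walker 1 at bottom
          2L, 1L, # swapped: walker 1 on top
          1L, 2L, # back down: one round trip
          1L, 2L
        ),
        ncol = 2, byrow = TRUE
      )
    ),
    class = "hremd_run"
  )
  expect_equal(mixing_diagnostics(fake_run)$round_trips, 1L)
})
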