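# Coarse-grained energy model: electrostatics, extensivity, sign
# preferences, minimization and the Bjerrum utility.

test_that("Bjerrum length matches the defining closed form", {
  # through water: ~7 Angstrom
  expect_equal(bjerrum_length(80, 300), 7.0, tolerance = 0.01)
  # through a peptide assembly dielectric: ~37 Angstrom
  expect_equal(bjerrum_length(15, 300), 37.1, tolerance = 0.01)
  # limit: infinite dielectric screens everything
  expect_lt(bjerrum_length(1e9, 300), 1e-3)
  expect_error(bjerrum_length(-1, 300), "> 0")
  expect_error(bjerrum_length(80, 0), "> 0")
})

test_that("two opposite unit charges at the Bjerrum length interact at -kBT", {
  eps <- 80
  temp <- 300
  lb <- bjerrum_length(eps, temp)
  beads <- tibble::tibble(
    peptide = c(1L, 2L), res_id = 1L, bead = "BB",
    x = c(0, lb), y = 0, z = 0, charge = c(1, -1)
  )
  m <- energy_model(
    eps_r = eps, debye_len = Inf, cutoff = 100,
    e_hb = 0, e_pack = 0, e_same = 0, k_rep = 0, solv_gamma = 0
  )
  rep <- total_energy(beads, m)
  kbt <- 0.0019872041 * temp
  expect_equal(unname(rep$terms["electrostatic"]), -kbt, tolerance = 1e-4)
})

test_that("energies are extensive and terms sum to the total", {
  s <- build_extended_strand("ILQINS")
  far <- s
  far$x <- far$x + 300
  far$peptide <- 2L
  both <- dplyr::bind_rows(s, far)
  class(both) <- class(s)
  m <- energy_model()
  r1 <- total_energy(s, m)
  r2 <- total_energy(both, m)
  expect_equal(r2$total, 2 * r1$total, tolerance = 1e-9)
  expect_equal(sum(r2$terms), r2$total, tolerance = 1e-8 * max(1, abs(r2$total)))
  expect_equal(nrow(r2$per_peptide), 2)
  expect_equal(sum(r2$per_peptide$energy), r2$total, tolerance = 1e-8)
})

test_that("energy is invariant under rigid motion", {
  dimer <- make_ideal_assembly("ILQINS", 5, dimer_geometry())
  m <- energy_model()
  e0 <- total_energy(dimer, m)$total
  e1 <- total_energy(rigid_motion(dimer), m)$total
  expect_equal(e1, e0, tolerance = 1e-9)
})

test_that("missing charges are rejected", {
  s <- build_extended_strand("AA")
  s$charge <- NULL
  expect_error(total_energy(s), "charge")
})

test_that("AP dimer electrostatics beats P, matching the 4-charge oracle", {
  m <- energy_model(cutoff = 100)
  e_p <- total_energy(make_ideal_assembly("ILQINS", 1, dimer_geometry()), m)
  e_ap <- total_energy(make_ideal_assembly("ILQINS", 5, dimer_geometry()), m)
  expect_lt(
    e_ap$terms[["electrostatic"]],
    e_p$terms[["electrostatic"]]
  )
  # oracle: direct screened-Coulomb sum over the four terminal charges
  oracle_elec <- function(frame) {
    beads <- coarse_grain(frame)
    ch <- beads[beads$charge != 0, ]
    tot <- 0
    for (i in seq_len(nrow(ch) - 1)) {
      for (j in seq(i + 1, nrow(ch))) {
        if (ch$peptide[i] == ch$peptide[j]) next
        r <- sqrt(sum((as.numeric(ch[i, c("x", "y", "z")]) -
          as.numeric(ch[j, c("x", "y", "z")]))^2))
        tot <- tot + 332.0637 * ch$charge[i] * ch$charge[j] *
          exp(-r / 7) / (80 * r)
      }
    }
    tot
  }
  expect_equal(e_p$terms[["electrostatic"]],
    oracle_elec(make_ideal_assembly("ILQINS", 1, dimer_geometry())),
    tolerance = 1e-6
  )
  expect_equal(e_ap$terms[["electrostatic"]],
    oracle_elec(make_ideal_assembly("ILQINS", 5, dimer_geometry())),
    tolerance = 1e-6
  )
})

test_that("zipper-interface packing favors the parallel arrangement", {
  m <- energy_model()
  pack <- function(cl) {
    z <- make_ideal_assembly("ILQINS", cl, zipper_n(6))
    a <- cut_block(z, c(1, 1, 6))
    b <- cut_block(z, c(1, 1, 6), origin = c(0, 1, 0))
    total_energy(z, m)$terms[["packing"]] -
      total_energy(a, m)$terms[["packing"]] -
      total_energy(b, m)$terms[["packing"]]
  }
  expect_lt(pack(1), pack(5))
})

test_that("the minimizer descends and converges on a quadratic bond potential", {
  # two bonded beads stretched past equilibrium: analytic minimum at r0
  beads <- tibble::tibble(
    peptide = 1L, res_id = c(1L, 2L), bead = "BB",
    x = c(0, 6), y = 0, z = 0, charge = 0
  )
  m <- interactions_off(energy_model())
  out <- minimize_configuration(beads, m, tolerance = 1e-5)
  expect_true(out$converged)
  d <- sqrt(sum((as.numeric(out$beads[2, c("x", "y", "z")]) -
    as.numeric(out$beads[1, c("x", "y", "z")]))^2))
  expect_equal(d, 3.80, tolerance = 1e-4)
  expect_equal(out$report$total, 0, tolerance = 1e-8)
  expect_lte(out$report$total, out$initial_energy)
})

test_that("minimization never increases the energy of a perturbed dimer", {
  dimer <- make_ideal_assembly("ILQINS", 5, dimer_geometry())
  set.seed(2)
  noisy <- dimer
  noisy$x <- noisy$x + rnorm(nrow(noisy), sd = 0.15)
  m <- energy_model()
  for (mode in c("cartesian", "rigid")) {
    out <- minimize_configuration(noisy, m, max_iterations = 60, mode = mode)
    expect_lte(out$report$total, out$initial_energy)
  }
})

test_that("an already-relaxed configuration stays put", {
  beads <- tibble::tibble(
    peptide = 1L, res_id = c(1L, 2L), bead = "BB",
    x = c(0, 3.80), y = 0, z = 0, charge = 0
  )
  m <- interactions_off(energy_model())
  out <- minimize_configuration(beads, m, tolerance = 1e-6)
  expect_equal(as.matrix(out$beads[, c("x", "y", "z")]),
    as.matrix(beads[, c("x", "y", "z")]),
    tolerance = 1e-6, ignore_attr = TRUE
  )
})

test_that("effective concentration of 64 peptides in a 50 A sphere is 0.2 M", {
  expect_equal(effective_concentration(64, 50), 0.2, tolerance = 0.02)
  expect_error(effective_concentration(0, 50), "positive")
})

test_that("tidy and glance methods summarise energy reports", {
  rep <- total_energy(make_ideal_assembly("ILQINS", 1, dimer_geometry()))
  td <- tidy(rep)
  expect_s3_class(td, "tbl_df")
  expect_true(all(c("bonded", "electrostatic", "hbond") %in% td$term))
  expect_equal(glance(rep)$total, rep$total)
})
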