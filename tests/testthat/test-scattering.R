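# Debye scattering, contrast form factors, Guinier fits, peak finding and
# profile comparison.

test_that("a single atom in vacuum scatters as f(q)^2", {
  atoms <- tibble::tibble(element = "C", x = 0, y = 0, z = 0)
  q <- seq(0.05, 1.5, by = 0.05)
  prof <- debye_profile(atoms, q)
  expect_equal(prof$intensity, contrast_form_factor("C", q, 0)^2, tolerance = 1e-12)
})

test_that("two identical point scatterers match the closed form to 1e-10", {
  d <- 7.3
  atoms <- tibble::tibble(element = "N", x = c(0, d), y = 0, z = 0)
  q <- seq(0.02, 2, by = 0.02)
  prof <- debye_profile(atoms, q, method = "direct")
  f <- contrast_form_factor("N", q, 0)
  expect_equal(prof$intensity, oracle_two_point(f, q, d), tolerance = 1e-10)
})

test_that("the Debye sum is invariant under rigid motion to 1e-10 relative", {
  set.seed(42)
  atoms <- tibble::tibble(
    element = sample(c("C", "N", "O"), 30, replace = TRUE),
    x = rnorm(30, sd = 5), y = rnorm(30, sd = 5), z = rnorm(30, sd = 5)
  )
  q <- seq(0.05, 1.2, by = 0.05)
  p0 <- debye_profile(atoms, q)
  p1 <- debye_profile(rigid_motion(atoms), q)
  expect_equal(p1$intensity, p0$intensity, tolerance = 1e-10)
})

test_that("I(q -> 0) equals the squared total contrast", {
  set.seed(7)
  atoms <- tibble::tibble(
    element = sample(c("C", "N", "O", "H"), 25, replace = TRUE),
    x = rnorm(25, sd = 4), y = rnorm(25, sd = 4), z = rnorm(25, sd = 4)
  )
  for (rho in c(0, 0.334)) {
    prof <- debye_profile(atoms, c(1e-6, 0.1), solvent_density = rho)
    f0 <- sum(vapply(atoms$element, contrast_form_factor, 1, q = 0, solvent_density = rho))
    expect_equal(prof$intensity[1], f0^2, tolerance = 1e-6)
  }
})

test_that("contrast form factors follow the dummy-atom convention", {
  q <- seq(0, 1, by = 0.1)
  # vacuum: contrast equals the Cromer-Mann factor
  expect_equal(contrast_form_factor("O", q, 0), contrast_form_factor("O", q))
  # carbon at q = 0 under water contrast: f(0) - rho * V_C
  f0 <- contrast_form_factor("C", 0, 0)
  expect_equal(contrast_form_factor("C", 0, 0.334), f0 - 0.334 * 16.44,
    tolerance = 1e-9
  )
  # hydrogen contrast magnitude is reduced under water contrast
  expect_lt(
    abs(contrast_form_factor("H", 0, 0.334)),
    contrast_form_factor("H", 0, 0)
  )
  expect_error(contrast_form_factor("Xx", 0.1, 0), "form factor")
  expect_error(debye_profile(tibble::tibble(element = "C", x = 0, y = 0, z = 0), 0.1, -1), ">= 0")
})

test_that("binned and direct Debye paths agree within 0.5 percent", {
  blk <- build_extended_strand("ILQINS") |>
    make_unit_cell(1) |>
    build_block(2, 2, 4)
  q <- seq(0.1, 1.5, by = 0.01)
  pd <- debye_profile(blk, q, method = "direct")
  pb <- debye_profile(blk, q, method = "binned")
  expect_lt(max(abs(pb$intensity - pd$intensity) / pd$intensity), 0.005)
  # and with solvent contrast on
  pd2 <- debye_profile(blk, q, solvent_density = 0.334, method = "direct")
  pb2 <- debye_profile(blk, q, solvent_density = 0.334, method = "binned")
  expect_lt(max(abs(pb2$intensity - pd2$intensity) / pmax(pd2$intensity, 1)), 0.005)
})

test_that("Guinier analysis recovers sphere and point radii", {
  q <- seq(0.005, 0.1, by = 0.001)
  radius <- 20
  prof <- scattering_profile(q, 1e6 * oracle_sphere_profile(q, radius))
  fit <- guinier_rg(prof, q_rg_max = 0.8)
  expect_equal(fit$rg, sqrt(3 / 5) * radius, tolerance = 0.01)
  expect_equal(fit$i0, 1e6, tolerance = 0.01)
  # a point scatterer (flat intensity) has Rg ~ 0
  pt <- scattering_profile(q, rep(100, length(q)))
  expect_lt(guinier_rg(pt)$rg, 0.1)
  expect_s3_class(glance(fit), "tbl_df")
})

test_that("Guinier Rg of a rod ensemble matches the coordinate second moment", {
  # rod of point carbons along z
  n <- 21
  atoms <- tibble::tibble(element = "C", x = 0, y = 0, z = seq(-25, 25, length.out = n))
  m <- as.matrix(atoms[, c("x", "y", "z")])
  rg_direct <- sqrt(mean(rowSums(sweep(m, 2, colMeans(m))^2)))
  q <- seq(0.002, 0.05, by = 0.001)
  fit <- guinier_rg(debye_profile(atoms, q), q_rg_max = 1.0)
  expect_equal(fit$rg, rg_direct, tolerance = 0.03)
})

test_that("peak finding reports d = 2 pi / q and ignores monotone profiles", {
  q <- seq(0.1, 1, by = 0.01)
  mono <- scattering_profile(q, exp(-q))
  expect_equal(nrow(find_peaks(mono)), 0)
  # empty q range is an empty list, not an error
  pk <- find_peaks(mono, c(2, 3))
  expect_equal(nrow(pk), 0)
  lat <- point_lattice(c(10, 10, 10), c(6, 6, 6))
  prof <- debye_profile(lat, seq(0.4, 0.9, by = 0.002), method = "binned")
  pk <- find_peaks(prof, c(0.5, 0.8))
  expect_gt(nrow(pk), 0)
  top <- pk[which.max(pk$prominence), ]
  expect_equal(top$q_peak, 2 * pi / 10, tolerance = 0.01)
  expect_equal(top$d_spacing * top$q_peak, 2 * pi, tolerance = 1e-12)
  expect_true(all(diff(pk$q_peak) > 0))
})

test_that("profile comparison fits scale and reports chi-square per point", {
  q <- seq(0.1, 1, by = 0.01)
  base <- scattering_profile(q, 100 * exp(-q) + 5)
  expect_equal(compare_profiles(base, base)$chi2_reduced, 0, tolerance = 1e-12)
  doubled <- scattering_profile(q, 2 * base$intensity)
  cmp <- compare_profiles(base, doubled)
  expect_equal(cmp$chi2_reduced, 0, tolerance = 1e-12)
  expect_equal(cmp$scale, 2, tolerance = 1e-12)
  # known noise -> reduced chi2 near 1
  set.seed(99)
  sig <- 0.05 * base$intensity
  noisy <- scattering_profile(q, base$intensity + rnorm(length(q), sd = sig), sigma = sig)
  chi2 <- compare_profiles(base, noisy)$chi2_reduced
  expect_gt(chi2, 0.5)
  expect_lt(chi2, 1.6)
  shifted <- scattering_profile(q + 10, base$intensity)
  expect_error(compare_profiles(base, shifted), "disjoint")
})

test_that("scattering profiles round-trip through 3-column dat files", {
  q <- seq(0.1, 0.5, by = 0.01)
  prof <- scattering_profile(q, exp(-q) * 100, sigma = rep(1, length(q)))
  f <- tempfile(fileext = ".dat")
  write_profile(prof, f)
  back <- read_profile(f)
  expect_equal(back$q, prof$q, tolerance = 1e-9)
  expect_equal(back$intensity, prof$intensity, tolerance = 1e-9)
  expect_equal(back$sigma, prof$sigma, tolerance = 1e-9)
  unlink(f)
})

test_that("profile validation enforces the q-grid and intensity invariants", {
  expect_error(scattering_profile(c(0.2, 0.1), c(1, 1)), "increasing")
  expect_error(scattering_profile(c(0.1, 0.2), c(1, NA)), "finite")
  expect_error(debye_profile(tibble::tibble(element = character(0), x = numeric(0), y = numeric(0), z = numeric(0)), 0.1), "at least one atom")
})
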