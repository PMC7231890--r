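# Backbone hydrogen bonds, strand directions, P/AP classification and
# time-series observables.

ap_sheet <- function(n = 2) make_ideal_assembly("ILQINS", 5, sheet_n(n))
p_sheet <- function(n = 2) make_ideal_assembly("ILQINS", 1, sheet_n(n))

# brute-force oracle: every donor H against every acceptor O over all
# peptide pairs, same geometric criterion
oracle_hbond_count <- function(frame, dcut = 2.5, acut = 135) {
  count <- 0
  peps <- unique(frame$peptide)
  for (pi in peps) {
    don <- frame[frame$peptide == pi, ]
    for (pj in setdiff(peps, pi)) {
      acc <- frame[frame$peptide == pj & frame$atom %in% c("O", "OXT"), ]
      for (r in unique(don$res_id)) {
        h <- don[don$res_id == r & don$atom == "H", ]
        n <- don[don$res_id == r & don$atom == "N", ]
        if (nrow(h) == 0) next
        for (k in seq_len(nrow(acc))) {
          hv <- as.numeric(h[1, c("x", "y", "z")])
          nv <- as.numeric(n[1, c("x", "y", "z")])
          ov <- as.numeric(acc[k, c("x", "y", "z")])
          dist <- sqrt(sum((hv - ov)^2))
          ang <- oracle_angle(nv, hv, ov)
          if (dist < dcut && ang > acut) count <- count + 1
        }
      }
    }
  }
  count
}

test_that("an isolated peptide has no inter-strand hydrogen bonds", {
  s <- build_extended_strand("ILQINS")
  expect_equal(nrow(detect_backbone_hbonds(s)), 0)
})

test_that("dimer hydrogen bonds match the brute-force pair enumeration", {
  for (frame in list(ap_sheet(2), p_sheet(2))) {
    hb <- detect_backbone_hbonds(frame)
    expect_equal(nrow(hb), oracle_hbond_count(frame))
    expect_gt(nrow(hb), 0) # the ideal dimers do hydrogen-bond
    expect_true(all(hb$donor_peptide != hb$acceptor_peptide))
    expect_true(all(hb$distance < 2.5))
    expect_true(all(hb$angle > 135))
  }
})

test_that("an n-strand ideal sheet has (n-1) interfaces worth of bonds", {
  per_interface <- nrow(detect_backbone_hbonds(p_sheet(2)))
  for (n in c(3, 5)) {
    expect_equal(nrow(detect_backbone_hbonds(p_sheet(n))), (n - 1) * per_interface)
  }
})

test_that("missing amide hydrogens are rejected with guidance", {
  s <- dplyr::filter(build_extended_strand("ILQINS"), atom != "H")
  expect_error(detect_backbone_hbonds(s), "amide hydrogens")
})

test_that("strand direction is the signed N-to-C principal axis", {
  s <- build_extended_strand("ILQINS")
  d <- strand_direction(s)
  expect_equal(sqrt(sum(d^2)), 1, tolerance = 1e-9)
  expect_gt(d[1], 0.99) # built along +x
  # reversing residue order negates the direction
  rev <- s
  rev$res_id <- max(rev$res_id) + 1L - rev$res_id
  expect_equal(strand_direction(rev), -d, tolerance = 1e-9)
  # bent strand: axis matches the leading singular vector of the CA cloud
  bent <- s
  bent$z <- bent$z + 0.3 * (bent$x)^2 / 10
  ca <- as.matrix(dplyr::filter(bent, atom == "CA")[, c("x", "y", "z")])
  sv <- svd(sweep(ca, 2, colMeans(ca)))$v[, 1]
  if (sum(sv * (ca[6, ] - ca[1, ])) < 0) sv <- -sv
  expect_equal(strand_direction(bent), unname(sv), tolerance = 1e-9)
  expect_error(strand_direction(s[s$atom == "N", ]), "at least 2")
})

test_that("pairing classification thresholds and unit-norm checks hold", {
  expect_equal(classify_pairing(c(1, 0, 0), c(1, 0, 0)), "P")
  expect_equal(classify_pairing(c(1, 0, 0), c(-1, 0, 0)), "AP")
  expect_equal(classify_pairing(c(1, 0, 0), c(0, 1, 0)), "unclassified")
  v <- c(1, 1, 0) / sqrt(2)
  expect_equal(classify_pairing(c(1, 0, 0), v, threshold = 0.5), "P")
  expect_error(classify_pairing(c(2, 0, 0), c(1, 0, 0)), "unit")
})

test_that("a static ideal AP sheet gives constant N_AP and zero N_P", {
  traj <- synth_trajectory(ap_sheet(3), 5, sigma = 0, seed = 3)
  ser <- hbond_series(traj)
  expect_true(all(ser$n_p == 0))
  expect_equal(length(unique(ser$n_ap)), 1)
  expect_gt(ser$n_ap[1], 0)
})

test_that("reversing one strand flips its pairing labels", {
  frame <- p_sheet(2)
  hb0 <- detect_backbone_hbonds(frame)
  expect_true(all(hb0$pairing == "P"))
  flipped <- frame
  sel <- flipped$peptide == 2
  # reverse the strand in place: 180 degree rotation about its own b axis
  sub <- flipped[sel, ]
  cen <- colMeans(as.matrix(sub[, c("x", "y", "z")]))
  m <- sweep(as.matrix(sub[, c("x", "y", "z")]), 2, cen)
  m <- m %*% diag(c(-1, 1, -1))
  flipped[sel, c("x", "y", "z")] <- as.data.frame(sweep(m, 2, cen, "+"))
  hb1 <- detect_backbone_hbonds(flipped, dist_cutoff = 3.5, angle_cutoff = 90)
  expect_true(all(hb1$pairing == "AP"))
})

test_that("bond counts are invariant under global rigid motion", {
  frame <- ap_sheet(3)
  hb0 <- detect_backbone_hbonds(frame)
  hb1 <- detect_backbone_hbonds(rigid_motion(frame))
  expect_equal(nrow(hb1), nrow(hb0))
  expect_equal(hb1$pairing, hb0$pairing)
})

test_that("progressive disorder gives non-increasing smoothed bond counts", {
  traj <- synth_trajectory(p_sheet(3), 30,
    sigma = 0.12, seed = 11,
    decay_rate = 1.5
  )
  ser <- hbond_series(traj, window_ns = 0.08)
  sm <- ser$n_p_smooth
  # smoothed trend declines from the first to the last quarter
  expect_lt(mean(tail(sm, 7)), mean(head(sm, 7)))
  expect_equal(nrow(ser), 30)
  expect_true(all(ser$n_p >= 0))
  expect_true(all(ser$n_p + ser$n_ap >= ser$n_p))
})

test_that("moving averages match the brute-force windowed mean", {
  set.seed(5)
  x <- rpois(40, 10)
  t <- (seq_along(x) - 1) * 0.1
  got <- moving_average(x, 0.5, time = t)
  want <- vapply(seq_along(x), function(i) {
    mean(x[t >= t[i] - 0.25 & t <= t[i] + 0.25])
  }, numeric(1))
  expect_equal(got, want)
  # constant series unchanged, impulse mass conserved
  expect_equal(moving_average(rep(3, 10), 2), rep(3, 10))
  imp <- c(rep(0, 5), 9, rep(0, 5))
  sm <- moving_average(imp, 3)
  expect_equal(length(sm), length(imp))
  expect_gt(max(sm), 0)
  expect_lt(max(sm), 9)
  expect_error(moving_average(x, 0), "positive")
})

test_that("an arrested endpoint-like state counts AP bonds far above P", {
  # a large AP sheet coexisting with one stray P dimer, mimicking the
  # late-aggregation regime where antiparallel sheets dominate
  ap <- make_ideal_assembly("ILQINS", 5, sheet_n(12))
  p2 <- make_ideal_assembly("ILQINS", 1, sheet_n(2))
  p2$x <- p2$x + 120
  p2$peptide <- p2$peptide + max(ap$peptide)
  state <- dplyr::bind_rows(ap, p2)
  class(state) <- class(ap)
  ser <- hbond_series(list(state))
  expect_gt(ser$n_ap, 10 * ser$n_p)
  expect_gt(ser$n_p, 0)
})

test_that("topology mismatch across frames is rejected", {
  a <- ap_sheet(2)
  b <- ap_sheet(3)
  expect_error(hbond_series(list(a, b)), "mismatch")
})
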