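# Backbone hydrogen-bond detection and parallel/antiparallel strand
# pairing over single frames and trajectories.

#' Detect inter-strand backbone hydrogen bonds
#'
#' A hydrogen bond is recorded for every donor (backbone N-H) / acceptor
#' (backbone carbonyl O, including OXT) pair on different peptides with
#' H...O distance below `dist_cutoff` and N-H...O angle above
#' `angle_cutoff`. Results are ordered deterministically by donor peptide,
#' donor residue, acceptor peptide, acceptor residue.
#'
#' @param frame A `zipper_atoms` table with backbone N, H, CA, C, O atoms.
#' @param dist_cutoff H...O distance cutoff, Angstrom (default 2.5).
#' @param angle_cutoff N-H...O angle cutoff, degrees (default 135).
#' @return A tibble with donor/acceptor identifiers, `distance`, `angle`
#'   and `pairing` (P / AP / unclassified from the two strands' direction
#'   vectors; `intra` never appears since intra-strand pairs are excluded).
#' @export
detect_backbone_hbonds <- function(frame, dist_cutoff = 2.5, angle_cutoff = 135) {
  don_n <- frame %>% filter(.data$atom == "N")
  don_h <- frame %>% filter(.data$atom == "H")
  acc <- frame %>% filter(.data$atom %in% c("O", "OXT"))
  if (nrow(don_h) == 0) {
    abort("no amide hydrogens in frame: add them (e.g. rebuild with build_extended_strand)")
  }
  don <- don_n %>%
    dplyr::inner_join(don_h, by = c("peptide", "res_id"), suffix = c("_n", "_h"))
  if (nrow(don) == 0 || nrow(acc) == 0) {
    return(empty_hbonds())
  }
  hx <- as.matrix(don[, c("x_h", "y_h", "z_h")])
  nx <- as.matrix(don[, c("x_n", "y_n", "z_n")])
  ax <- as.matrix(acc[, c("x", "y", "z")])
  d2 <- outer(rowSums(hx^2), rep(1, nrow(ax))) +
    outer(rep(1, nrow(hx)), rowSums(ax^2)) - 2 * hx %*% t(ax)
  d2[d2 < 0] <- 0
  hits <- which(sqrt(d2) < dist_cutoff, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(empty_hbonds())
  }
  di <- hits[, 1]
  ai <- hits[, 2]
  keep <- don$peptide[di] != acc$peptide[ai]
  di <- di[keep]
  ai <- ai[keep]
  if (length(di) == 0) {
    return(empty_hbonds())
  }
  hn <- nx[di, , drop = FALSE] - hx[di, , drop = FALSE]
  ho <- ax[ai, , drop = FALSE] - hx[di, , drop = FALSE]
  cosang <- rowSums(hn * ho) /
    (sqrt(rowSums(hn^2)) * sqrt(rowSums(ho^2)))
  ang <- acos(pmax(-1, pmin(1, cosang))) * 180 / pi
  keep2 <- ang > angle_cutoff
  di <- di[keep2]
  ai <- ai[keep2]
  ang <- ang[keep2]
  if (length(di) == 0) {
    return(empty_hbonds())
  }
  dirs <- strand_directions(frame)
  pair_lab <- vapply(seq_along(di), function(k) {
    classify_pairing(
      dirs[[as.character(don$peptide[di[k]])]],
      dirs[[as.character(acc$peptide[ai[k]])]]
    )
  }, character(1))
  out <- tibble(
    donor_peptide = don$peptide[di],
    donor_res = don$res_id[di],
    acceptor_peptide = acc$peptide[ai],
    acceptor_res = acc$res_id[ai],
    distance = sqrt(d2[cbind(di, ai)]),
    angle = ang,
    pairing = pair_lab
  ) %>%
    arrange(
      .data$donor_peptide, .data$donor_res,
      .data$acceptor_peptide, .data$acceptor_res
    )
  out
}

empty_hbonds <- function() {
  tibble(
    donor_peptide = integer(0), donor_res = integer(0),
    acceptor_peptide = integer(0), acceptor_res = integer(0),
    distance = numeric(0), angle = numeric(0), pairing = character(0)
  )
}

#' Signed direction vector of a strand
#'
#' Principal axis through the Calpha (or backbone-bead) positions, signed
#' from the N to the C terminus, unit norm.
#'
#' @param peptide_atoms Atom or bead rows of a single peptide.
#' @return Unit numeric 3-vector.
#' @export
strand_direction <- function(peptide_atoms) {
  ca <- if ("atom" %in% names(peptide_atoms)) {
    peptide_atoms[peptide_atoms$atom == "CA", ]
  } else if ("bead" %in% names(peptide_atoms)) {
    peptide_atoms[peptide_atoms$bead == "BB", ]
  } else {
    abort("need an `atom` or `bead` column")
  }
  ca <- ca[order(ca$res_id), ]
  if (nrow(ca) < 2) abort("strand_direction needs at least 2 Calpha positions")
  m <- as.matrix(ca[, c("x", "y", "z")])
  m0 <- sweep(m, 2, colMeans(m))
  v <- svd(m0)$v[, 1]
  if (sum(v * (m[nrow(m), ] - m[1, ])) < 0) v <- -v
  unname(v)
}

strand_directions <- function(frame) {
  peps <- unique(frame$peptide)
  out <- lapply(peps, function(p) strand_direction(frame[frame$peptide == p, ]))
  names(out) <- as.character(peps)
  out
}

#' Classify a strand pairing as parallel or antiparallel
#'
#' @param dir_i,dir_j Unit direction vectors.
#' @param threshold Dot-product threshold (default 0.5): `>= threshold` is
#'   P, `<= -threshold` is AP, otherwise unclassified.
#' @return One of `"P"`, `"AP"`, `"unclassified"`.
#' @examples
#' classify_pairing(c(1, 0, 0), c(-1, 0, 0))
#' @export
classify_pairing <- function(dir_i, dir_j, threshold = 0.5) {
  for (v in list(dir_i, dir_j)) {
    if (abs(vnorm(v) - 1) > 1e-6) {
      abort("direction vectors must be unit norm (not normalized silently)")
    }
  }
  d <- sum(dir_i * dir_j)
  if (d >= threshold) "P" else if (d <= -threshold) "AP" else "unclassified"
}

#' Parallel/antiparallel hydrogen-bond time series over a trajectory
#'
#' Runs hydrogen-bond detection and strand-pairing classification on every
#' frame. For atomic frames the geometric N-H...O criterion is used; for
#' coarse-grained bead frames (no amide hydrogens) a backbone-bead contact
#' criterion (BB-BB distance within `bead_contact` Angstrom between
#' different peptides) is the hydrogen-bond surrogate. A bond inherits the
#' P/AP classification of its two strands; bonds between unclassified
#' pairs are excluded from both counts.
#'
#' @param trajectory A `zipper_trajectory` (see [synth_trajectory()]) or a
#'   list of frames.
#' @param dist_cutoff,angle_cutoff Atomic hydrogen-bond criterion.
#' @param bead_contact Contact distance for bead frames (default 5.5).
#' @param window_ns Optional moving-average window (ns); adds smoothed
#'   columns.
#' @return A tibble of class `hbond_series` with `time_ns`, `n_p`, `n_ap`
#'   (and `n_p_smooth`, `n_ap_smooth` when `window_ns` is given).
#' @export
hbond_series <- function(trajectory, dist_cutoff = 2.5, angle_cutoff = 135,
                         bead_contact = 5.5, window_ns = NULL) {
  frames <- if (inherits(trajectory, "zipper_trajectory")) trajectory$frames else trajectory
  times <- if (inherits(trajectory, "zipper_trajectory")) {
    trajectory$time_ns
  } else {
    seq_along(frames) - 1
  }
  if (length(frames) == 0) abort("trajectory has no frames")
  sig <- function(f) paste(n_peptides(f), nrow(f))
  if (length(unique(vapply(frames, sig, character(1)))) != 1) {
    abort("topology mismatch across frames")
  }
  counts <- purrr::map(frames, function(f) {
    if ("atom" %in% names(f) && any(f$atom == "H")) {
      hb <- detect_backbone_hbonds(f, dist_cutoff, angle_cutoff)
      tibble(
        n_p = sum(hb$pairing == "P"),
        n_ap = sum(hb$pairing == "AP")
      )
    } else {
      bead_contact_counts(f, bead_contact)
    }
  }) %>% bind_rows()
  out <- tibble(time_ns = times, n_p = as.integer(counts$n_p), n_ap = as.integer(counts$n_ap))
  if (!is.null(window_ns)) {
    out$n_p_smooth <- moving_average(out$n_p, window_ns, time = out$time_ns)
    out$n_ap_smooth <- moving_average(out$n_ap, window_ns, time = out$time_ns)
  }
  structure(out, class = c("hbond_series", class(tibble())))
}

bead_contact_counts <- function(beads, bead_contact) {
  bb <- beads[beads$bead == "BB", ]
  m <- as.matrix(bb[, c("x", "y", "z")])
  d <- as.matrix(stats::dist(m))
  contact <- d < bead_contact &
    outer(bb$peptide, bb$peptide, "!=") &
    upper.tri(d)
  hits <- which(contact, arr.ind = TRUE)
  if (nrow(hits) == 0) {
    return(tibble(n_p = 0L, n_ap = 0L))
  }
  dirs <- strand_directions(bb)
  labs <- vapply(seq_len(nrow(hits)), function(k) {
    classify_pairing(
      dirs[[as.character(bb$peptide[hits[k, 1]])]],
      dirs[[as.character(bb$peptide[hits[k, 2]])]]
    )
  }, character(1))
  tibble(n_p = sum(labs == "P"), n_ap = sum(labs == "AP"))
}

#' Centered moving average with truncated edge windows
#'
#' @param series Numeric vector, or an `hbond_series` tibble (then both
#'   count columns are smoothed and the tibble is returned).
#' @param window Window length in the units of `time` (ns for trajectory
#'   series).
#' @param time Optional time grid; defaults to unit spacing.
#' @return Smoothed numeric vector (or tibble with `*_smooth` columns).
#' @export
moving_average <- function(series, window, time = NULL) {
  if (window <= 0) abort("window must be positive")
  if (inherits(series, "hbond_series")) {
    series$n_p_smooth <- moving_average(series$n_p, window, series$time_ns)
    series$n_ap_smooth <- moving_average(series$n_ap, window, series$time_ns)
    return(series)
  }
  x <- as.numeric(series)
  n <- length(x)
  t <- if (is.null(time)) seq_len(n) - 1 else as.numeric(time)
  half <- window / 2
  vapply(seq_len(n), function(i) {
    mean(x[t >= t[i] - half & t <= t[i] + half])
  }, numeric(1))
}

#' Plot parallel/antiparallel hydrogen-bond time series
#'
#' @param object An `hbond_series`.
#' @param ... Ignored.
#' @return A ggplot object; raw counts as thin lines, smoothed (if
#'   present) as thick lines.
#' @export
autoplot.hbond_series <- function(object, ...) {
  df <- as_tibble(object) %>%
    tidyr::pivot_longer(dplyr::starts_with("n_"),
      names_to = "which", values_to = "count"
    ) %>%
    mutate(
      pairing = ifelse(grepl("ap", .data$which), "AP", "P"),
      smoothed = grepl("smooth", .data$which)
    )
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$time_ns, y = .data$count,
    colour = .data$pairing, linewidth = .data$smoothed
  )) +
    ggplot2::geom_line() +
    ggplot2::scale_linewidth_manual(values = c(`FALSE` = 0.3, `TRUE` = 1.1)) +
    ggplot2::labs(x = "time (ns)", y = "hydrogen bonds")
}
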