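#' Recursive exponentially weighted moving average
#'
#' `s[1] = x[1]; s[t] = factor * x[t] + (1 - factor) * s[t-1]`. Used to
#' smooth groove-distance time series for display and threshold crossing.
#'
#' @param x Numeric vector.
#' @param factor Smoothing factor in (0, 1], default 0.1.
#' @return Numeric vector, same length as `x`.
#' @export
ewma <- function(x, factor = 0.1) {
  if (length(x) == 0) stop("ewma: empty series", call. = FALSE)
  s <- numeric(length(x))
  s[1] <- x[1]
  if (length(x) > 1) {
    for (t in 2:length(x)) s[t] <- factor * x[t] + (1 - factor) * s[t - 1]
  }
  s
}

min_cross_dist <- function(A, B) {
  # minimum Euclidean distance between two point sets (n x 3, m x 3)
  d2 <- outer(rowSums(A^2), rowSums(B^2), `+`) - 2 * (A %*% t(B))
  sqrt(max(0, min(d2)))
}

#' Per-frame minimum TM4-TM6 groove distance
#'
#' For every frame, the minimum Euclidean distance over all bead pairs (all
#' beads of each residue: side chain plus backbone; residues without side
#' chains contribute their backbone bead) between the TM4 and TM6 residue
#' sets, with a recursive EWMA-smoothed companion series.
#'
#' @param traj A [cg_trajectory()].
#' @param tm4,tm6 Residue number ranges (vectors) for the two helices, e.g.
#'   from [tm_groove_ranges()]. Defaults select by TM label instead.
#' @param chain Chain id (default `"A"`).
#' @param ewma_factor Smoothing factor (default 0.1).
#' @return Tibble with columns `time`, `distance`, `distance_smooth`,
#'   `chain`.
#' @export
groove_distance_series <- function(traj, tm4 = NULL, tm6 = NULL, chain = "A",
                                   ewma_factor = 0.1) {
  b4 <- if (is.null(tm4)) {
    residue_beads(traj$topology, tm = "TM4", chain = chain)
  } else {
    residue_beads(traj$topology, resid = tm4, chain = chain)
  }
  b6 <- if (is.null(tm6)) {
    residue_beads(traj$topology, tm = "TM6", chain = chain)
  } else {
    residue_beads(traj$topology, resid = tm6, chain = chain)
  }
  nf <- n_frames(traj)
  d <- numeric(nf)
  for (f in seq_len(nf)) {
    d[f] <- min_cross_dist(matrix(traj$coords[b4, , f], ncol = 3),
                           matrix(traj$coords[b6, , f], ncol = 3))
  }
  tibble::tibble(time = traj$times, distance = d,
                 distance_smooth = ewma(d, ewma_factor), chain = chain)
}

#' Groove/thickness scrambling-competence summary
#'
#' Summarizes a groove-distance series (median with Q1/Q3 quartiles of the
#' raw series, open fraction above the 6 A threshold) together with the
#' minimal membrane thickness, and assigns the competence quadrant: robust
#' scrambling requires thickness below `thickness_open` (14 A) and a median
#' groove distance above `groove_open` (6 A).
#'
#' @param groove Tibble from [groove_distance_series()].
#' @param surfaces A `leaflet_surfaces` object, or a precomputed thickness
#'   tibble from [min_thickness()], or a single numeric thickness (A).
#' @param groove_open Groove-open threshold (A, default 6).
#' @param thickness_open Thickness threshold (A, default 14).
#' @return One-row tibble: `median_distance`, `q1`, `q3`, `open_fraction`,
#'   `min_thickness`, `quadrant`.
#' @export
competence_summary <- function(groove, surfaces, groove_open = 6,
                               thickness_open = 14) {
  mt <- if (is.numeric(surfaces)) {
    surfaces
  } else if (inherits(surfaces, "leaflet_surfaces")) {
    min_thickness(surfaces)$min_thickness
  } else {
    surfaces$min_thickness
  }
  q <- stats::quantile(groove$distance, c(0.25, 0.5, 0.75), names = FALSE)
  open_frac <- mean(groove$distance > groove_open)
  open_groove <- q[2] > groove_open
  thin <- mt < thickness_open
  quadrant <- if (thin && open_groove) {
    "robust_scrambling"
  } else if (thin) {
    "thin_closed"
  } else if (open_groove) {
    "thick_open"
  } else {
    "thick_closed"
  }
  tibble::tibble(median_distance = q[2], q1 = q[1], q3 = q[3],
                 open_fraction = open_frac, min_thickness = mt,
                 quadrant = quadrant)
}

#' Per-frame dimer-cleft width
#'
#' Minimum inter-chain distance between a TM3 residue set on one chain and a
#' TM10 set on the other, restricted to beads below the membrane midplane
#' (the lower-leaflet cleft entrance). Frames where either set is empty
#' after the z restriction get `NA`.
#'
#' @param traj A [cg_trajectory()].
#' @param tm3,tm10 Residue ranges (`NULL` selects by TM label).
#' @param chain_a,chain_b Chains carrying TM3 and TM10 (defaults `"A"`,
#'   `"B"`).
#' @param midplane_z Membrane midplane (A, default 0; use the midpoint of
#'   the two leaflet surface means when available).
#' @return Tibble with columns `time`, `width`.
#' @export
dimer_cleft_width <- function(traj, tm3 = NULL, tm10 = NULL, chain_a = "A",
                              chain_b = "B", midplane_z = 0) {
  b3 <- if (is.null(tm3)) {
    residue_beads(traj$topology, tm = "TM3", chain = chain_a)
  } else {
    residue_beads(traj$topology, resid = tm3, chain = chain_a)
  }
  b10 <- if (is.null(tm10)) {
    residue_beads(traj$topology, tm = "TM10", chain = chain_b)
  } else {
    residue_beads(traj$topology, resid = tm10, chain = chain_b)
  }
  nf <- n_frames(traj)
  w <- rep(NA_real_, nf)
  for (f in seq_len(nf)) {
    A <- matrix(traj$coords[b3, , f], ncol = 3)
    B <- matrix(traj$coords[b10, , f], ncol = 3)
    A <- A[A[, 3] < midplane_z, , drop = FALSE]
    B <- B[B[, 3] < midplane_z, , drop = FALSE]
    if (nrow(A) == 0 || nrow(B) == 0) next
    w[f] <- min_cross_dist(A, B)
  }
  tibble::tibble(time = traj$times, width = w)
}
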