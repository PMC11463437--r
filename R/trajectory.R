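#' Build a coarse-grained trajectory
#'
#' A trajectory is an ordered set of frames of bead coordinates (Angstrom) at
#' strictly increasing, uniformly spaced times (ns), with per-frame
#' orthorhombic box lengths and a topology describing every bead. The
#' convention throughout the package is that production frames are written at
#' `t = dt, 2*dt, ...` so that "discard the first microsecond" removes exactly
#' the frames with `t <= 1000` ns.
#'
#' @param coords Numeric array of dimension `n_beads x 3 x n_frames`, or a
#'   list of `n_beads x 3` matrices (one per frame).
#' @param times Numeric vector of frame times in ns.
#' @param box Per-frame box lengths: either a length-3 vector (constant box)
#'   or an `n_frames x 3` matrix.
#' @param topology A [cg_topology()].
#'
#' @return An object of class `cg_trajectory` with elements `coords`, `times`,
#'   `box` and `topology`.
#' @export
cg_trajectory <- function(coords, times, box, topology) {
  if (is.list(coords)) {
    nb <- nrow(coords[[1]])
    coords <- array(unlist(coords, use.names = FALSE),
                    dim = c(nb, 3L, length(coords)))
  }
  stopifnot(is.array(coords), length(dim(coords)) == 3L, dim(coords)[2] == 3L)
  nf <- dim(coords)[3]
  if (length(times) != nf) {
    stop("format error: length(times) must equal the number of frames",
         call. = FALSE)
  }
  if (is.null(dim(box))) box <- matrix(box, nrow = nf, ncol = 3, byrow = TRUE)
  traj <- structure(
    list(coords = coords, times = as.numeric(times), box = box,
         topology = topology),
    class = "cg_trajectory"
  )
  validate_cg_trajectory(traj)
}

validate_cg_trajectory <- function(traj, time_tol = 1e-6) {
  if (dim(traj$coords)[1] != traj$topology$n_beads) {
    stop("format error: frame bead count (", dim(traj$coords)[1],
         ") does not match topology size (", traj$topology$n_beads, ")",
         call. = FALSE)
  }
  if (!all(is.finite(traj$coords))) {
    stop("format error: non-finite coordinates", call. = FALSE)
  }
  tt <- traj$times
  if (length(tt) > 1) {
    dt <- diff(tt)
    if (any(dt <= 0)) {
      stop("format error: times must be strictly increasing", call. = FALSE)
    }
    if (max(dt) - min(dt) > time_tol) {
      stop("format error: frame spacing must be uniform (tolerance 1e-6 ns)",
           call. = FALSE)
    }
  }
  traj
}

#' @export
print.cg_trajectory <- function(x, ...) {
  cat("<cg_trajectory> ", n_frames(x), " frames x ", n_beads(x), " beads, t = ",
      format(x$times[1]), "..", format(x$times[n_frames(x)]), " ns (dt = ",
      format(frame_dt(x)), " ns)\n", sep = "")
  print(x$topology)
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj A [cg_trajectory()].
#' @return Integer scalar.
#' @export
n_frames <- function(traj) dim(traj$coords)[3]

#' Number of beads in a trajectory
#' @param traj A [cg_trajectory()].
#' @return Integer scalar.
#' @export
n_beads <- function(traj) dim(traj$coords)[1]

#' Frame spacing in ns
#' @param traj A [cg_trajectory()].
#' @return Numeric scalar (spacing of the first frame pair; spacing is
#'   validated to be uniform).
#' @export
frame_dt <- function(traj) {
  if (n_frames(traj) < 2) return(NA_real_)
  traj$times[2] - traj$times[1]
}

#' Convert a time window to a frame count
#'
#' Window lengths stated in ns (100 ns smoothing, 1 us blocks, 6 ns gaps) are
#' converted to frame counts by rounding to the nearest integer.
#'
#' @param traj A [cg_trajectory()].
#' @param window_ns Window length in ns.
#' @return Integer number of frames (at least 1).
#' @export
frames_per_window <- function(traj, window_ns) {
  max(1L, as.integer(round(window_ns / frame_dt(traj))))
}

subset_frames <- function(traj, keep) {
  traj$coords <- traj$coords[, , keep, drop = FALSE]
  traj$times <- traj$times[keep]
  traj$box <- traj$box[keep, , drop = FALSE]
  traj
}

#' Discard the equilibration phase of a trajectory
#'
#' Removes all frames with `time <= cutoff_ns`. Times are preserved, not
#' re-zeroed, so downstream block edges stay aligned with production time.
#'
#' @param traj A [cg_trajectory()].
#' @param cutoff_ns Equilibration cutoff in ns (default 1000, i.e. the first
#'   microsecond).
#' @return A [cg_trajectory()] restricted to production frames.
#' @export
discard_equilibration <- function(traj, cutoff_ns = 1000) {
  keep <- traj$times > cutoff_ns
  if (!any(keep)) {
    stop("empty-trajectory error: equilibration cutoff (", cutoff_ns,
         " ns) removes every frame", call. = FALSE)
  }
  subset_frames(traj, which(keep))
}

#' Align one subunit to its starting coordinates (translation only)
#'
#' Each frame is rigidly translated so that the centroid of the chain's
#' backbone beads matches its centroid in the reference frame. All beads in
#' the frame are shifted identically; this is the alignment used before
#' density accumulation and contact analysis. Only backbone beads enter the
#' centroid (side-chain beads would bias it toward bulky residues); this is a
#' documented choice, see the methods vignette.
#'
#' @param traj A [cg_trajectory()].
#' @param chain Chain id of the subunit to align on.
#' @param ref_frame Reference frame index (default 1).
#' @return The translated [cg_trajectory()].
#' @export
align_subunit <- function(traj, chain, ref_frame = 1L) {
  stopifnot(ref_frame >= 1, ref_frame <= n_frames(traj))
  beads <- residue_beads(traj$topology, chain = chain, what = "backbone")
  ref <- colMeans(matrix(traj$coords[beads, , ref_frame], ncol = 3))
  for (f in seq_len(n_frames(traj))) {
    cen <- colMeans(matrix(traj$coords[beads, , f], ncol = 3))
    shift <- ref - cen
    traj$coords[, , f] <- sweep(traj$coords[, , f], 2L, shift, `+`)
  }
  traj
}

#' Rotate a trajectory so a helix pair's principal axis lies along y
#'
#' Computes, from the reference frame, the in-plane (xy) principal axis of the
#' selected backbone beads (by convention the TM7/TM8 helices) and applies the
#' single rotation about z that maps that axis onto the global y axis. The
#' same rotation, about the selection's reference-frame centroid, is applied
#' to every frame, so the alignment is an isometry per frame.
#'
#' @param traj A [cg_trajectory()].
#' @param resid Residue numbers of the alignment selection, or `NULL` to use
#'   all residues labelled `tm` below.
#' @param tm TM labels used when `resid` is `NULL` (default `c("TM7","TM8")`).
#' @param chain Optional chain restriction.
#' @param beads Optional explicit bead indices (overrides `resid`/`tm`).
#' @param ref_frame Reference frame index (default 1).
#' @return The rotated [cg_trajectory()].
#' @export
align_membrane_frame <- function(traj, resid = NULL, tm = c("TM7", "TM8"),
                                 chain = NULL, beads = NULL, ref_frame = 1L) {
  if (is.null(beads)) {
    beads <- residue_beads(traj$topology, resid = resid, chain = chain,
                           tm = if (is.null(resid)) tm else NULL,
                           what = "backbone")
  }
  xy <- matrix(traj$coords[beads, 1:2, ref_frame], ncol = 2)
  cen2 <- colMeans(xy)
  cc <- sweep(xy, 2L, cen2)
  cov2 <- crossprod(cc) / nrow(cc)
  ev <- eigen(cov2, symmetric = TRUE)
  if (ev$values[1] < 1e-12 || ev$values[2] / ev$values[1] > 1 - 1e-9) {
    stop("alignment error: selection is isotropic in xy; principal axis ",
         "undefined", call. = FALSE)
  }
  v <- ev$vectors[, 1]
  # canonical sign so the applied rotation is the minimal one
  if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) v <- -v
  phi <- pi / 2 - atan2(v[2], v[1])
  rot <- matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2, 2)
  for (f in seq_len(n_frames(traj))) {
    m <- traj$coords[, 1:2, f]
    m <- sweep(m, 2L, cen2)
    traj$coords[, 1:2, f] <- sweep(m %*% t(rot), 2L, cen2, `+`)
  }
  traj
}

#' Rigidly transform a trajectory (testing and symmetry checks)
#'
#' @param traj A [cg_trajectory()].
#' @param shift Length-3 translation (Angstrom) applied to every bead.
#' @param zrot Rotation angle about the z axis (radians) about the origin.
#' @param mirror_z If `TRUE`, negate all z coordinates.
#' @return The transformed [cg_trajectory()].
#' @export
transform_trajectory <- function(traj, shift = c(0, 0, 0), zrot = 0,
                                 mirror_z = FALSE) {
  rot <- matrix(c(cos(zrot), sin(zrot), -sin(zrot), cos(zrot)), 2, 2)
  for (f in seq_len(n_frames(traj))) {
    m <- traj$coords[, , f]
    if (zrot != 0) m[, 1:2] <- m[, 1:2] %*% t(rot)
    if (mirror_z) m[, 3] <- -m[, 3]
    traj$coords[, , f] <- sweep(m, 2L, shift, `+`)
  }
  traj
}
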