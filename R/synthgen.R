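#' Specification for a synthetic coarse-grained bilayer
#'
#' Describes a DOPC-like coarse-grained bilayer on a jittered lattice: two
#' leaflets of 6-bead lipids (NC3, PO4, GL1, GL2, C4A, C4B) whose glycerol
#' planes sit at `+/- d/2` (bulk glycerol-to-glycerol thickness `d`, default
#' 30 A), with the choline bead `head_offset` above the glycerol plane and
#' the terminal tail beads `tail_length` below it, pointing into the membrane
#' core. An optional `thickness_field` `h(x, y)` (A) locally reduces the
#' glycerol separation to `d - h(x, y)`, emulating protein-induced thinning.
#'
#' @param lipids_per_leaflet Number of lipids in each leaflet.
#' @param box_xy Lateral box lengths (A), length 2.
#' @param box_z Box height (A).
#' @param d Bulk glycerol-plane separation (A).
#' @param head_offset Choline height above the glycerol plane (A).
#' @param tail_length Terminal tail depth below the glycerol plane (A).
#' @param sigma Isotropic Gaussian positional noise per bead per frame (A).
#' @param wander Amplitude of the rigid lateral wander of each lipid around
#'   its lattice site (A, uniform per frame; the whole lipid translates, so
#'   orientation angles are unaffected). Defaults to the lattice cell size,
#'   which makes each leaflet cover the box; set 0 for frozen lipids.
#' @param thickness_field Optional function `h(x, y)` returning the local
#'   thinning (A); local separation is `d - h(x, y)`.
#' @param seed Random seed; identical spec + seed gives a bit-identical
#'   trajectory.
#' @return A list of class `bilayer_spec`.
#' @export
bilayer_spec <- function(lipids_per_leaflet = 64, box_xy = c(76, 76),
                         box_z = 120, d = 30, head_offset = 5,
                         tail_length = 12, sigma = 0.5, wander = NULL,
                         thickness_field = NULL, seed = 1L) {
  if (d <= 0) stop("spec error: d must be > 0", call. = FALSE)
  if (lipids_per_leaflet <= 0) {
    stop("spec error: lipids_per_leaflet must be > 0", call. = FALSE)
  }
  if (sigma < 0) stop("spec error: sigma must be >= 0", call. = FALSE)
  nx <- ceiling(sqrt(lipids_per_leaflet))
  if (min(box_xy) / nx < 6) {
    stop("spec error: lattice overflow - too many lipids for the box",
         call. = FALSE)
  }
  structure(list(lipids_per_leaflet = as.integer(lipids_per_leaflet),
                 box_xy = box_xy, box_z = box_z, d = d,
                 head_offset = head_offset, tail_length = tail_length,
                 sigma = sigma, wander = wander,
                 thickness_field = thickness_field,
                 seed = as.integer(seed)),
            class = "bilayer_spec")
}

# Bead offsets for a lipid pose: center C (glycerol midpoint, F x 3), unit
# head-to-tail axis V (F x 3). The lateral perpendicular is the global y axis
# (poses are parameterized in the xz plane), so the mean tail-minus-choline
# vector is exactly along V.
pose_beads <- function(C, V, head_offset, tail_length) {
  p <- matrix(rep(c(0, 1, 0), each = nrow(C)), ncol = 3)
  list(
    NC3 = C - head_offset * V,
    PO4 = C - 0.5 * head_offset * V,
    GL1 = C + 0.8 * p,
    GL2 = C - 0.8 * p,
    C4A = C + tail_length * V + 1.0 * p,
    C4B = C + tail_length * V - 1.0 * p
  )
}

#' Generate a synthetic bilayer trajectory
#'
#' Lipids are placed on a jittered square lattice per leaflet; upper-leaflet
#' lipids point their choline-to-tail vector toward -z (orientation angle
#' exactly 180 degrees at zero noise) and lower-leaflet lipids are mirrored.
#' Poses are static apart from per-bead Gaussian jitter; scripted dynamics
#' are layered on with [apply_flips()], [add_protein_scaffold()] and
#' [add_tracers()].
#'
#' @param spec A [bilayer_spec()].
#' @param n_frames Number of frames.
#' @param dt Frame spacing (ns); frames are written at `t = dt, 2*dt, ...`.
#' @return A [cg_trajectory()] carrying the spec and per-lipid lattice
#'   metadata as attributes.
#' @export
make_bilayer <- function(spec, n_frames, dt = 1) {
  n <- spec$lipids_per_leaflet
  nx <- ceiling(sqrt(n))
  ny <- ceiling(n / nx)
  sx <- spec$box_xy[1] / nx
  sy <- spec$box_xy[2] / ny
  set.seed(spec$seed)
  cell <- seq_len(n) - 1L
  base_xy <- cbind((cell %% nx + 0.5) * sx, (cell %/% nx + 0.5) * sy)
  jit_u <- matrix(stats::runif(2 * n, -0.5, 0.5), ncol = 2)
  jit_l <- matrix(stats::runif(2 * n, -0.5, 0.5), ncol = 2)
  # lower leaflet offset by half a cell so leaflets do not stack exactly
  xy_u <- base_xy + jit_u
  xy_l <- base_xy + jit_l + rep(c(sx / 2, sy / 2), each = n)
  xy_l[, 1] <- xy_l[, 1] %% spec$box_xy[1]
  xy_l[, 2] <- xy_l[, 2] %% spec$box_xy[2]

  sep_at <- function(xy) {
    if (is.null(spec$thickness_field)) {
      rep(spec$d, nrow(xy))
    } else {
      spec$d - spec$thickness_field(xy[, 1], xy[, 2])
    }
  }
  info <- tibble::tibble(
    lipid = seq_len(2L * n),
    x0 = c(xy_u[, 1], xy_l[, 1]),
    y0 = c(xy_u[, 2], xy_l[, 2]),
    sep = c(sep_at(xy_u), sep_at(xy_l)),
    leaflet = rep(c("upper", "lower"), each = n)
  )

  n_lip <- nrow(info)
  nb <- 6L * n_lip
  roles <- c("NC3", "PO4", "GL1", "GL2", "C4A", "C4B")
  lipids <- tibble::tibble(lipid = info$lipid)
  for (k in seq_along(roles)) {
    lipids[[roles[k]]] <- (info$lipid - 1L) * 6L + k
  }
  lipids$leaflet <- info$leaflet
  topo <- cg_topology(lipids = lipids, n_beads = nb)

  zsign <- ifelse(info$leaflet == "upper", 1, -1)
  vz <- -zsign                                 # head-to-tail z direction
  wander <- spec$wander %||% max(sx, sy)
  idx <- lapply(seq_along(roles), function(k) (seq_len(n_lip) - 1L) * 6L + k)
  coords <- array(NA_real_, dim = c(nb, 3L, n_frames))
  for (f in seq_len(n_frames)) {
    if (wander > 0) {
      off <- matrix(stats::runif(2L * n_lip, -wander / 2, wander / 2),
                    ncol = 2)
    } else {
      off <- matrix(0, n_lip, 2)
    }
    x <- (info$x0 + off[, 1]) %% spec$box_xy[1]
    y <- (info$y0 + off[, 2]) %% spec$box_xy[2]
    sep <- sep_at(cbind(x, y))
    cz <- zsign * sep / 2
    fr <- matrix(NA_real_, nb, 3)
    fr[idx[[1]], ] <- cbind(x, y, cz - spec$head_offset * vz)
    fr[idx[[2]], ] <- cbind(x, y, cz - 0.5 * spec$head_offset * vz)
    fr[idx[[3]], ] <- cbind(x, y + 0.8, cz)
    fr[idx[[4]], ] <- cbind(x, y - 0.8, cz)
    fr[idx[[5]], ] <- cbind(x, y + 1.0, cz + spec$tail_length * vz)
    fr[idx[[6]], ] <- cbind(x, y - 1.0, cz + spec$tail_length * vz)
    if (spec$sigma > 0) {
      fr <- fr + matrix(stats::rnorm(nb * 3L, 0, spec$sigma), nb, 3)
    }
    coords[, , f] <- fr
  }
  traj <- cg_trajectory(coords, times = seq_len(n_frames) * dt,
                        box = c(spec$box_xy, spec$box_z), topology = topo)
  attr(traj, "synth_spec") <- spec
  attr(traj, "synth_lipids") <- info
  traj
}

#' Script complete flips and partial excursions into a bilayer
#'
#' Scripted lipids move along a smooth three-dimensional path while their
#' choline-to-tail axis rotates continuously, so the smoothed orientation
#' trace crosses the 90-degree midline and the far threshold; after a flip
#' the lipid stays mirrored in the destination leaflet until its next flip.
#' Partial excursions rotate to `max_angle` and return, never crossing the
#' far threshold. Flip directions are inferred from each lipid's leaflet
#' state at the flip start; the realized ground truth (direction, completion
#' time) is attached as attribute `"flip_truth"`.
#'
#' @param traj A bilayer from [make_bilayer()].
#' @param schedule Tibble with columns `lipid`, `t_start` (ns), `duration`
#'   (ns, default column 20) and optional `x_path`, `y_path`: the lateral
#'   waypoint the lipid passes through at mid-transition (e.g. the groove
#'   mouth); `NA` keeps the lipid at its lattice site.
#' @param excursions Optional tibble with columns `lipid`, `t_start`,
#'   `duration`, `max_angle` (degrees reached before returning).
#' @param jitter Positional noise added to scripted beads (A); defaults to
#'   the spec's `sigma`.
#' @param seed Seed for the scripted-bead jitter; defaults to spec seed +
#'   1000.
#' @return The trajectory with scripted lipids overwritten.
#' @export
apply_flips <- function(traj, schedule, excursions = NULL, jitter = NULL,
                        seed = NULL) {
  spec <- attr(traj, "synth_spec")
  info <- attr(traj, "synth_lipids")
  if (is.null(spec) || is.null(info)) {
    stop("apply_flips needs a trajectory from make_bilayer()", call. = FALSE)
  }
  schedule <- tibble::as_tibble(schedule)
  if (nrow(schedule) > 0 && !"duration" %in% names(schedule)) {
    schedule$duration <- 20
  }
  if (!"x_path" %in% names(schedule)) schedule$x_path <- NA_real_
  if (!"y_path" %in% names(schedule)) schedule$y_path <- NA_real_
  if (any(schedule$duration <= 0)) {
    stop("schedule error: durations must be > 0", call. = FALSE)
  }
  if (!all(schedule$lipid %in% info$lipid)) {
    stop("schedule error: unknown lipid id", call. = FALSE)
  }
  exc <- if (is.null(excursions)) {
    tibble::tibble(lipid = integer(), t_start = numeric(),
                   duration = numeric(), max_angle = numeric())
  } else {
    tibble::as_tibble(excursions)
  }
  # flips and excursions of one lipid must not overlap in time
  iv <- dplyr::bind_rows(
    schedule[, c("lipid", "t_start", "duration")],
    exc[, c("lipid", "t_start", "duration")]
  )
  for (id in unique(iv$lipid)) {
    s <- iv[iv$lipid == id, ]
    s <- s[order(s$t_start), ]
    if (nrow(s) > 1 &&
        any(s$t_start[-1] < (s$t_start + s$duration)[-nrow(s)])) {
      stop("schedule error: overlapping flips for lipid ", id, call. = FALSE)
    }
  }

  jitter <- jitter %||% spec$sigma
  seed <- seed %||% (spec$seed + 1000L)
  set.seed(seed)
  tt <- traj$times
  nf <- length(tt)
  roles <- c("NC3", "PO4", "GL1", "GL2", "C4A", "C4B")
  truth <- list()

  for (id in unique(c(schedule$lipid, exc$lipid))) {
    row <- info[info$lipid == id, ]
    fl <- schedule[schedule$lipid == id, , drop = FALSE]
    fl <- fl[order(fl$t_start), , drop = FALSE]
    ex <- exc[exc$lipid == id, , drop = FALSE]

    up0 <- row$leaflet == "upper"
    half <- row$sep / 2
    # leaflet sign per frame: +1 upper, -1 lower, flipping at each completion
    sgn <- rep(if (up0) 1 else -1, nf)
    if (nrow(fl) > 0) {
      for (k in seq_len(nrow(fl))) {
        done <- tt >= fl$t_start[k] + fl$duration[k]
        sgn[done] <- -sgn[done]
      }
    }
    # static pose baseline
    psi <- rep(0, nf)            # rotation away from the leaflet pole (rad)
    zc <- sgn * half
    xyw <- rep(0, nf)            # waypoint mixing weight
    xp <- rep(row$x0, nf)
    yp <- rep(row$y0, nf)
    dir_sign <- rep(1, nf)       # +1: rotating from +z pole downward

    if (nrow(fl) > 0) {
      state_up <- up0
      for (k in seq_len(nrow(fl))) {
        inwin <- tt >= fl$t_start[k] & tt < fl$t_start[k] + fl$duration[k]
        f <- (tt[inwin] - fl$t_start[k]) / fl$duration[k]
        psi[inwin] <- pi * f
        zc[inwin] <- (if (state_up) 1 else -1) * half * cos(pi * f)
        dir_sign[inwin] <- if (state_up) 1 else -1
        if (!is.na(fl$x_path[k])) {
          w <- sin(pi * f)
          xyw[inwin] <- w
          xp[inwin] <- (1 - w) * row$x0 + w * fl$x_path[k]
          yp[inwin] <- (1 - w) * row$y0 + w * fl$y_path[k]
        }
        truth[[length(truth) + 1L]] <- tibble::tibble(
          lipid = id, t_start = fl$t_start[k],
          t_complete = fl$t_start[k] + fl$duration[k],
          direction = if (state_up) "upper_to_lower" else "lower_to_upper")
        state_up <- !state_up
      }
    }
    if (nrow(ex) > 0) {
      for (k in seq_len(nrow(ex))) {
        inwin <- tt >= ex$t_start[k] & tt < ex$t_start[k] + ex$duration[k]
        f <- (tt[inwin] - ex$t_start[k]) / ex$duration[k]
        state_up <- sgn[which(inwin)[1]] > 0
        amp <- if (state_up) {
          (180 - ex$max_angle[k]) * pi / 180
        } else {
          ex$max_angle[k] * pi / 180
        }
        psi[inwin] <- amp * sin(pi * f)
        zc[inwin] <- (if (state_up) 1 else -1) * half * cos(amp * sin(pi * f))
        dir_sign[inwin] <- if (state_up) 1 else -1
      }
    }

    # orientation axis: at psi = 0 the axis sits at the leaflet pole
    # (-z for upper, +z for lower) and rotates by psi in the xz plane
    up_like <- dir_sign > 0
    vz <- ifelse(up_like, -cos(psi), cos(psi))
    vx <- sin(psi)
    V <- cbind(vx, 0, vz)
    # outside transition windows the axis must match the current leaflet
    stat <- psi == 0
    V[stat, 1] <- 0
    V[stat, 3] <- -sgn[stat]
    C <- cbind(xp, yp, zc)
    bd <- pose_beads(C, V, spec$head_offset, spec$tail_length)
    for (k in seq_along(roles)) {
      b <- traj$topology$lipids[[roles[k]]][traj$topology$lipids$lipid == id]
      m <- t(bd[[roles[k]]])
      if (jitter > 0) m <- m + stats::rnorm(length(m), 0, jitter)
      traj$coords[b, , ] <- m
    }
  }
  truth <- if (length(truth) > 0) {
    dplyr::arrange(dplyr::bind_rows(truth), .data$t_complete)
  } else {
    tibble::tibble(lipid = integer(), t_start = numeric(),
                   t_complete = numeric(), direction = character())
  }
  attr(traj, "flip_truth") <- truth
  traj
}

#' Add a static protein scaffold with a groove and a dimer-cleft site
#'
#' Appends backbone-only residue beads forming two vertical walls, labelled
#' TM4 and TM6, at a configurable separation (a stand-in for the TM4/TM6
#' groove), and optionally a second pair of walls labelled TM3 (chain A) and
#' TM10 (chain B) at a cleft site. The groove centerline is registered as
#' attribute `"groove_path"` (a vertical polyline) and the cleft position as
#' `"cleft_site"`; TM ranges are registered in the topology.
#'
#' @param traj A [cg_trajectory()].
#' @param groove_center Length-2 xy position of the groove centerline (A).
#' @param separation TM4-TM6 wall separation (A); a scalar, or a per-frame
#'   vector for piecewise-varying groove width.
#' @param cleft_center Optional length-2 xy position of the dimer cleft.
#' @param cleft_separation TM3-TM10 separation at the cleft (A).
#' @param z_range Vertical extent of the walls (A).
#' @param beads_per_wall Beads (one residue each) per wall.
#' @return The extended trajectory.
#' @export
add_protein_scaffold <- function(traj, groove_center, separation = 6,
                                 cleft_center = NULL, cleft_separation = 10,
                                 z_range = c(-16, 16), beads_per_wall = 13L) {
  box <- traj$box[1, ]
  if (any(groove_center < 0) || any(groove_center > box[1:2])) {
    stop("spec error: groove center outside box", call. = FALSE)
  }
  nf <- n_frames(traj)
  nb0 <- n_beads(traj)
  zz <- seq(z_range[1], z_range[2], length.out = beads_per_wall)
  sep <- rep_len(separation, nf)

  walls <- list(
    list(tm = "TM4", chain = "A", resid = 327:(327 + beads_per_wall - 1L),
         axis = "x", side = -1, center = groove_center),
    list(tm = "TM6", chain = "A", resid = 430:(430 + beads_per_wall - 1L),
         axis = "x", side = +1, center = groove_center)
  )
  if (!is.null(cleft_center)) {
    if (any(cleft_center < 0) || any(cleft_center > box[1:2])) {
      stop("spec error: cleft center outside box", call. = FALSE)
    }
    walls <- c(walls, list(
      list(tm = "TM3", chain = "A", resid = 301:(301 + beads_per_wall - 1L),
           axis = "y", side = -1, center = cleft_center),
      list(tm = "TM10", chain = "B", resid = 701:(701 + beads_per_wall - 1L),
           axis = "y", side = +1, center = cleft_center)
    ))
  }
  n_new <- length(walls) * beads_per_wall
  coords <- array(NA_real_, dim = c(nb0 + n_new, 3L, nf))
  coords[seq_len(nb0), , ] <- traj$coords

  res_rows <- list()
  bead <- nb0
  for (w in walls) {
    wall_sep <- if (w$tm %in% c("TM4", "TM6")) sep else
      rep_len(cleft_separation, nf)
    for (i in seq_len(beads_per_wall)) {
      bead <- bead + 1L
      if (w$axis == "x") {
        coords[bead, 1, ] <- w$center[1] + w$side * wall_sep / 2
        coords[bead, 2, ] <- w$center[2]
      } else {
        coords[bead, 1, ] <- w$center[1]
        coords[bead, 2, ] <- w$center[2] + w$side * wall_sep / 2
      }
      coords[bead, 3, ] <- zz[i]
      res_rows[[length(res_rows) + 1L]] <- tibble::tibble(
        resid = w$resid[i], chain = w$chain, backbone = bead,
        sidechain = list(integer()), tm = w$tm)
    }
  }
  topo <- traj$topology
  topo$residues <- dplyr::bind_rows(topo$residues, dplyr::bind_rows(res_rows))
  topo$n_beads <- nb0 + n_new
  topo <- validate_cg_topology(topo)

  out <- cg_trajectory(coords, traj$times, traj$box, topo)
  for (a in c("synth_spec", "synth_lipids", "flip_truth")) {
    attr(out, a) <- attr(traj, a)
  }
  attr(out, "groove_path") <- tibble::tibble(
    x = groove_center[1], y = groove_center[2],
    z = seq(z_range[2] + 6, z_range[1] - 6, by = -1))
  if (!is.null(cleft_center)) attr(out, "cleft_site") <- cleft_center
  out
}

#' Add scripted membrane-crossing tracers (water or ions)
#'
#' Each scheduled crossing adds one particle that waits in one bath, transits
#' the membrane slab along the trajectory's registered groove path (or at a
#' fixed lateral offset from it) over `duration` ns centered on the scheduled
#' time, and stays in the destination bath. Wanderers jitter in the upper
#' bath and never cross.
#'
#' @param traj A [cg_trajectory()] (with a `"groove_path"` attribute, or
#'   supply `path_xy`).
#' @param species `"water"`, `"Na"` or `"Cl"`.
#' @param crossings Numeric vector of crossing mid-times (ns).
#' @param direction `"down"`, `"up"` or `"alternate"`.
#' @param duration Transit duration (ns).
#' @param lateral_offset Lateral displacement from the path during transit
#'   (A); use a value beyond the tube radius to script off-path crossings.
#' @param n_wanderers Particles that stay in the upper bath.
#' @param path_xy Length-2 xy of the crossing path (defaults to the
#'   registered groove path).
#' @param bath_z Resting |z| of the baths (A).
#' @param sigma Positional jitter for tracers (A).
#' @param seed Seed for tracer jitter.
#' @return The extended trajectory.
#' @export
add_tracers <- function(traj, species = c("water", "Na", "Cl"),
                        crossings = numeric(), direction = "down",
                        duration = 10, lateral_offset = 0, n_wanderers = 0L,
                        path_xy = NULL, bath_z = 35, sigma = 0.3,
                        seed = 99L) {
  species <- match.arg(species)
  tt <- traj$times
  if (length(crossings) > 0 &&
      (min(crossings) < min(tt) || max(crossings) > max(tt))) {
    stop("spec error: crossing times outside trajectory span", call. = FALSE)
  }
  if (is.null(path_xy)) {
    gp <- attr(traj, "groove_path")
    if (is.null(gp)) {
      stop("spec error: no registered groove path; supply path_xy",
           call. = FALSE)
    }
    path_xy <- c(gp$x[1], gp$y[1])
  }
  nf <- n_frames(traj)
  nb0 <- n_beads(traj)
  n_new <- length(crossings) + n_wanderers
  if (n_new == 0) return(traj)
  set.seed(seed)
  coords <- array(NA_real_, dim = c(nb0 + n_new, 3L, nf))
  coords[seq_len(nb0), , ] <- traj$coords

  dirs <- switch(direction,
                 down = rep("down", length(crossings)),
                 up = rep("up", length(crossings)),
                 alternate = rep(c("down", "up"),
                                 length.out = length(crossings)))
  bead <- nb0
  for (i in seq_along(crossings)) {
    bead <- bead + 1L
    t0 <- crossings[i] - duration / 2
    f <- pmin(1, pmax(0, (tt - t0) / duration))
    z <- if (dirs[i] == "down") bath_z * (1 - 2 * f) else bath_z * (2 * f - 1)
    coords[bead, 1, ] <- path_xy[1] + lateral_offset +
      stats::rnorm(nf, 0, sigma)
    coords[bead, 2, ] <- path_xy[2] + stats::rnorm(nf, 0, sigma)
    coords[bead, 3, ] <- z + stats::rnorm(nf, 0, sigma)
  }
  for (i in seq_len(n_wanderers)) {
    bead <- bead + 1L
    coords[bead, 1, ] <- path_xy[1] + 5 + stats::rnorm(nf, 0, sigma)
    coords[bead, 2, ] <- path_xy[2] + 5 + stats::rnorm(nf, 0, sigma)
    coords[bead, 3, ] <- bath_z + 5 + abs(stats::rnorm(nf, 0, sigma))
  }

  topo <- traj$topology
  new_idx <- nb0 + seq_len(n_new)
  if (species == "water") {
    topo$waters <- c(topo$waters, as.integer(new_idx))
  } else {
    topo$ions <- dplyr::bind_rows(
      topo$ions, tibble::tibble(bead = as.integer(new_idx), species = species))
  }
  topo$n_beads <- nb0 + n_new
  topo <- validate_cg_topology(topo)
  out <- cg_trajectory(coords, traj$times, traj$box, topo)
  for (a in c("synth_spec", "synth_lipids", "flip_truth", "groove_path",
              "cleft_site")) {
    attr(out, a) <- attr(traj, a)
  }
  out
}

#' Lipids nearest a lateral position
#'
#' Convenience selector for scenario building: lipid ids sorted by distance
#' of their lattice site from `xy`, optionally per leaflet. Scripting flips
#' on lipids local to their waypoint keeps transit paths away from other
#' registered sites.
#'
#' @param traj A bilayer from [make_bilayer()].
#' @param xy Length-2 lateral position (A).
#' @param leaflet `"upper"`, `"lower"` or `NULL` for both.
#' @param n Number of ids to return.
#' @return Integer vector of lipid ids.
#' @export
nearest_lipids <- function(traj, xy, leaflet = NULL, n = 1L) {
  info <- attr(traj, "synth_lipids")
  if (is.null(info)) {
    stop("nearest_lipids needs a trajectory from make_bilayer()",
         call. = FALSE)
  }
  if (!is.null(leaflet)) info <- info[info$leaflet == leaflet, ]
  d <- sqrt((info$x0 - xy[1])^2 + (info$y0 - xy[2])^2)
  info$lipid[order(d)][seq_len(min(n, nrow(info)))]
}

#' Build a round-robin flip schedule
#'
#' Places `n_flips` complete flips uniformly over a time span, cycling
#' through a pool of lipids so no lipid's flips overlap, with an optional
#' shared lateral waypoint.
#'
#' @param n_flips Number of flips.
#' @param t_span Length-2 time span (ns) containing all flip midpoints.
#' @param lipids Pool of lipid ids to cycle through.
#' @param duration Flip duration (ns).
#' @param waypoint Optional length-2 xy waypoint passed at mid-transition.
#' @return A schedule tibble for [apply_flips()].
#' @export
make_flip_schedule <- function(n_flips, t_span, lipids, duration = 20,
                               waypoint = NULL) {
  if (n_flips == 0) {
    return(tibble::tibble(lipid = integer(), t_start = numeric(),
                          duration = numeric(), x_path = numeric(),
                          y_path = numeric()))
  }
  mids <- t_span[1] + (seq_len(n_flips) - 0.5) / n_flips * diff(t_span)
  tibble::tibble(
    lipid = rep_len(lipids, n_flips),
    t_start = mids - duration / 2,
    duration = duration,
    x_path = if (is.null(waypoint)) NA_real_ else waypoint[1],
    y_path = if (is.null(waypoint)) NA_real_ else waypoint[2]
  )
}
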