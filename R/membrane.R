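#' Ensemble-averaged leaflet surfaces
#'
#' Splats each lipid's glycerol beads (GL1, GL2) onto a rectilinear xy grid
#' (default 1 A spacing over the box) with bilinear weights, separately for
#' the upper and lower leaflet using the per-frame leaflet assignment, and
#' averages the deposited z over all frames. Grid nodes with lipid occupancy
#' below `occupancy_min` (fraction of frames with nonzero weight, default 2%)
#' are masked out, and clusters of valid nodes disconnected (4-connectivity)
#' from the largest connected component - the bulk membrane surface - are
#' removed.
#'
#' @param traj A [cg_trajectory()], already aligned and with equilibration
#'   discarded.
#' @param leaflets Per-frame leaflet assignment: tibble with `lipid`, `time`,
#'   `leaflet` (from [compute_angle_traces()] /
#'   [assign_leaflets_per_frame()]). If `NULL`, the topology's static labels
#'   are used for every frame.
#' @param spacing Grid spacing (A, default 1).
#' @param occupancy_min Minimum occupancy fraction (default 0.02).
#' @return Object of class `leaflet_surfaces`: grid vectors `x`, `y` and for
#'   each leaflet matrices `z` (mean height), `occupancy` and logical `mask`.
#'   Has `tidy()`, `glance()` and `autoplot()` methods.
#' @export
average_surfaces <- function(traj, leaflets = NULL, spacing = 1,
                             occupancy_min = 0.02) {
  lip <- traj$topology$lipids
  if (nrow(lip) == 0) stop("surface error: no lipids", call. = FALSE)
  box <- traj$box[1, ]
  nx <- floor(box[1] / spacing) + 1L
  ny <- floor(box[2] / spacing) + 1L
  xg <- (seq_len(nx) - 1L) * spacing
  yg <- (seq_len(ny) - 1L) * spacing
  nf <- n_frames(traj)

  if (is.null(leaflets)) {
    up_mat <- matrix(lip$leaflet == "upper", nrow = nrow(lip), ncol = nf)
  } else {
    key <- order(leaflets$time, leaflets$lipid)
    up_mat <- matrix(leaflets$leaflet[key] == "upper",
                     nrow = nrow(lip), ncol = nf)
  }

  acc <- function() list(wz = matrix(0, nx, ny), w = matrix(0, nx, ny),
                         occ = matrix(0L, nx, ny))
  A <- list(upper = acc(), lower = acc())
  gl_idx <- cbind(lip$GL1, lip$GL2)

  splat <- function(A1, px, py, pz) {
    # clamp into the grid and deposit bilinear weights on 4 nodes
    px <- pmin(pmax(px, 0), (nx - 1L) * spacing - 1e-9)
    py <- pmin(pmax(py, 0), (ny - 1L) * spacing - 1e-9)
    ix <- floor(px / spacing) + 1L
    iy <- floor(py / spacing) + 1L
    fx <- px / spacing - (ix - 1L)
    fy <- py / spacing - (iy - 1L)
    seen <- rep(FALSE, nx * ny)
    for (corner in 1:4) {
      cx <- ix + (corner - 1L) %% 2L
      cy <- iy + (corner - 1L) %/% 2L
      w <- (if ((corner - 1L) %% 2L == 0L) 1 - fx else fx) *
        (if ((corner - 1L) %/% 2L == 0L) 1 - fy else fy)
      keep <- w > 0
      if (!any(keep)) next
      lin <- (cy[keep] - 1L) * nx + cx[keep]
      agg <- rowsum(cbind(w[keep] * pz[keep], w[keep]), lin)
      tgt <- as.integer(rownames(agg))
      A1$wz[tgt] <- A1$wz[tgt] + agg[, 1]
      A1$w[tgt] <- A1$w[tgt] + agg[, 2]
      seen[tgt] <- TRUE
    }
    A1$occ <- A1$occ + matrix(seen, nx, ny)
    A1
  }

  for (f in seq_len(nf)) {
    fr <- traj$coords[, , f]
    for (side in c("upper", "lower")) {
      sel <- if (side == "upper") up_mat[, f] else !up_mat[, f]
      if (!any(sel)) next
      beads <- as.vector(gl_idx[sel, , drop = FALSE])
      A[[side]] <- splat(A[[side]], fr[beads, 1], fr[beads, 2], fr[beads, 3])
    }
  }

  finish <- function(A1) {
    z <- matrix(NA_real_, nx, ny)
    nzw <- A1$w > 0
    z[nzw] <- A1$wz[nzw] / A1$w[nzw]
    occ <- A1$occ / nf
    mask <- occ >= occupancy_min & nzw
    mask <- keep_largest_component(mask)
    list(z = z, occupancy = occ, mask = mask, weight = A1$w)
  }
  up <- finish(A$upper)
  lo <- finish(A$lower)
  if (!any(up$mask) || !any(lo$mask)) {
    stop("surface error: no valid surface nodes after filtering",
         call. = FALSE)
  }
  structure(list(x = xg, y = yg, spacing = spacing, n_frames = nf,
                 occupancy_min = occupancy_min, upper = up, lower = lo),
            class = "leaflet_surfaces")
}

# keep only the largest 4-connected component of a logical matrix
keep_largest_component <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  nr <- nrow(mask)
  nc <- ncol(mask)
  sizes <- integer()
  for (start in which(mask)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    size <- 0L
    while (length(queue) > 0) {
      cell <- queue[length(queue)]
      queue <- queue[-length(queue)]
      size <- size + 1L
      i <- (cell - 1L) %% nr + 1L
      j <- (cell - 1L) %/% nr + 1L
      for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
        ii <- i + d[1]
        jj <- j + d[2]
        if (ii >= 1L && ii <= nr && jj >= 1L && jj <= nc) {
          nb <- (jj - 1L) * nr + ii
          if (mask[nb] && lab[nb] == 0L) {
            lab[nb] <- cur
            queue <- c(queue, nb)
          }
        }
      }
    }
    sizes[cur] <- size
  }
  if (cur == 0L) return(mask)
  mask & lab == which.max(sizes)
}

#' @export
print.leaflet_surfaces <- function(x, ...) {
  cat("<leaflet_surfaces> ", length(x$x), "x", length(x$y), " grid (",
      x$spacing, " A), ", sum(x$upper$mask), "/", sum(x$lower$mask),
      " valid upper/lower nodes over ", x$n_frames, " frames\n", sep = "")
  invisible(x)
}

#' @export
#' @rdname average_surfaces
#' @param x A `leaflet_surfaces` object.
#' @param ... Unused.
tidy.leaflet_surfaces <- function(x, ...) {
  grid <- expand.grid(x = x$x, y = x$y)
  tibble::tibble(
    x = grid$x, y = grid$y,
    z_upper = as.vector(x$upper$z), z_lower = as.vector(x$lower$z),
    occupancy_upper = as.vector(x$upper$occupancy),
    occupancy_lower = as.vector(x$lower$occupancy),
    mask_upper = as.vector(x$upper$mask),
    mask_lower = as.vector(x$lower$mask)
  )
}

#' @export
#' @rdname average_surfaces
glance.leaflet_surfaces <- function(x, ...) {
  mt <- min_thickness(x)
  tibble::tibble(n_valid_upper = sum(x$upper$mask),
                 n_valid_lower = sum(x$lower$mask),
                 mean_z_upper = mean(x$upper$z[x$upper$mask]),
                 mean_z_lower = mean(x$lower$z[x$lower$mask]),
                 min_thickness = mt$min_thickness)
}

#' Minimal membrane thickness between ensemble-averaged surfaces
#'
#' The minimal three-dimensional Euclidean distance between any valid point
#' on the upper surface and any valid point on the lower surface (full 3D
#' distance, not the vertical gap), computed exhaustively over all valid
#' node pairs in blocks.
#'
#' @param surfaces A `leaflet_surfaces` object from [average_surfaces()].
#' @return One-row tibble: `min_thickness` (A) and the argmin pair
#'   (`x_upper`, `y_upper`, `z_upper`, `x_lower`, `y_lower`, `z_lower`).
#' @export
min_thickness <- function(surfaces) {
  pts <- function(side) {
    m <- surfaces[[side]]$mask
    if (!any(m)) stop("surface error: empty mask", call. = FALSE)
    idx <- which(m, arr.ind = TRUE)
    cbind(surfaces$x[idx[, 1]], surfaces$y[idx[, 2]],
          surfaces[[side]]$z[m])
  }
  U <- pts("upper")
  L <- pts("lower")
  l_sq <- rowSums(L^2)
  best <- Inf
  best_pair <- c(NA_integer_, NA_integer_)
  block <- 512L
  for (s in seq(1L, nrow(U), by = block)) {
    e <- min(s + block - 1L, nrow(U))
    Ub <- U[s:e, , drop = FALSE]
    d2 <- outer(rowSums(Ub^2), l_sq, `+`) - 2 * (Ub %*% t(L))
    mi <- which.min(d2)
    if (d2[mi] < best) {
      best <- d2[mi]
      best_pair <- c(s - 1L + (mi - 1L) %% nrow(Ub) + 1L,
                     (mi - 1L) %/% nrow(Ub) + 1L)
    }
  }
  u <- U[best_pair[1], ]
  l <- L[best_pair[2], ]
  tibble::tibble(min_thickness = sqrt(max(0, best)),
                 x_upper = u[1], y_upper = u[2], z_upper = u[3],
                 x_lower = l[1], y_lower = l[2], z_lower = l[3])
}

#' Accumulate a 3D bead density grid
#'
#' Nearest-voxel binning of the selected beads over all frames into a
#' rectilinear grid (default 100x100x150 A extent at 0.5 A spacing centered
#' on a reference point). Raw counts are conserved: their sum equals the
#' number of in-bounds bead-frame observations. Out-of-bounds observations
#' are counted separately.
#'
#' @param traj A [cg_trajectory()] (subunit-aligned for protein work).
#' @param beads Integer vector of bead indices to bin.
#' @param center Grid center (length 3, A); default is the box center at
#'   z = 0.
#' @param extent Grid extent (length 3, A).
#' @param spacing Voxel spacing (A).
#' @return Object of class `density_grid`: `counts` (3D array), `origin`,
#'   `spacing`, `dims`, `n_frames`, `n_inbounds`, `n_out`.
#' @export
accumulate_density <- function(traj, beads, center = NULL,
                               extent = c(100, 100, 150), spacing = 0.5) {
  if (any(extent <= 0) || spacing <= 0) {
    stop("spec error: zero-extent grid", call. = FALSE)
  }
  if (is.null(center)) {
    center <- c(traj$box[1, 1] / 2, traj$box[1, 2] / 2, 0)
  }
  dims <- as.integer(round(extent / spacing))
  origin <- center - dims * spacing / 2
  nf <- n_frames(traj)
  nbd <- length(beads)
  px <- as.vector(traj$coords[beads, 1, ])
  py <- as.vector(traj$coords[beads, 2, ])
  pz <- as.vector(traj$coords[beads, 3, ])
  ix <- floor((px - origin[1]) / spacing) + 1L
  iy <- floor((py - origin[2]) / spacing) + 1L
  iz <- floor((pz - origin[3]) / spacing) + 1L
  ok <- ix >= 1L & ix <= dims[1] & iy >= 1L & iy <= dims[2] &
    iz >= 1L & iz <= dims[3]
  lin <- (iz[ok] - 1L) * dims[1] * dims[2] + (iy[ok] - 1L) * dims[1] + ix[ok]
  counts <- array(tabulate(lin, nbins = prod(dims)), dim = dims)
  structure(list(counts = counts, origin = origin, spacing = spacing,
                 dims = dims, n_frames = nf,
                 n_inbounds = sum(ok), n_out = sum(!ok)),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat("<density_grid> ", paste(x$dims, collapse = "x"), " voxels at ",
      x$spacing, " A; ", x$n_inbounds, " observations (",
      x$n_out, " out of bounds)\n", sep = "")
  invisible(x)
}

#' Normalized view of a density grid
#'
#' @param grid A `density_grid`.
#' @param mode `"counts"` (raw), `"probability"` (counts / total counts) or
#'   `"number_density"` (counts per A^3 per frame).
#' @return 3D array.
#' @export
grid_density <- function(grid, mode = c("counts", "probability",
                                        "number_density")) {
  mode <- match.arg(mode)
  switch(mode,
         counts = grid$counts,
         probability = grid$counts / sum(grid$counts),
         number_density = grid$counts / (grid$spacing^3 * grid$n_frames))
}

#' Average several density grids voxel-wise
#'
#' Used to average per-chain grids after each subunit has been aligned
#' individually.
#'
#' @param grids List of compatible `density_grid` objects.
#' @return A `density_grid` with averaged counts.
#' @export
average_density_grids <- function(grids) {
  g <- grids[[1]]
  for (h in grids[-1]) {
    if (!all(h$dims == g$dims)) {
      stop("spec error: incompatible grids", call. = FALSE)
    }
    g$counts <- g$counts + h$counts
    g$n_inbounds <- g$n_inbounds + h$n_inbounds
    g$n_out <- g$n_out + h$n_out
  }
  g$counts <- g$counts / length(grids)
  g$n_inbounds <- g$n_inbounds / length(grids)
  g
}

#' Write a density grid as an OpenDX scalar field
#'
#' Plain-text OpenDX (.dx) volumetric output loadable by VMD, ChimeraX and
#' PyMOL.
#'
#' @param grid A `density_grid`.
#' @param path Output file.
#' @param mode Normalization passed to [grid_density()].
#' @return `path`, invisibly.
#' @export
write_dx <- function(grid, path, mode = "counts") {
  vals <- grid_density(grid, mode)
  d <- grid$dims
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("object 1 class gridpositions counts %d %d %d", d[1], d[2], d[3]),
    sprintf("origin %g %g %g", grid$origin[1] + grid$spacing / 2,
            grid$origin[2] + grid$spacing / 2, grid$origin[3] + grid$spacing / 2),
    sprintf("delta %g 0 0", grid$spacing),
    sprintf("delta 0 %g 0", grid$spacing),
    sprintf("delta 0 0 %g", grid$spacing),
    sprintf("object 2 class gridconnections counts %d %d %d",
            d[1], d[2], d[3]),
    sprintf("object 3 class array type double rank 0 items %d data follows",
            prod(d))
  ), con)
  # dx is z-fastest
  v <- aperm(vals, c(3, 2, 1))
  v <- as.vector(v)
  pad <- (-length(v)) %% 3
  if (pad > 0) v <- c(v, rep(NA, pad))
  m <- matrix(v, ncol = 3, byrow = TRUE)
  lines <- apply(m, 1L, function(r) paste(stats::na.omit(r), collapse = " "))
  writeLines(lines, con)
  writeLines('attribute "dep" string "positions"', con)
  invisible(path)
}

#' Free-energy profile along a pathway by Boltzmann inversion
#'
#' For each pathway vertex, averages the voxel density within `tube_radius`
#' of the vertex in its z layer and converts to a free energy
#' `F(s) = -ln(rho(s) / rho_max)` in units of kT (the inversion is
#' temperature-free in kT units). The profile is offset so its minimum is 0;
#' slabs with zero density are reported as `Inf` and flagged.
#'
#' @param grid A `density_grid`.
#' @param path Pathway polyline tibble (`x`, `y`, `z`).
#' @param tube_radius Lateral tube radius (A, default 8).
#' @return Tibble with columns `s` (arclength from the first vertex, A), `x`,
#'   `y`, `z`, `density`, `free_energy` (kT) and `empty` (logical).
#' @export
pmf_from_density <- function(grid, path, tube_radius = 8) {
  dims <- grid$dims
  xc <- grid$origin[1] + (seq_len(dims[1]) - 0.5) * grid$spacing
  yc <- grid$origin[2] + (seq_len(dims[2]) - 0.5) * grid$spacing
  zc <- grid$origin[3] + (seq_len(dims[3]) - 0.5) * grid$spacing
  rho <- rep(NA_real_, nrow(path))
  for (i in seq_len(nrow(path))) {
    iz <- which.min(abs(zc - path$z[i]))
    if (abs(zc[iz] - path$z[i]) > grid$spacing) {
      stop("spec error: pathway vertex outside grid", call. = FALSE)
    }
    in_tube <- outer((xc - path$x[i])^2, (yc - path$y[i])^2, `+`) <=
      tube_radius^2
    if (!any(in_tube)) {
      rho[i] <- 0
      next
    }
    layer <- grid$counts[, , iz]
    rho[i] <- mean(layer[in_tube])
  }
  if (all(rho == 0)) stop("pmf error: all-zero tube", call. = FALSE)
  fe <- -log(rho / max(rho))
  seg <- sqrt(diff(path$x)^2 + diff(path$y)^2 + diff(path$z)^2)
  tibble::tibble(s = c(0, cumsum(seg)), x = path$x, y = path$y, z = path$z,
                 density = rho, free_energy = fe, empty = rho == 0)
}
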