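#' Centered running mean with truncated edges
#'
#' Truncated-window centered moving average: element `t` is the mean of
#' `x[max(1, t-h) : min(n, t+h)]` with `h = floor(w/2)`.
#'
#' @param x Numeric vector.
#' @param w Window length in samples.
#' @return Numeric vector, same length as `x`.
#' @export
running_mean <- function(x, w) {
  n <- length(x)
  h <- floor(w / 2)
  if (h == 0 || n == 1) return(x)
  cs <- cumsum(c(0, x))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Per-lipid orientation angle traces
#'
#' For every lipid and frame, the orientation vector is the mean of the two
#' choline-to-terminal-tail vectors, `v = ((C4A - NC3) + (C4B - NC3)) / 2`,
#' and the angle is measured against the +z axis:
#' `theta = acos(v.z / |v|)` in degrees. Upper-leaflet lipids sit near 150
#' degrees, lower-leaflet lipids near 30 degrees. A centered running average
#' (window `smooth_window_ns`) denoises each trace, and each frame gets a
#' leaflet assignment from the smoothed angle (upper iff >= 90 degrees,
#' inclusive).
#'
#' @param traj A [cg_trajectory()] with lipid roles resolved.
#' @param smooth_window_ns Running-average window (ns, default 100).
#' @return Tibble with columns `lipid`, `time`, `angle`, `angle_smooth`,
#'   `leaflet` (one row per lipid per frame).
#' @export
compute_angle_traces <- function(traj, smooth_window_ns = 100) {
  lip <- traj$topology$lipids
  if (nrow(lip) == 0) stop("no lipids in topology", call. = FALSE)
  nf <- n_frames(traj)
  nc3 <- traj$coords[lip$NC3, , , drop = FALSE]
  c4a <- traj$coords[lip$C4A, , , drop = FALSE]
  c4b <- traj$coords[lip$C4B, , , drop = FALSE]
  v <- (c4a + c4b) / 2 - nc3                     # n_lip x 3 x nf
  vn <- sqrt(v[, 1, ]^2 + v[, 2, ]^2 + v[, 3, ]^2)
  vn <- matrix(vn, nrow = nrow(lip), ncol = nf)
  if (any(vn < 1e-9)) {
    stop("degenerate-lipid error: zero-length orientation vector",
         call. = FALSE)
  }
  cosz <- matrix(v[, 3, ], nrow = nrow(lip), ncol = nf) / vn
  ang <- acos(pmin(pmax(cosz, -1), 1)) * 180 / pi

  w <- frames_per_window(traj, smooth_window_ns)
  sm <- t(apply(ang, 1L, running_mean, w = w))
  if (nf == 1) sm <- matrix(sm, nrow = nrow(lip))

  tibble::tibble(
    lipid = rep(lip$lipid, times = nf),
    time = rep(traj$times, each = nrow(lip)),
    angle = as.vector(ang),
    angle_smooth = as.vector(sm),
    leaflet = ifelse(as.vector(sm) >= 90, "upper", "lower")
  )
}

#' Per-frame leaflet assignment
#'
#' Thin accessor over [compute_angle_traces()] output: a lipid belongs to the
#' upper leaflet at a frame iff its smoothed angle is >= 90 degrees
#' (inclusive boundary).
#'
#' @param traces Tibble from [compute_angle_traces()].
#' @return Tibble with columns `lipid`, `time`, `leaflet`.
#' @export
assign_leaflets_per_frame <- function(traces) {
  traces[, c("lipid", "time", "leaflet")]
}

#' Detect leaflet-transition (scrambling) events
#'
#' Runs a hysteresis state machine on each lipid's smoothed angle trace. The
#' lipid's leaflet state is initialized from the side of 90 degrees of its
#' first smoothed angle and changes only at far-threshold crossings: an
#' upper-leaflet lipid completes an event when its smoothed angle reaches
#' `<= angle_lower` (35 degrees), a lower-leaflet lipid when it reaches
#' `>= angle_upper` (145 degrees). Partial excursions that turn back before
#' the far threshold are never counted; repeated back-and-forth transits each
#' count. The transition window opens at the last frame the trace was beyond
#' the origin-leaflet reference angle (150 or 30 degrees) before completion.
#'
#' @param traces Tibble from [compute_angle_traces()].
#' @param angle_lower,angle_upper Far thresholds in degrees (default 35/145).
#' @param ref_lower,ref_upper Leaflet reference angles used for the
#'   transition-window entry (default 30/150).
#' @return Tibble with columns `lipid`, `direction` (`"upper_to_lower"` or
#'   `"lower_to_upper"`), `t_entry`, `t_complete` (ns).
#' @export
detect_events <- function(traces, angle_lower = 35, angle_upper = 145,
                          ref_lower = 30, ref_upper = 150) {
  ids <- unique(traces$lipid)
  out <- list()
  for (id in ids) {
    tr <- traces[traces$lipid == id, ]
    s <- tr$angle_smooth
    tt <- tr$time
    state_up <- s[1] >= 90
    pos <- 1L
    n <- length(s)
    while (pos <= n) {
      idx <- if (state_up) {
        which(s[pos:n] <= angle_lower)
      } else {
        which(s[pos:n] >= angle_upper)
      }
      if (length(idx) == 0) break
      ci <- pos + idx[1] - 1L
      beyond <- if (state_up) {
        which(s[seq_len(ci)] >= ref_upper)
      } else {
        which(s[seq_len(ci)] <= ref_lower)
      }
      entry <- if (length(beyond) > 0) max(beyond) else 1L
      out[[length(out) + 1L]] <- tibble::tibble(
        lipid = id,
        direction = if (state_up) "upper_to_lower" else "lower_to_upper",
        t_entry = tt[entry], t_complete = tt[ci])
      state_up <- !state_up
      pos <- ci + 1L
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(lipid = integer(), direction = character(),
                          t_entry = numeric(), t_complete = numeric()))
  }
  dplyr::arrange(dplyr::bind_rows(out), .data$t_complete)
}

#' Block-averaged scrambling rate
#'
#' Partitions the analysed window into consecutive blocks (default 1 us),
#' counts event completions per block (a trailing partial block is dropped),
#' and reports the mean and population standard deviation of the per-block
#' counts as events per microsecond. When the blocks tile the window exactly,
#' the mean equals total events / analysed duration.
#'
#' @param events Event tibble from [detect_events()], or a numeric vector of
#'   completion times (ns).
#' @param duration_ns Analysed duration (ns).
#' @param block_ns Block length (ns, default 1000).
#' @param start_ns Start of the analysed window (ns, default 0); events at
#'   `start_ns < t <= start_ns + n_blocks * block_ns` are counted.
#' @return Object of class `rate_estimate` with [tidy()] (per-block counts)
#'   and [glance()] (one-row summary) methods.
#' @export
estimate_rate <- function(events, duration_ns, block_ns = 1000,
                          start_ns = 0) {
  if (duration_ns < block_ns) {
    stop("rate error: analysed duration is shorter than one block",
         call. = FALSE)
  }
  times <- if (is.numeric(events)) events else events$t_complete
  n_blocks <- floor(duration_ns / block_ns)
  edges <- start_ns + block_ns * (0:n_blocks)
  inside <- times > edges[1] & times <= edges[n_blocks + 1]
  bin <- findInterval(times[inside], edges, left.open = TRUE,
                      rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_blocks)
  per_us <- counts / (block_ns / 1000)
  m <- mean(per_us)
  s <- sqrt(mean((per_us - m)^2))
  structure(list(mean_rate = m, sd_rate = s, counts = counts,
                 block_ns = block_ns, n_blocks = n_blocks,
                 start_ns = start_ns, n_events = sum(counts),
                 n_dropped = sum(!inside)),
            class = "rate_estimate")
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Scrambling rate: %.1f +/- %.1f events/us (%d events in %d x %g ns blocks)\n",
              x$mean_rate, x$sd_rate, x$n_events, x$n_blocks, x$block_ns))
  invisible(x)
}

#' @export
#' @rdname estimate_rate
#' @param x A `rate_estimate`.
#' @param ... Unused.
tidy.rate_estimate <- function(x, ...) {
  tibble::tibble(block = seq_along(x$counts),
                 t_start = x$start_ns + (seq_along(x$counts) - 1) * x$block_ns,
                 count = x$counts,
                 rate = x$counts / (x$block_ns / 1000))
}

#' @export
#' @rdname estimate_rate
glance.rate_estimate <- function(x, ...) {
  tibble::tibble(mean_rate = x$mean_rate, sd_rate = x$sd_rate,
                 n_events = x$n_events, n_blocks = x$n_blocks,
                 block_ns = x$block_ns)
}

#' Maximum-density pathway through a density grid
#'
#' For each z layer of the grid (optionally restricted to a z range and a
#' lateral window), takes the center of the maximum-density voxel, smooths
#' the resulting chain of points with a 3-layer moving average, and returns
#' the polyline ordered top to bottom. Layers with zero density are linearly
#' interpolated from their neighbours; ties are broken toward the lowest
#' voxel index with a warning.
#'
#' @param grid A [density_grid] from [accumulate_density()].
#' @param z_range Optional length-2 z range (A).
#' @param xy_window Optional `c(xmin, xmax, ymin, ymax)` lateral crop (A).
#' @return Tibble polyline with columns `x`, `y`, `z`, z descending.
#' @export
build_density_path <- function(grid, z_range = NULL, xy_window = NULL) {
  dims <- grid$dims
  xc <- grid$origin[1] + (seq_len(dims[1]) - 0.5) * grid$spacing
  yc <- grid$origin[2] + (seq_len(dims[2]) - 0.5) * grid$spacing
  zc <- grid$origin[3] + (seq_len(dims[3]) - 0.5) * grid$spacing
  zi <- seq_len(dims[3])
  if (!is.null(z_range)) {
    zi <- which(zc >= min(z_range) & zc <= max(z_range))
    if (length(zi) == 0) stop("path error: empty z range", call. = FALSE)
  }
  xi <- seq_len(dims[1])
  yi <- seq_len(dims[2])
  if (!is.null(xy_window)) {
    xi <- which(xc >= xy_window[1] & xc <= xy_window[2])
    yi <- which(yc >= xy_window[3] & yc <= xy_window[4])
  }
  px <- py <- rep(NA_real_, length(zi))
  ties <- 0L
  for (k in seq_along(zi)) {
    layer <- grid$counts[xi, yi, zi[k], drop = FALSE]
    mx <- max(layer)
    if (mx <= 0) next
    hits <- which(layer == mx)
    if (length(hits) > 1) ties <- ties + 1L
    hit <- hits[1]
    ix <- (hit - 1L) %% length(xi) + 1L
    iy <- (hit - 1L) %/% length(xi) + 1L
    px[k] <- xc[xi[ix]]
    py[k] <- yc[yi[iy]]
  }
  if (all(is.na(px))) {
    stop("path error: density is zero in every layer", call. = FALSE)
  }
  if (ties > 0) {
    warning("density path: ", ties,
            " layer(s) had tied maxima; lowest voxel index used")
  }
  zz <- zc[zi]
  if (anyNA(px)) {
    ok <- !is.na(px)
    px <- stats::approx(zz[ok], px[ok], xout = zz, rule = 2)$y
    py <- stats::approx(zz[ok], py[ok], xout = zz, rule = 2)$y
  }
  px <- running_mean(px, 3L)
  py <- running_mean(py, 3L)
  ord <- order(zz, decreasing = TRUE)
  tibble::tibble(x = px[ord], y = py[ord], z = zz[ord])
}

# minimum distance from points (n x 3 matrix) to a polyline (m x 3)
dist_to_polyline <- function(pts, path) {
  P <- as.matrix(path[, c("x", "y", "z")])
  if (nrow(P) == 1) {
    d2 <- (pts[, 1] - P[1, 1])^2 + (pts[, 2] - P[1, 2])^2 +
      (pts[, 3] - P[1, 3])^2
    return(sqrt(d2))
  }
  A <- P[-nrow(P), , drop = FALSE]
  B <- P[-1, , drop = FALSE]
  AB <- B - A
  len2 <- rowSums(AB^2)
  len2[len2 == 0] <- 1e-12
  best <- rep(Inf, nrow(pts))
  for (s in seq_len(nrow(A))) {
    AP <- sweep(pts, 2L, A[s, ])
    t <- pmin(1, pmax(0, (AP %*% AB[s, ]) / len2[s]))
    proj <- outer(as.vector(t), AB[s, ]) + rep(A[s, ], each = nrow(pts))
    d2 <- rowSums((pts - proj)^2)
    best <- pmin(best, d2)
  }
  sqrt(best)
}

#' Classify scrambling events as in- or out-of-the-groove
#'
#' An event is in-the-groove iff the minimum, over its transition window, of
#' its PO4-bead distance to the maximum-density pathway is within
#' `pathway_cutoff` (4.7 A, inclusive). Out-of-groove events are sub-labelled
#' `dimer_cleft` when, at the frame where the headgroup crosses the membrane
#' midplane, it is laterally nearer the registered dimer-cleft site than the
#' groove pathway; otherwise `other`.
#'
#' @param events Tibble from [detect_events()].
#' @param traj The (aligned) [cg_trajectory()] the events came from.
#' @param path Pathway polyline tibble (`x`, `y`, `z`), e.g. from
#'   [build_density_path()].
#' @param pathway_cutoff In-groove cutoff (A, default 4.7, inclusive).
#' @param cleft_site Optional length-2 xy of the dimer-cleft site (defaults
#'   to the trajectory's registered `"cleft_site"` attribute, if any).
#' @param midplane_z z of the membrane midplane (A, default 0).
#' @return `events` with added columns `pathway` (`"in_groove"` /
#'   `"out_of_groove"`), `sub_label` (`"dimer_cleft"` / `"other"` / `NA`) and
#'   `min_path_dist` (A).
#' @export
classify_events <- function(events, traj, path, pathway_cutoff = 4.7,
                            cleft_site = NULL, midplane_z = 0) {
  if (is.null(cleft_site)) cleft_site <- attr(traj, "cleft_site")
  lip <- traj$topology$lipids
  tt <- traj$times
  n <- nrow(events)
  min_dist <- rep(NA_real_, n)
  pathway <- rep(NA_character_, n)
  sub <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    if (events$t_entry[i] < tt[1] - 1e-9 ||
        events$t_complete[i] > tt[length(tt)] + 1e-9) {
      stop("consistency error: event window outside trajectory", call. = FALSE)
    }
    fr <- which(tt >= events$t_entry[i] & tt <= events$t_complete[i])
    po4 <- lip$PO4[lip$lipid == events$lipid[i]]
    pts <- t(traj$coords[po4, , fr])
    d <- dist_to_polyline(pts, path)
    min_dist[i] <- min(d)
    if (min_dist[i] <= pathway_cutoff) {
      pathway[i] <- "in_groove"
    } else {
      pathway[i] <- "out_of_groove"
      if (!is.null(cleft_site)) {
        p <- pts[which.min(abs(pts[, 3] - midplane_z)), ]
        d_cleft <- sqrt((p[1] - cleft_site[1])^2 + (p[2] - cleft_site[2])^2)
        d_groove <- min(dist_to_polyline(matrix(p, 1, 3), path))
        sub[i] <- if (d_cleft < d_groove) "dimer_cleft" else "other"
      } else {
        sub[i] <- "other"
      }
    }
  }
  events$pathway <- pathway
  events$sub_label <- sub
  events$min_path_dist <- min_dist
  events
}

#' Dispersion-index test for Poisson-distributed event times
#'
#' Bins event completion times into fixed blocks (default 1 us), computes the
#' index of dispersion `D = Var / Mean` of the per-block counts, and tests
#' `(n - 1) * D` against the chi-square distribution with `n - 1` degrees of
#' freedom (two-sided). Regular (underdispersed) and clustered
#' (overdispersed) streams are both rejected. With fewer than 10 events the
#' test is flagged insufficient and no p-value is produced.
#'
#' @param times Numeric vector of event completion times (ns).
#' @param duration_ns Analysed duration (ns).
#' @param block_ns Block length (ns, default 1000).
#' @param start_ns Start of the analysed window (ns, default 0).
#' @return Object of class `dispersion_test` with `tidy()`/`glance()`
#'   methods; fields `dispersion`, `statistic`, `df`, `p.value`,
#'   `insufficient`.
#' @export
poisson_interval_test <- function(times, duration_ns, block_ns = 1000,
                                  start_ns = 0) {
  n_blocks <- floor(duration_ns / block_ns)
  edges <- start_ns + block_ns * (0:n_blocks)
  inside <- times > edges[1] & times <= edges[n_blocks + 1]
  if (sum(inside) < 10) {
    return(structure(list(dispersion = NA_real_, statistic = NA_real_,
                          df = n_blocks - 1L, p.value = NA_real_,
                          counts = NULL, insufficient = TRUE),
                     class = "dispersion_test"))
  }
  bin <- findInterval(times[inside], edges, left.open = TRUE,
                      rightmost.closed = TRUE)
  counts <- tabulate(bin, nbins = n_blocks)
  m <- mean(counts)
  D <- stats::var(counts) / m
  stat <- (n_blocks - 1) * D
  lo <- stats::pchisq(stat, df = n_blocks - 1)
  p <- min(1, 2 * min(lo, 1 - lo))
  structure(list(dispersion = D, statistic = stat, df = n_blocks - 1L,
                 p.value = p, counts = counts, insufficient = FALSE),
            class = "dispersion_test")
}

#' @export
print.dispersion_test <- function(x, ...) {
  if (x$insufficient) {
    cat("Dispersion test: insufficient data (< 10 events)\n")
  } else {
    cat(sprintf("Dispersion test: D = %.3f, X2(%d) = %.2f, p = %.4g\n",
                x$dispersion, x$df, x$statistic, x$p.value))
  }
  invisible(x)
}

#' @export
#' @rdname poisson_interval_test
#' @param x A `dispersion_test`.
#' @param ... Unused.
tidy.dispersion_test <- function(x, ...) {
  if (is.null(x$counts)) return(tibble::tibble(block = integer(),
                                               count = integer()))
  tibble::tibble(block = seq_along(x$counts), count = x$counts)
}

#' @export
#' @rdname poisson_interval_test
glance.dispersion_test <- function(x, ...) {
  tibble::tibble(dispersion = x$dispersion, statistic = x$statistic,
                 df = x$df, p.value = x$p.value,
                 insufficient = x$insufficient)
}
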