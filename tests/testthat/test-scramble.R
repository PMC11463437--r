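test_that("orientation angle matches hand-computed vectors", {
  # straight upper-leaflet lipid: choline above tails
  t1 <- one_lipid_traj(nc3 = c(0, 0, 10), c4a = c(0, 0, 0), c4b = c(0, 0, 0))
  expect_equal(compute_angle_traces(t1)$angle, 180)
  # straight lower-leaflet lipid
  t2 <- one_lipid_traj(nc3 = c(0, 0, 0), c4a = c(0, 0, 10), c4b = c(0, 0, 10))
  expect_equal(compute_angle_traces(t2)$angle, 0)
  # splayed tails average to a vertical vector
  t3 <- one_lipid_traj(nc3 = c(0, 0, 0), c4a = c(10, 0, -10),
                       c4b = c(-10, 0, -10))
  expect_equal(compute_angle_traces(t3)$angle, 180)
  # z-mirror maps theta to 180 - theta
  t4 <- one_lipid_traj(nc3 = c(0, 0, 0), c4a = c(10, 0, -10),
                       c4b = c(0, 0, -5))
  a <- compute_angle_traces(t4)$angle
  a_m <- compute_angle_traces(transform_trajectory(t4, mirror_z = TRUE))$angle
  expect_equal(a_m, 180 - a)
  # degenerate lipid
  t5 <- one_lipid_traj(nc3 = c(0, 0, 0), c4a = c(0, 0, 0), c4b = c(0, 0, 0))
  expect_error(compute_angle_traces(t5), "degenerate-lipid")
})

test_that("running mean uses centered truncated windows", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(running_mean(x, 3), c(1.5, 2, 3, 4, 4.5))
  expect_equal(running_mean(x, 1), x)
  expect_equal(running_mean(rep(7, 10), 5), rep(7, 10))
})

test_that("leaflet assignment uses the inclusive 90-degree convention", {
  tr <- trace_from_smoothed(c(89.999, 90, 90.001))
  lab <- assign_leaflets_per_frame(tr)
  expect_equal(lab$leaflet, c("lower", "upper", "upper"))
})

test_that("event detection follows the hysteresis state machine", {
  # monotone crossing: one event at the first frame <= 35
  s <- seq(150, 30, length.out = 121)
  ev <- detect_events(trace_from_smoothed(s))
  expect_equal(nrow(ev), 1)
  expect_equal(ev$direction, "upper_to_lower")
  expect_equal(ev$t_complete, which(s <= 35)[1])
  # partial transition to 60 degrees: no event
  s2 <- c(seq(150, 60, length.out = 50), seq(60, 150, length.out = 50))
  expect_equal(nrow(detect_events(trace_from_smoothed(s2))), 0)
  # full round trip: one event in each direction
  s3 <- c(seq(150, 30, length.out = 60), seq(30, 150, length.out = 60))
  ev3 <- detect_events(trace_from_smoothed(s3))
  expect_equal(ev3$direction, c("upper_to_lower", "lower_to_upper"))
  # repeated transits each count
  s4 <- rep(c(seq(150, 30, length.out = 40),
              seq(30, 150, length.out = 40)), 3)
  expect_equal(nrow(detect_events(trace_from_smoothed(s4))), 6)
})

test_that("transition window opens at the last frame beyond the reference angle", {
  s <- c(rep(155, 10), seq(155, 30, length.out = 51))
  ev <- detect_events(trace_from_smoothed(s))
  # last frame >= 150: index 12 of the descent (155, 152.5, 150, ...)
  expect_equal(ev$t_entry, max(which(s >= 150)))
  expect_lt(ev$t_entry, ev$t_complete)
})

test_that("event counts are invariant under rigid motion and z-mirror flips directions", {
  spec <- bilayer_spec(lipids_per_leaflet = 16, box_xy = c(40, 40),
                       sigma = 0.5, seed = 9)
  traj <- make_bilayer(spec, n_frames = 500)
  sch <- tibble::tibble(lipid = c(3L, 21L), t_start = c(150, 300),
                        duration = 20)
  traj <- apply_flips(traj, sch)
  ev0 <- detect_events(compute_angle_traces(traj))
  moved <- transform_trajectory(traj, shift = c(11, -4, 3), zrot = 0.7)
  ev1 <- detect_events(compute_angle_traces(moved))
  expect_equal(ev1[, c("lipid", "direction", "t_complete")],
               ev0[, c("lipid", "direction", "t_complete")])
  mirrored <- transform_trajectory(traj, mirror_z = TRUE)
  ev2 <- detect_events(compute_angle_traces(mirrored))
  expect_equal(nrow(ev2), nrow(ev0))
  swap <- c(upper_to_lower = "lower_to_upper",
            lower_to_upper = "upper_to_lower")
  expect_equal(ev2$direction, unname(swap[ev0$direction]))
})

test_that("block-averaged rates reproduce printed-count arithmetic", {
  # uniform stream with the strongest scrambler's count over 9 us
  times <- 9000 * (seq_len(220) - 0.5) / 220
  r <- estimate_rate(times, 9000)
  expect_equal(round(r$mean_rate, 1), 24.4)
  expect_equal(r$mean_rate, 220 / 9)
  # no events
  r0 <- estimate_rate(numeric(), 9000)
  expect_equal(r0$mean_rate, 0)
  expect_equal(r0$sd_rate, 0)
  # exactly one event per block: zero variance
  r1 <- estimate_rate(500 + 0:8 * 1000, 9000)
  expect_equal(r1$mean_rate, 1)
  expect_equal(r1$sd_rate, 0)
  expect_error(estimate_rate(1:3, 500), "shorter than one block")
  # trailing partial block dropped, with its events
  r2 <- estimate_rate(c(500, 1500, 2500, 3100), 3500)
  expect_equal(r2$n_blocks, 3)
  expect_equal(r2$mean_rate, 1)
  expect_equal(r2$n_dropped, 1)
  # tidy/glance accessors
  expect_equal(nrow(tidy(r1)), 9)
  expect_equal(glance(r1)$n_events, 9)
})

test_that("maximum-density pathway follows constructed ridges", {
  # single high-density vertical column
  a <- array(0, dim = c(21, 21, 30))
  a[8, 13, ] <- 100
  g <- grid_from_array(a, origin = c(0, 0, -15), spacing = 1)
  p <- build_density_path(g)
  expect_true(all(p$x == 7.5))
  expect_true(all(p$y == 12.5))
  expect_true(all(diff(p$z) < 0))
  # helical ridge recovered within one voxel
  a2 <- array(0, dim = c(41, 41, 40))
  zc <- -20 + (1:40) - 0.5
  hx <- 20.5 + 8 * cos(2 * pi * zc / 40)
  hy <- 20.5 + 8 * sin(2 * pi * zc / 40)
  for (k in 1:40) {
    a2[round(hx[k]) , round(hy[k]), k] <- 50
  }
  g2 <- grid_from_array(a2, origin = c(0, 0, -20), spacing = 1)
  p2 <- build_density_path(g2)
  ord <- order(p2$z)
  expect_lt(max(abs(p2$x[ord] - (round(hx) - 0.5))), 1.5)
  expect_lt(max(abs(p2$y[ord] - (round(hy) - 0.5))), 1.5)
  # uniform density: ambiguous, ties flagged
  a3 <- array(1, dim = c(5, 5, 6))
  g3 <- grid_from_array(a3, origin = c(0, 0, -3), spacing = 1)
  expect_warning(build_density_path(g3), "tied maxima")
  # all-empty grid
  a4 <- array(0, dim = c(5, 5, 6))
  expect_error(build_density_path(grid_from_array(a4, c(0, 0, -3), 1)),
               "path error")
  # zero-density layers interpolated linearly
  a5 <- array(0, dim = c(11, 11, 10))
  a5[3, 3, c(1:4, 7:10)] <- 9
  g5 <- grid_from_array(a5, origin = c(0, 0, -5), spacing = 1)
  p5 <- build_density_path(g5)
  expect_true(all(is.finite(p5$x)))
})

test_that("in/out-of-groove classification respects the 4.7 A cutoff inclusively", {
  # hand-built: a lipid flipping in place, a vertical pathway at a known
  # lateral distance
  mk_flip_traj <- function() {
    nf <- 40
    z <- seq(15, -15, length.out = nf)
    nc3 <- cbind(0, 0, z + 5)
    c4a <- cbind(0.5, 0, z - 5)
    c4b <- cbind(-0.5, 0, z - 5)
    one_lipid_traj(nc3, c4a, c4b, n_frames = nf)
  }
  traj <- mk_flip_traj()
  ev <- tibble::tibble(lipid = 1L, direction = "upper_to_lower",
                       t_entry = 1, t_complete = 40)
  path_at <- function(dx) tibble::tibble(x = dx, y = 0, z = seq(25, -25))
  # PO4 sits at x = 0.25 during the whole descent
  hit <- classify_events(ev, traj, path_at(0.25 + 4.7))
  expect_equal(hit$pathway, "in_groove")
  expect_equal(hit$min_path_dist, 4.7, tolerance = 1e-9)
  miss <- classify_events(ev, traj, path_at(0.25 + 4.7 + 1e-6))
  expect_equal(miss$pathway, "out_of_groove")
  # cleft sub-label: nearer the registered cleft site than the pathway
  lab <- classify_events(ev, traj, path_at(20), cleft_site = c(1, 0))
  expect_equal(lab$sub_label, "dimer_cleft")
  lab2 <- classify_events(ev, traj, path_at(6), cleft_site = c(30, 0))
  expect_equal(lab2$sub_label, "other")
  # event window outside trajectory
  bad <- tibble::tibble(lipid = 1L, direction = "upper_to_lower",
                        t_entry = 1, t_complete = 99)
  expect_error(classify_events(bad, traj, path_at(3)), "consistency error")
})

test_that("scripted groove and cleft flips classify by construction", {
  spec <- bilayer_spec(lipids_per_leaflet = 36, box_xy = c(57, 57),
                       sigma = 0.5, seed = 4)
  traj <- make_bilayer(spec, n_frames = 900)
  groove_xy <- c(19, 19)
  cleft_xy <- c(43, 43)
  lip_g <- nearest_lipids(traj, groove_xy, "upper", 2)
  lip_c <- nearest_lipids(traj, cleft_xy, "upper", 1)
  sch <- tibble::tibble(
    lipid = c(lip_g, lip_c),
    t_start = c(200, 500, 350),
    duration = 20,
    x_path = c(groove_xy[1], groove_xy[1], cleft_xy[1]),
    y_path = c(groove_xy[2], groove_xy[2], cleft_xy[2]))
  traj <- apply_flips(traj, sch)
  traj <- add_protein_scaffold(traj, groove_xy, separation = 8,
                               cleft_center = cleft_xy)
  ev <- detect_events(compute_angle_traces(traj))
  expect_equal(nrow(ev), 3)
  cl <- classify_events(ev, traj, attr(traj, "groove_path"))
  got <- cl$pathway[match(sch$lipid, cl$lipid)]
  expect_equal(got, c("in_groove", "in_groove", "out_of_groove"))
  expect_equal(cl$sub_label[cl$lipid == lip_c], "dimer_cleft")
})

test_that("dispersion test calibrates under the Poisson null and rejects structure", {
  set.seed(1234)
  pass <- logical(200)
  for (i in seq_len(200)) {
    n <- rpois(1, 90)
    pt <- poisson_interval_test(sort(runif(n, 0, 9000)), 9000)
    pass[i] <- !pt$insufficient && pt$p.value > 0.05
  }
  expect_gte(mean(pass), 0.9)
  # perfectly regular stream: underdispersed, rejected
  reg <- poisson_interval_test(seq(100, 9000, by = 100), 9000)
  expect_lt(reg$dispersion, 0.1)
  expect_lt(reg$p.value, 0.05)
  # fully clustered stream: overdispersed, rejected
  clus <- poisson_interval_test(runif(90, 4000, 4999), 9000)
  expect_gt(clus$dispersion, 1)
  expect_lt(clus$p.value, 0.05)
  # insufficient data flag below 10 events
  few <- poisson_interval_test(c(100, 200, 300), 9000)
  expect_true(few$insufficient)
  expect_true(is.na(few$p.value))
})
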