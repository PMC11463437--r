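test_that("flat leaflet surfaces average to the construction heights", {
  traj <- flat_bilayer(n_frames = 120, sigma = 0)
  tr <- compute_angle_traces(traj)
  surf <- average_surfaces(traj, assign_leaflets_per_frame(tr))
  expect_true(all(abs(surf$upper$z[surf$upper$mask] - 15) < 1e-9))
  expect_true(all(abs(surf$lower$z[surf$lower$mask] + 15) < 1e-9))
  # static labels give the same result for a non-scrambling bilayer
  surf2 <- average_surfaces(traj)
  expect_equal(surf2$upper$z[surf2$upper$mask],
               surf$upper$z[surf$upper$mask])
})

test_that("occupancy and connectivity filters remove holes and islands", {
  # hand-built single-frame scatter: dense sheet with a hole, plus an island
  set.seed(8)
  n <- 4000
  xy <- cbind(runif(n, 0, 40), runif(n, 0, 40))
  hole <- (xy[, 1] - 15)^2 + (xy[, 2] - 15)^2 < 6^2
  xy <- xy[!hole, ]
  island <- cbind(runif(4, 34, 35), runif(4, 34, 35))
  moat <- xy[, 1] > 30 & xy[, 2] > 30
  pts <- rbind(xy[!moat, ], island)
  nl <- nrow(pts)
  lip <- tibble::tibble(lipid = seq_len(nl),
                        NC3 = 0:(nl - 1) * 6 + 1, PO4 = 0:(nl - 1) * 6 + 2,
                        GL1 = 0:(nl - 1) * 6 + 3, GL2 = 0:(nl - 1) * 6 + 4,
                        C4A = 0:(nl - 1) * 6 + 5, C4B = 0:(nl - 1) * 6 + 6,
                        leaflet = "upper")
  co <- array(0, dim = c(nl * 6, 3, 1))
  for (i in seq_len(nl)) {
    for (b in 1:6) co[(i - 1) * 6 + b, , 1] <- c(pts[i, ], 15)
    co[(i - 1) * 6 + 5, 3, 1] <- 3   # tails below (angle defined)
    co[(i - 1) * 6 + 6, 3, 1] <- 3
  }
  # a token lower leaflet so both masks exist
  lower <- flat_bilayer(n_frames = 1, sigma = 0, lipids = 16,
                        box = c(40, 40))
  low_lip <- lower$topology$lipids[lower$topology$lipids$leaflet == "lower", ]
  nlow <- nrow(low_lip)
  co2 <- array(0, dim = c((nl + nlow) * 6, 3, 1))
  co2[seq_len(nl * 6), , ] <- co
  for (j in seq_len(nlow)) {
    src <- as.integer(low_lip[j, c("NC3", "PO4", "GL1", "GL2", "C4A", "C4B")])
    dst <- (nl + j - 1) * 6 + 1:6
    co2[dst, , 1] <- lower$coords[src, , 1]
  }
  lip_all <- dplyr::bind_rows(
    lip,
    tibble::tibble(lipid = nl + seq_len(nlow),
                   NC3 = (nl + 0:(nlow - 1)) * 6 + 1,
                   PO4 = (nl + 0:(nlow - 1)) * 6 + 2,
                   GL1 = (nl + 0:(nlow - 1)) * 6 + 3,
                   GL2 = (nl + 0:(nlow - 1)) * 6 + 4,
                   C4A = (nl + 0:(nlow - 1)) * 6 + 5,
                   C4B = (nl + 0:(nlow - 1)) * 6 + 6,
                   leaflet = "lower"))
  topo <- cg_topology(lipids = lip_all, n_beads = (nl + nlow) * 6)
  traj <- cg_trajectory(co2, times = 1, box = c(40, 40, 100),
                        topology = topo)
  surf <- average_surfaces(traj, spacing = 1, occupancy_min = 0.5)
  # center of the lipid-free disk is masked out
  expect_false(surf$upper$mask[16, 16])
  # the isolated island beyond the masked moat is removed
  expect_false(any(surf$upper$mask[35:36, 35:36]))
  # bulk sheet survives
  expect_true(surf$upper$mask[6, 6])
})

test_that("minimal thickness matches constructions and a brute-force oracle", {
  traj <- flat_bilayer(n_frames = 100, sigma = 0)
  surf <- average_surfaces(traj, NULL)
  expect_equal(min_thickness(surf)$min_thickness, 30, tolerance = 1e-6)

  # single-node bump: upper flat at +15, one lower node raised to +1
  surf_b <- surf
  i <- which(surf_b$lower$mask, arr.ind = TRUE)[40, ]
  surf_b$lower$z[i[1], i[2]] <- 1
  mt <- min_thickness(surf_b)
  expect_equal(mt$min_thickness, 14, tolerance = 1e-9)

  # seeded random smooth surfaces: equals exhaustive all-pairs minimum
  brute <- function(s) {
    U <- cbind(expand.grid(x = s$x, y = s$y)[as.vector(s$upper$mask), ],
               z = s$upper$z[s$upper$mask])
    L <- cbind(expand.grid(x = s$x, y = s$y)[as.vector(s$lower$mask), ],
               z = s$lower$z[s$lower$mask])
    min(sqrt(outer(rowSums(U^2), rowSums(L^2), `+`) -
               2 * as.matrix(U) %*% t(as.matrix(L))))
  }
  for (seed in 1:20) {
    set.seed(seed)
    s <- surf
    nx <- length(s$x)
    ny <- length(s$y)
    bump <- function(amp) {
      cx <- runif(1, 10, 60); cy <- runif(1, 10, 60); w <- runif(1, 5, 15)
      g <- outer(s$x, s$y, function(x, y) {
        amp * exp(-((x - cx)^2 + (y - cy)^2) / (2 * w^2))
      })
      g
    }
    s$upper$z <- s$upper$z - bump(runif(1, 0, 9))
    s$lower$z <- s$lower$z + bump(runif(1, 0, 9))
    expect_equal(min_thickness(s)$min_thickness, brute(s),
                 tolerance = 1e-9)
  }
})

test_that("scripted thinning spans the reported deformation range", {
  for (thin in c(0, 7, 16, 18)) {
    tf <- if (thin == 0) {
      NULL
    } else {
      local({
        th <- thin
        function(x, y) ifelse((x - 38)^2 + (y - 38)^2 < 12^2, th, 0)
      })
    }
    traj <- flat_bilayer(n_frames = 120, sigma = 0, thickness_field = tf,
                         seed = thin + 1)
    surf <- average_surfaces(traj, NULL)
    expect_equal(min_thickness(surf)$min_thickness, 30 - thin,
                 tolerance = 1)
  }
})

test_that("surface averaging is linear over disjoint frame blocks", {
  traj <- flat_bilayer(n_frames = 60, sigma = 0.4, seed = 12)
  s_all <- average_surfaces(traj, NULL)
  s_a <- average_surfaces(subset_frames_for_test(traj, 1:20), NULL)
  s_b <- average_surfaces(subset_frames_for_test(traj, 21:60), NULL)
  # deposited-weight-weighted recombination reproduces the pooled mean
  w_a <- s_a$upper$weight
  w_b <- s_b$upper$weight
  z_comb <- matrix(NA_real_, nrow(w_a), ncol(w_a))
  nz <- (w_a + w_b) > 0
  za <- s_a$upper$z
  zb <- s_b$upper$z
  za[is.na(za)] <- 0
  zb[is.na(zb)] <- 0
  z_comb[nz] <- (za * w_a + zb * w_b)[nz] / (w_a + w_b)[nz]
  m <- s_all$upper$mask
  expect_equal(z_comb[m], s_all$upper$z[m], tolerance = 1e-9)
  # occupancy bookkeeping combines by frame counts exactly
  occ_split <- (20 * s_a$upper$occupancy + 40 * s_b$upper$occupancy) / 60
  expect_equal(s_all$upper$occupancy, occ_split, tolerance = 1e-12)
})

test_that("density grids conserve raw counts and match a histogram oracle", {
  traj <- flat_bilayer(n_frames = 40, sigma = 0.5, seed = 3)
  beads <- traj$topology$lipids$PO4
  g <- accumulate_density(traj, beads, center = c(38, 38, 0),
                          extent = c(80, 80, 60), spacing = 1)
  expect_equal(sum(g$counts), g$n_inbounds)
  expect_equal(g$n_inbounds + g$n_out, length(beads) * n_frames(traj))

  # brute-force binning oracle on uniform random beads
  set.seed(21)
  nb <- 50
  co <- array(runif(nb * 3 * 10, 0, 20), dim = c(nb, 3, 10))
  topo <- cg_topology(lipids = empty_lipids(), waters = seq_len(nb),
                      n_beads = nb)
  tr <- cg_trajectory(co, 1:10, c(20, 20, 20), topo)
  g2 <- accumulate_density(tr, seq_len(nb), center = c(10, 10, 10),
                           extent = c(20, 20, 20), spacing = 2)
  oracle <- array(0L, dim = g2$dims)
  for (f in 1:10) {
    for (b in seq_len(nb)) {
      v <- floor((co[b, , f] - g2$origin) / 2) + 1
      if (all(v >= 1) && all(v <= g2$dims)) {
        oracle[v[1], v[2], v[3]] <- oracle[v[1], v[2], v[3]] + 1L
      }
    }
  }
  expect_equal(g2$counts, oracle, ignore_attr = TRUE)
  # static beads at one voxel center
  co3 <- array(rep(c(5, 5, 5), each = 1), dim = c(1, 3, 7))
  topo3 <- cg_topology(lipids = empty_lipids(), waters = 1L, n_beads = 1)
  tr3 <- cg_trajectory(co3, 1:7, c(10, 10, 10), topo3)
  g3 <- accumulate_density(tr3, 1L, center = c(5, 5, 5),
                           extent = c(10, 10, 10), spacing = 1)
  expect_equal(max(g3$counts), 7)
  expect_equal(sum(g3$counts), 7)
  expect_error(accumulate_density(tr3, 1L, extent = c(0, 10, 10)),
               "zero-extent")
})

test_that("OpenDX output is well-formed and complete", {
  a <- array(seq_len(2 * 3 * 4), dim = c(2, 3, 4))
  g <- grid_from_array(a, origin = c(0, 0, 0), spacing = 0.5)
  f <- withr::local_tempfile()
  write_dx(g, f)
  lines <- readLines(f)
  expect_match(lines[1], "gridpositions counts 2 3 4")
  vals <- as.numeric(unlist(strsplit(lines[8:15], " ")))
  expect_equal(sort(vals), as.numeric(1:24))
})

test_that("Boltzmann inversion recovers constructed free-energy profiles", {
  dims <- c(21, 21, 40)
  Fstar <- function(z) 1.5 * (1 - cos(2 * pi * z / 40)) / 2
  a <- array(0, dim = dims)
  zc <- -20 + (1:40) - 0.5
  for (k in 1:40) a[, , k] <- 1e6 * exp(-Fstar(zc[k]))
  g <- grid_from_array(a, origin = c(0, 0, -20), spacing = 1)
  path <- tibble::tibble(x = 10.5, y = 10.5, z = rev(zc))
  pmf <- pmf_from_density(g, path, tube_radius = 5)
  expect_lt(max(abs(pmf$free_energy - (Fstar(pmf$z) - min(Fstar(zc))))),
            0.05)
  expect_equal(min(pmf$free_energy), 0)
  # uniform density: identically zero
  g2 <- g
  g2$counts[] <- 4
  expect_true(all(pmf_from_density(g2, path, 5)$free_energy == 0))
  # density at rho_max / e gives exactly 1 kT
  g3 <- g
  g3$counts[] <- 100
  g3$counts[, , 20] <- 100 / exp(1)
  pmf3 <- pmf_from_density(g3, path, tube_radius = 30)
  expect_equal(pmf3$free_energy[pmf3$z == zc[20]], 1, tolerance = 1e-12)
  # empty slabs flagged as +Inf
  g4 <- g
  g4$counts[, , 10] <- 0
  pmf4 <- pmf_from_density(g4, path, tube_radius = 5)
  expect_true(pmf4$empty[pmf4$z == zc[10]])
  expect_true(is.infinite(pmf4$free_energy[pmf4$z == zc[10]]))
  g5 <- g
  g5$counts[] <- 0
  expect_error(pmf_from_density(g5, path, 5), "all-zero tube")
})
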