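# Hand-built minimal fixtures used across test files. Everything is
# generated in code; no binary data.

# A protein-free topology with `n` empty lipid slots (for trajectories that
# only need raw beads).
empty_lipids <- function() {
  tibble::tibble(lipid = integer(), NC3 = integer(), PO4 = integer(),
                 GL1 = integer(), GL2 = integer(), C4A = integer(),
                 C4B = integer(), leaflet = character())
}

# Single-lipid trajectory with explicit per-frame bead coordinates.
# `nc3`, `c4a`, `c4b` are 3-vectors or n_frames x 3 matrices.
one_lipid_traj <- function(nc3, c4a, c4b, n_frames = 1) {
  as_mat <- function(v) {
    if (is.null(dim(v))) matrix(v, n_frames, 3, byrow = TRUE) else v
  }
  nc3 <- as_mat(nc3); c4a <- as_mat(c4a); c4b <- as_mat(c4b)
  lip <- tibble::tibble(lipid = 1L, NC3 = 1L, PO4 = 2L, GL1 = 3L, GL2 = 4L,
                        C4A = 5L, C4B = 6L, leaflet = "unassigned")
  topo <- cg_topology(lipids = lip, n_beads = 6L)
  co <- array(0, dim = c(6, 3, n_frames))
  for (f in seq_len(n_frames)) {
    co[1, , f] <- nc3[f, ]
    co[2, , f] <- (nc3[f, ] + c4a[f, ]) / 2
    co[3, , f] <- nc3[f, ] + c(0.5, 0, 0)
    co[4, , f] <- nc3[f, ] - c(0.5, 0, 0)
    co[5, , f] <- c4a[f, ]
    co[6, , f] <- c4b[f, ]
  }
  cg_trajectory(co, seq_len(n_frames), c(100, 100, 100), topo)
}

# Traces tibble for a single lipid from a raw smoothed-angle series (the
# detector consumes smoothed traces; tests can feed the series directly).
trace_from_smoothed <- function(s, lipid = 1L) {
  tibble::tibble(lipid = lipid, time = seq_along(s), angle = s,
                 angle_smooth = s,
                 leaflet = ifelse(s >= 90, "upper", "lower"))
}

# Small standard bilayer used by several membrane tests.
flat_bilayer <- function(n_frames = 150, sigma = 0, seed = 1,
                         thickness_field = NULL, lipids = 64,
                         box = c(76, 76)) {
  make_bilayer(bilayer_spec(lipids_per_leaflet = lipids, box_xy = box,
                            sigma = sigma, thickness_field = thickness_field,
                            seed = seed),
               n_frames = n_frames)
}

# Frame subset without touching package internals.
subset_frames_for_test <- function(traj, keep) {
  traj$coords <- traj$coords[, , keep, drop = FALSE]
  traj$times <- traj$times[keep]
  traj$box <- traj$box[keep, , drop = FALSE]
  traj
}

# Density grid object built directly from an array (for oracle tests).
grid_from_array <- function(counts, origin, spacing) {
  structure(list(counts = counts, origin = origin, spacing = spacing,
                 dims = dim(counts), n_frames = 1,
                 n_inbounds = sum(counts), n_out = 0),
            class = "density_grid")
}
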