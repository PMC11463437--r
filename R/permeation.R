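#' Count permeation events along a membrane-spanning pathway
#'
#' A particle completes a permeation event when it moves from below the
#' lower slab boundary to above the upper one (or the reverse) while every
#' frame it spends inside the slab lies within `tube_radius` of the pathway
#' polyline. Particles that leave the tube mid-slab are not counted;
#' returning to the origin side resets the state machine.
#'
#' @param traj A [cg_trajectory()].
#' @param species `"water"`, `"Na"` or `"Cl"`.
#' @param path Pathway polyline tibble (`x`, `y`, `z`); defaults to the
#'   trajectory's registered `"groove_path"`.
#' @param tube_radius Tube radius (A, default 8).
#' @param slab Length-2 slab bounds `c(z_lower, z_upper)` (A); by
#'   convention the leaflet-surface heights at the groove +/- 2 A.
#' @return Tibble of events: `particle` (bead index), `species`, `direction`
#'   (`"up"`/`"down"`), `t_entry`, `t_exit` (ns).
#' @export
count_permeation <- function(traj, species = c("water", "Na", "Cl"),
                             path = NULL, tube_radius = 8,
                             slab = c(-15, 15)) {
  species <- match.arg(species)
  if (slab[1] >= slab[2]) {
    stop("spec error: slab bounds inverted", call. = FALSE)
  }
  if (is.null(path)) {
    path <- attr(traj, "groove_path")
    if (is.null(path)) {
      stop("spec error: no pathway; supply `path`", call. = FALSE)
    }
  }
  beads <- if (species == "water") {
    traj$topology$waters
  } else {
    traj$topology$ions$bead[traj$topology$ions$species == species]
  }
  events <- list()
  tt <- traj$times
  # lateral tube check: interpolate the path xy at the particle's z
  pz <- path$z
  ord <- order(pz)
  for (b in beads) {
    x <- traj$coords[b, 1, ]
    y <- traj$coords[b, 2, ]
    z <- traj$coords[b, 3, ]
    zone <- ifelse(z < slab[1], -1L, ifelse(z > slab[2], 1L, 0L))
    inside <- zone == 0L
    lat_ok <- rep(TRUE, length(z))
    if (any(inside)) {
      px <- stats::approx(pz[ord], path$x[ord], xout = z[inside],
                          rule = 2)$y
      py <- stats::approx(pz[ord], path$y[ord], xout = z[inside],
                          rule = 2)$y
      lat_ok[inside] <- (x[inside] - px)^2 + (y[inside] - py)^2 <=
        tube_radius^2
    }
    origin <- 0L      # side the particle last occupied (0 = unset)
    t_entry <- NA_real_
    violated <- FALSE
    for (f in seq_along(z)) {
      if (zone[f] != 0L) {
        if (origin != 0L && zone[f] == -origin && !violated) {
          events[[length(events) + 1L]] <- tibble::tibble(
            particle = b, species = species,
            direction = if (origin < 0L) "up" else "down",
            t_entry = if (is.na(t_entry)) tt[f] else t_entry,
            t_exit = tt[f])
        }
        origin <- zone[f]
        t_entry <- NA_real_
        violated <- FALSE
      } else if (origin != 0L) {
        if (is.na(t_entry)) t_entry <- tt[f]
        if (!lat_ok[f]) violated <- TRUE
      }
    }
  }
  if (length(events) == 0) {
    return(tibble::tibble(particle = integer(), species = character(),
                          direction = character(), t_entry = numeric(),
                          t_exit = numeric()))
  }
  dplyr::bind_rows(events)
}

#' Permeation count summary and cation-to-anion selectivity
#'
#' Counts events per species and reports the selectivity ratio
#' `P_Na/P_Cl = count(Na) / count(Cl)` from total counts. A low-count flag
#' is set when either ion count is below 10 (count-ratio selectivities from
#' few events are statistically fragile); a zero Cl count leaves the ratio
#' undefined (`NA`) with the flag set.
#'
#' @param events Event tibble from [count_permeation()] (possibly several
#'   species bound together).
#' @return One-row tibble: `n_water`, `n_na`, `n_cl`, `selectivity_na_cl`,
#'   `low_count`.
#' @export
selectivity <- function(events) {
  n_w <- sum(events$species == "water")
  n_na <- sum(events$species == "Na")
  n_cl <- sum(events$species == "Cl")
  ratio <- if (n_cl == 0) NA_real_ else n_na / n_cl
  tibble::tibble(n_water = n_w, n_na = n_na, n_cl = n_cl,
                 selectivity_na_cl = ratio,
                 low_count = n_na < 10 || n_cl < 10)
}
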