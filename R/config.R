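#' Analysis configuration
#'
#' Collects every fixed constant of the analysis pipeline in one place, with
#' the defaults used throughout: 1 us equilibration, 35/145 degree far
#' thresholds with 150/30 degree leaflet reference angles, a 100 ns running
#' average, 1 us rate blocks, 7 A contacts with 6 ns gap tolerance, a 6 A
#' groove-open threshold and 14 A thickness threshold, a 4.7 A in-groove
#' pathway cutoff, 1 A surface grids with a 2% occupancy filter, 100x100x150 A
#' density grids at 0.5 A spacing, EWMA smoothing factor 0.1 and 310 K.
#'
#' @param equilibration_ns Equilibration cutoff (ns).
#' @param angle_lower,angle_upper Far thresholds for event completion
#'   (degrees).
#' @param ref_lower,ref_upper Leaflet reference angles (degrees) used to set
#'   the transition-window entry point.
#' @param smooth_window_ns Running-average window for angle traces (ns).
#' @param block_ns Block length for rate averaging (ns).
#' @param contact_cutoff Contact distance cutoff (A, strict `<`).
#' @param gap_ns Dwell-time gap tolerance (ns).
#' @param groove_open Groove-open TM4-TM6 distance threshold (A).
#' @param thickness_open Membrane-thickness threshold for robust scrambling
#'   (A).
#' @param pathway_cutoff In-groove classification cutoff: maximum PO4 distance
#'   to the maximum-density pathway (A, inclusive).
#' @param surface_spacing Leaflet-surface grid spacing (A).
#' @param occupancy_min Minimum lipid occupancy fraction for a surface grid
#'   node.
#' @param density_extent Density-grid extent (A, length 3).
#' @param density_spacing Density-grid voxel spacing (A).
#' @param ewma_factor Smoothing factor of the recursive exponentially weighted
#'   moving average.
#' @param temperature Temperature (K); free-energy profiles are reported in
#'   kT so this only matters for unit conversion.
#'
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(equilibration_ns = 1000,
                            angle_lower = 35, angle_upper = 145,
                            ref_lower = 30, ref_upper = 150,
                            smooth_window_ns = 100,
                            block_ns = 1000,
                            contact_cutoff = 7,
                            gap_ns = 6,
                            groove_open = 6,
                            thickness_open = 14,
                            pathway_cutoff = 4.7,
                            surface_spacing = 1,
                            occupancy_min = 0.02,
                            density_extent = c(100, 100, 150),
                            density_spacing = 0.5,
                            ewma_factor = 0.1,
                            temperature = 310) {
  cfg <- list(
    equilibration_ns = equilibration_ns,
    angle_lower = angle_lower, angle_upper = angle_upper,
    ref_lower = ref_lower, ref_upper = ref_upper,
    smooth_window_ns = smooth_window_ns,
    block_ns = block_ns,
    contact_cutoff = contact_cutoff,
    gap_ns = gap_ns,
    groove_open = groove_open,
    thickness_open = thickness_open,
    pathway_cutoff = pathway_cutoff,
    surface_spacing = surface_spacing,
    occupancy_min = occupancy_min,
    density_extent = density_extent,
    density_spacing = density_spacing,
    ewma_factor = ewma_factor,
    temperature = temperature
  )
  lengths_pos <- c("smooth_window_ns", "block_ns", "contact_cutoff",
                   "groove_open", "thickness_open", "pathway_cutoff",
                   "surface_spacing", "density_spacing")
  for (nm in lengths_pos) {
    if (cfg[[nm]] <= 0) stop("config error: ", nm, " must be > 0", call. = FALSE)
  }
  if (cfg$angle_lower >= cfg$angle_upper) {
    stop("config error: angle_lower must be below angle_upper", call. = FALSE)
  }
  structure(cfg, class = "analysis_config")
}

#' Registry of TM4/TM6 groove residue ranges per homolog
#'
#' Residue ranges (experimental numbering) used for the TM4-TM6 groove
#' dilation distance, one 13-residue span per helix per homolog. The TMEM16F
#' TM4 span is 512-524.
#'
#' @return Tibble with columns `homolog`, `tm4_first`, `tm4_last`,
#'   `tm6_first`, `tm6_last`.
#' @export
tm_groove_ranges <- function() {
  tibble::tribble(
    ~homolog,    ~tm4_first, ~tm4_last, ~tm6_first, ~tm6_last,
    "nhTMEM16",  327L, 339L, 430L, 452L,
    "afTMEM16",  319L, 331L, 426L, 438L,
    "TMEM16K",   365L, 377L, 434L, 446L,
    "TMEM16F",   512L, 524L, 613L, 625L,
    "TMEM16A",   541L, 553L, 635L, 647L
  )
}

#' Published scrambling event counts per structure
#'
#' In-groove and out-of-groove scrambling event counts and block-averaged
#' rates for the surveyed TMEM16 structures (18 systems, 9 us of analysed
#' trajectory each), shipped as plain-text package data. These printed counts
#' are inputs for rate-arithmetic reconstruction: a uniform event stream with
#' `total` events over 9 us, block-averaged at 1 us, reproduces `rate_mean`.
#'
#' @return Tibble with columns `homolog`, `structure`, `in_groove`,
#'   `out_groove`, `total`, `rate_mean`, `rate_sd`.
#' @export
scrambling_event_counts <- function() {
  path <- system.file("extdata", "scrambling_event_counts.csv",
                      package = "memscramble", mustWork = TRUE)
  tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
}
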