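---
title: "Quantifying lipid scrambling in coarse-grained membrane simulations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying lipid scrambling in coarse-grained membrane simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Scramblases such as the TMEM16 family catalyse passive flip-flop of
phospholipids between bilayer leaflets, most prominently through a hydrophilic
groove between transmembrane helices TM4 and TM6 ("credit-card" scrambling:
the headgroup slides along the polar groove while the tails stay in the
membrane core). Coarse-grained MD (Martini-style, ~4 heavy atoms per bead)
reaches the multi-microsecond timescales where hundreds of such events occur,
but turning raw bead trajectories into defensible scrambling statistics takes
a pipeline of interlocking conventions — orientation angles, smoothing,
hysteresis thresholds, block averaging, surface construction, contact rules.
`memscramble` implements that pipeline as tested, reusable R code, together
with a synthetic trajectory generator that provides exact ground truth for
every stage.

## Event detection model

For each lipid and frame the orientation vector is the mean of the two
choline-to-terminal-tail bead vectors,
$v = \tfrac12\,[(\mathrm{C4A}-\mathrm{NC3}) + (\mathrm{C4B}-\mathrm{NC3})]$,
and the orientation angle is $\theta = \arccos(v_z/\lVert v\rVert)$ in
degrees. Upper-leaflet lipids sit near 150–180°, lower-leaflet lipids near
0–30°. Raw traces are noisy at CG resolution, so each trace is smoothed with
a 100 ns running average before any decision is made.

Detection is a hysteresis state machine. A lipid's leaflet state is
initialized by the side of 90° of its first smoothed angle and changes
*only* at far-threshold crossings: an upper-leaflet lipid completes an event
when its smoothed angle reaches ≤ 35°, a lower-leaflet lipid at ≥ 145°.
These far thresholds (rather than, say, 55°/125°) deliberately reject
partial transitions — excursions that cross the 90° midline but turn back
never fire. Repeated back-and-forth transits each count, in both directions.

Three conventions here were genuinely open and are the package's choices:

* **Centered smoothing.** A "running average" can be trailing or centered;
  we use a centered window (truncated at the trace edges) because a trailing
  window systematically lags completion times by half a window. The
  remaining timing uncertainty of a detected completion is about half the
  smoothing window (±50 ns at defaults); the synthetic-data tests assert
  recovery of scripted completion times to within one full window.
* **Initial leaflet by first smoothed angle.** With reference angles of
  150°/30° for the two leaflets, the 90° midline is the natural separatrix.
* **Transition window.** For pathway classification each event needs a time
  window, which the detection rule itself does not define. We open the
  window at the last frame the smoothed trace was beyond the origin-leaflet
  reference angle (≥ 150° or ≤ 30°) before the completion frame.

### Rates

Rates are block averages: the analysed window (production time after
discarding the first microsecond for equilibration) is tiled with 1 µs
blocks, a trailing partial block is dropped, and the per-block event counts
give the mean rate and its spread. We report the *population* standard
deviation of the block counts; with only ~9 blocks the sample/population
choice changes the SD by ~6% and the published convention is not stated.
When blocks tile the window exactly the mean equals total events divided by
analysed time — the package's rate arithmetic reproduces, from the published
per-structure event counts over 9 µs, every printed rate to one decimal
(e.g. 220 events → 24.4 µs⁻¹).

### Poisson character of event streams

To ask whether events arrive independently we use the index-of-dispersion
test on 1 µs block counts: $D = s^2/\bar n$, with $(n-1)D \sim
\chi^2_{n-1}$ under a homogeneous Poisson process, two-sided. The underlying
statistical test used in the original analyses is not public; the dispersion
test is the standard choice, detects both regularity ($D \ll 1$) and
clustering ($D \gg 1$), and calibrates well at the survey's scale (simulated
null streams at 10 events/µs over 9 µs pass at ≥ 90% across seeds, by
construction of the test at the 5% level). Below 10 events we refuse to
report a p-value.

## Pathway classification

An event is "in the groove" iff, over its transition window, the minimum
distance from the lipid's PO4 bead to the maximum-density pathway is within
4.7 Å (inclusive). The pathway itself is extracted from a 3D headgroup
density grid: per 0.5 Å z-layer the maximum-density voxel center, smoothed
with a 3-layer moving average, empty layers interpolated, ties broken toward
the lowest voxel index with a warning. Out-of-groove events are sub-labelled
`dimer_cleft` when, at their midplane crossing, the headgroup is laterally
nearer a registered dimer-interface site (TM3 of one chain / TM10 of the
other) than the groove pathway.

## Membrane surfaces and minimal thickness

Each lipid's two glycerol beads are deposited onto a 1 Å xy grid with
bilinear weights ("scatter-to-grid" — the only direction in which linear
interpolation of scattered bead positions to a rectilinear grid makes sense
for surface building), separately per leaflet using the *per-frame* leaflet
assignment from the smoothed angle (≥ 90° = upper, inclusive). Averaging the
deposited heights over frames yields the two ensemble surfaces. Nodes with
lipid occupancy (fraction of frames with any deposit) below 2% are
discarded, and clusters of surviving nodes disconnected from the bulk
surface — 4-connectivity, bulk = largest connected component — are removed
so that stray lipids in a protein cavity cannot masquerade as membrane.
Minimal membrane thickness is the minimal full 3D Euclidean distance between
any two valid points of the opposing surfaces (not the vertical gap), and
the implementation is tested against an exhaustive all-pairs oracle.

The occupancy denominator is the number of *analysed* frames (after the
equilibration cut), which is the only self-consistent reading.

## Density grids and free-energy profiles

Bead densities are nearest-voxel histograms on a rectilinear grid (default
100×100×150 Å at 0.5 Å spacing, centered on the groove), with raw counts
conserved exactly — the sum of voxel counts equals the number of in-bounds
bead-frame observations, a property tested directly. Per-chain grids, built
after aligning each subunit to its own starting coordinates
(translation-only, backbone-bead centroid; rotational superposition would
distort the membrane frame), can be averaged voxel-wise. Grids are written
as plain-text OpenDX for standard visualization tools.

A free-energy profile along a pathway is obtained by Boltzmann inversion of
the mean density in a tube around the pathway, $F(s) = -\ln
\rho(s)/\rho_{\max}$ in kT — temperature-free in these units; the 310 K
configuration value exists only for conversions. Referencing $\rho_{\max}$
makes $F \ge 0$ with its minimum at 0; empty slabs are reported as `Inf`
and flagged rather than silently interpolated.

## Groove geometry

Groove dilation is the per-frame minimum distance between residue sets on
TM4 and TM6 — all beads of each residue (side-chain plus backbone, the most
inclusive reading, and what a generic minimum-distance call computes) — with
the registry of 13-residue spans per homolog (`tm_groove_ranges()`). The
published TMEM16F TM4 span contains an inconsistent second bound; we use
512–524, the unique 13-residue reading consistent with every other homolog.
Display smoothing uses the recursive EWMA $s_t = 0.1\,x_t + 0.9\,s_{t-1}$;
medians and quartiles are computed on the *raw* series — smoothing is for
visualization and threshold-crossing display only. The competence summary
combines the median groove width and the minimal membrane thickness into the
empirically motivated quadrants: robust scrambling requires thickness
< 14 Å *and* median TM4–TM6 distance > 6 Å. The dimer-cleft width applies
the same minimum-distance rule across chains, restricted to beads below the
membrane midplane (midpoint of the leaflet surface means, 0 for the
symmetric synthetic bilayers).

## Protein–lipid contacts

A contact is a distance strictly below 7 Å between the residue's outermost
side-chain bead and the lipid's NC3 or PO4 bead. "Outermost" is resolved
*per frame* (the side-chain bead farthest from the backbone bead that
frame): CG side chains move, and per-frame resolution is deterministic.
Glycine-like residues use their backbone bead. Dwell events merge
interruptions of up to 6 ns, and the dwell duration counts both endpoints
and the merged gap frames — whether gaps were included in the original
protocol's durations is not documented, so this choice is flagged for
sensitivity analysis (with 1 ns frames and ≤ 6 ns gaps it shifts long dwells
by at most a few ns). Per residue, the headgroup bead (NC3 vs PO4) with the
higher mean dwell is kept; the frequency is the contact-frame fraction
averaged over the chains carrying the residue; the "top-50%" dwell statistic
averages the longer half of the events (ceiling count when odd).

## Permeation counting

A water bead or ion completes a permeation event when it moves from below
the lower slab boundary to above the upper one (or the reverse) while every
in-slab frame lies within a tube around the pathway of maximum density.
Particles leaving the tube mid-slab are discarded; returns to the origin
side reset the state machine, so the count is time-reversal symmetric up to
direction. The tube radius (default 8 Å) and the slab convention
(leaflet-surface heights at the groove ± 2 Å) are package choices — the
original crossing criterion is not public — and both are configurable;
event counts are monotone in the tube radius, which is tested. Martini
waters are 4:1 mapped, so water counts are bead events. The cation/anion
selectivity is the count ratio Na⁺/Cl⁻, with a low-count flag below 10
events per species because count ratios from a handful of events are
statistically fragile.

## The synthetic generator: what it does and does not show

`make_bilayer()` builds a DOPC-like bilayer: 6-bead lipids on a jittered
lattice, glycerol planes at ±15 Å (bulk glycerol-to-glycerol thickness 30 Å),
choline 5 Å above the glycerol plane, terminal tails 12 Å below it, Gaussian
bead jitter (default σ = 0.5 Å), and a rigid per-lipid lateral wander that
stands in for lateral diffusion (the whole lipid translates, so orientation
angles are exactly 180°/0° at zero jitter). An optional thickness field
h(x, y) locally pinches the glycerol separation to d − h, emulating
protein-induced thinning. `apply_flips()` scripts complete flips (20 ns
default duration, matching sub-20 ns transit dwell times through open
grooves) along smooth 3D paths with continuously rotating orientation, and
partial excursions that approach but never cross the far threshold;
`add_protein_scaffold()` adds static TM4/TM6 walls at a configurable — and
per-frame variable — separation plus a TM3/TM10 cleft site;
`add_tracers()` scripts membrane crossings along the registered pathway.

The generator is deterministic (identical spec + seed gives a bit-identical
trajectory) and deliberately minimal: there are no lipid–lipid interactions,
no energetics, no protein dynamics, and the lateral motion is white noise
rather than diffusion. Consequently, passing tests demonstrate that the
*analysis* is correct — that scripted truth is recovered exactly under
realistic noise — not that any force field scrambles lipids. Statistics that
depend on real dynamics (rate magnitudes, dwell-time distributions,
selectivity values of a particular protein) cannot be validated this way and
are reconstructed instead from published event counts, which the rate
arithmetic reproduces exactly.

## Numerical choices

* Time base: frames at $t = \Delta t, 2\Delta t, \dots$ ns with constant
  spacing (validated to 10⁻⁶ ns); "discard the first microsecond" removes
  frames with $t \le 1000$ ns, and times are never re-zeroed so block edges
  stay aligned.
* All window lengths (100 ns, 1 µs, 6 ns) convert to frame counts by
  rounding to the nearest integer.
* Coordinates are Å; bead indices are 1-based; residue numbers follow the
  experimental numbering so published TM ranges apply verbatim.
* Periodic boundaries: analyses act on whole-molecule coordinates; no
  minimum-image correction is applied to distances, appropriate for a
  protein centered in a box far larger than any cutoff. Triclinic boxes and
  variable frame spacing are unsupported.
* Boundary conventions, all tested: leaflet assignment at exactly 90° is
  upper; the in-groove cutoff at exactly 4.7 Å is in; a contact at exactly
  7 Å is not a contact; smoothed-trace threshold crossings are inclusive
  (≤ 35°, ≥ 145°).
* Ties in the density-path maximum go to the lowest voxel index with a
  warning; degenerate (isotropic) alignment selections are an error, not a
  silent identity.

## Problem sizes

The shipped tests and the acceptance script use bilayers of 64 lipids per
leaflet in ~76×76 Å boxes, trajectories of 2.5–10 µs at 1 ns/frame for
detector work (including a 220-flip, 10 µs run), 120–150 frames for surface
averaging, and 0.5–1 Å grids over reduced extents for densities. These sizes
were chosen so every ground-truth property is exercised at full stringency
while the whole suite runs on a laptop core in minutes; all of them are
ordinary function arguments, and nothing in the package assumes them.

## Known limitations

* XTC/GRO trajectories have no R reader; ingest is via the plain-text
  fixture format or multi-model PDB (bio3d). Convert externally for other
  formats.
* The subunit alignment is translation-only by design; systems where the
  protein rotates substantially in the membrane plane would need an
  orientational pre-alignment step before density averaging.
* The dispersion test assumes equal-length blocks and loses power below
  ~10 events; strongly rate-inhomogeneous streams can evade it.
* Scrambling free energies are *descriptive* Boltzmann inversions of
  observed densities, not converged PMFs; barriers from sparse densities
  carry the counting noise of the underlying events.
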