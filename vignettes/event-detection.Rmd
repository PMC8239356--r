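---
title: "Detecting and quantifying intercellular calcium events without ROIs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting and quantifying intercellular calcium events without ROIs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(astrowave)
```

## The problem

Astrocytes signal through transient rises of intracellular Ca²⁺ that are
visible as fluorescence increases of an indicator such as GCaMP6f. Some
transients stay confined to a subcellular compartment; others spread as
waves across several coupled cells. Quantifying this network-level
signalling from time-lapse recordings with per-cell regions of interest
(ROIs) is unreliable, because astrocyte borders are hard to draw and events
do not respect them. `astrowave` therefore detects events wherever the
signal exceeds its own temporal variability, segments them as
spatiotemporal objects in (x, y, t), and quantifies their intercellular
propagation — no ROI drawing at any stage.

## The detection model

Each frame is tiled into non-overlapping square blocks of side
`grain_size` pixels ("grains"; trailing partial blocks keep their actual
pixel count). For grain $b$ the temporal trace of its block-mean intensity
$m_b(t)$ is taken over the *whole* recording, with trace mean $\mu_b$ and
sample standard deviation $\sigma_b$. The grain is foreground at frame $t$
iff

$$ m_b(t) \ge \mu_b + k\,\sigma_b, $$

with $k$ = `sd_threshold` (default 5). All pixels of a grain switch
together, and grains with $\sigma_b = 0$ are always background, so a
constant recording contains no events by construction.

Three consequences of this design matter in practice:

* **The statistics include the events themselves.** $\mu_b$ and $\sigma_b$
  are computed over the full trace, transients included. An event that
  occupies a large fraction of the trace inflates $\sigma_b$ and thereby
  raises its own detection threshold. For a single-frame spike the largest
  attainable $z$-score in a trace of $T$ frames is about $\sqrt{T}$, so at
  $k = 5$ a spike can only ever be detected when $T \gtrsim 27$ — and
  comfortably detected only when the event's time support is a small
  fraction of the recording. This is inherent to the thresholding rule, not
  an implementation artifact; the reference recordings (3 min at
  5 frames/s, 900 frames) sit well inside the safe regime. For short
  recordings or frequently re-firing sites, a lower `sd_threshold` (2–3) is
  the appropriate setting, which is also the recommended regime for noisy
  chemical indicators such as Fluo-3.
* **The comparison is inclusive** (`>=`), so the threshold value itself is
  the detection boundary.
* **Grain size trades resolution against noise.** Block-averaging over
  $g^2$ pixels reduces noise SD by $g$; grain 4 with a low threshold suits
  high-noise recordings, grain 1 preserves single-pixel resolution.

The SD multiplier is interpreted as a multiple of the trace's standard
deviation throughout; a mean-multiple variant is deliberately not offered.

## Segmentation

Foreground voxels are grouped by connected-component labelling with the
full 26-neighbourhood in (x, y, t): face, edge and corner contacts all
connect, because a propagating wave advances diagonally in x-y-t. Event IDs
are assigned by the (t, y, x)-lexicographic order of each component's first
voxel, so numbering is reproducible across reruns.

With `use_watershed = TRUE`, each component is further split by a seeded 3D
watershed so that touching events with distinct intensity peaks separate:
the intensity volume is smoothed with a separable Gaussian (SD 1 px in x
and y, 1 frame in t), seeds are placed at the regional maxima of the
smoothed intensity inside the component (plateaus of equal value collapse
to one seed at their lexicographically first voxel), and the component is
flooded from the seeds in order of decreasing smoothed intensity, ties
broken by lexicographic rank. The split is conservative by construction:
the foreground voxel multiset is unchanged and every output region is
connected.

`cleanup()` then removes events with *strictly fewer* than
`volume_threshold` voxels (default 40) — an event of exactly the threshold
volume survives — and renumbers survivors contiguously in their original
order.

## The event catalogue

Every event is described by its voxel list with intensities, its volume,
onset and end frames, axis-aligned bounding-box extents (voxel-count
convention: a single-voxel event has extent 1 on each axis), and its
**intensity-weighted** centre of mass. Weighting by intensity is this
package's choice; the unweighted mean is used only as a flagged fallback
for degenerate zero-intensity events. Pairwise centre distances are
computed in the xy plane only, because every downstream use of distance
(propagation speed, neighbourhood radius) is spatial, with time handled
separately by the tolerances.

## Neighbourhood, repeats, summaries

A boundary box is centred at each event's centroid. Its half-width per axis
is the maximum centroid-to-extreme-voxel distance along that axis plus the
tolerance (`tolerance_xy` = 50 px, `tolerance_t` = 5 frames by default).
Centring on the centroid while padding the extreme points reconciles the
two natural box definitions for asymmetric events. Any other event with at
least one voxel inside the box (boundaries inclusive, so the tolerance is
itself the reachable limit) is a neighbour; both directions are evaluated
independently and each qualifying ordered pair is recorded.

Two neighbours are linked as **repeats** when their xy footprints overlap
by strictly more than `intersection_threshold` (default 0.8). The overlap
fraction is $|P_E \cap P_F| / \min(|P_E|, |P_F|)$: the min-denominator
makes the fraction symmetric and the repeat relation well defined, which
the directional phrasing of the underlying rule leaves open. Repeats chain
by transitive closure (connected components of the link graph); chains are
ordered by onset and consecutive onset differences are the inter-repeat
gaps.

Recording-level metrics, with physical units applied only here
(`pixel_size` 0.586 µm/px and `frame_interval` 0.2 s by default):

* **incidence** — events · cell⁻¹ · min⁻¹ (cell count is user-supplied);
* **propagation speed** — per unordered neighbour pair with distinct
  onsets, centre-to-centre xy distance divided by the onset-time lag;
  simultaneous pairs are excluded. Onset frames (first foreground frame)
  time the propagation;
* **duration** — temporal extent × frame interval;
* **distance travelled** — defined here as the xy bounding-box diagonal
  $\sqrt{e_x^2 + e_y^2} \cdot \text{pixel size}$; the maximum pairwise
  voxel distance was rejected as quadratic in event size for near-identical
  values on wave-like events;
* **neighbour count** — only neighbours with strictly *later* onset count
  ("consequent" waves), so simultaneous pairs contribute to neither member.

Per-recording medians over events/pairs are exported; group-comparison
statistics are intentionally left to external tooling.

## Pre-processing

Both corrections are optional and off by default.

* **Frame-mean intensity correction** matches every frame's mean to its
  predecessor's; cascaded, this equals scaling every frame to the first
  frame's mean, which is how it is implemented (multiplicative, so the
  spatial pattern of each frame is untouched). It removes photobleaching
  and global illumination drift.
* **Rigid motion correction** divides the field into an 8×8 subregion grid
  (override with `grid`), selects as reference the tiles with
  below-median temporal SD and above-median temporal mean — bright, quiet
  tissue with no Ca²⁺ activity — falling back deterministically to the
  single best mean/(SD+ε) tile when the intersection is empty. Per-frame
  integer shifts are the cross-correlation peak between the frame's
  reference crop and *frame 1's* crop; registering against frame 1 rather
  than the preceding frame prevents accumulation of estimation errors.
  Shifts are integer-only (no subpixel interpolation), vacated margins are
  zero-filled, and a shift larger than half the frame is treated as an
  estimation failure, flagged, and replaced by the previous frame's shift.
  When both corrections run, motion goes first so that zero-filled borders
  cannot bias the frame means.

## The synthetic generator

`generate_stack()` renders `baseline × bleach(t) + Σ events + noise`, then
applies the drift schedule. Each planted transient is a spatial Gaussian
footprint with an exponential-rise/exponential-decay envelope normalised to
peak 1, optionally drifting across the field (an intercellular wave) or
re-firing at the same site (repeats). Ground truth records each
transient's centre, onset, chain membership, and a detector-independent
reference volume: the voxel count of its noise-free rendering above half
its maximum.

Default conditions were chosen once as a realistic low-noise GCaMP6f
regime: baseline 100 AU, additive Gaussian noise SD 2 AU, event amplitude
10 noise-SD (≈20 % ΔF/F), spatial radius 4 px, rise 1.5 frames and decay 4
frames (≈0.3 s / 0.8 s at 5 frames/s). Verification scenes use a
160 × 160 px field over 300 frames (1 min at 5 frames/s) — more than a
tenfold shrink of the reference recordings, chosen so the whole suite runs
in seconds while keeping the event duty cycle representative. The generator
emulates noisy baselines, bleaching, rigid drift, propagating multi-site
waves and repeated firing; it does **not** emulate astrocyte morphology,
Poisson photon statistics (noise is additive Gaussian), non-rigid motion,
or biophysical Ca²⁺/IP₃ dynamics. Passing the verification suite therefore
demonstrates correctness of the pipeline's arithmetic and decision
boundaries under controlled conditions, not detector performance on real
tissue.

```{r, eval = FALSE}
g <- generate_stack(wave_scene(n_sites = 5, spacing_px = 30, delay_frames = 3))
p <- run_pipeline(g$stack, wave_config(n_cells = 5))
p$summary$median_speed_um_s # planted: 30 * 0.586 / (3 * 0.2) = 29.3 um/s
```

## Numerical choices and degenerate inputs

* Temporal SDs are sample SDs (n − 1 denominator).
* All tie-breaks are lexicographic on (t, y, x), making every stage a pure
  function of (stack, configuration); reruns produce byte-identical
  artifacts, which the manifest checksums make checkable.
* Constant stacks, empty masks and empty catalogues flow through every
  stage and produce header-only CSVs and all-zero arrays.
* Medians over empty sets are reported as `NA`, never 0.
* A frame with zero mean aborts intensity correction (degenerate input)
  rather than silently dividing by zero.

## Known limitations

* Without per-cell labelling, some "neighbours" may be successive events
  within one cell; in monolayer cultures this is unresolvable by design,
  and downstream interpretation should treat neighbour counts accordingly.
* The full-trace threshold statistics penalise sites that fire for a large
  fraction of the recording (see above); a robust-baseline estimator is
  out of scope.
* Motion correction assumes a rigid field and integer shifts; slow
  non-rigid deformation is not corrected.
* The watershed flooding uses an exact priority order and is quadratic in
  component size; it is intended for splitting touching events, not for
  re-segmenting very large merged volumes.
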