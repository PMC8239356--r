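# astrowave

ROI-free detection, segmentation and intercellular-propagation analysis of
calcium events in fluorescence time-lapse recordings of astrocytic
networks.

Astrocytes communicate through transient Ca²⁺ rises — some confined to a
subcellular compartment, some propagating as waves across gap-junction
coupled cells. Drawing per-cell regions of interest to quantify this is
unreliable: astrocyte borders are hard to detect and events ignore them.
`astrowave` instead finds events wherever the signal exceeds its own
temporal variability and treats each event as a connected object in
(x, y, t). It is intended for researchers analysing GCaMP6f (or dye-based)
monolayer or slice recordings who need network-level metrics — event
incidence, intercellular propagation speed, event duration and size, and
repeat-firing classification — without cell segmentation.

## Method

For every `grain_size` × `grain_size` pixel block *b*, the temporal trace
of its block-mean intensity *m\_b(t)* is taken over the whole recording,
with mean μ\_b and SD σ\_b. The block is foreground at frame *t* iff

&nbsp;&nbsp;&nbsp;&nbsp;*m\_b(t)* ≥ μ\_b + *k*·σ\_b&nbsp;&nbsp;&nbsp;&nbsp;(*k* = `sd_threshold`, default 5)

Foreground voxels are grouped by 26-connected labelling in (x, y, t), with
an optional seeded 3D watershed to split touching events at intensity
saddles; events smaller than `volume_threshold` voxels (default 40) are
discarded as noise. Each surviving event gets an intensity-weighted
centroid, bounding-box extents and pairwise centre distances. Events are
neighbours when one lies inside the other's tolerance-padded bounding box
(`tolerance_xy` = 50 px, `tolerance_t` = 5 frames); neighbours whose xy
footprints overlap by more than `intersection_threshold` (0.8) are repeats
of one firing site rather than propagation. Propagation speed for a
neighbour pair is the centre-to-centre xy distance divided by the onset
lag. Optional pre-processing supplies rigid motion correction
(cross-correlation against reference subregions) and frame-mean intensity
(photobleaching) correction.

A synthetic-movie generator with exact ground truth (planted transients,
propagating waves, repeat schedules, bleaching, rigid drift) backs the
whole test suite; no external data are needed.

## Worked example

Simulate a five-cell calcium wave (sites 30 px apart, each igniting
3 frames after its predecessor) and run the full pipeline at default
parameters:

```r
library(astrowave)

g <- generate_stack(wave_scene(n_sites = 5, spacing_px = 30, delay_frames = 3, seed = 11))
p <- run_pipeline(g$stack, wave_config(n_cells = 5))
p
#> <wave_pipeline> 5 events, 9 neighbour records
#> # A tibble: 1 × 7
#>   n_events n_neighbour_pairs incidence_per_cell_min median_speed_um_s
#>      <int>             <int>                  <dbl>             <dbl>
#> 1        5                 5                      1              29.4
#> # i 3 more variables: median_duration_s <dbl>, median_distance_um <dbl>,
#> #   mean_neighbour_count <dbl>
```

All five planted events are recovered (one per site, `n_events = 5`;
incidence 5 events / 5 cells / 1 min = 1.0). The recovered median
propagation speed, 29.4 µm/s, matches the planted speed
30 px × 0.586 µm/px / (3 frames × 0.2 s/frame) = 29.3 µm/s to within a
fraction of a pixel of centroid noise. The catalogue itself is a tibble:

```r
tidy(p$catalog)
#> # A tibble: 5 × 11
#>      id volume t_onset t_end extent_x extent_y extent_t centroid_t centroid_y ...
#> 1     1    111      51    54        9        9        4       52.3       59.9
#> 2     2    124      54    57       11       11        4       55.3       59.9
#> ...
```

— onsets 3 frames apart and centroids 30 px apart in x, as planted.
`persist_artifacts(p, "out/")` writes the standard artifact set
(`waves.npy`, `labelled_waves.npy`, `black_and_white.tiff`,
`neighbours.csv`, `neighbour_statistics.csv`, `repeats.csv`,
`singles.csv`, `events.csv`, `summary.csv`) plus a checksum manifest, and
`autoplot(p$catalog)` maps the detected events. A command-line front end
over the same functions lives at `inst/cli/astrowave.R`
(`run` / `detect` / `segment` / `neighbours` / `summarise` / `simulate`).

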