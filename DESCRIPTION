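Package: astrowave
Title: ROI-Free Detection and Propagation Analysis of Calcium Events in
    Astrocytic Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects, segments and quantifies transient calcium events in
    fluorescence time-lapse stacks of astrocytic networks without drawing
    per-cell regions of interest. Frames are tiled into pixel grains whose
    temporal traces are thresholded at a multiple of their standard
    deviation; suprathreshold voxels are grouped into spatiotemporal
    (x, y, t) events by 26-connected labelling with optional seeded
    watershed splitting; events are catalogued (volume, extents,
    intensity-weighted centroid, pairwise centre distances), linked into
    neighbour graphs through tolerance-padded bounding boxes, classified
    as single or repeated firing sites by footprint overlap, and summarised
    as per-recording incidence, intercellular propagation speed, duration
    and distance travelled. Includes rigid motion correction, frame-mean
    intensity (photobleaching) correction, and a synthetic movie generator
    with ground truth for end-to-end verification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
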