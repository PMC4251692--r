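Package: veinviz
Title: Near-Infrared Vein Visualization Phantoms, Enhancement and
    Evaluation Statistics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Offline toolkit for near-infrared (NIR) vein-visualization
    pipelines. Renders synthetic NIR reflectance phantoms of a forearm
    with subcutaneous veins (Beer-Lambert depth attenuation, radial LED
    illumination, depth-dependent scatter blur) together with ground-truth
    masks and depth maps; emulates a capture layer (gain, exposure,
    contrast and named profiles); provides the enhancement operators used
    by mobile vein finders (percentile contrast stretch, difference of
    Gaussians, Laplacian of Gaussian, region-of-interest processing);
    segments veins with morphological cleanup and centerline extraction,
    decides marker hits, and estimates the maximum visible vein depth by
    phantom sweep; and computes the descriptive evaluation statistics of
    venipuncture studies (failure-rate tables, Likert summaries, System
    Usability Scale scoring and banding, usage-log analytics).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    EBImage,
    igraph,
    jsonlite,
    png,
    tiff
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Roxygen: list(markdown = TRUE)
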