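Package: osmodrop
Title: Droplet Swimming Assay and Calcium Imaging Analysis for Worm
    Osmotic-Upshift Behavior
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies the behavioral and imaging readouts of Caenorhabditis
    elegans osmotic-upshift experiments. Implements equivalent-ellipse
    eccentricity turn calling for the droplet swimming assay, Schmitt-trigger
    body-thrash counting, additive solution-osmolarity calculation with
    reconciliation against osmometer measurements, blinded body-area
    (dehydration) measurement, GCaMP delta-F/F analysis with exponential
    photobleaching correction, and the group statistics layer (mean +/- SEM
    summaries, pooled-variance t tests, genotype-by-osmolarity interaction
    ANOVA with Type II sums of squares). A synthetic-data generator produces
    swim videos, dehydration image pairs, and fluorescence traces with known
    ground truth so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    car,
    minpack.lm,
    rlang,
    stats,
    tibble,
    tiff,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
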