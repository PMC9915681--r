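Package: cepscore
Title: Automated Scoring of Dopaminergic Dendrite Degeneration in C. elegans
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An automated, unbiased image-analysis pipeline that quantifies
    degeneration of the four cephalic (CEP) dopaminergic neurons in
    Caenorhabditis elegans from a single maximum-intensity-projection
    fluorescence image and the camera pixel size. The pipeline locates the
    cell bodies, isolates and crops the dendrite region, detects bleb
    ("beads on a string") features with Chan-Vese refinement, traces up to
    four dendrites, detects breaks, and compiles 19 named degeneration
    metrics plus a 0-4 categorical score per dendrite. Includes group
    comparison statistics (z-scores versus control, one-way ANOVA with
    Bonferroni or resampling-based many-to-one correction), a synthetic
    phantom generator with exact ground truth for validation, and a batch
    command-line driver.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    tools
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    withr,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
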