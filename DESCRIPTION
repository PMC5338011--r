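Package: colonypatch
Title: Clonal Patch Width Quantification for Two-Genotype Colony Images
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Quantifies spatial self-organization (genetic demixing versus
    intermixing) of two-genotype microbial colonies during radial range
    expansion. Given a pair of registered single-channel grayscale
    fluorescence images (one per fluorophore-tagged genotype), the pipeline
    coarsens the images, samples circular intensity profiles at increasing
    radius from the inoculation zone, applies a per-radius Otsu threshold,
    and derives crossing statistics: the mean clonal patch (strand) width
    along the colony front as a function of radial distance. A synthetic
    colony-image generator with exact per-radius ground truth (fixed,
    narrowing or widening sectors, and an annihilating boundary random walk
    emulating demixing) makes every stage verifiable without microscopy
    data. A small utility converts liquid-column height to water matric
    potential for porous-surface hydration control.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    grDevices,
    graphics,
    jsonlite,
    png,
    stats,
    utils,
    yaml
Suggests:
    knitr,
    optparse,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
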