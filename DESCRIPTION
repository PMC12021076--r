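Package: axonreg
Title: Quantification of Axon Regeneration and Retinal Cell Survival from
    Fluorescence Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An automated, tested implementation of a standard quantification
    scheme for axon regeneration after nerve injury: maximum-intensity
    Z-projection of confocal stacks into fixed-thickness optical sections,
    regenerating-fiber counts at fixed distances distal to the crush site,
    top-k axon length statistics, axonal tip morphometry with retraction-bulb
    versus growth-cone classification by the tip/shaft width ratio, U-turn and
    branching trajectory metrics, optic-chiasm fate classification, and
    retinal ganglion cell survival, transduction and marker-fraction ratios
    from whole-mount retina fields. A synthetic-data module generates
    ground-truth axon trajectories, rasterized image stacks with PSF blur and
    shot noise, and retina cell fields, so that every metric is validated by
    oracle equivalence and parameter recovery. Includes geodesic axon tracing
    from binary masks, SWC input/output, and the statistical comparisons
    (Student's t, one-sample t, one-way ANOVA with Tukey HSD) used to compare
    experimental conditions.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    igraph,
    jsonlite,
    Rcpp,
    stats,
    tiff,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
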