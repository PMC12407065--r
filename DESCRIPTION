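Package: hullmass
Title: Convex-Hull Volumetric Body Mass Properties for Fossil Skeletons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates body segment and whole-body mass properties of fossil
    vertebrates from segmented skeletal meshes. Computes minimal convex hulls
    per body segment, expands hull volumes to soft-tissue volumes under
    configurable allometric or isometric scaling models with floor rules and
    ornament exemptions, assembles heterogeneous-density masses and centres of
    mass with mean-percentage-prediction-error bounds, and supports sensitivity
    variants (alternative densities, osteoderm exclusion, rigid neck reposing).
    Downstream comparative tools cover normalised centre-of-mass coordinates,
    stylopodial circumference mass estimates, Spearman rank agreement,
    ordinary and phylogenetic generalised least squares allometry under
    Brownian motion, AICc, ancestral state reconstruction and phylomorphospace
    coordinates. A synthetic-skeleton generator with analytically known hull
    volumes makes every pipeline stage testable without external scan data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    nlme,
    phytools,
    graphics,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
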