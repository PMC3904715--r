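Package: disectr
Title: Design-Based Stereology for Unbiased Particle Counting with the
    Optical Disector
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for unbiased estimation of particle number per cell in
    thick biological specimens by design-based stereology: the optical
    disector (3D unbiased brick probe with exclusion surfaces), the double
    disector, the 2D unbiased counting frame, point-grid area estimation and
    Cavalieri volume estimation, together with systematic uniform random
    (SUR) section sampling. Includes a synthetic mesophyll-tissue generator
    (spheroidal chloroplasts inside model cells inside a needle-like tissue
    block), voxelized labelled z-stack rendering standing in for confocal
    acquisitions, and pipeline experiments demonstrating that counting
    particle profiles in 2D sections underestimates particle number per cell
    by roughly the particle-to-cell caliper-height ratio.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    grDevices,
    jsonlite,
    stats,
    tiff,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
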