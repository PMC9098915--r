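Package: hpindex
Title: Habitat Protection Indexes for Coastal and Marine Conservation Monitoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A standardized workflow that measures how much of each coastal and
    marine habitat lies within protected or conserved areas (PCAs). Cleans
    WDPA/WD-OECM-style records, buffers point records to their reported area,
    projects geometries to an equal-area grid, rasterizes them at 1 km
    resolution with the centroid rule, counts habitat and protected-habitat
    pixels per jurisdiction (including areas beyond national jurisdiction),
    and computes the Local and Global Proportion of Habitats Protected
    Indexes (LPHPI, GPHPI) together with a targeted 30-percent-coverage gap
    score. Includes a synthetic-world generator with analytically known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    mgcv,
    geosphere,
    optparse
Config/testthat/edition: 3
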