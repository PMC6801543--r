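Package: pestfate
Title: Mapping Geospatial Processes Affecting the Environmental Fate of
    Agricultural Pesticides
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A raster pipeline for mapping the relative vulnerability of
    landscapes to five processes governing the environmental fate of
    agricultural pesticides: leaching (a DRASTIC-weighted index), surface
    runoff generation, transfer and accumulation (IRIP-style susceptibility
    indicators), sedimentation (USLE erosion, watershed sediment load and
    stream velocity), soil storage and filtering capacity, and
    volatilization (monthly climate index with annual mean and seasonal
    dispersion).  Includes the terrain and hydrology derivatives the models
    require (pit filling, D8 flow routing, flow accumulation, watershed
    delineation, topographic wetness index), a one-at-a-time sensitivity
    analysis, an insecticide-residue observation database with validation
    and summary funnels, and seeded synthetic-data generators so the whole
    pipeline can be exercised end-to-end without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'grid-core.R'
    'grid-io.R'
    'leaching.R'
    'pestfate-package.R'
    'pipeline.R'
    'residue-db.R'
    'runoff.R'
    'sedimentation.R'
    'sensitivity.R'
    'storage-filtering.R'
    'synthetic.R'
    'terrain.R'
    'volatilization.R'
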