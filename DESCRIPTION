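Package: geoaccess
Title: Travel-Time Accessibility to Healthcare Facilities on Raster Friction Surfaces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models physical access to healthcare on a gridded landscape.
    Builds a friction (impedance) surface from land cover, a classified road
    network and water barriers; computes exact multi-source least-cost travel
    time from every raster cell to the nearest facility of a target class
    (hospitals, or facilities of any type pooled from two registries) with an
    8-connected cost-distance algorithm; aggregates travel time to a
    population grid; and summarises population-weighted travel-time
    distributions for adults aged 60 years and older, including cut-off
    category shares with Wilson score confidence intervals, worst-quintile
    weighted median and interquartile range, and facility densities per
    100,000 population. A synthetic-landscape generator provides reproducible
    inputs with the spatial structure the analysis assumes (clustered
    settlements, spanning-tree road networks, partially overlapping facility
    registries, water and forest barriers) so the full pipeline runs offline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'facilities.R'
    'grid.R'
    'friction.R'
    'geoaccess-package.R'
    'stats.R'
    'io.R'
    'maps.R'
    'traveltime.R'
    'synthetic.R'
    'pipeline.R'
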