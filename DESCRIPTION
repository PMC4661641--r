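Package: landriskr
Title: Landscape Ecological Risk Assessment and Markov-CA Land-Change Simulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for landscape-level ecological risk analysis of categorical
    land-cover rasters: land-change accounting (dynamic degree index and Markov
    transition matrices), landscape pattern metrics (splitting index, patch
    density, contagion, Shannon diversity, perimeter-area fractal dimension) at
    class, landscape and zonal level, a disturbance-by-vulnerability ecological
    risk index with five risk categories, least-squares support vector machine
    (LSSVM) suitability modelling of land conversions from spatial driver
    variables, Markov-constrained cellular-automata simulation of future land
    cover, and policy scenario analysis (farmland protection, ecological
    conservation, urban development). Includes a seeded synthetic landscape
    generator so the full pipeline is testable without external GIS data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    kernlab,
    e1071
Config/testthat/edition: 3
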