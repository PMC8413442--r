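Package: eairisk
Title: Environmental Area Index Ecological-Risk Assessment
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Composite ecological-risk assessment for high-altitude
    landscapes built around the Environmental Area Index (EAI).
    Environmental factor rasters (climate, soil, vegetation) are scored
    through reclassification lookup tables, combined into climate, soil
    and vegetation quality indices by geometric mean, and aggregated
    into a weighted EAI whose low values flag high ecological risk.
    Includes five-class grading by Fisher-Jenks natural breaks or fixed
    breakpoints, elevation-band zonal accounting, climate-scenario trend
    rates, random-forest based index weighting, and a fully synthetic
    scene generator so the whole pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
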