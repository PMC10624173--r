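Package: soilsuit
Title: Soil Quality Index and Land-Suitability Assessment with AHP Weighting
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for GIS-style land-suitability assessment of agricultural
    soils, built around a weighted linear soil quality index (SQI). Raw soil
    parameters measured at survey points are rescaled to dimensionless
    suitability scores with standard scoring functions; criterion weights are
    derived from pairwise-comparison matrices by the analytic hierarchy
    process (AHP) with consistency certification; continuous parameter
    surfaces are produced by inverse-distance weighting, radial-basis splines
    or kriging, selected per parameter by leave-one-out cross-validated RMSE;
    the SQI surface is classified into FAO-style suitability classes
    (S1-S2-S3-N1-N2), masked for non-agricultural land and tabulated by area;
    and the index is validated against observed yields by regression. A
    seeded geostatistical simulator generates synthetic soil surveys with
    prescribed marginal moments and spatial autocorrelation so that the whole
    pipeline is testable without field data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
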