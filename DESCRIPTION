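Package: laketherm
Title: Harmonized Seasonal Lake Surface Temperature Means from Irregular
    In Situ and Satellite Records
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Turns irregular lake surface water temperature observations into
    comparable 3-month "summer" means. Resolves hemisphere- and
    tropics-dependent seasonal averaging windows, computes in situ seasonal
    means by daily linear interpolation with a parabolic day-of-year
    extrapolation routine for truncated sampling seasons, screens and merges
    nighttime thermal-infrared satellite retrievals (view-zenith and spatial
    homogeneity tests, skin-to-bulk correction) and smooths them with robust
    locally weighted regression, quantifies the seasonal-mean error introduced
    by sparse sampling via bootstrap subsampling, and cross-validates
    satellite against in situ series through RMSE of means, anomalies and
    trends. Includes readers and writers for the archive CSV schemas and a
    synthetic-data generator for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
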