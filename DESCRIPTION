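Package: eslines
Title: Constraint Lines Between Ecosystem Services on Raster Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Computes four ecosystem services (net primary productivity,
    food production, soil conservation by RUSLE, water yield by a Budyko
    curve) on gridded landscapes, extracts the upper constraint line of
    each pairwise service scatter cloud by segmented quantile regression,
    tracks the fitted characteristic values (hump threshold, exponential
    decay base k and intercept b) across years, and attributes their
    interannual variation to climatic, vegetation, landscape-composition,
    landscape-configuration and socioeconomic drivers with interaction
    terms and normalized relative importance.  A synthetic-landscape
    generator with known statistical structure makes every stage testable
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    optparse
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
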