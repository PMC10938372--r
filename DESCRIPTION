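Package: pmscape
Title: Neighbourhood-Scale Particulate-Matter Mapping from Low-Cost Monitor Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn a small network of low-cost optical particulate-matter
    monitors into daily neighbourhood-scale concentration maps. The pipeline
    calibrates raw sensor readings against a reference with ridge polynomial
    regression using temperature and relative humidity as support variables,
    engineers a 151-feature representation of any (location, day) from monitor,
    reanalysis-meteorology and road-network data, trains a small per-size
    multilayer perceptron, evaluates it by holding out whole monitors, runs
    one-at-a-time sensitivity analysis, and predicts PM1, PM2.5 and PM10 over a
    rectangular grid. A self-contained synthetic-town generator with known
    ground truth supports development and testing without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tibble,
    utils
Suggests:
    geosphere,
    glmnet,
    ncdf4,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
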