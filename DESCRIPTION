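Package: rscmlai
Title: Remote-Sensing-Integrated Crop Modelling with Machine-Learned Leaf Area Index
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates leaf area index (LAI) from three-band canopy
    reflectance through vegetation indices (MTVI1, NDVI, OSAVI, RDVI) with a
    benchmarked family of regression models, and assimilates those LAI
    estimates into a daily process-based crop simulator (growing-degree-day
    phenology, Beer-Lambert light interception, radiation-use-efficiency
    growth) for rice and soybean. Within-season recalibration of the four
    growth parameters (initial LAI, leaf-allocation magnitude and shape,
    senescence rate) uses Powell's derivative-free method, optionally
    penalised by Gaussian priors. Includes Nash-Sutcliffe, RMSE and MAE
    evaluation statistics, a synthetic-data generator for weather,
    reflectance and LAI-VI datasets, CSV readers/writers and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    e1071,
    minpack.lm,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
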