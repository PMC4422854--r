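Package: alsagb
Title: Plot-Size Effects in Airborne Laser Scanning Assisted Biomass Inventories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying how field plot size affects aboveground
    biomass (AGB) estimation in airborne laser scanning (ALS) assisted
    forest inventories. Simulates tropical forest stands and normalized
    lidar echo clouds with crown-mediated plot boundary effects, extracts
    area-based ALS metrics (height percentiles, canopy densities, summary
    statistics) for nested circular plots, fits log-scale OLS biomass
    models by exhaustive best-subset selection under BIC with a variance
    inflation factor screen, validates them by leave-one-out
    cross-validation, quantifies plot boundary effects with linear mixed
    models, and compares simple-random-sampling and model-assisted (GREG)
    variance estimators via relative efficiency across plot sizes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    nlme,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
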