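Package: childcap
Title: Child-Based Capability Index from Birth-History Survey Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds a child-based human development (capability) index from
    DHS-style birth-recode microdata: sample restriction and outcome coding for
    under-five survival, maternal schooling and asset-based household wealth;
    principal-component wealth scores with survey-weighted quintiles;
    survey-weighted aggregation to national and subnational cells; min-max
    (goalpost) normalization and geometric-mean index construction with ranking
    and within-country dispersion; sensitivity variants (birth windows, infant
    survival, maternal-age restriction, arithmetic mean, fixed goalposts,
    provided wealth quintiles); comparison against external indices,
    thin-plate-spline development-spectrum surfaces and choropleth export.
    Includes a clustered synthetic survey generator with stored ground truth so
    the whole pipeline is testable without access-restricted microdata.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    rlang,
    stats,
    utils,
    jsonlite,
    yaml,
    digest,
    ggplot2,
    withr
Suggests:
    arrow,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
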