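Package: bulkscc
Title: Bulk-Tank Somatic Cell Count Compliance Analysis for Dairy Herds
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bulk-tank somatic cell count (SCC) records
    from dairy herds against EU raw-milk eligibility rules. Implements
    cleaning of collection-day records, monthly and three-month rolling
    geometric mean SCC under the two legislated calculation methods, the
    Irish winter seasonality adjustment, the warning/suspension eligibility
    state machine, and scenario comparison of compliance outcomes with and
    without the seasonality adjustment. Includes a synthetic longitudinal
    herd-data generator emulating the statistical structure and data-quality
    defects of national bulk-tank collection datasets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    readr,
    generics,
    ggplot2,
    withr,
    yaml,
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
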