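Package: roostinfo
Title: Movement-Based Tests of Roost Information Transfer in Fruit Bats
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to test whether communal roosts act as information
    centres for central-place foraging fruit bats tracked with
    high-frequency reverse-GPS tags. Provides covariance- and speed-based
    fix filtering, first-passage segmentation of tracks into tree visits,
    a resampling null that compares post-manipulation visitation of focal
    trees against routine movement, dyadic tree-encounter detection with
    per-lag logistic models of new-tree discovery, and a synthetic
    trajectory generator with ground-truth visit logs so the whole
    pipeline can be exercised without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    readr,
    rlang,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2,
    jsonlite,
    optparse
Config/testthat/edition: 3
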