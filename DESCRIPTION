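Package: mesometab
Title: Mesocosm Metabolism: Net Community Production, Photosynthesis-Irradiance
    Models, and Heatwave Severity from Closed-Incubation Sensor Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to turn high-frequency oxygen, temperature and irradiance
    sensor series from closed mesocosm incubations into net community
    production (NCP) rates, temperature-binned and temperature-modified
    hyperbolic-tangent photosynthesis-irradiance model fits, accumulated
    production with Monte-Carlo confidence intervals, and marine-heatwave
    threshold-exceedance and cumulative-severity statistics. Includes a
    seeded scenario generator that emulates a 23-day Arctic kelp mesocosm
    heatwave experiment (constant warming and single/double heatwave
    treatments) so the full pipeline can be exercised and validated against
    known ground truth without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    lubridate,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
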