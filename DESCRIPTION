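Package: aeroplume
Title: Airport-Level Aviation PM2.5 Emissions and Gaussian Plume Concentrations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes monthly airport-level fine particulate matter (PM2.5)
    attributable to aircraft landing-take-off (LTO) activity. National
    monthly transport turnover is apportioned to airports, converted to
    fuel burn via unit ton-kilometre consumption, to PM2.5 emission mass
    via a pluggable emission intensity (g per kg fuel), and to an emission
    flow in g/s. A steady-state Gaussian diffusion model with ground and
    mixing-layer image-source reflection terms then yields 24-hour average
    concentrations per airport and month. Includes inverse-distance-weighted
    validation against monitoring-station observations, a synthetic scenario
    generator emulating seasonal, growth and shock structure in aviation
    activity, and readers/writers for the wide year-by-airport monthly table
    layout.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
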