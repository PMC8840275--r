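Package: platewaste
Title: Monte Carlo Forecasting of School Lunch Plate Waste
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Stochastic simulation of school-lunch plate waste. Generates
    weekly lunch menus from regulated portion-component distributions and
    child agents with eating rates, competitive-food behaviour and
    per-weekday food rejection, then decomposes each plate into eaten mass
    and waste attributable to competitive food, rejected food and
    insufficient lunch time. Includes closed-form cumulative food-intake
    kinetics (quadratic and cubic eating-rate models), Monte Carlo parameter
    sweeps over lunch duration and the share of unsatisfied children,
    optimal-duration analysis under ideal conditions, and RMSE/MAPE forecast
    validation against (synthetic) per-school weekly observations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
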