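#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a plate-waste simulation
#'
#' @param x A `plate_waste_sim` from [run_simulation()].
#' @param ... Unused.
#' @return The per-component tibble of mean waste fractions by cause.
#' @export
tidy.plate_waste_sim <- function(x, ...) x$components

#' @rdname tidy.plate_waste_sim
#' @return `glance()`: the one-row summary (mean weekly waste fraction,
#'   sd, Monte Carlo standard error, quantiles, scenario parameters).
#' @export
glance.plate_waste_sim <- function(x, ...) x$summary

#' Tidy a forecast validation
#'
#' @param x A `waste_validation` from [validate_forecasts()].
#' @param ... Unused.
#' @return `tidy()`: per-record residual tibble; `glance()`: one-row tibble
#'   with `rmse`, `mape` and `n`.
#' @export
tidy.waste_validation <- function(x, ...) x$residuals

#' @rdname tidy.waste_validation
#' @export
glance.waste_validation <- function(x, ...) {
  tibble::tibble(rmse = x$rmse, mape = x$mape, n = x$n)
}

#' Tidy a duration scan
#'
#' @param x A `duration_scan` from [optimal_duration()].
#' @param ... Unused.
#' @return `tidy()`: the waste-vs-duration curve; `glance()`: one row with
#'   `optimal_min` and `threshold`.
#' @export
tidy.duration_scan <- function(x, ...) x$curve

#' @rdname tidy.duration_scan
#' @export
glance.duration_scan <- function(x, ...) {
  tibble::tibble(optimal_min = x$optimal_min, threshold = x$threshold)
}
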