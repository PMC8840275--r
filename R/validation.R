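#' Forecast error metrics
#'
#' `rmse()` is the root of the mean squared forecast--observation
#' difference. `mape()` is the mean absolute percentage error,
#' `100/N * sum(|forecast - observation| / observation)`; the absolute value
#' is taken so that errors of opposite sign cannot cancel.
#'
#' @param forecasts,observations Paired numeric vectors in the same units
#'   (both weekly grams or both waste fractions).
#' @return `rmse()`: error in the input units; `mape()`: percent.
#' @examples
#' rmse(c(0.25, 0.30), c(0.20, 0.34)) # 0.04528
#' mape(c(110, 90), c(100, 100))      # 10
#' @export
rmse <- function(forecasts, observations) {
  stopifnot(is.numeric(forecasts), is.numeric(observations))
  if (length(forecasts) == 0L) stop("empty pairing: need at least one pair.")
  if (length(forecasts) != length(observations)) {
    stop("`forecasts` and `observations` must have equal length.")
  }
  sqrt(mean((forecasts - observations)^2))
}

#' @rdname rmse
#' @export
mape <- function(forecasts, observations) {
  stopifnot(is.numeric(forecasts), is.numeric(observations))
  if (length(forecasts) == 0L) stop("empty pairing: need at least one pair.")
  if (length(forecasts) != length(observations)) {
    stop("`forecasts` and `observations` must have equal length.")
  }
  if (any(observations == 0)) {
    stop("MAPE is undefined for zero observations; remove or reweight them.")
  }
  100 * mean(abs(forecasts - observations) / abs(observations))
}

#' Synthesize per-school plate-waste observations
#'
#' Stands in for unpublished field observations: for each requested lunch
#' duration the simulator is run at the walking-adjusted duration, and each
#' synthetic school's weekly waste fraction is the simulated mean perturbed
#' by multiplicative normal noise. The output schema is the observation
#' file format (`school`, `duration_min`, `observed_weekly_waste`, `unit`,
#' `n_children`), plus the simulator's Monte Carlo standard error per
#' duration (`sim_se`) for downstream self-consistency checks.
#'
#' @param cfg A [simulation_config()].
#' @param durations Nominal lunch durations to observe (default
#'   `c(15, 20, 25, 30)`).
#' @param n_schools Number of synthetic schools per duration (default 7).
#' @param noise_sd Standard deviation of the multiplicative noise (0 means
#'   observations equal the simulated means).
#' @return A tibble flagged `unit = "fraction"`.
#' @export
synthesize_observations <- function(cfg, durations = c(15, 20, 25, 30),
                                    n_schools = 7, noise_sd = 0.03) {
  stopifnot(inherits(cfg, "simulation_config"), n_schools >= 1,
            noise_sd >= 0)
  purrr::map_dfr(seq_along(durations), function(k) {
    cc <- cfg
    cc$lunch_duration <- durations[k]
    cc$seed <- cell_seed(cfg$seed, k)
    g <- run_simulation(cc)$summary
    noise <- stats::rnorm(n_schools, 1, noise_sd)
    tibble::tibble(
      school = sprintf("school_%02d", seq_len(n_schools)),
      duration_min = durations[k],
      observed_weekly_waste = g$mean_waste_frac * noise,
      unit = "fraction",
      n_children = cfg$repetitions,
      sim_se = g$se_waste_frac
    )
  })
}

#' Validate simulator forecasts against observations
#'
#' Computes forecasts at each observed lunch duration (walking-adjusted),
#' pairs them with the observations by duration, and reports RMSE, MAPE,
#' the number of observations N, and the per-record residual table.
#' Forecast and observation units must match; observation durations that
#' cannot be paired raise an error rather than being silently dropped.
#'
#' @param cfg A [simulation_config()] used to forecast.
#' @param observations Observation tibble with columns `school`,
#'   `duration_min`, `observed_weekly_waste` and `unit` (must be
#'   `"fraction"`: the simulator forecasts waste fractions).
#' @param forecasts Optional precomputed forecast tibble with columns
#'   `duration_min` and `forecast_weekly_waste` (one row per duration). If
#'   omitted, forecasts are simulated from `cfg`.
#' @return An object of class `waste_validation`: list with `rmse`, `mape`,
#'   `n`, `residuals` (tibble `school`, `duration_min`, `observed`,
#'   `forecast`, `residual`) and `forecasts`. [generics::glance()] returns
#'   the metrics; [generics::tidy()] the residual table.
#' @export
validate_forecasts <- function(cfg, observations, forecasts = NULL) {
  stopifnot(inherits(cfg, "simulation_config"), is.data.frame(observations))
  need <- c("school", "duration_min", "observed_weekly_waste", "unit")
  if (!all(need %in% names(observations))) {
    stop("observations must have columns ", paste(need, collapse = ", "), ".")
  }
  if (nrow(observations) == 0L) stop("empty observations.")
  if (!all(observations$unit == "fraction")) {
    stop("unit mismatch: forecasts are waste fractions; observations must ",
         "declare unit = 'fraction'.")
  }
  if (any(observations$observed_weekly_waste < 0)) {
    stop("observed plate waste must be non-negative.")
  }
  durs <- sort(unique(observations$duration_min))
  if (is.null(forecasts)) {
    forecasts <- purrr::map_dfr(seq_along(durs), function(k) {
      cc <- cfg
      cc$lunch_duration <- durs[k]
      # offset the seed stream so forecasts are independent of any
      # synthetic observations generated from the same base seed
      cc$seed <- cell_seed(cfg$seed, 10000L + k)
      g <- run_simulation(cc)$summary
      tibble::tibble(duration_min = durs[k],
                     forecast_weekly_waste = g$mean_waste_frac,
                     forecast_se = g$se_waste_frac)
    })
  } else {
    stopifnot(is.data.frame(forecasts),
              all(c("duration_min", "forecast_weekly_waste") %in%
                    names(forecasts)))
    if (anyDuplicated(forecasts$duration_min)) {
      stop("pairing error: duplicated durations in `forecasts`.")
    }
    missing <- setdiff(durs, forecasts$duration_min)
    if (length(missing)) {
      stop("pairing error: no forecast for observed duration(s) ",
           paste(missing, collapse = ", "), ".")
    }
  }
  residuals <- observations |>
    dplyr::inner_join(forecasts, by = "duration_min") |>
    dplyr::transmute(.data$school, .data$duration_min,
                     observed = .data$observed_weekly_waste,
                     forecast = .data$forecast_weekly_waste,
                     residual = .data$forecast - .data$observed)
  structure(list(
    rmse = rmse(residuals$forecast, residuals$observed),
    mape = mape(residuals$forecast, residuals$observed),
    n = nrow(residuals),
    residuals = residuals,
    forecasts = tibble::as_tibble(forecasts)
  ), class = "waste_validation")
}

#' @export
print.waste_validation <- function(x, ...) {
  cat(sprintf("<waste_validation> N = %d observations\n", x$n))
  cat(sprintf("  RMSE: %.4f (waste-fraction units)\n", x$rmse))
  cat(sprintf("  MAPE: %.2f%%\n", x$mape))
  invisible(x)
}
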