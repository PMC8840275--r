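#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a sweep grid as a waste surface
#'
#' Heat-map of the mean weekly waste fraction over the (lunch duration,
#' unsatisfied share) grid -- a flat rendering of the simulation surface.
#'
#' @param object A `waste_sweep` from [sweep_grid()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.waste_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(
    x = .data$duration_min, y = .data$unsatisfied_share,
    fill = .data$mean_waste_frac
  )) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "Mean waste\nfraction",
                                  labels = scales_percent) +
    ggplot2::labs(x = "Nominal lunch duration (min)",
                  y = "Share of unsatisfied children") +
    ggplot2::theme_minimal()
}

# percent labeller without depending on the scales namespace directly
scales_percent <- function(x) sprintf("%.0f%%", 100 * x)

#' Plot per-component waste causes of a simulation
#'
#' Stacked bars of the mean fraction of each served component lost to
#' competitive food, rejected food and insufficient time.
#'
#' @param object A `plate_waste_sim` from [run_simulation()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.plate_waste_sim <- function(object, ...) {
  long <- object$components |>
    tidyr::pivot_longer(c("w_ef_frac", "w_h_frac", "w_t_frac"),
                        names_to = "cause", values_to = "frac") |>
    dplyr::mutate(cause = dplyr::recode(.data$cause,
      w_ef_frac = "competitive food", w_h_frac = "rejected food",
      w_t_frac = "insufficient time"))
  ggplot2::ggplot(long, ggplot2::aes(
    x = factor(.data$component, levels = meal_components()),
    y = .data$frac, fill = .data$cause
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = scales_percent) +
    ggplot2::labs(x = "Portion component",
                  y = "Mean share of served mass wasted", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the ideal-conditions duration curve
#'
#' Mean waste fraction against lunch duration under ideal conditions, with
#' the adequacy threshold and the minimal adequate duration marked.
#'
#' @param object A `duration_scan` from [optimal_duration()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.duration_scan <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(
    x = .data$duration_min, y = .data$mean_waste_frac
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = object$threshold, linetype = 2) +
    ggplot2::geom_vline(xintercept = object$optimal_min, linetype = 3) +
    ggplot2::scale_y_continuous(labels = scales_percent) +
    ggplot2::labs(x = "Eating duration (min, walking excluded)",
                  y = "Mean weekly waste fraction") +
    ggplot2::theme_minimal()
}
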