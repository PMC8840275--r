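#' Eating-rate model parameters
#'
#' Parameters of the cumulative food-mass intake model
#' \deqn{e(t) = v_0 t + a_0 t^2/2 + x t^3/3,}
#' the integral of the instantaneous eating speed
#' \eqn{v(t) = v_0 + a_0 t + x t^2}. The integration constant is fixed at
#' zero: intake at `t = 0` is zero. With `x = 0` this is the quadratic
#' (decelerating) intake model; with `a0 = x = 0` it reduces to constant-speed
#' (linear) intake.
#'
#' @param v0 Initial eating speed in g/min. Must be non-negative.
#' @param a0 Initial eating-speed acceleration in g/min^2 (negative for
#'   deceleration). Default 0.
#' @param x Eating-speed acceleration of the cubic model in g/min^3.
#'   Default 0.
#'
#' @return An object of class `intake_params`.
#' @examples
#' girls <- intake_params(v0 = 34, a0 = -5.2)
#' cumulative_intake(girls, extremum_time(34, -5.2))
#' @export
intake_params <- function(v0, a0 = 0, x = 0) {
  stopifnot(is.numeric(v0), length(v0) == 1L, is.finite(v0),
            is.numeric(a0), length(a0) == 1L, is.finite(a0),
            is.numeric(x), length(x) == 1L, is.finite(x))
  if (v0 < 0) stop("`v0` must be non-negative (initial eating speed).")
  structure(list(v0 = v0, a0 = a0, x = x), class = "intake_params")
}

#' @export
print.intake_params <- function(x, ...) {
  cat(sprintf("<intake_params> v0 = %g g/min, a0 = %g g/min^2, x = %g g/min^3\n",
              x$v0, x$a0, x$x))
  invisible(x)
}

# Intervals of t >= 0 on which the speed polynomial v(t) = v0 + a0 t + x t^2
# is negative. Intake clamps the speed at zero there: it plateaus during the
# dip and, for x > 0, resumes once the speed turns positive again.
speed_negative_window <- function(p) {
  if (p$x == 0) {
    if (p$a0 >= 0) return(NULL)
    return(c(p$v0 / abs(p$a0), Inf))
  }
  disc <- p$a0^2 - 4 * p$x * p$v0
  if (disc < 0) return(NULL) # only possible for x > 0: speed always positive
  r <- sort((-p$a0 + c(-1, 1) * sqrt(disc)) / (2 * p$x))
  if (p$x > 0) {
    # opens upward: negative between the roots
    if (r[2] <= 0) return(NULL)
    c(max(r[1], 0), r[2])
  } else {
    # opens downward: negative after the larger root
    c(max(r[2], 0), Inf)
  }
}

#' Cumulative food-mass intake
#'
#' Evaluates the cumulative intake polynomial
#' \eqn{e(t) = v_0 t + a_0 t^2/2 + x t^3/3} at time `t`. The model is valid
#' while the eating speed is non-negative; past the first speed zero the
#' intake plateaus (a child cannot "un-eat" food), so the value at the
#' extremum is returned for later times.
#'
#' @param params An [intake_params()] object.
#' @param t Time in minutes; vectorised, must be non-negative.
#' @return Intake in grams, same length as `t`.
#' @examples
#' cumulative_intake(intake_params(34, -5.2), 6.538462) # ~111.15 g
#' @export
cumulative_intake <- function(params, t) {
  stopifnot(inherits(params, "intake_params"), is.numeric(t))
  if (any(t < 0)) stop("`t` must be non-negative.")
  poly <- function(u) params$v0 * u + params$a0 * u^2 / 2 + params$x * u^3 / 3
  win <- speed_negative_window(params)
  if (is.null(win)) return(poly(t))
  # skip the integral accumulated while the clamped speed would be negative
  out <- poly(pmin(t, win[1]))
  if (is.finite(win[2])) {
    past <- t > win[2]
    out[past] <- out[past] + poly(t[past]) - poly(win[2])
  }
  out
}

#' Extremum time of the quadratic intake model
#'
#' Time at which the decelerating eating speed \eqn{v(t) = v_0 + a t}
#' reaches zero, i.e. \eqn{t^\ast = v_0/|a|}.
#'
#' @param v0 Initial eating speed (g/min).
#' @param a Deceleration (g/min^2); must be strictly negative.
#' @return Time in minutes.
#' @examples
#' extremum_time(34, -5.2) # 6.54 min for girls
#' extremum_time(42, -5.4) # 7.78 min for boys
#' @export
extremum_time <- function(v0, a) {
  stopifnot(is.numeric(v0), is.numeric(a))
  if (any(a >= 0)) {
    stop("no extremum: with `a` >= 0 the eating speed never reaches zero.")
  }
  v0 / abs(a)
}

#' Maximal intake of the quadratic model
#'
#' Cumulative intake at the extremum time, \eqn{v_0^2 / (2|a|)}: the total
#' food mass a child eating with initial speed `v0` and deceleration `a`
#' can consume before the speed hits zero.
#'
#' @inheritParams extremum_time
#' @return Mass in grams.
#' @examples
#' max_intake(34, -5.2) # 111.15 g
#' max_intake(42, -5.4) # 163.33 g
#' @export
max_intake <- function(v0, a) {
  stopifnot(is.numeric(v0), is.numeric(a))
  if (any(a >= 0)) {
    stop("unbounded intake: with `a` >= 0 cumulative intake never plateaus.")
  }
  v0^2 / (2 * abs(a))
}

#' Double a reported eating-speed deceleration
#'
#' Converts a deceleration reported for the quadratic cumulative-intake
#' parameterisation \eqn{e(t) = k t^2 + v_0 t} into the acceleration of the
#' speed model \eqn{v(t) = v_0 + a t}: integrating \eqn{v} halves the
#' coefficient, so the declared value must be doubled before use here.
#'
#' @param reported Reported deceleration (g/min^2).
#' @return `2 * reported`.
#' @examples
#' doubled_deceleration(-2.6) # -5.2
#' @export
doubled_deceleration <- function(reported) {
  stopifnot(is.numeric(reported))
  2 * reported
}

#' Solve for the cubic eating-speed acceleration
#'
#' Given initial speed, initial deceleration, and an observed total intake at
#' lunch end, returns the cubic coefficient `x` such that the cumulative
#' intake model reproduces the observed total:
#' \eqn{x = 3 (E - v_0 t - a_0 t^2/2) / t^3}.
#'
#' @param v0 Initial eating speed (g/min).
#' @param a0 Initial deceleration (g/min^2).
#' @param total_intake Observed total intake `E` at time `t` (g).
#' @param t Lunch duration (min); must be strictly positive.
#' @return Cubic acceleration `x` in g/min^3.
#' @examples
#' solve_cubic_acceleration(42, -5.4, 289, 8.8) # ~0.566 for boys
#' @export
solve_cubic_acceleration <- function(v0, a0, total_intake, t) {
  stopifnot(is.numeric(v0), is.numeric(a0), is.numeric(total_intake),
            is.numeric(t))
  if (any(t <= 0)) stop("`t` must be strictly positive.")
  3 * (total_intake - v0 * t - a0 * t^2 / 2) / t^3
}

#' Average eating speed over a lunch
#'
#' \eqn{\bar v = e(t)/t}: the constant speed that yields the same cumulative
#' intake as the full model over `[0, t]`.
#'
#' @inheritParams cumulative_intake
#' @return Speed in g/min.
#' @examples
#' average_speed(intake_params(42, -5.4, 0.56), 8.8) # ~32.7 g/min
#' @export
average_speed <- function(params, t) {
  if (any(t <= 0)) stop("`t` must be strictly positive.")
  cumulative_intake(params, t) / t
}

#' Linear intake--speed relation
#'
#' The empirical linear relation between school-lunch food-mass intake `E`
#' (g) and objective eating rate `v` (g/min): `E(v) = slope * v + intercept`
#' and its inverse `v(E) = (E - intercept)/slope`.
#'
#' @param slope Minutes-equivalent coefficient (default 6.8).
#' @param intercept Intercept in grams (default 125).
#' @return An object of class `intake_speed_relation`.
#' @export
intake_speed_relation <- function(slope = 6.8, intercept = 125) {
  stopifnot(is.numeric(slope), length(slope) == 1L,
            is.numeric(intercept), length(intercept) == 1L)
  if (slope <= 0) stop("`slope` must be strictly positive.")
  structure(list(slope = slope, intercept = intercept),
            class = "intake_speed_relation")
}

#' @rdname intake_speed_relation
#' @param v Eating rate (g/min), non-negative; vectorised.
#' @param rel An [intake_speed_relation()].
#' @examples
#' intake_from_speed(35)  # 363 g
#' speed_from_intake(540) # ~61 g/min
#' @export
intake_from_speed <- function(v, rel = intake_speed_relation()) {
  stopifnot(inherits(rel, "intake_speed_relation"), is.numeric(v))
  if (any(v < 0)) stop("`v` must be non-negative.")
  rel$slope * v + rel$intercept
}

#' @rdname intake_speed_relation
#' @param E Food-mass intake (g); vectorised. Values below the intercept
#'   yield a negative (flagged) speed.
#' @export
speed_from_intake <- function(E, rel = intake_speed_relation()) {
  stopifnot(inherits(rel, "intake_speed_relation"), is.numeric(E))
  v <- (E - rel$intercept) / rel$slope
  if (any(v < 0)) {
    warning("intake below the relation intercept gives a negative speed.")
  }
  v
}

#' Worked kinetics table for a group
#'
#' For one or more groups described by initial speed, deceleration, observed
#' total intake and lunch duration, computes the quadratic model's extremum
#' time and maximal intake, the cubic coefficient recalibrated to reproduce
#' the observed intake, and the resulting average speed.
#'
#' @param groups A data frame with columns `group`, `v0` (g/min),
#'   `a0` (g/min^2, negative), `total_intake` (g) and `t` (min).
#' @return A tibble with one row per group and columns `extremum_min`,
#'   `max_intake_g`, `x_gpm3`, `avg_speed_gpm` added.
#' @examples
#' kinetics_table(tibble::tibble(
#'   group = c("girls", "boys"), v0 = c(34, 42), a0 = c(-5.2, -5.4),
#'   total_intake = c(258, 289), t = c(10.7, 8.8)
#' ))
#' @export
kinetics_table <- function(groups) {
  stopifnot(is.data.frame(groups),
            all(c("group", "v0", "a0", "total_intake", "t") %in% names(groups)))
  groups |>
    tibble::as_tibble() |>
    dplyr::mutate(
      extremum_min  = extremum_time(.data$v0, .data$a0),
      max_intake_g  = max_intake(.data$v0, .data$a0),
      x_gpm3        = solve_cubic_acceleration(.data$v0, .data$a0,
                                               .data$total_intake, .data$t),
      avg_speed_gpm = purrr::pmap_dbl(
        list(.data$v0, .data$a0, .data$x_gpm3, .data$t),
        function(v0, a0, x, t) average_speed(intake_params(v0, a0, x), t)
      )
    )
}
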