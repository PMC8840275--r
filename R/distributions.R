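#' Bounded component distribution
#'
#' Describes the sampling distribution of one portion component: a family,
#' its location/scale parameters (grams), and a closed support interval.
#' Samples are kept inside the bounds by rejection (resampling), which
#' preserves the distribution's shape inside the interval, rather than by
#' clipping, which would pile mass on the endpoints. For the shifted
#' exponential the location is the support start itself, so only the upper
#' bound ever rejects.
#'
#' @param family One of `"normal"`, `"gumbel"`, `"exponential"` (shifted:
#'   `location + Exp(scale)`), or `"constant"`.
#' @param location Location parameter in grams (mean for normal, location
#'   for gumbel, shift for exponential, the value for constant).
#' @param scale Scale parameter in grams (sd for normal; ignored for
#'   constant).
#' @param bounds Closed interval `c(min, max)` the samples must lie in.
#' @return An object of class `component_dist`.
#' @examples
#' soup <- component_dist("normal", 225, 37.5, c(150, 300))
#' range(draw_component(soup, 1000))
#' @export
component_dist <- function(family, location, scale = NA_real_,
                           bounds = c(-Inf, Inf)) {
  family <- match.arg(family, c("normal", "gumbel", "exponential", "constant"))
  stopifnot(is.numeric(location), length(location) == 1L,
            is.numeric(bounds), length(bounds) == 2L)
  if (bounds[1] > bounds[2]) stop("`bounds` must satisfy min <= max.")
  if (family != "constant" && (!is.finite(scale) || scale <= 0)) {
    stop("`scale` must be a positive number for family '", family, "'.")
  }
  if (family == "constant" &&
      (location < bounds[1] || location > bounds[2])) {
    stop("constant value lies outside `bounds`.")
  }
  structure(list(family = family, location = location, scale = scale,
                 bounds = bounds),
            class = "component_dist")
}

#' @export
print.component_dist <- function(x, ...) {
  cat(sprintf("<component_dist> %s(%g%s) on [%g, %g] g\n", x$family,
              x$location, if (is.na(x$scale)) "" else paste0(", ", x$scale),
              x$bounds[1], x$bounds[2]))
  invisible(x)
}

raw_draw <- function(dist, n) {
  switch(dist$family,
    normal      = stats::rnorm(n, dist$location, dist$scale),
    # max-Gumbel via inverse CDF, location/scale parameterisation
    gumbel      = dist$location - dist$scale * log(-log(stats::runif(n))),
    exponential = dist$location + stats::rexp(n, rate = 1 / dist$scale),
    constant    = rep(dist$location, n)
  )
}

#' Sample from a bounded component distribution
#'
#' @param dist A [component_dist()].
#' @param n Number of samples.
#' @return A numeric vector of `n` samples in grams, all inside
#'   `dist$bounds`.
#' @export
draw_component <- function(dist, n = 1) {
  stopifnot(inherits(dist, "component_dist"), n >= 0)
  x <- raw_draw(dist, n)
  if (dist$family == "constant") return(x)
  for (iter in seq_len(1000L)) {
    bad <- x < dist$bounds[1] | x > dist$bounds[2]
    if (!any(bad)) return(x)
    x[bad] <- raw_draw(dist, sum(bad))
  }
  stop("rejection sampling failed to land inside bounds after 1000 rounds; ",
       "check the distribution parameters against the bounds.")
}
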