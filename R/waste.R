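#' Rejected-food waste-fraction configuration
#'
#' Per-category distributions of the fraction of a served component wasted
#' on a hated day, plus the stable preference skips: half of children do not
#' eat soup and 8% do not eat the main dish, in which case the whole
#' component is left. Milk has no observed rejected-waste category and
#' defaults to a constant fraction of 0. All sampled fractions are clamped
#' to `[0, 1]`.
#'
#' @param fractions Named list (components `m, s, sd, ld, b, fp, mk`) of
#'   `list(family, location, scale)` fraction specs, `family` one of
#'   `"normal"` or `"constant"`.
#' @param soup_skip_prob Probability that the whole soup is left (default
#'   0.5).
#' @param main_skip_prob Probability that the whole main dish is left
#'   (default 0.08).
#' @param skips_on_hated_days_only If `TRUE`, the soup/main skips apply only
#'   on hated days; by default they encode stable dislikes and apply every
#'   day.
#' @return An object of class `waste_fraction_config`.
#' @export
waste_fraction_config <- function(fractions = list(
                                    m  = list("normal", 0.30, 0.05),
                                    s  = list("normal", 0.15, 0.03),
                                    sd = list("constant", 0.02),
                                    ld = list("normal", 0.35, 0.07),
                                    b  = list("constant", 0.05),
                                    fp = list("normal", 0.30, 0.10),
                                    mk = list("constant", 0)
                                  ),
                                  soup_skip_prob = 0.5,
                                  main_skip_prob = 0.08,
                                  skips_on_hated_days_only = FALSE) {
  stopifnot(all(meal_components() %in% names(fractions)))
  for (nm in c("soup_skip_prob", "main_skip_prob")) {
    p <- get(nm)
    if (!is.numeric(p) || p < 0 || p > 1) {
      stop("`", nm, "` must be a probability in [0,1].")
    }
  }
  for (f in fractions) {
    if (!f[[1]] %in% c("normal", "constant")) {
      stop("waste-fraction families must be 'normal' or 'constant'.")
    }
  }
  structure(list(fractions = fractions, soup_skip_prob = soup_skip_prob,
                 main_skip_prob = main_skip_prob,
                 skips_on_hated_days_only = isTRUE(skips_on_hated_days_only)),
            class = "waste_fraction_config")
}

#' Competitive-food impact configuration
#'
#' When a child eats competitive food, a displacement level `k` is drawn
#' uniformly from four midpoints and each portion component is wasted in a
#' fraction `normal(k, k_sd)`, clamped to `[0, 1]` (the `"literal"`
#' semantics, following the model's pseudocode). The alternative
#' `"complement"` semantics reads `k` as an *eaten* fraction with
#' survey-derived bin weights and wastes `1 - normal(k, k_sd)`.
#'
#' @param k_values Displacement midpoints (default
#'   `c(0.12, 0.37, 0.62, 0.87)`).
#' @param k_sd Spread of the per-component fraction around `k` (default
#'   0.06).
#' @param semantics `"literal"` (default) or `"complement"`.
#' @param complement_weights Bin weights for the `"complement"` reading
#'   (default: the survey's answer shares averaged over the two
#'   competitive-food sources, normalised).
#' @return An object of class `competitive_config`.
#' @export
competitive_config <- function(k_values = c(0.12, 0.37, 0.62, 0.87),
                               k_sd = 0.06,
                               semantics = c("literal", "complement"),
                               complement_weights = c(0.236, 0.1805,
                                                      0.2915, 0.2915)) {
  semantics <- match.arg(semantics)
  if (any(k_values < 0) || any(k_values > 1)) {
    stop("`k_values` must lie in [0,1].")
  }
  stopifnot(is.numeric(k_sd), k_sd >= 0,
            length(complement_weights) == length(k_values),
            all(complement_weights >= 0))
  structure(list(k_values = k_values, k_sd = k_sd, semantics = semantics,
                 complement_weights =
                   complement_weights / sum(complement_weights)),
            class = "competitive_config")
}

portion_matrix <- function(portions) {
  stopifnot(is.data.frame(portions),
            all(meal_components() %in% names(portions)))
  as.matrix(portions[meal_components()])
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

# --- stage 1: competitive food -------------------------------------------

competitive_waste_matrix <- function(P, ef, cfg) {
  n <- nrow(P)
  if (cfg$semantics == "literal") {
    k <- sample(cfg$k_values, n, replace = TRUE)
    frac <- clamp01(matrix(stats::rnorm(n * 7L, mean = k, sd = cfg$k_sd),
                           n, 7L))
  } else {
    k <- sample(cfg$k_values, n, replace = TRUE,
                prob = cfg$complement_weights)
    frac <- clamp01(1 - matrix(stats::rnorm(n * 7L, mean = k, sd = cfg$k_sd),
                               n, 7L))
  }
  P * frac * ef
}

# --- stage 2: rejected food ----------------------------------------------

rejected_waste_matrix <- function(P, W_ef, hated, cfg) {
  n <- nrow(P)
  Fh <- matrix(0, n, 7L, dimnames = list(NULL, meal_components()))
  for (j in seq_along(meal_components())) {
    f <- cfg$fractions[[meal_components()[j]]]
    Fh[, j] <- if (f[[1]] == "constant") f[[2]] else
      clamp01(stats::rnorm(n, f[[2]], f[[3]]))
  }
  W <- P * Fh * hated
  skip_active <- if (cfg$skips_on_hated_days_only) hated else rep(1L, n)
  hs <- stats::rbinom(n, 1L, cfg$soup_skip_prob) * skip_active
  hm <- stats::rbinom(n, 1L, cfg$main_skip_prob) * skip_active
  W[, "s"] <- ifelse(hs == 1L, P[, "s"], W[, "s"])
  W[, "m"] <- ifelse(hm == 1L, P[, "m"], W[, "m"])
  # a child already filled by competitive food cannot reject more than
  # remains on the plate
  pmax(pmin(W, P - W_ef), 0)
}

# --- stage 3: insufficient time ------------------------------------------

time_waste_matrix <- function(R, vs, vl, stops, t_avail) {
  if (!is.numeric(t_avail) || length(t_avail) != 1L || t_avail < 0) {
    stop("`t_avail` must be a single non-negative number of minutes.")
  }
  n <- nrow(R)
  rate <- matrix(vs, n, 7L)
  liq <- match(liquid_components(), meal_components())
  rate[, liq] <- vl
  Tm <- R / rate
  Ct <- Tm
  for (j in 2:7) Ct[, j] <- Ct[, j - 1L] + Tm[, j]
  frac <- (t_avail - (Ct - Tm)) / Tm
  frac[Tm == 0] <- 1
  frac <- clamp01(frac)
  W <- R * (1 - frac)
  W[stops == 0L, ] <- 0 # the child eats on and arrives late instead
  W
}

simulate_days_matrix <- function(P, vs, vl, ef, stops, hated, t_avail,
                                 waste, competitive, ideal = FALSE) {
  if (ideal) {
    ef <- rep(0L, nrow(P))
    hated <- rep(0L, nrow(P))
    waste$soup_skip_prob <- 0
    waste$main_skip_prob <- 0
  }
  w_ef <- competitive_waste_matrix(P, ef, competitive)
  w_h <- rejected_waste_matrix(P, w_ef, hated, waste)
  w_t <- time_waste_matrix(P - w_ef - w_h, vs, vl, stops, t_avail)
  list(w_ef = w_ef, w_h = w_h, w_t = w_t,
       eaten = P - w_ef - w_h - w_t)
}

breakdown_tibble <- function(P, parts, extra = NULL) {
  out <- tibble::tibble(
    component = rep(meal_components(), each = nrow(P)),
    portion_g = as.vector(P),
    eaten_g = as.vector(parts$eaten),
    w_ef_g = as.vector(parts$w_ef),
    w_h_g = as.vector(parts$w_h),
    w_t_g = as.vector(parts$w_t)
  )
  if (!is.null(extra)) out <- dplyr::bind_cols(extra, out)
  out
}

# --- public per-child surface --------------------------------------------

#' Competitive-food waste
#'
#' Stage 1 of the plate-waste decomposition. For children flagged as
#' competitive-food eaters, each component of the portion is displaced by a
#' fraction drawn around a random impact level; other children waste
#' nothing at this stage.
#'
#' @param portions A portion tibble (rows are child-days) with the seven
#'   component columns.
#' @param child A one-row tibble from [generate_child()] (or a tibble with
#'   `nrow(portions)` rows, matched row-wise).
#' @param cfg A [competitive_config()].
#' @return A tibble of the same shape as the component columns of
#'   `portions`, holding grams wasted per component.
#' @export
competitive_impact <- function(portions, child, cfg = competitive_config()) {
  P <- portion_matrix(portions)
  ef <- rep_len(child$ef, nrow(P))
  tibble::as_tibble(as.data.frame(competitive_waste_matrix(P, ef, cfg)))
}

#' Rejected-food waste
#'
#' Stage 2 of the decomposition. On a hated day each component is wasted in
#' its category fraction; every day, the whole soup is left with probability
#' 0.5 and the whole main dish with probability 0.08 (stable dislikes).
#' Finally the rejected amount is capped at what competitive food left on
#' the plate (and floored at zero).
#'
#' @param portions Portion tibble (rows are child-days).
#' @param w_ef Competitive-food waste from [competitive_impact()], same
#'   shape.
#' @param day_hated Binary vector (recycled): is this a hated day for the
#'   child?
#' @param cfg A [waste_fraction_config()].
#' @return Tibble of rejected-food grams per component.
#' @export
rejected_impact <- function(portions, w_ef, day_hated,
                            cfg = waste_fraction_config()) {
  P <- portion_matrix(portions)
  W_ef <- portion_matrix(w_ef)
  if (any(W_ef > P + 1e-9)) {
    stop("`w_ef` exceeds the portion componentwise; invalid input.")
  }
  hated <- rep_len(as.integer(day_hated), nrow(P))
  tibble::as_tibble(as.data.frame(
    rejected_waste_matrix(P, W_ef, hated, cfg)
  ))
}

#' Insufficient-time waste
#'
#' Stage 3 of the decomposition. The remaining food is consumed in eating
#' order (main part, then dessert, then bread / fresh product / milk),
#' liquids at rate `vl` and solids at `vs`. If the required time exceeds the
#' available time and the child stops eating, the unconsumed remainder is
#' wasted; a child who eats on (arriving late) wastes nothing at this
#' stage.
#'
#' @param remaining Tibble of grams still on the plate per component (rows
#'   are child-days).
#' @param child One-row tibble with `vs`, `vl` and `stops` (recycled).
#' @param t_avail Available eating time in minutes (single non-negative
#'   number).
#' @return Tibble of time-limited waste grams per component.
#' @export
time_limited_waste <- function(remaining, child, t_avail) {
  R <- portion_matrix(remaining)
  n <- nrow(R)
  tibble::as_tibble(as.data.frame(time_waste_matrix(
    R, rep_len(child$vs, n), rep_len(child$vl, n),
    rep_len(child$stops, n), t_avail
  )))
}

#' Simulate one child-day plate
#'
#' Applies the three waste stages in order -- competitive food, rejected
#' food (using the child's hated-day flag for `day_index`), insufficient
#' time -- and returns a tidy conservation-satisfying breakdown: for every
#' component, `portion = eaten + w_ef + w_h + w_t`.
#'
#' @param portion One-row portion tibble.
#' @param child One-row child tibble from [generate_child()].
#' @param day_index Weekday index 1 (Mon) .. 5 (Fri).
#' @param t_avail Available eating time in minutes.
#' @param waste A [waste_fraction_config()].
#' @param competitive A [competitive_config()].
#' @param ideal If `TRUE`, competitive food, hated days and preference skips
#'   are disabled so that only the time constraint can produce waste.
#' @return A 7-row tibble with columns `component`, `portion_g`, `eaten_g`,
#'   `w_ef_g`, `w_h_g`, `w_t_g`.
#' @examples
#' set.seed(1)
#' simulate_child_day(generate_portion(), generate_child(),
#'                    day_index = 1, t_avail = 19)
#' @export
simulate_child_day <- function(portion, child, day_index, t_avail,
                               waste = waste_fraction_config(),
                               competitive = competitive_config(),
                               ideal = FALSE) {
  stopifnot(nrow(portion) == 1L, nrow(child) == 1L,
            day_index %in% 1:5)
  P <- portion_matrix(portion)
  hated <- as.integer(child[[c("hd_mon", "hd_tue", "hd_wed", "hd_thu",
                               "hd_fri")[day_index]]])
  parts <- simulate_days_matrix(P, child$vs, child$vl, child$ef,
                                child$stops, hated, t_avail,
                                waste, competitive, ideal)
  breakdown_tibble(P, parts)
}

#' Simulate a child's school week
#'
#' Runs [simulate_child_day()] over the five days of a week menu and sums
#' the breakdown per component; weekly conservation
#' `sum(portion) = sum(eaten + w_ef + w_h + w_t)` holds by construction.
#'
#' @param child One-row child tibble.
#' @param week A 5-row week menu from [generate_week()].
#' @inheritParams simulate_child_day
#' @return A 7-row tibble of weekly per-component totals, same columns as
#'   [simulate_child_day()].
#' @export
run_week <- function(child, week, t_avail,
                     waste = waste_fraction_config(),
                     competitive = competitive_config(),
                     ideal = FALSE) {
  stopifnot(nrow(child) == 1L, nrow(week) == 5L)
  P <- portion_matrix(week)
  hated <- as.integer(child[c("hd_mon", "hd_tue", "hd_wed", "hd_thu",
                              "hd_fri")])
  parts <- simulate_days_matrix(P, rep(child$vs, 5L), rep(child$vl, 5L),
                                rep(child$ef, 5L), rep(child$stops, 5L),
                                hated, t_avail, waste, competitive, ideal)
  breakdown_tibble(P, parts) |>
    dplyr::group_by(.data$component) |>
    dplyr::summarise(dplyr::across(dplyr::everything(), sum),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$component, meal_components()))
}

#' Total waste fraction of a breakdown
#'
#' Mass-weighted waste fraction of a per-component breakdown: total wasted
#' grams over total served grams. Optionally excludes the liquid dessert
#' from both numerator and denominator (a common reporting convention,
#' since drinks dominate the wasted mass).
#'
#' @param breakdown A breakdown tibble from [simulate_child_day()] or
#'   [run_week()].
#' @param exclude_liquid_dessert Drop the `ld` rows before computing the
#'   fraction.
#' @return A single waste fraction in `[0, 1]`.
#' @export
waste_fraction <- function(breakdown, exclude_liquid_dessert = FALSE) {
  stopifnot(is.data.frame(breakdown),
            all(c("component", "portion_g", "w_ef_g", "w_h_g", "w_t_g")
                %in% names(breakdown)))
  if (exclude_liquid_dessert) {
    breakdown <- dplyr::filter(breakdown, .data$component != "ld")
  }
  with(breakdown, sum(w_ef_g + w_h_g + w_t_g) / sum(portion_g))
}
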