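#' Simulation scenario configuration
#'
#' Bundles the two scenario inputs -- nominal lunch duration and the share
#' of children unsatisfied with school food -- with the behavioural and
#' distributional sub-configurations and the Monte Carlo settings. The
#' scenario-level `pr_unsatisfied` and `ef_prob` override the corresponding
#' population fields so the two sweep axes stay in one place.
#'
#' @param lunch_duration Nominal lunch duration in minutes (> 0).
#' @param pr_unsatisfied Share of unsatisfied children (default 0.27).
#' @param ef_prob Competitive-food probability (default 0.30).
#' @param repetitions Monte Carlo repetitions; one repetition is one
#'   (child, week-menu) pair (default 10000).
#' @param walking_delay Minutes of the nominal break spent walking to and
#'   from the canteen (default 6: about 3 min each way), subtracted before
#'   eating starts.
#' @param seed Optional integer seed; if set, results are bit-reproducible.
#' @param ideal_mode If `TRUE`, competitive food, hated days and preference
#'   skips are disabled, so only the time constraint produces waste.
#' @param menu A [menu_config()].
#' @param population A [population_config()].
#' @param waste A [waste_fraction_config()].
#' @param competitive A [competitive_config()].
#' @return An object of class `simulation_config`.
#' @examples
#' cfg <- simulation_config(lunch_duration = 25, repetitions = 500, seed = 1)
#' run_simulation(cfg)
#' @export
simulation_config <- function(lunch_duration = 25, pr_unsatisfied = 0.27,
                              ef_prob = 0.30, repetitions = 10000,
                              walking_delay = 6, seed = NULL,
                              ideal_mode = FALSE,
                              menu = menu_config(),
                              population = population_config(),
                              waste = waste_fraction_config(),
                              competitive = competitive_config()) {
  if (!is.numeric(lunch_duration) || length(lunch_duration) != 1L ||
      lunch_duration <= 0) {
    stop("invalid `lunch_duration`: must be a single positive number of minutes.")
  }
  if (!is.numeric(repetitions) || repetitions < 1) {
    stop("invalid `repetitions`: must be at least 1.")
  }
  if (!is.numeric(walking_delay) || walking_delay < 0) {
    stop("invalid `walking_delay`: must be non-negative minutes.")
  }
  for (nm in c("pr_unsatisfied", "ef_prob")) {
    p <- get(nm)
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
      stop("invalid `", nm, "`: must be a probability in [0,1].")
    }
  }
  if (!is.null(seed)) {
    if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
      stop("invalid `seed`: must be a single integer or NULL.")
    }
    seed <- as.integer(seed %% .Machine$integer.max)
  }
  stopifnot(inherits(menu, "menu_config"),
            inherits(population, "population_config"),
            inherits(waste, "waste_fraction_config"),
            inherits(competitive, "competitive_config"))
  population$pr_unsatisfied <- pr_unsatisfied
  population$ef_prob <- ef_prob
  structure(list(lunch_duration = lunch_duration,
                 pr_unsatisfied = pr_unsatisfied, ef_prob = ef_prob,
                 repetitions = as.integer(repetitions),
                 walking_delay = walking_delay, seed = seed,
                 ideal_mode = isTRUE(ideal_mode), menu = menu,
                 population = population, waste = waste,
                 competitive = competitive),
            class = "simulation_config")
}

#' Effective eating time
#'
#' Subtracts the walking delay (time spent reaching and leaving the
#' canteen) from the nominal lunch duration, floored at zero.
#'
#' @param nominal Nominal lunch duration in minutes (> 0).
#' @param walking_delay Walking delay in minutes (default 6).
#' @return Effective minutes available for eating.
#' @examples
#' effective_duration(15) # 9
#' @export
effective_duration <- function(nominal, walking_delay = 6) {
  stopifnot(is.numeric(nominal), is.numeric(walking_delay))
  if (any(nominal <= 0)) stop("`nominal` duration must be positive.")
  pmax(0, nominal - walking_delay)
}

# Vectorised engine: simulates `reps` independent (child, week-menu) pairs
# in one set of matrix operations over rep-day rows.
simulate_weeks <- function(cfg) {
  reps <- cfg$repetitions
  t_avail <- effective_duration(cfg$lunch_duration, cfg$walking_delay)
  P <- portion_matrix(generate_portions(reps * 5L, cfg$menu))
  ch <- generate_population(reps, cfg$population)
  i <- rep(seq_len(reps), each = 5L)
  day <- rep.int(1:5, reps)
  hd <- as.matrix(ch[c("hd_mon", "hd_tue", "hd_wed", "hd_thu", "hd_fri")])
  parts <- simulate_days_matrix(
    P, ch$vs[i], ch$vl[i], ch$ef[i], ch$stops[i],
    hd[cbind(i, day)], t_avail, cfg$waste, cfg$competitive,
    ideal = cfg$ideal_mode
  )
  list(P = P, parts = parts, rep = i)
}

#' Run a Monte Carlo plate-waste simulation
#'
#' Simulates `repetitions` independent (child, week-menu) pairs at the
#' walking-adjusted lunch duration, decomposes every plate into eaten mass
#' and the three waste components, and aggregates mass-weighted weekly
#' waste fractions. With `ideal_mode`, only insufficient time can produce
#' waste. Fully reproducible when `seed` is set in the configuration.
#'
#' @param cfg A [simulation_config()].
#' @return An object of class `plate_waste_sim` with elements `weekly`
#'   (per-repetition tibble: `rep`, `portion_g`, `waste_g`, `waste_frac`,
#'   `waste_frac_excl_ld`), `components` (per-component mean fractions of
#'   served mass lost to each waste cause), `summary` (one-row tibble:
#'   mean, sd, Monte Carlo standard error, quantiles) and `config`.
#'   [generics::tidy()] returns the component table, [generics::glance()]
#'   the summary row.
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "simulation_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  sim <- simulate_weeks(cfg)
  P <- sim$P; parts <- sim$parts; rp <- sim$rep

  waste_all <- parts$w_ef + parts$w_h + parts$w_t
  ld <- match("ld", meal_components())
  tot_p <- unname(rowsum(rowSums(P), rp)[, 1])
  tot_w <- unname(rowsum(rowSums(waste_all), rp)[, 1])
  tot_p_x <- unname(rowsum(rowSums(P[, -ld, drop = FALSE]), rp)[, 1])
  tot_w_x <- unname(rowsum(rowSums(waste_all[, -ld, drop = FALSE]), rp)[, 1])

  weekly <- tibble::tibble(
    rep = sort(unique(rp)),
    portion_g = tot_p,
    waste_g = tot_w,
    waste_frac = tot_w / tot_p,
    waste_frac_excl_ld = tot_w_x / tot_p_x
  )
  comp_p <- colSums(P)
  components <- tibble::tibble(
    component = meal_components(),
    served_g_mean = comp_p / cfg$repetitions,
    w_ef_frac = colSums(parts$w_ef) / comp_p,
    w_h_frac = colSums(parts$w_h) / comp_p,
    w_t_frac = colSums(parts$w_t) / comp_p
  ) |>
    dplyr::mutate(waste_frac = .data$w_ef_frac + .data$w_h_frac +
                    .data$w_t_frac)

  q <- stats::quantile(weekly$waste_frac, c(0.05, 0.25, 0.5, 0.75, 0.95))
  summary <- tibble::tibble(
    n_reps = cfg$repetitions,
    lunch_duration = cfg$lunch_duration,
    effective_min = effective_duration(cfg$lunch_duration,
                                       cfg$walking_delay),
    pr_unsatisfied = cfg$pr_unsatisfied,
    ef_prob = cfg$ef_prob,
    ideal_mode = cfg$ideal_mode,
    mean_waste_frac = mean(weekly$waste_frac),
    mean_waste_frac_excl_ld = mean(weekly$waste_frac_excl_ld),
    sd_waste_frac = stats::sd(weekly$waste_frac),
    se_waste_frac = stats::sd(weekly$waste_frac) / sqrt(cfg$repetitions),
    q05 = q[[1]], q25 = q[[2]], median = q[[3]], q75 = q[[4]], q95 = q[[5]]
  )
  structure(list(weekly = weekly, components = components,
                 summary = summary, config = cfg),
            class = "plate_waste_sim")
}

#' @export
print.plate_waste_sim <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0("<plate_waste_sim> %d reps | %g min lunch (%g min eating) | ",
           "unsatisfied %.2f | competitive %.2f%s\n"),
    s$n_reps, s$lunch_duration, s$effective_min, s$pr_unsatisfied,
    s$ef_prob, if (s$ideal_mode) " | ideal" else ""))
  cat(sprintf("  mean weekly waste: %.2f%% of served mass (SE %.3f%%)\n",
              100 * s$mean_waste_frac, 100 * s$se_waste_frac))
  cat(sprintf("  excluding liquid dessert: %.2f%%\n",
              100 * s$mean_waste_frac_excl_ld))
  invisible(x)
}

cell_seed <- function(base, idx) {
  if (is.null(base)) return(NULL)
  as.integer((as.numeric(base) + 7919 * idx) %% (.Machine$integer.max - 1) + 1)
}

#' Sweep lunch duration and unsatisfied share
#'
#' Runs [run_simulation()] over the grid of lunch durations and unsatisfied
#' shares, with a per-cell seed derived from the base seed so the grid is
#' reproducible regardless of evaluation order. The long-format result is
#' the basis of the surface "tomograms" of mean waste over the two scenario
#' axes.
#'
#' @param cfg A [simulation_config()] providing everything but the two axes.
#' @param durations Numeric vector of nominal lunch durations (minutes).
#' @param shares Numeric vector of unsatisfied shares (probabilities).
#' @return A tibble of class `waste_sweep` with columns `duration_min`,
#'   `unsatisfied_share`, `mean_waste_frac`, `se`, `n_reps`.
#' @export
sweep_grid <- function(cfg, durations, shares) {
  stopifnot(inherits(cfg, "simulation_config"),
            length(durations) >= 1, length(shares) >= 1)
  grid <- tidyr::expand_grid(duration_min = durations,
                             unsatisfied_share = shares)
  res <- purrr::pmap_dfr(
    list(grid$duration_min, grid$unsatisfied_share, seq_len(nrow(grid))),
    function(d, u, idx) {
      cell <- cfg
      cell$lunch_duration <- d
      cell$pr_unsatisfied <- u
      cell$population$pr_unsatisfied <- u
      cell$seed <- cell_seed(cfg$seed, idx)
      g <- run_simulation(cell)$summary
      tibble::tibble(duration_min = d, unsatisfied_share = u,
                     mean_waste_frac = g$mean_waste_frac,
                     se = g$se_waste_frac, n_reps = g$n_reps)
    }
  )
  class(res) <- c("waste_sweep", class(res))
  res
}

#' Minimal adequate lunch duration under ideal conditions
#'
#' Scans a grid of lunch durations with competitive food and food rejection
#' disabled (only the time constraint binds) and returns the smallest
#' duration at which the mean weekly waste fraction drops below a
#' threshold. The scan uses the lower recalculated eating rate (27(2)
#' g/min by default) so the answer covers slower eaters, excludes walking
#' time, and couples all durations on one random stream (same seed per
#' duration) so the curve is monotone by construction.
#'
#' @param cfg A [simulation_config()]; `ideal_mode` is forced on and
#'   `walking_delay` to 0.
#' @param durations Duration grid in minutes (default `1:40`, 1-min steps).
#' @param rate_mean,rate_sd Eating rate used for the scan (default 27(2)
#'   g/min).
#' @param threshold Waste-fraction threshold defining "adequate" (default
#'   0.02).
#' @return An object of class `duration_scan`: list with `optimal_min`,
#'   `threshold`, and the `curve` tibble (`duration_min`,
#'   `mean_waste_frac`, `se`). If the threshold is never reached the grid
#'   maximum is returned with a warning.
#' @export
optimal_duration <- function(cfg = simulation_config(),
                             durations = 1:40,
                             rate_mean = 27, rate_sd = 2,
                             threshold = 0.02) {
  stopifnot(inherits(cfg, "simulation_config"), length(durations) >= 1,
            threshold >= 0)
  cfg$ideal_mode <- TRUE
  cfg$walking_delay <- 0
  cfg$population$rate_mean <- rate_mean
  cfg$population$rate_sd <- rate_sd
  durations <- sort(durations)
  curve <- purrr::map_dfr(durations, function(d) {
    cc <- cfg
    cc$lunch_duration <- d
    g <- run_simulation(cc)$summary # same seed per duration: coupled replay
    tibble::tibble(duration_min = d, mean_waste_frac = g$mean_waste_frac,
                   se = g$se_waste_frac)
  })
  below <- curve$duration_min[curve$mean_waste_frac < threshold]
  if (length(below) == 0L) {
    warning("threshold ", threshold, " not reached on the duration grid; ",
            "returning the grid maximum.")
    opt <- max(durations)
  } else {
    opt <- min(below)
  }
  structure(list(optimal_min = opt, threshold = threshold, curve = curve),
            class = "duration_scan")
}

#' @export
print.duration_scan <- function(x, ...) {
  cat(sprintf(
    "<duration_scan> minimal adequate eating duration: %g min (waste < %g%%)\n",
    x$optimal_min, 100 * x$threshold))
  invisible(x)
}
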