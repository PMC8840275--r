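#' Child-population configuration
#'
#' Parameters for generating child agents: the compromise eating rate for
#' solid food (liquids are drunk at twice the solid rate), the probability of
#' eating competitive food (home food, the optional school menu, or food
#' bought outside school), the share of children unsatisfied with the school
#' meal, the propensity to stop eating when lunch time runs out (the
#' alternative being to eat on and arrive late to class), and the weekly
#' hated-day count distributions for satisfied and unsatisfied children.
#'
#' @param pr_unsatisfied Probability a child is unsatisfied with school food
#'   (default 0.27, survey-derived).
#' @param ef_prob Probability a child eats competitive food (default 0.30).
#' @param rate_mean,rate_sd Mean and sd of the solid-food eating rate in
#'   g/min (default 35(5), the compromise rate).
#' @param stop_prob Probability a child stops eating when time is
#'   insufficient (default 0.67).
#' @param hated_mean_unsat,hated_mean_sat,hated_sd Normal parameters of the
#'   weekly hated-day count: mean 3 for unsatisfied and 0 for satisfied
#'   children, sd 0.5; draws are clamped to `[0, 5]` and rounded.
#' @return An object of class `population_config`.
#' @export
population_config <- function(pr_unsatisfied = 0.27, ef_prob = 0.30,
                              rate_mean = 35, rate_sd = 5, stop_prob = 0.67,
                              hated_mean_unsat = 3, hated_mean_sat = 0,
                              hated_sd = 0.5) {
  for (nm in c("pr_unsatisfied", "ef_prob", "stop_prob")) {
    p <- get(nm)
    if (!is.numeric(p) || length(p) != 1L || p < 0 || p > 1) {
      stop("`", nm, "` must be a probability in [0,1].")
    }
  }
  if (!is.numeric(rate_mean) || rate_mean <= 0) {
    stop("`rate_mean` must be strictly positive.")
  }
  if (!is.numeric(rate_sd) || rate_sd < 0) stop("`rate_sd` must be >= 0.")
  structure(list(pr_unsatisfied = pr_unsatisfied, ef_prob = ef_prob,
                 rate_mean = rate_mean, rate_sd = rate_sd,
                 stop_prob = stop_prob, hated_mean_unsat = hated_mean_unsat,
                 hated_mean_sat = hated_mean_sat, hated_sd = hated_sd),
            class = "population_config")
}

# Rank of each entry within its row for an n x 5 matrix (no ties in
# practice: continuous draws). Used to pick h distinct hated weekdays
# uniformly at random without an apply() loop.
row_ranks5 <- function(U) {
  rk <- matrix(1L, nrow(U), 5L)
  for (j in 1:5) {
    for (k in 1:5) if (k != j) rk[, j] <- rk[, j] + (U[, k] < U[, j])
  }
  rk
}

#' Generate hated-day vectors
#'
#' Draws the weekly count of hated (rejected-food) days from a normal
#' distribution whose mean depends on satisfaction -- 3(0.5) days for
#' unsatisfied children, 0(0.5) for satisfied -- clamps it to `[0, 5]`,
#' rounds to the nearest integer, and marks that many distinct weekdays
#' (chosen uniformly at random) as hated.
#'
#' @param u Integer vector of unsatisfied flags (0/1), one per child.
#' @param cfg A [population_config()].
#' @return A binary matrix with `length(u)` rows and 5 columns (Mon--Fri);
#'   row sums equal the drawn hated-day counts.
#' @export
generate_hated_days <- function(u, cfg = population_config()) {
  stopifnot(inherits(cfg, "population_config"), all(u %in% c(0, 1)))
  n <- length(u)
  mu <- ifelse(u == 1, cfg$hated_mean_unsat, cfg$hated_mean_sat)
  h <- round(pmin(pmax(stats::rnorm(n, mu, cfg$hated_sd), 0), 5))
  rk <- row_ranks5(matrix(stats::runif(n * 5L), n, 5L))
  hd <- 1L * (rk <= h)
  colnames(hd) <- c("hd_mon", "hd_tue", "hd_wed", "hd_thu", "hd_fri")
  hd
}

#' Generate a population of child agents
#'
#' Each child carries a solid-food eating rate `vs` (normal, resampled if
#' non-positive), the liquid rate `vl = 2 vs`, a competitive-food flag `ef`,
#' an unsatisfied flag `u`, a stop-when-out-of-time propensity `stops`
#' (drawn once per child: a stable disposition), and a binary hated-day
#' vector for the five weekdays.
#'
#' @param n Number of children (>= 1).
#' @param cfg A [population_config()].
#' @return A tibble with `n` rows and columns `child_id`, `vs`, `vl`, `ef`,
#'   `u`, `stops`, `hd_mon` .. `hd_fri`.
#' @examples
#' set.seed(1)
#' generate_population(3)
#' @export
generate_population <- function(n, cfg = population_config()) {
  stopifnot(inherits(cfg, "population_config"))
  if (!is.numeric(n) || length(n) != 1L || n < 1) {
    stop("`n` must be a positive count.")
  }
  n <- as.integer(n)
  vs <- stats::rnorm(n, cfg$rate_mean, cfg$rate_sd)
  for (iter in seq_len(1000L)) {
    bad <- vs <= 0
    if (!any(bad)) break
    vs[bad] <- stats::rnorm(sum(bad), cfg$rate_mean, cfg$rate_sd)
  }
  u <- stats::rbinom(n, 1L, cfg$pr_unsatisfied)
  out <- tibble::tibble(
    child_id = seq_len(n),
    vs = vs,
    vl = 2 * vs,
    ef = stats::rbinom(n, 1L, cfg$ef_prob),
    u = u,
    stops = stats::rbinom(n, 1L, cfg$stop_prob)
  )
  dplyr::bind_cols(out, tibble::as_tibble(generate_hated_days(u, cfg)))
}

#' @rdname generate_population
#' @export
generate_child <- function(cfg = population_config()) {
  generate_population(1L, cfg)
}
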