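# Shared fixtures: built in code, no stored data.

# A fixed single portion with every component present (grams).
fixed_portion <- function() {
  tibble::tibble(m = 230, s = 255, sd = 40, ld = 200, b = 25, fp = 30,
                 mk = 200)
}

# A deterministic child: fast eater, no behavioural flags.
calm_child <- function(vs = 35, ef = 0L, stops = 1L, hated = rep(0L, 5)) {
  tibble::tibble(child_id = 1L, vs = vs, vl = 2 * vs, ef = as.integer(ef),
                 u = 0L, stops = as.integer(stops),
                 hd_mon = hated[1], hd_tue = hated[2], hd_wed = hated[3],
                 hd_thu = hated[4], hd_fri = hated[5])
}

# Waste config with every behavioural channel switched off.
no_rejection_waste <- function() {
  waste_fraction_config(
    fractions = list(
      m = list("constant", 0), s = list("constant", 0),
      sd = list("constant", 0), ld = list("constant", 0),
      b = list("constant", 0), fp = list("constant", 0),
      mk = list("constant", 0)
    ),
    soup_skip_prob = 0, main_skip_prob = 0
  )
}

# Scenario with all waste-producing behaviour off and ample time.
zero_waste_config <- function(reps = 50, seed = 11) {
  simulation_config(
    lunch_duration = 1000, pr_unsatisfied = 0, ef_prob = 0,
    repetitions = reps, walking_delay = 0, seed = seed,
    waste = no_rejection_waste()
  )
}

# Numerical oracle for cumulative intake: integrate the speed clamped at
# zero, independent of the closed-form path under test.
intake_oracle <- function(v0, a0, x, t) {
  stats::integrate(function(u) pmax(v0 + a0 * u + x * u^2, 0), 0, t,
                   rel.tol = 1e-10)$value
}
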