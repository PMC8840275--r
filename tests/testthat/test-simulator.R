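test_that("effective duration subtracts the walking delay, floored at 0", {
  expect_equal(effective_duration(15, 6), 9)
  expect_equal(effective_duration(30, 6), 24)
  expect_equal(effective_duration(10, 0), 10)
  expect_equal(effective_duration(4, 6), 0)
  expect_error(effective_duration(0, 6), "positive")
})

test_that("configuration rejects invalid fields by name", {
  expect_error(simulation_config(lunch_duration = -5), "lunch_duration")
  expect_error(simulation_config(repetitions = 0), "repetitions")
  expect_error(simulation_config(pr_unsatisfied = 1.4), "pr_unsatisfied")
  expect_error(simulation_config(ef_prob = -0.1), "ef_prob")
  expect_error(simulation_config(seed = "abc"), "seed")
})

test_that("the scenario axes override the population fields", {
  cfg <- simulation_config(pr_unsatisfied = 0.5, ef_prob = 0.1)
  expect_equal(cfg$population$pr_unsatisfied, 0.5)
  expect_equal(cfg$population$ef_prob, 0.1)
})

test_that("simulations are bit-reproducible under a fixed seed", {
  cfg <- simulation_config(repetitions = 300, seed = 401)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$weekly, r2$weekly)
  expect_identical(r1$summary, r2$summary)
})

test_that("a single repetition reports that week's own fractions", {
  cfg <- simulation_config(repetitions = 1, seed = 402)
  r <- run_simulation(cfg)
  expect_identical(nrow(r$weekly), 1L)
  expect_equal(r$summary$mean_waste_frac, r$weekly$waste_frac)
  expect_equal(r$summary$sd_waste_frac, NA_real_)
})

test_that("weekly fractions are conserved and bounded", {
  r <- run_simulation(simulation_config(repetitions = 500, seed = 403))
  expect_true(all(r$weekly$waste_frac >= 0 & r$weekly$waste_frac <= 1))
  expect_true(all(r$components$waste_frac >= 0 &
                    r$components$waste_frac <= 1))
  # component fractions decompose additively into the three causes
  expect_equal(r$components$waste_frac,
               with(r$components, w_ef_frac + w_h_frac + w_t_frac))
})

test_that("ideal mode with unlimited time produces essentially no waste", {
  cfg <- simulation_config(lunch_duration = 10000, repetitions = 300,
                           seed = 404, ideal_mode = TRUE)
  r <- run_simulation(cfg)
  expect_lt(r$summary$mean_waste_frac, 0.001)
})

test_that("the zero-behaviour scenario wastes exactly nothing", {
  r <- run_simulation(zero_waste_config(reps = 100))
  expect_equal(max(r$weekly$waste_frac), 0)
})

test_that("Monte Carlo standard errors follow the sqrt(n) law", {
  se_at <- function(n, seed) {
    run_simulation(simulation_config(repetitions = n,
                                     seed = seed))$summary$se_waste_frac
  }
  se1 <- se_at(800, 405)
  se4 <- se_at(3200, 406)
  expect_lt(abs(se1 / se4 - 2), 0.4) # quadrupling reps halves the SE
})

test_that("mean waste is monotone in duration and unsatisfied share", {
  # coupled replay along the duration axis: the same seed replays the same
  # menus, children and behavioural draws, only the time budget changes
  waste_at <- function(d, u = 0.27) {
    run_simulation(simulation_config(
      lunch_duration = d, pr_unsatisfied = u, repetitions = 2000,
      seed = 407
    ))$summary$mean_waste_frac
  }
  by_dur <- vapply(c(8, 12, 16, 20, 25, 30, 40), waste_at, numeric(1))
  expect_true(all(diff(by_dur) <= 1e-12))
  by_share <- vapply(c(0, 0.25, 0.5, 0.75, 1),
                     function(u) waste_at(30, u), numeric(1))
  expect_true(all(diff(by_share) > 0))
})

test_that("sweeps are reproducible grids with one cell per combination", {
  cfg <- simulation_config(repetitions = 200, seed = 408)
  g <- sweep_grid(cfg, durations = c(15, 25), shares = c(0, 0.27, 0.8))
  expect_identical(nrow(g), 6L)
  expect_s3_class(g, "waste_sweep")
  expect_true(all(g$n_reps == 200))
  g2 <- sweep_grid(cfg, durations = c(15, 25), shares = c(0, 0.27, 0.8))
  expect_identical(as.data.frame(g), as.data.frame(g2))
  # a 1x1 grid is a single run at the derived cell seed
  g1 <- sweep_grid(cfg, durations = 25, shares = 0.27)
  cell <- cfg
  cell$seed <- platewaste:::cell_seed(cfg$seed, 1L)
  expect_equal(g1$mean_waste_frac,
               run_simulation(cell)$summary$mean_waste_frac)
})

test_that("waste grows linearly with the unsatisfied share at ample time", {
  cfg <- simulation_config(lunch_duration = 60, repetitions = 2000,
                           seed = 409)
  g <- sweep_grid(cfg, durations = 60, shares = seq(0, 1, by = 0.1))
  fit <- lm(mean_waste_frac ~ unsatisfied_share, data = g)
  expect_gt(summary(fit)$r.squared, 0.95)
  expect_gt(coef(fit)[2], 0)
})

test_that("optimal duration scan returns a monotone curve and threshold", {
  cfg <- simulation_config(repetitions = 800, seed = 410)
  scan <- optimal_duration(cfg, durations = seq(4, 34, by = 2))
  expect_true(all(diff(scan$curve$mean_waste_frac) <= 1e-12))
  expect_true(scan$optimal_min %in% scan$curve$duration_min)
  # threshold 1 is met everywhere: the grid minimum is returned
  all_ok <- optimal_duration(cfg, durations = seq(10, 20, by = 5),
                             threshold = 1)
  expect_equal(all_ok$optimal_min, 10)
  expect_warning(
    optimal_duration(cfg, durations = 1:2, threshold = 1e-6),
    "not reached"
  )
})

test_that("tidiers expose the summary and component tables", {
  r <- run_simulation(simulation_config(repetitions = 100, seed = 411))
  expect_identical(generics::glance(r), r$summary)
  expect_identical(generics::tidy(r), r$components)
  expect_s3_class(ggplot2::autoplot(r), "ggplot")
  g <- sweep_grid(simulation_config(repetitions = 50, seed = 412),
                  c(15, 25), c(0, 0.5))
  expect_s3_class(ggplot2::autoplot(g), "ggplot")
})
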