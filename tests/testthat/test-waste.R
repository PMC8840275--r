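test_that("competitive food wastes nothing for non-users", {
  set.seed(301)
  w <- competitive_impact(fixed_portion(), calm_child(ef = 0))
  expect_true(all(as.matrix(w) == 0))
})

test_that("competitive impact averages the four displacement midpoints", {
  set.seed(302)
  n <- 10000
  P <- fixed_portion()[rep(1, n), ]
  w <- competitive_impact(P, calm_child(ef = 1))
  frac <- rowSums(as.matrix(w)) / portion_mass(P)
  # mean of {0.12, 0.37, 0.62, 0.87} is 0.495 (enumerating the four
  # equally likely outcomes); clamping at [0,1] shifts it negligibly
  expect_lt(abs(mean(frac) - 0.495), 0.01)
  expect_true(all(as.matrix(w) >= 0))
  expect_true(all(as.matrix(w) <= as.matrix(P[meal_components()]) + 1e-12))
})

test_that("complement semantics wastes one minus the eaten fraction", {
  set.seed(303)
  cfg <- competitive_config(semantics = "complement")
  n <- 10000
  P <- fixed_portion()[rep(1, n), ]
  w <- competitive_impact(P, calm_child(ef = 1), cfg)
  frac <- rowSums(as.matrix(w)) / portion_mass(P)
  # expected 1 - sum(weights * midpoints), enumerated over the four bins
  expected <- 1 - sum(cfg$complement_weights * cfg$k_values)
  expect_lt(abs(mean(frac) - expected), 0.01)
})

test_that("a plate already emptied by competitive food rejects nothing", {
  set.seed(304)
  P <- fixed_portion()
  w_ef <- P # everything displaced
  w_h <- rejected_impact(P, w_ef, day_hated = 1)
  expect_true(all(as.matrix(w_h) == 0))
  expect_error(rejected_impact(P, P * 2, 1), "exceeds")
})

test_that("hated-day main-dish waste mixes the category fraction and skip", {
  set.seed(305)
  n <- 10000
  P <- fixed_portion()[rep(1, n), ]
  zero <- P; zero[] <- 0
  w_h <- rejected_impact(P, zero, day_hated = 1)
  # mixture: full rejection at 8%, else normal(0.30, 0.05) of the dish
  expect_lt(abs(mean(w_h$m / P$m) - (0.92 * 0.30 + 0.08)), 0.01)
  # soup: full soup with probability 0.5, else the 15% category fraction
  expect_lt(abs(mean(w_h$s / P$s) - (0.5 * 0.15 + 0.5)), 0.01)
  # solid dessert and bread use constant fractions when not displaced
  expect_true(all(w_h$sd == 0.02 * P$sd | w_h$sd == 0))
  # milk has no rejected-waste category
  expect_true(all(w_h$mk == 0))
})

test_that("preference skips can be restricted to hated days", {
  set.seed(306)
  cfg <- waste_fraction_config(skips_on_hated_days_only = TRUE)
  n <- 2000
  P <- fixed_portion()[rep(1, n), ]
  zero <- P; zero[] <- 0
  w_h <- rejected_impact(P, zero, day_hated = 0, cfg)
  expect_true(all(as.matrix(w_h) == 0))
})

test_that("time-limited waste follows the linear two-rate model", {
  ch <- calm_child(vs = 35, stops = 1)
  solid <- tibble::tibble(m = 350, s = 0, sd = 0, ld = 0, b = 0, fp = 0,
                          mk = 0)
  w <- time_limited_waste(solid, ch, t_avail = 5)
  expect_equal(w$m, 350 - 35 * 5) # 175 g left when time runs out
  expect_true(all(as.matrix(time_limited_waste(solid, ch, 1000)) == 0))
  w0 <- time_limited_waste(fixed_portion(), ch, 0)
  expect_equal(as.matrix(w0), as.matrix(fixed_portion()[meal_components()]),
               ignore_attr = TRUE)
  # liquids are drunk at twice the solid rate
  liquid <- tibble::tibble(m = 0, s = 350, sd = 0, ld = 0, b = 0, fp = 0,
                           mk = 0)
  expect_equal(time_limited_waste(liquid, ch, 5)$s, 350 - 70 * 5)
  # a child who eats on (arriving late) wastes nothing to time
  late <- calm_child(vs = 35, stops = 0)
  expect_true(all(as.matrix(time_limited_waste(solid, late, 1)) == 0))
  expect_error(time_limited_waste(solid, ch, -1), "non-negative")
})

test_that("consumption allocates in eating order under time pressure", {
  ch <- calm_child(vs = 35, stops = 1)
  P <- fixed_portion() # m 230, s 255, sd 40, ld 200, b 25, fp 30, mk 200
  # main dish takes 230/35 = 6.571 min; give just enough for it plus half
  # the soup (soup at 70 g/min)
  t <- 230 / 35 + (255 / 2) / 70
  w <- time_limited_waste(P, ch, t)
  expect_equal(w$m, 0, tolerance = 1e-9)
  expect_equal(w$s, 255 / 2, tolerance = 1e-9)
  expect_equal(w$sd, 40)   # later courses untouched
  expect_equal(w$mk, 200)
})

test_that("every simulated child-day conserves mass componentwise", {
  set.seed(308)
  cfg <- simulation_config(repetitions = 2000, seed = 308)
  sim <- platewaste:::simulate_weeks(cfg) # 10,000 child-days
  resid <- sim$P - sim$parts$eaten - sim$parts$w_ef - sim$parts$w_h -
    sim$parts$w_t
  expect_lt(max(abs(resid)), 1e-9)
  expect_true(all(sim$parts$w_ef >= 0) && all(sim$parts$w_h >= 0) &&
                all(sim$parts$w_t >= 0) && all(sim$parts$eaten >= -1e-9))
  # rejected food never exceeds what competitive food left
  expect_true(all(sim$parts$w_h <= sim$P - sim$parts$w_ef + 1e-9))
})

test_that("simulate_child_day composes the three stages tidily", {
  set.seed(309)
  bd <- simulate_child_day(generate_portion(), generate_child(), 3, 10)
  expect_identical(nrow(bd), 7L)
  expect_equal(bd$portion_g, bd$eaten_g + bd$w_ef_g + bd$w_h_g + bd$w_t_g,
               tolerance = 1e-9)
  f <- waste_fraction(bd)
  expect_true(f >= 0 && f <= 1)
  # excluding a category never increases wasted grams
  keep <- dplyr::filter(bd, component != "ld")
  expect_lte(sum(keep$w_ef_g + keep$w_h_g + keep$w_t_g),
             sum(bd$w_ef_g + bd$w_h_g + bd$w_t_g))
})

test_that("with all behaviour off and ample time a week wastes nothing", {
  set.seed(310)
  ch <- calm_child(ef = 0)
  wk <- run_week(ch, generate_week(), t_avail = 1000,
                 waste = no_rejection_waste())
  expect_identical(nrow(wk), 7L)
  expect_true(all(wk$w_ef_g == 0 & wk$w_h_g == 0 & wk$w_t_g == 0))
  expect_equal(wk$eaten_g, wk$portion_g)
})

test_that("hated weeks waste at least as much as calm weeks, coupled", {
  set.seed(311)
  wk_menu <- generate_week()
  hated <- calm_child(ef = 0, hated = rep(1L, 5))
  calm <- calm_child(ef = 0, hated = rep(0L, 5))
  # the waste stages draw the same number of variates whatever the flags,
  # so re-seeding replays identical draws for both children
  set.seed(3111)
  w1 <- run_week(hated, wk_menu, 12)
  set.seed(3111)
  w0 <- run_week(calm, wk_menu, 12)
  expect_gte(sum(w1$w_ef_g + w1$w_h_g + w1$w_t_g),
             sum(w0$w_ef_g + w0$w_h_g + w0$w_t_g) - 1e-9)
})

test_that("total waste is non-increasing in available time, coupled", {
  grid <- c(0, 3, 6, 9, 12, 15, 20, 30)
  totals <- vapply(grid, function(t) {
    set.seed(312) # identical draws at every duration
    bd <- simulate_child_day(generate_portion(), generate_child(), 1, t)
    sum(bd$w_ef_g + bd$w_h_g + bd$w_t_g)
  }, numeric(1))
  expect_true(all(diff(totals) <= 1e-9))
})
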