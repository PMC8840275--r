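test_that("quadratic model reproduces the girls' and boys' worked numbers", {
  # girls: v0 = 34 g/min, doubled deceleration -5.2 g/min^2
  expect_equal(doubled_deceleration(-2.6), -5.2)
  expect_equal(extremum_time(34, -5.2), 6.538462, tolerance = 1e-6)
  expect_equal(max_intake(34, -5.2), 111.1538, tolerance = 1e-6)
  expect_equal(cumulative_intake(intake_params(34, -5.2), 34 / 5.2),
               max_intake(34, -5.2), tolerance = 1e-9)
  # boys: v0 = 42 g/min, doubled deceleration -5.4 g/min^2
  expect_equal(doubled_deceleration(-2.7), -5.4)
  expect_equal(extremum_time(42, -5.4), 7.777778, tolerance = 1e-6)
  expect_equal(max_intake(42, -5.4), 163.3333, tolerance = 1e-6)
  expect_equal(max_intake(0, -1), 0)
})

test_that("cumulative intake handles trivial and cubic cases", {
  expect_equal(cumulative_intake(intake_params(34, -5.2), 0), 0)
  expect_equal(cumulative_intake(intake_params(35), 2), 70)
  # cubic polynomial evaluated directly: 42*8.8 - 2.7*8.8^2 + (0.56/3)*8.8^3
  expect_equal(cumulative_intake(intake_params(42, -5.4, 0.56), 8.8),
               42 * 8.8 - 2.7 * 8.8^2 + 0.56 * 8.8^3 / 3, tolerance = 1e-12)
  expect_error(cumulative_intake(intake_params(35), -1), "non-negative")
})

test_that("intake plateaus once the eating speed reaches zero", {
  p <- intake_params(34, -5.2)
  t_star <- extremum_time(34, -5.2)
  expect_equal(cumulative_intake(p, c(t_star, 10, 100)),
               rep(max_intake(34, -5.2), 3), tolerance = 1e-9)
  # intake is never decreasing in t
  tt <- seq(0, 15, by = 0.25)
  expect_true(all(diff(cumulative_intake(p, tt)) >= -1e-12))
})

test_that("closed forms agree with numerical integration of clamped speed", {
  set.seed(42)
  for (i in 1:200) {
    v0 <- runif(1, 10, 60)
    a0 <- runif(1, -8, 0)
    x <- runif(1, 0, 1)
    t <- runif(1, 0, 15)
    p <- intake_params(v0, a0, x)
    # quadrature across the clamp kink limits the oracle's own precision
    expect_equal(cumulative_intake(p, t), intake_oracle(v0, a0, x, t),
                 tolerance = 1e-5)
    if (a0 < 0) {
      expect_equal(max_intake(v0, a0),
                   cumulative_intake(intake_params(v0, a0),
                                     extremum_time(v0, a0)),
                   tolerance = 1e-9)
    }
  }
})

test_that("speed never reaching zero is reported, not silently handled", {
  expect_error(extremum_time(10, 0), "no extremum")
  expect_error(max_intake(10, 0.5), "unbounded")
})

test_that("cubic recalibration round-trips the observed intake", {
  # boys' recalculation: x ~ 0.5656 (printed truncated as 0.56)
  x_b <- solve_cubic_acceleration(42, -5.4, 289, 8.8)
  expect_equal(x_b, 0.5656344, tolerance = 1e-6)
  expect_equal(cumulative_intake(intake_params(42, -5.4, x_b), 8.8), 289,
               tolerance = 1e-9)
  # girls' stated inputs give ~0.470, not the printed 0.55; both are exact
  # outputs of the same rearrangement and neither is silently corrected
  x_g <- solve_cubic_acceleration(34, -5.2, 258, 10.7)
  expect_equal(x_g, 0.469879, tolerance = 1e-5)
  expect_equal(cumulative_intake(intake_params(34, -5.2, x_g), 10.7), 258,
               tolerance = 1e-9)
  expect_equal(solve_cubic_acceleration(30, 0, 30 * 4, 4), 0)
  expect_error(solve_cubic_acceleration(30, 0, 120, 0), "positive")
  set.seed(7)
  for (i in 1:50) {
    v0 <- runif(1, 20, 50); a0 <- runif(1, -6, 0)
    t <- runif(1, 4, 15); E <- runif(1, 150, 400)
    x <- solve_cubic_acceleration(v0, a0, E, t)
    expect_equal(v0 * t + a0 * t^2 / 2 + x * t^3 / 3, E, tolerance = 1e-9)
  }
})

test_that("average speed satisfies the mean-value identity", {
  expect_equal(average_speed(intake_params(42, -5.4, 0.56), 8.8), 32.69546,
               tolerance = 1e-5) # prints as the reported 32.7 g/min
  expect_equal(average_speed(intake_params(34, -5.2, 0.55), 10.7), 27.16983,
               tolerance = 1e-5)
  expect_equal(average_speed(intake_params(40), 3.7), 40)
  expect_error(average_speed(intake_params(40), 0), "positive")
  set.seed(3)
  for (i in 1:50) {
    p <- intake_params(runif(1, 10, 60), runif(1, -5, 0), runif(1, 0, 0.8))
    t <- runif(1, 1, 12)
    expect_equal(average_speed(p, t) * t, cumulative_intake(p, t),
                 tolerance = 1e-9)
  }
})

test_that("intake-speed relation evaluates and inverts", {
  expect_equal(intake_from_speed(0), 125)
  expect_equal(intake_from_speed(35), 6.8 * 35 + 125)
  expect_equal(speed_from_intake(540), 61.02941, tolerance = 1e-5)
  expect_equal(speed_from_intake(390), 38.97059, tolerance = 1e-5)
  expect_equal(speed_from_intake(125), 0)
  v <- c(0, 10, 35, 61)
  expect_equal(speed_from_intake(intake_from_speed(v)), v, tolerance = 1e-12)
  expect_warning(speed_from_intake(100), "negative")
  expect_error(intake_speed_relation(slope = -1), "positive")
})

test_that("kinetics_table reproduces the per-group worked values", {
  tab <- kinetics_table(tibble::tibble(
    group = c("girls", "boys"), v0 = c(34, 42), a0 = c(-5.2, -5.4),
    total_intake = c(258, 289), t = c(10.7, 8.8)
  ))
  expect_equal(round(tab$extremum_min, 1), c(6.5, 7.8))
  expect_equal(tab$max_intake_g, c(111.1538, 163.3333), tolerance = 1e-6)
  expect_equal(tab$x_gpm3, c(0.469879, 0.565634), tolerance = 1e-5)
  expect_equal(tab$avg_speed_gpm, c(258 / 10.7, 289 / 8.8),
               tolerance = 1e-9)
})
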