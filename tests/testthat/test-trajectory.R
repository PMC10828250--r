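test_that("S1 decline is linear in the baseline: 1 %/yr halves the function by 80", {
  spec <- scenario_spec("S1", baseline_mean = 100, baseline_sd = 0)
  expect_identical(trajectory_value(spec, 100, 80), 50)
  # not compounding: (1 - 0.01)^50 would leave ~60.5
  expect_false(isTRUE(all.equal(trajectory_value(spec, 100, 80), 100 * 0.99^50)))
})

test_that("no time elapsed returns the baseline in every scenario", {
  for (s in all_scenarios) {
    spec <- default_spec(s)
    expect_identical(
      trajectory_value(spec, 73.5, spec$baseline_age, slope = 0.4), 73.5
    )
  }
})

test_that("S4 matches a per-year gap-subtraction loop", {
  # independent oracle: lose convergence_rate * (b - floor) of the *original*
  # gap each year, i.e. the gap shrinks linearly
  spec <- scenario_spec("S4", convergence_floor = 20, convergence_rate = 0.016)
  loop_value <- function(b, years) {
    annual_loss <- spec$convergence_rate * (b - spec$convergence_floor)
    v <- b
    for (i in seq_len(years)) v <- v - annual_loss
    v
  }
  expect_equal(trajectory_value(spec, 100, 80), loop_value(100, 50)) # 36
  expect_equal(trajectory_value(spec, 100, 80), 36)
  expect_equal(trajectory_value(spec, 64, 55), loop_value(64, 25))
})

test_that("trajectories are affine in age: second differences vanish", {
  ages <- c(35, 50, 65)
  for (s in all_scenarios) {
    spec <- default_spec(s)
    v <- trajectory_value(spec, rep(88, 3), ages, slope = 0.7)
    expect_equal(diff(v, differences = 2), 0, tolerance = 1e-12)
  }
})

test_that("out-of-range ages and negative values raise classed errors", {
  spec <- scenario_spec("S2", absolute_rate = 1)
  expect_error(trajectory_value(spec, 100, 81), class = "agecovar_error_range")
  expect_error(trajectory_value(spec, 100, 20), class = "agecovar_error_range")
  # a baseline of 40 under 1 unit/yr loss crosses zero before 80
  err <- expect_error(
    trajectory_value(spec, 40, 75, subject = "s0007"),
    class = "agecovar_error_domain"
  )
  expect_match(conditionMessage(err), "s0007")
  expect_match(conditionMessage(err), "75")
  expect_error(trajectory_value(scenario_spec("S3"), 40, 75, slope = 1),
               class = "agecovar_error_domain")
  # S4 baseline below the floor is inadmissible
  expect_error(trajectory_value(scenario_spec("S4"), 10, 40),
               class = "agecovar_error_domain")
})

test_that("analytic moments carry each scenario's dispersion signature", {
  ages <- seq(30, 80, by = 1)

  s1 <- moment_trajectory(scenario_spec("S1", baseline_mean = 80, baseline_sd = 20), ages)
  expect_true(all(diff(s1$sd) < 0))
  expect_lt(diff(range(s1$covar)) / mean(s1$covar), 1e-12) # COVAR constant
  expect_equal(s1$covar[1], 25)

  s2 <- moment_trajectory(scenario_spec("S2", baseline_mean = 80, baseline_sd = 20,
                                        absolute_rate = 0.5), ages)
  expect_equal(diff(range(s2$sd)), 0)
  expect_true(all(diff(s2$covar) > 0))

  s3 <- moment_trajectory(scenario_spec("S3"), ages)
  expect_true(all(diff(s3$sd) > 0))
  expect_true(all(diff(s3$covar) > 0))

  s4 <- moment_trajectory(scenario_spec("S4"), ages)
  expect_true(all(diff(s4$sd) < 0))
  expect_true(all(diff(s4$covar) < 0))
})

test_that("three fixed S2 trajectories reproduce the brute-force moments", {
  # oracle: evaluate the three trajectories directly and take sample moments
  spec <- scenario_spec("S2", baseline_mean = 80, baseline_sd = 20, absolute_rate = 1)
  values_at_80 <- vapply(c(100, 80, 60), function(b) b - 1 * 50, numeric(1))
  expect_equal(values_at_80, c(50, 30, 10))
  m <- analytic_moments(spec, 80)
  expect_equal(m$mean, mean(values_at_80))           # 30
  expect_equal(m$sd, sd(values_at_80))               # 20 (n-1 denominator)
  expect_equal(m$covar, 100 * 20 / 30, tolerance = 1e-12)
})

test_that("S3 sd uses the truncated slope distribution", {
  # negligible-truncation case: matches the parent-normal closed form
  spec <- scenario_spec("S3", baseline_mean = 80, baseline_sd = 10,
                        slope_mean = 0.5, slope_sd = 0.2)
  m <- analytic_moments(spec, 80)
  # parent-normal closed form; truncation at -2.5 sigma shifts the sd ~1 %
  expect_equal(m$sd, sqrt(100 + 2500 * 0.04), tolerance = 0.02)

  # heavy-truncation case: compare against numerical integration of the
  # zero-truncated normal density (independent oracle)
  mu <- 0.2; sg <- 0.5
  z <- pnorm(0, mu, sg, lower.tail = FALSE)
  m1 <- integrate(function(x) x * dnorm(x, mu, sg) / z, 0, Inf)$value
  m2 <- integrate(function(x) x^2 * dnorm(x, mu, sg) / z, 0, Inf)$value
  tm <- truncnorm_moments(mu, sg)
  expect_equal(tm$mean, m1, tolerance = 1e-8)
  expect_equal(tm$sd, sqrt(m2 - m1^2), tolerance = 1e-8)
})

test_that("degenerate S4 with a zero floor reproduces S1 exactly", {
  ages <- seq(30, 80, length.out = 51)
  s1 <- moment_trajectory(scenario_spec("S1", relative_rate = 0.016), ages)
  s4 <- moment_trajectory(scenario_spec("S4", convergence_floor = 0,
                                        convergence_rate = 0.016), ages)
  expect_equal(s4, s1, tolerance = 1e-15)
})

test_that("moment trajectories anchor the S1 midpoint and endpoint", {
  m <- moment_trajectory(scenario_spec("S1"), c(30, 55, 80))
  expect_equal(m$mean, c(100, 75, 50))
  expect_equal(moment_trajectory(scenario_spec("S1"), 55),
               analytic_moments(scenario_spec("S1"), 55))
  expect_error(moment_trajectory(scenario_spec("S1"), c(40, 40)),
               class = "agecovar_error_contract")
})

test_that("COVAR is refused where the population mean is non-positive", {
  spec <- scenario_spec("S2", baseline_mean = 40, absolute_rate = 1, baseline_sd = 0)
  expect_error(analytic_moments(spec, 75), class = "agecovar_error_domain")
})
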