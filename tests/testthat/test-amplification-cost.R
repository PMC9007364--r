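test_that("a noiseless logistic is recovered essentially exactly", {
  times <- seq(0, 100, by = 2)
  fit <- fit_amplification(times, logistic_curve(times, tinf = 30))
  expect_true(fit$converged)
  expect_false(fit$failed_amplification)
  expect_lt(abs(fit$tinf - 30), 1e-6)
  expect_lt(abs(fit$rate - 0.2), 1e-6)
})

test_that("flat curves are flagged as failed amplification", {
  times <- seq(0, 100, by = 2)
  flat <- fit_amplification(times, rep(0.3, length(times)))
  expect_true(flat$failed_amplification)
  expect_identical(cost_of(flat), Inf)

  withr::with_seed(1, {
    noisy_flat <- fit_amplification(times, 0.3 + rnorm(length(times), 0, 0.05))
  })
  expect_true(noisy_flat$failed_amplification)
  expect_identical(cost_of(noisy_flat), Inf)
})

test_that("input contracts are enforced", {
  expect_error(fit_amplification(1:5, 1:5), class = "sagdiv_invalid_input")
  expect_error(fit_amplification(c(1, 2, 2, 3, 4, 5, 6, 7), rep(1, 8)),
               class = "sagdiv_invalid_input")
  expect_error(fit_amplification(1:8, c(1:7, NA)),
               class = "sagdiv_invalid_input")
})

test_that("tinf maximizes the fitted derivative and cost is affine-invariant", {
  times <- seq(0, 120, by = 2)
  for (s in 1:5) {
    y <- withr::with_seed(s, {
      logistic_curve(times, f0 = 0.1, a = 1, r = 0.15, tinf = 20 + 10 * s) +
        rnorm(length(times), 0, 0.03)
    })
    fit <- fit_amplification(times, y)
    expect_true(fit$converged)
    # analytic property: the logistic's steepest point is tinf
    grid <- seq(min(times), max(times), length.out = 2001)
    f <- fit$f0 + fit$amplitude / (1 + exp(-fit$rate * (grid - fit$tinf)))
    expect_lt(abs(grid[which.max(diff(f))] - fit$tinf), diff(grid)[1] * 2)
    # affine rescaling of fluorescence leaves the cost unchanged
    fit2 <- fit_amplification(times, 7.5 * y + 120)
    expect_equal(cost_of(fit2), cost_of(fit), tolerance = 1e-4)
  }
})

test_that("costs order cells and exclude failures", {
  times <- seq(0, 100, by = 2)
  early <- fit_amplification(times, logistic_curve(times, tinf = 20))
  late <- fit_amplification(times, logistic_curve(times, tinf = 40))
  expect_lt(cost_of(early), cost_of(late))
  expect_equal(cost_of(early), early$tinf)
})

test_that("ground-truth inflection is recovered from noisy curves", {
  cfg <- sim_config(seed = 31, n_cells = 30, curve_noise_sd = 0.05,
                    failure_rate = 0.1)
  cv <- sim_curves(cfg)
  costs <- amplification_costs(cv$curves)
  joined <- dplyr::left_join(costs, cv$truth, by = "cell_id")
  ok <- !joined$failed.y
  step <- 2 # grid spacing in minutes
  err <- abs(joined$tinf[ok] - joined$true_inflection[ok])
  expect_lte(median(err), 0.5 * step)
  expect_gte(mean(err <= 2 * step), 0.95)
  expect_true(all(joined$failed.x[!joined$failed.y] == FALSE))
  expect_true(all(is.infinite(joined$cost[joined$failed.y])))
})

test_that("FSC calibration recovers the generating log-linear model", {
  fsc <- c(10, 100, 1000, 10000)
  identity_model <- fit_fsc_calibration(fsc, fsc)
  expect_equal(identity_model$a, 1, tolerance = 1e-9)
  expect_equal(identity_model$b, 0, tolerance = 1e-9)
  expect_equal(identity_model$r_squared, 1, tolerance = 1e-12)

  d <- 10^(0.5 * log10(fsc) - 1)
  m <- fit_fsc_calibration(fsc, d)
  expect_equal(m$a, 0.5, tolerance = 1e-9)
  expect_equal(m$b, 1, tolerance = 1e-9)

  two <- fit_fsc_calibration(c(50, 500), c(1.1, 2.9))
  expect_equal(two$r_squared, 1, tolerance = 1e-12)

  expect_error(fit_fsc_calibration(c(5, 5), c(1, 2)),
               class = "sagdiv_invalid_input")
  expect_error(fit_fsc_calibration(c(-1, 10), c(1, 2)),
               class = "sagdiv_invalid_input")
})

test_that("diameter prediction follows D = 10^(a log10(FSC) - b)", {
  m1 <- structure(list(a = 1, b = 0, r_squared = 1, n = 2),
                  class = "sag_calibration")
  expect_equal(predict_diameter(m1, 100), 100)
  m2 <- structure(list(a = 0.5, b = 0, r_squared = 1, n = 2),
                  class = "sag_calibration")
  expect_equal(predict_diameter(m2, 100), 10)
  m3 <- structure(list(a = 1, b = 1, r_squared = 1, n = 2),
                  class = "sag_calibration")
  expect_equal(predict_diameter(m3, 100), 10)
  expect_error(predict_diameter(m1, -5), class = "sagdiv_invalid_input")

  # round trip through fit + predict on noiseless data
  fsc <- c(20, 80, 300, 1500)
  d <- 10^(0.7 * log10(fsc) - 0.3)
  m <- fit_fsc_calibration(fsc, d)
  expect_equal(predict_diameter(m, fsc), d, tolerance = 1e-9)
})

test_that("fit objects expose tidy/glance summaries", {
  times <- seq(0, 100, by = 2)
  fit <- fit_amplification(times, logistic_curve(times))
  td <- generics::tidy(fit)
  expect_identical(td$term, c("f0", "amplitude", "rate", "tinf"))
  expect_false(generics::glance(fit)$failed_amplification)
  cal <- fit_fsc_calibration(c(10, 100), c(1, 2))
  expect_identical(generics::tidy(cal)$term, c("a", "b"))
  expect_equal(generics::glance(cal)$r.squared, 1)
})
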