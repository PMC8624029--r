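test_that("noiseless log-release data are recovered exactly and round-trip", {
  tt <- c(5, 12, 24, 48, 96, 168, 240, 336, 432, 504)
  truth <- log_release_fit(-4.709, 34.822)
  frac <- cumulative_release_fraction(tt, truth)
  fit <- fit_log_release(release_profile(tt, frac, 34.822))
  expect_equal(fit$slope_a, -4.709, tolerance = 1e-10)
  expect_equal(fit$intercept_b, 34.822, tolerance = 1e-10)
  # round-trip identity: evaluating the fit reproduces the inputs
  expect_equal(cumulative_release_fraction(tt, fit), frac, tolerance = 1e-10)

  # flat profile (no release): slope 0, intercept = initial concentration
  flat <- fit_log_release(release_profile(tt, rep(0, length(tt)), 20))
  expect_equal(flat$slope_a, 0, tolerance = 1e-12)
  expect_equal(flat$intercept_b, 20, tolerance = 1e-12)
})

test_that("fit_log_release rejects degenerate input", {
  expect_error(fit_log_release(release_profile(c(1, 2), c(0, 0.1), 30)),
               "at least 3")
  expect_error(release_profile(c(0, 1, 2), c(0, 0.1, 0.2), 30),
               "positive")
  expect_error(release_profile(c(1, 2, 3), c(0, NA, 0.2), 30),
               "non-finite")
  expect_error(release_profile(c(1, 2, 3), c(0, 0.5, 1.2), 30),
               "\\[0, 1\\]")
})

test_that("hydrogel concentration follows the clamped log curve", {
  fit <- default_release_fit()
  expect_identical(hydrogel_concentration(1, fit), 34.822)
  expect_equal(hydrogel_concentration(0.25, fit), 34.822)  # held below t_floor
  expect_equal(hydrogel_concentration(504, fit), 5.51989, tolerance = 1e-4)
  expect_identical(hydrogel_concentration(10000, fit), 0)  # beyond t_zero
  expect_error(hydrogel_concentration(-1, fit), "non-negative")
})

test_that("cumulative release fraction matches the plateau and saturates", {
  fit <- default_release_fit()
  expect_identical(cumulative_release_fraction(1, fit), 0)
  expect_equal(cumulative_release_fraction(504, fit), 0.84148,
               tolerance = 1e-4)
  expect_identical(cumulative_release_fraction(fit$t_zero, fit), 1)
  expect_identical(cumulative_release_fraction(5000, fit), 1)
})

test_that("predicted cumulative release is monotone and bounded", {
  set.seed(42)
  for (rep in 1:25) {
    fit <- log_release_fit(slope_a = -runif(1, 0.5, 10),
                           intercept_b = runif(1, 5, 60),
                           t_floor = runif(1, 0.1, 2))
    tt <- sort(runif(40, 0, 3000))
    frac <- cumulative_release_fraction(tt, fit)
    expect_true(all(frac >= 0 & frac <= 1))
    expect_true(all(diff(frac) >= -1e-12))
  }
})

test_that("encapsulation efficiency handles the reported masses and edges", {
  expect_equal(encapsulation_efficiency(60, 34), 56.667, tolerance = 1e-4)
  expect_equal(round(encapsulation_efficiency(60, 34)), 57)
  expect_identical(encapsulation_efficiency(25, 25), 100)
  expect_identical(encapsulation_efficiency(25, 0), 0)
  expect_error(encapsulation_efficiency(10, 12), "retained")
  expect_error(encapsulation_efficiency(0, 0), "positive")
})

test_that("initial burst interpolates linearly within the observed range", {
  prof <- release_profile(c(5, 10, 20, 24), c(0.1, 0.2, 0.4, 0.36 + 0.04),
                          34.822)
  expect_equal(initial_burst(prof, 24), 40)        # observed point, exact
  expect_equal(initial_burst(prof, 15), 30)        # midpoint interpolation
  expect_equal(initial_burst(prof, 5), 10)         # first timepoint
  expect_error(initial_burst(prof, 2), "outside")
  expect_error(initial_burst(prof, 30), "outside")
})

test_that("slope recovery from noisy profiles is unbiased and accurate", {
  set.seed(2026)
  n_rep <- 200
  a_hat <- replicate(n_rep, {
    prof <- generate_release_profile(noise_sd = 0.5)
    fit_log_release(prof)$slope_a
  })
  # mean recovered slope within 3 standard errors of the truth
  se <- stats::sd(a_hat) / sqrt(n_rep)
  expect_lt(abs(mean(a_hat) - (-4.709)), 3 * se)
  # and individually accurate: median absolute error below 0.25 mg/mL/log-h
  expect_lt(stats::median(abs(a_hat - (-4.709))), 0.25)
})

test_that("profiles and fits survive CSV/YAML round-trips", {
  prof <- generate_release_profile(noise_sd = 0.3, seed = 7)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_release_profile(prof, csv)
  back <- read_release_profile(csv, prof$initial_concentration)
  expect_equal(back$times, prof$times)
  expect_equal(back$cumulative_released, prof$cumulative_released,
               tolerance = 1e-6)

  fit <- fit_log_release(prof)
  yml <- withr::local_tempfile(fileext = ".yaml")
  write_release_fit(fit, yml)
  fit2 <- read_release_fit(yml)
  expect_equal(fit2$slope_a, fit$slope_a)
  expect_equal(fit2$intercept_b, fit$intercept_b)
  expect_equal(fit2$t_floor, fit$t_floor)
})
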