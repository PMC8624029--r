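test_that("the solver matches closed forms for constant-input systems", {
  r <- 0.05; k <- 0.12
  one <- constant_input_system("c1", empty_transfers(), c(c1 = k), "c1", r)
  traj <- simulate_system(one, horizon = 100)
  exact <- single_compartment_solution(traj$time_h, r, k)
  idx <- traj$time_h > 0
  expect_lt(max(abs(traj$c1[idx] - exact[idx]) / exact[idx]), 1e-6)

  # loss-free compartment accumulates linearly
  acc <- constant_input_system("c1", empty_transfers(), NULL, "c1", r)
  traj <- simulate_system(acc, horizon = 50)
  expect_equal(traj$c1, r * traj$time_h, tolerance = 1e-8)

  # two-compartment cascade against the Bateman solution
  k1 <- 0.8; k2 <- 0.05
  casc <- constant_input_system(
    c("c1", "c2"),
    data.frame(source = "c1", target = "c2", rate_per_hr = k1),
    c(c2 = k2), "c1", r)
  traj <- simulate_system(casc, horizon = 200)
  exact <- bateman_cascade_solution(traj$time_h, r, k1, k2)
  idx <- traj$time_h > 0
  expect_lt(max(abs(traj$c1[idx] - exact$c1[idx]) / exact$c1[idx]), 1e-6)
  expect_lt(max(abs(traj$c2[idx] - exact$c2[idx]) / exact$c2[idx]), 1e-6)
})

test_that("adaptive and brute-force RK4 integrations agree on all routes", {
  p <- set_kin(default_parameters(), 1.4e-3)
  for (r in routes()) {
    sys <- build_model(r, p)
    traj <- simulate_system(sys, horizon = 150)
    ref <- rk4_vitreous(sys, horizon = 150, step = 0.01)
    num <- traj$vitreous[match(ref$time_h, traj$time_h)]
    expect_lt(max(abs(num - ref$vitreous)), 1e-6)
  }
})

test_that("mass balances against the analytic release integral", {
  p <- set_kin(default_parameters(), 1.4e-3)
  fit <- default_release_fit()
  a <- fit$slope_a; b <- fit$intercept_b
  horizon <- 400
  # kin * [ b*t_floor + integral_{t_floor}^{T} (a ln t + b) dt ]
  released <- p$kin * (b * 1 +
    (a * (horizon * log(horizon) - horizon) + b * horizon) -
    (a * (1 * log(1) - 1) + b * 1))
  for (r in routes()) {
    sys <- build_model(r, p)
    sys$eliminations[] <- 0
    traj <- simulate_system(sys, horizon = horizon)
    total <- sum(traj[nrow(traj), sys$compartments])
    expect_lt(abs(total - released) / released, 1e-6)
  }
})

test_that("concentrations stay non-negative under rate perturbations", {
  set.seed(5)
  for (r in routes()) {
    p <- default_parameters()
    p$permeation <- p$permeation * exp(runif(length(p$permeation), -0.7, 0.7))
    p$elimination <- p$elimination * exp(runif(2, -0.7, 0.7))
    p <- set_kin(p, 10^runif(1, -4, -2.5))
    traj <- simulate_system(build_model(r, p), horizon = 300)
    expect_gt(min(as.matrix(traj[, -1])), -1e-9)
  }
})

test_that("the system is linear in the depot outflow rate", {
  p1 <- set_kin(default_parameters(), 1e-3)
  p2 <- set_kin(default_parameters(), 2e-3)
  t1 <- simulate_system(build_model("subconjunctival", p1), horizon = 300)
  t2 <- simulate_system(build_model("subconjunctival", p2), horizon = 300)
  expect_lt(max(abs(t2$vitreous - 2 * t1$vitreous)) / max(t2$vitreous),
            1e-6)
})

test_that("threshold crossings are detected, refined, and grid-stable", {
  # hand-built piecewise-linear trajectory rising 0 -> 0.014 over 2 h
  traj <- structure(data.frame(time_h = c(0, 2), vitreous = c(0, 0.014)),
                    class = c("pk_trajectory", "data.frame"),
                    route = "custom")
  ev <- find_threshold_crossing(traj, "vitreous", 0.007)
  expect_equal(ev$crossing_time, 1)
  expect_identical(ev$direction, "upward")

  # never reached
  ev2 <- find_threshold_crossing(traj, "vitreous", 0.05)
  expect_true(is.na(ev2$crossing_time))

  expect_error(find_threshold_crossing(traj, "retina", 0.007),
               "unknown compartment")

  # crossing time invariant to grid refinement
  p <- calibrated_params()
  sys <- build_model("subconjunctival", p)
  coarse <- simulate_system(sys, horizon = 40)
  fine <- simulate_system(sys, horizon = 40,
                          times = seq(0, 40, by = 0.25))
  tc <- find_threshold_crossing(coarse, "vitreous", 0.007)$crossing_time
  tf <- find_threshold_crossing(fine, "vitreous", 0.007)$crossing_time
  expect_lt(abs(tc - tf), 0.05)
})

test_that("peak detection refines the grid maximum without undershooting", {
  # monotone series peaks at the horizon
  up <- structure(data.frame(time_h = 0:10, vitreous = (0:10)^1.5),
                  class = c("pk_trajectory", "data.frame"), route = "custom")
  pk <- find_peak(up, "vitreous")
  expect_equal(pk$t_peak, 10)

  # symmetric unimodal series peaks at the mode
  tt <- seq(0, 10, by = 0.5)
  bell <- structure(data.frame(time_h = tt, vitreous = exp(-(tt - 5)^2)),
                    class = c("pk_trajectory", "data.frame"), route = "custom")
  pk <- find_peak(bell, "vitreous")
  expect_equal(pk$t_peak, 5, tolerance = 1e-6)

  # refined peak is never below the grid maximum, on every route
  p <- calibrated_params()
  for (r in routes()) {
    traj <- simulate_system(build_model(r, p), horizon = 400)
    pk <- find_peak(traj, "vitreous")
    expect_gte(pk$c_peak, max(traj$vitreous))
  }
})

test_that("kin calibration is linear, self-consistent, and plausible", {
  p <- default_parameters()
  k1 <- calibrate_kin(p, target_peak = 0.34)
  k2 <- calibrate_kin(p, target_peak = 0.68)
  expect_equal(k2, 2 * k1, tolerance = 1e-10)

  # fixed point: the calibrated system reproduces the target peak
  traj <- simulate_system(build_model("intravitreal", set_kin(p, k1)))
  expect_equal(find_peak(traj, "vitreous")$c_peak, 0.34, tolerance = 1e-6)

  # magnitude agrees with the quasi-steady estimate
  qs <- 0.34 * (0.0234 + 0.0234 + 0.0329) / 34.822
  expect_gt(k1, qs / 3)
  expect_lt(k1, qs * 3)

  expect_error(calibrate_kin(p, target_peak = -1), "positive")
})

test_that("trajectories round-trip through CSV", {
  p <- calibrated_params()
  traj <- simulate_system(build_model("intravitreal", p), horizon = 50)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_trajectory(traj, csv)
  back <- read_trajectory(csv, route = "intravitreal")
  expect_identical(names(back), names(as.data.frame(traj)))
  expect_equal(back$vitreous, traj$vitreous, tolerance = 1e-6)
})
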