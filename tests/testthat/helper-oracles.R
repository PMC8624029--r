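# Independent oracles used across the suite:
#  - closed-form solutions for constant-input linear compartments,
#  - a plain fixed-step RK4 integrator built from the system's edge list
#    (no deSolve), for cross-checking the adaptive solver.

# single compartment, constant input r, first-order loss k (k may be 0)
single_compartment_solution <- function(t, r, k) {
  if (k == 0) r * t else (r / k) * (1 - exp(-k * t))
}

# cascade r -> C1 --k1--> C2 --k2--> out, zero initial conditions
bateman_cascade_solution <- function(t, r, k1, k2) {
  stopifnot(k1 != k2, k1 > 0, k2 > 0)
  c1 <- (r / k1) * (1 - exp(-k1 * t))
  c2 <- r / k2 + (r / (k1 - k2)) * exp(-k1 * t) -
    (r / k2 + r / (k1 - k2)) * exp(-k2 * t)
  list(c1 = c1, c2 = c2)
}

# constant-input system via the package's constructor: a flat release fit
# (slope 0) with kin = 1 injects exactly r mg/mL/hr
constant_input_system <- function(compartments, transfers, eliminations,
                                  input, r) {
  compartment_system(route = "custom", compartments = compartments,
                     transfers = transfers, eliminations = eliminations,
                     input_compartment = input, kin = 1,
                     release_fit = log_release_fit(0, r))
}

empty_transfers <- function() {
  data.frame(source = character(), target = character(),
             rate_per_hr = numeric())
}

# fixed-step classical RK4; derivative assembled from the edge list and
# the release fit directly, independent of simulate_system()/rhs()
rk4_vitreous <- function(system, horizon, step = 0.01, record_every = 1) {
  comps <- system$compartments
  n <- length(comps)
  A <- matrix(0, n, n, dimnames = list(comps, comps))
  tr <- system$transfers
  for (i in seq_len(nrow(tr))) {
    A[tr$target[i], tr$source[i]] <- A[tr$target[i], tr$source[i]] +
      tr$rate_per_hr[i]
    A[tr$source[i], tr$source[i]] <- A[tr$source[i], tr$source[i]] -
      tr$rate_per_hr[i]
  }
  diag(A) <- diag(A) - system$eliminations[comps]
  e_in <- as.numeric(comps == system$input_compartment)
  fit <- system$release_fit
  a <- fit$slope_a; b <- fit$intercept_b; tf <- fit$t_floor
  ch <- function(t) min(max(a * log(max(t, tf)) + b, 0), b)
  f <- function(t, y) as.vector(A %*% y) + e_in * system$kin * ch(t)
  n_steps <- round(horizon / step)
  y <- numeric(n)
  rec_t <- seq(0, horizon, by = record_every)
  out <- matrix(NA_real_, length(rec_t), 1)
  out[1] <- 0
  ri <- 2L
  vi <- match("vitreous", comps)
  t <- 0
  for (s in seq_len(n_steps)) {
    k1 <- f(t, y)
    k2 <- f(t + step / 2, y + step / 2 * k1)
    k3 <- f(t + step / 2, y + step / 2 * k2)
    k4 <- f(t + step, y + step * k3)
    y <- y + step / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    t <- s * step
    if (ri <= length(rec_t) && abs(t - rec_t[ri]) < step / 2) {
      out[ri] <- y[vi]
      ri <- ri + 1L
    }
  }
  data.frame(time_h = rec_t, vitreous = out[, 1])
}

calibrated_params <- function() {
  p <- default_parameters()
  set_kin(p, calibrate_kin(p))
}
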