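#' Generate a synthetic hydrogel release profile
#'
#' Emulates the in vitro release experiment: the remaining gel
#' concentration follows `true_a * ln(t) + true_b` with additive Gaussian
#' measurement noise, is clamped to the physical range `[0, true_b]`, and
#' is converted to a cumulative released fraction. Noise is additive on
#' the remaining concentration (symmetric, matching mean +/- SD
#' reporting), so consecutive fractions can decrease slightly; see
#' [release_profile()].
#'
#' Default timepoints mirror the three-week sampling schedule of the
#' release study: 5, 12, 24, 48, 96, 168, 240, 336, 432 and 504 h.
#'
#' @param true_a Generating slope, mg/mL per log-hour; default -4.709.
#' @param true_b Generating intercept (initial concentration), mg/mL;
#'   default 34.822.
#' @param timepoints Sampling times in hours, strictly increasing, `> 0`.
#' @param noise_sd Additive Gaussian SD on the remaining concentration,
#'   mg/mL, `>= 0`; default 0.5, the scale of the reported replicate SDs.
#' @param seed Optional integer seed for reproducibility.
#' @return A [release_profile()].
#' @export
#' @examples
#' prof <- generate_release_profile(noise_sd = 0, seed = 1)
#' prof$cumulative_released[length(prof$times)]  # ~0.842 at 504 h
generate_release_profile <- function(true_a = -4.709, true_b = 34.822,
                                     timepoints = c(5, 12, 24, 48, 96, 168,
                                                    240, 336, 432, 504),
                                     noise_sd = 0.5, seed = NULL) {
  stopifnot(is.numeric(true_a), is.numeric(true_b), true_b > 0,
            is.numeric(timepoints), all(timepoints > 0),
            all(diff(timepoints) > 0),
            is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  fit <- log_release_fit(true_a, true_b)
  remaining <- hydrogel_concentration(timepoints, fit) +
    stats::rnorm(length(timepoints), 0, noise_sd)
  remaining <- pmin(pmax(remaining, 0), true_b)
  release_profile(timepoints, 1 - remaining / true_b, true_b)
}

#' Generate noisy vitreous concentration observations
#'
#' Simulates one administration route and samples the vitreous
#' concentration at the requested times, applying multiplicative
#' lognormal noise with a given coefficient of variation (concentrations
#' are positive, so noise is multiplicative). The noise factor has mean
#' one, so replicate averages converge to the noiseless simulation.
#'
#' @param route One of [routes()].
#' @param params An `ocular_params` with `kin` set.
#' @param sample_times Observation times in hours, strictly increasing,
#'   `>= 0`.
#' @param noise_cv Coefficient of variation of the multiplicative noise,
#'   `>= 0`; default 0.1.
#' @param seed Optional integer seed.
#' @param release_fit A [log_release_fit()] for the depot input.
#' @return A data frame with columns `time_h` and `vitreous_mg_ml`.
#' @export
generate_observed_trajectory <- function(route, params, sample_times,
                                         noise_cv = 0.1, seed = NULL,
                                         release_fit = default_release_fit()) {
  stopifnot(is.numeric(sample_times), all(sample_times >= 0),
            all(diff(sample_times) > 0),
            is.numeric(noise_cv), length(noise_cv) == 1L, noise_cv >= 0)
  if (!is.null(seed)) set.seed(seed)
  sys <- build_model(route, params, release_fit = release_fit)
  traj <- simulate_system(sys, horizon = max(sample_times, 1))
  clean <- stats::approx(traj$time_h, traj$vitreous, xout = sample_times)$y
  if (noise_cv > 0) {
    sdlog <- sqrt(log(1 + noise_cv^2))
    clean <- clean * stats::rlnorm(length(clean), meanlog = -sdlog^2 / 2,
                                   sdlog = sdlog)
  }
  data.frame(time_h = sample_times, vitreous_mg_ml = clean)
}
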