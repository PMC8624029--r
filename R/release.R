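#' Construct a cumulative drug-release profile
#'
#' Container for an in vitro release experiment: drug released from a unit
#' volume of hydrogel, expressed as the cumulative fraction of the
#' encapsulated dose at each sampling time.
#'
#' Times must be strictly increasing and positive; cumulative fractions
#' must lie in \[0, 1\]. Small decreases between consecutive fractions are
#' tolerated because measured (or synthetic) profiles carry additive
#' assay noise; the model-predicted release curve
#' ([cumulative_release_fraction()]) is always non-decreasing.
#'
#' @param times Sampling times in hours, strictly increasing, all `> 0`.
#' @param cumulative_released Cumulative released fraction of the
#'   encapsulated dose at each time, in \[0, 1\].
#' @param initial_concentration Drug concentration in the gel at `t = 0`,
#'   mg/mL.
#' @return An object of class `release_profile`.
#' @seealso [fit_log_release()], [generate_release_profile()]
#' @export
#' @examples
#' release_profile(c(5, 24, 504), c(0.23, 0.36, 0.84), 34.822)
release_profile <- function(times, cumulative_released, initial_concentration) {
  if (!is.numeric(times) || !is.numeric(cumulative_released))
    stop("'times' and 'cumulative_released' must be numeric", call. = FALSE)
  if (length(times) != length(cumulative_released))
    stop("'times' and 'cumulative_released' must have equal length", call. = FALSE)
  if (anyNA(times) || any(!is.finite(times)) ||
      anyNA(cumulative_released) || any(!is.finite(cumulative_released)))
    stop("release profile contains non-finite values", call. = FALSE)
  if (any(times <= 0) || any(diff(times) <= 0))
    stop("'times' must be positive and strictly increasing", call. = FALSE)
  if (any(cumulative_released < 0) || any(cumulative_released > 1))
    stop("'cumulative_released' must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(initial_concentration) || length(initial_concentration) != 1L ||
      !is.finite(initial_concentration) || initial_concentration <= 0)
    stop("'initial_concentration' must be a single positive number", call. = FALSE)
  structure(
    list(times = as.numeric(times),
         cumulative_released = as.numeric(cumulative_released),
         initial_concentration = as.numeric(initial_concentration)),
    class = "release_profile")
}

#' @export
print.release_profile <- function(x, ...) {
  cat("Release profile:", length(x$times), "timepoints over",
      format(max(x$times)), "h;",
      "initial concentration", format(x$initial_concentration), "mg/mL\n")
  invisible(x)
}

#' @export
as.data.frame.release_profile <- function(x, ...) {
  data.frame(time_h = x$times, cumulative_fraction = x$cumulative_released)
}

#' Logarithmic hydrogel release fit
#'
#' Parameters of the depot input function
#' \eqn{C_H(t) = a \ln t + b} describing the drug concentration remaining
#' in the hydrogel. The curve is held at `intercept_b` for
#' `t <= t_floor` (the log singularity at `t = 0` is unphysical) and
#' clamped at zero beyond `t_zero = exp(-b/a)`, the time of complete
#' release.
#'
#' @param slope_a Slope in mg/mL per log-hour; negative for a releasing
#'   depot.
#' @param intercept_b Concentration at `t = 1` h, mg/mL; must be positive.
#' @param t_floor Time in hours below which the curve is held constant at
#'   `intercept_b`; default 1 h, the scale of the first release
#'   observations.
#' @return An object of class `log_release_fit` with fields `slope_a`,
#'   `intercept_b`, `t_floor` and the derived `t_zero`.
#' @seealso [default_release_fit()], [hydrogel_concentration()]
#' @export
log_release_fit <- function(slope_a, intercept_b, t_floor = 1) {
  stopifnot(is.numeric(slope_a), length(slope_a) == 1L, is.finite(slope_a),
            is.numeric(intercept_b), length(intercept_b) == 1L,
            is.numeric(t_floor), length(t_floor) == 1L, is.finite(t_floor))
  if (!is.finite(intercept_b) || intercept_b <= 0)
    stop("'intercept_b' must be positive", call. = FALSE)
  if (t_floor < 0)
    stop("'t_floor' must be non-negative", call. = FALSE)
  t_zero <- if (slope_a < 0) exp(-intercept_b / slope_a) else Inf
  structure(
    list(slope_a = as.numeric(slope_a), intercept_b = as.numeric(intercept_b),
         t_floor = as.numeric(t_floor), t_zero = t_zero),
    class = "log_release_fit")
}

#' @export
print.log_release_fit <- function(x, ...) {
  cat(sprintf("Log release fit: C_H(t) = %.4g ln(t) + %.4g mg/mL (t_floor = %g h, t_zero = %.4g h)\n",
              x$slope_a, x$intercept_b, x$t_floor, x$t_zero))
  invisible(x)
}

#' Default hydrogel release fit
#'
#' The input function fitted to the in vitro release of vancomycin from a
#' 1 mL non-degradable PNIPAAm-PEG-DA hydrogel:
#' \eqn{C_H(t) = -4.709 \ln t + 34.822} mg/mL.
#'
#' @return A [log_release_fit()] with slope -4.709, intercept 34.822 and
#'   `t_floor = 1` h.
#' @export
#' @examples
#' hydrogel_concentration(1, default_release_fit())   # 34.822
#' hydrogel_concentration(504, default_release_fit()) # ~5.52
default_release_fit <- function() {
  log_release_fit(-4.709, 34.822, t_floor = 1)
}

#' Fit the logarithmic release model to a profile
#'
#' Ordinary least squares of the remaining hydrogel concentration,
#' `initial_concentration * (1 - cumulative_released)`, on `ln(time)`.
#'
#' @param profile A [release_profile()] with at least three timepoints.
#' @return A [log_release_fit()].
#' @export
#' @examples
#' tt <- c(5, 12, 24, 48, 96, 168, 240, 336, 432, 504)
#' frac <- cumulative_release_fraction(tt, default_release_fit())
#' fit <- fit_log_release(release_profile(tt, frac, 34.822))
#' fit$slope_a  # -4.709 recovered exactly
fit_log_release <- function(profile) {
  if (!inherits(profile, "release_profile"))
    stop("'profile' must be a release_profile", call. = FALSE)
  if (length(profile$times) < 3L)
    stop("at least 3 timepoints are required to fit the release model",
         call. = FALSE)
  remaining <- profile$initial_concentration * (1 - profile$cumulative_released)
  fit <- stats::lm(remaining ~ log(profile$times))
  cf <- unname(stats::coef(fit))
  log_release_fit(slope_a = cf[2L], intercept_b = cf[1L])
}

#' Drug concentration remaining in the hydrogel
#'
#' Evaluates the depot input function
#' \eqn{C_H(t) = \mathrm{clamp}(a \ln(\max(t, t_{floor})) + b,\ 0,\ b)}.
#'
#' @param t Time(s) in hours, `>= 0`.
#' @param fit A [log_release_fit()]; defaults to [default_release_fit()].
#' @return Concentration(s) in mg/mL.
#' @export
hydrogel_concentration <- function(t, fit = default_release_fit()) {
  if (!inherits(fit, "log_release_fit"))
    stop("'fit' must be a log_release_fit", call. = FALSE)
  if (!is.numeric(t) || anyNA(t) || any(!is.finite(t)))
    stop("'t' must be finite numeric", call. = FALSE)
  if (any(t < 0))
    stop("'t' must be non-negative", call. = FALSE)
  raw <- fit$slope_a * log(pmax(t, fit$t_floor)) + fit$intercept_b
  pmin(pmax(raw, 0), fit$intercept_b)
}

#' Model-predicted cumulative release fraction
#'
#' Fraction of the encapsulated dose released by time `t` according to a
#' log release fit: `1 - C_H(t) / intercept_b`. Non-decreasing in `t` and
#' bounded in \[0, 1\]; equals 1 for `t >= t_zero`.
#'
#' @inheritParams hydrogel_concentration
#' @return Fraction(s) in \[0, 1\].
#' @export
#' @examples
#' cumulative_release_fraction(504, default_release_fit())  # ~0.842
cumulative_release_fraction <- function(t, fit = default_release_fit()) {
  1 - hydrogel_concentration(t, fit) / fit$intercept_b
}

#' Encapsulation efficiency
#'
#' Percentage of the loaded drug retained in the delivery system after the
#' washing phases, determined indirectly from the loaded and retained
#' masses.
#'
#' @param loaded_mass Drug mass added at synthesis, mg; `> 0`.
#' @param retained_mass Drug mass remaining after washing, mg; in
#'   `[0, loaded_mass]`.
#' @return Encapsulation efficiency in percent.
#' @export
#' @examples
#' encapsulation_efficiency(60, 34)  # ~56.7%
encapsulation_efficiency <- function(loaded_mass, retained_mass) {
  stopifnot(is.numeric(loaded_mass), is.numeric(retained_mass))
  if (anyNA(loaded_mass) || anyNA(retained_mass) ||
      any(!is.finite(loaded_mass)) || any(!is.finite(retained_mass)))
    stop("masses must be finite", call. = FALSE)
  if (any(loaded_mass <= 0))
    stop("'loaded_mass' must be positive", call. = FALSE)
  if (any(retained_mass < 0) || any(retained_mass > loaded_mass))
    stop("'retained_mass' must lie in [0, loaded_mass]", call. = FALSE)
  100 * retained_mass / loaded_mass
}

#' Initial burst release
#'
#' Percentage of the encapsulated dose released within an early horizon
#' (conventionally 5, 12 or 24 h), linearly interpolated between the
#' bracketing observations when the horizon is not a sampled time.
#'
#' @param profile A [release_profile()].
#' @param horizon Time in hours; must lie within the observed time range.
#' @return Released percentage at the horizon.
#' @export
initial_burst <- function(profile, horizon) {
  if (!inherits(profile, "release_profile"))
    stop("'profile' must be a release_profile", call. = FALSE)
  stopifnot(is.numeric(horizon), length(horizon) == 1L, is.finite(horizon))
  if (horizon < min(profile$times) || horizon > max(profile$times))
    stop("'horizon' lies outside the observed time range [",
         min(profile$times), ", ", max(profile$times), "] h", call. = FALSE)
  100 * stats::approx(profile$times, profile$cumulative_released,
                      xout = horizon)$y
}

# --- serialisation -----------------------------------------------------

#' Read or write release profiles and fits
#'
#' Release profiles use CSV with header `time_h,cumulative_fraction`; fits
#' are YAML mappings `{a, b, t_floor}`.
#'
#' @param path File path.
#' @param profile A [release_profile()].
#' @param initial_concentration Initial gel concentration (mg/mL) to attach
#'   when reading, since the CSV stores only times and fractions.
#' @param fit A [log_release_fit()].
#' @return `read_release_profile()` returns a [release_profile()];
#'   `read_release_fit()` a [log_release_fit()]; the writers return the
#'   path invisibly.
#' @name release_io
NULL

#' @rdname release_io
#' @export
write_release_profile <- function(profile, path) {
  if (!inherits(profile, "release_profile"))
    stop("'profile' must be a release_profile", call. = FALSE)
  utils::write.csv(as.data.frame(profile), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname release_io
#' @export
read_release_profile <- function(path, initial_concentration) {
  df <- utils::read.csv(path)
  if (!identical(names(df), c("time_h", "cumulative_fraction")))
    stop("expected CSV header 'time_h,cumulative_fraction' in ", path,
         call. = FALSE)
  release_profile(df$time_h, df$cumulative_fraction, initial_concentration)
}

#' @rdname release_io
#' @export
write_release_fit <- function(fit, path) {
  if (!inherits(fit, "log_release_fit"))
    stop("'fit' must be a log_release_fit", call. = FALSE)
  yaml::write_yaml(list(a = fit$slope_a, b = fit$intercept_b,
                        t_floor = fit$t_floor), path)
  invisible(path)
}

#' @rdname release_io
#' @export
read_release_fit <- function(path) {
  y <- yaml::read_yaml(path)
  log_release_fit(y$a, y$b, t_floor = if (is.null(y$t_floor)) 1 else y$t_floor)
}
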