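#' Integrate a compartment system over time
#'
#' Solves the linear ODE system from zero initial concentrations with a
#' stiff-capable adaptive integrator (`deSolve::ode`, method `lsoda`).
#' The output grid is dense (0.1 h) over the first five hours, where the
#' depot input changes fastest, and 1 h elsewhere.
#'
#' @param system A [compartment_system()].
#' @param horizon Simulation horizon in hours, `> 0`; default 1500.
#' @param rel_tol,abs_tol Solver tolerances; defaults 1e-8 and 1e-10.
#' @param times Optional explicit output grid (strictly increasing,
#'   starting at 0); overrides the default grid.
#' @return A `pk_trajectory`: a data frame with column `time_h` followed
#'   by one concentration column (mg/mL) per compartment, with attributes
#'   `route` and `params_fingerprint`.
#' @export
#' @examples
#' p <- set_kin(default_parameters(), 1e-3)
#' traj <- simulate_system(build_model("intravitreal", p), horizon = 100)
#' find_peak(traj, "vitreous")
simulate_system <- function(system, horizon = 1500,
                            rel_tol = 1e-8, abs_tol = 1e-10,
                            times = NULL) {
  if (!inherits(system, "compartment_system"))
    stop("'system' must be a compartment_system", call. = FALSE)
  stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon > 0)
  if (is.null(times)) {
    times <- sort(unique(c(seq(0, min(5, horizon), by = 0.1),
                           seq(0, horizon, by = 1), horizon)))
  } else {
    stopifnot(is.numeric(times), times[1] == 0, all(diff(times) > 0))
  }
  A <- transfer_matrix(system)
  e_in <- as.numeric(system$compartments == system$input_compartment)
  fit <- system$release_fit
  kin <- system$kin
  deriv <- function(t, y, parms) {
    list(as.vector(A %*% y) + e_in * kin * hydrogel_concentration(t, fit))
  }
  y0 <- stats::setNames(numeric(length(system$compartments)),
                        system$compartments)
  out <- deSolve::ode(y = y0, times = times, func = deriv, parms = NULL,
                      method = "lsoda", rtol = rel_tol, atol = abs_tol)
  diag <- attr(out, "istate")
  if (!is.null(diag) && diag[1L] < 0)
    stop("ODE integration failed for route '", system$route,
         "' (lsoda istate ", diag[1L], ")", call. = FALSE)
  df <- as.data.frame(out)
  names(df)[1L] <- "time_h"
  structure(df,
            class = c("pk_trajectory", "data.frame"),
            route = system$route,
            params_fingerprint = paste0("kin=", format(kin, digits = 15)))
}

#' @export
print.pk_trajectory <- function(x, ...) {
  cat(sprintf("Trajectory (%s route): %d timepoints over %g h; compartments: %s\n",
              attr(x, "route"), nrow(x), max(x$time_h),
              paste(setdiff(names(x), "time_h"), collapse = ", ")))
  invisible(x)
}

#' First upward crossing of a concentration threshold
#'
#' Finds the first time a compartment's concentration rises through
#' `level`, refined by linear interpolation between the bracketing grid
#' points (exact for the piecewise-linear interpolant of the solution).
#'
#' @param traj A `pk_trajectory` from [simulate_system()].
#' @param compartment Compartment name; default `"vitreous"`.
#' @param level Threshold concentration in mg/mL, `> 0`.
#' @return An object of class `threshold_event`: a list with
#'   `compartment`, `level`, `crossing_time` (hours, or `NA` if the level
#'   is never reached) and `direction = "upward"`.
#' @export
find_threshold_crossing <- function(traj, compartment = "vitreous", level) {
  y <- traj_series(traj, compartment)
  stopifnot(is.numeric(level), length(level) == 1L, level > 0)
  tt <- traj$time_h
  above <- y >= level
  ct <- NA_real_
  if (above[1L]) {
    ct <- tt[1L]
  } else if (any(above)) {
    i <- which(above)[1L]
    ct <- tt[i - 1L] + (level - y[i - 1L]) * (tt[i] - tt[i - 1L]) /
      (y[i] - y[i - 1L])
  }
  structure(list(compartment = compartment, level = level,
                 crossing_time = ct, direction = "upward"),
            class = "threshold_event")
}

#' @export
print.threshold_event <- function(x, ...) {
  cat(sprintf("Threshold %g mg/mL in '%s': %s\n", x$level, x$compartment,
              if (is.na(x$crossing_time)) "never reached"
              else sprintf("first crossed upward at %.3g h", x$crossing_time)))
  invisible(x)
}

#' Peak concentration in a compartment
#'
#' Global maximum of the simulated series, refined by a local quadratic
#' fit through the grid maximum and its neighbours (when interior). The
#' refined peak is never below the grid maximum.
#'
#' @inheritParams find_threshold_crossing
#' @return A list with `t_peak` (hours) and `c_peak` (mg/mL).
#' @export
find_peak <- function(traj, compartment = "vitreous") {
  y <- traj_series(traj, compartment)
  tt <- traj$time_h
  i <- which.max(y)
  t_peak <- tt[i]; c_peak <- y[i]
  if (i > 1L && i < length(y)) {
    t3 <- tt[(i - 1L):(i + 1L)]; y3 <- y[(i - 1L):(i + 1L)]
    co <- try(unname(solve(cbind(1, t3, t3^2), y3)), silent = TRUE)
    if (!inherits(co, "try-error") && is.finite(co[3L]) && co[3L] < 0) {
      tv <- -co[2L] / (2 * co[3L])
      if (tv >= t3[1L] && tv <= t3[3L]) {
        cv <- co[1L] + co[2L] * tv + co[3L] * tv^2
        if (cv >= c_peak) {
          t_peak <- tv
          c_peak <- cv
        }
      }
    }
  }
  list(t_peak = t_peak, c_peak = c_peak)
}

traj_series <- function(traj, compartment) {
  if (!inherits(traj, "pk_trajectory"))
    stop("'traj' must be a pk_trajectory", call. = FALSE)
  if (!compartment %in% names(traj))
    stop("unknown compartment '", compartment, "'; trajectory has: ",
         paste(setdiff(names(traj), "time_h"), collapse = ", "),
         call. = FALSE)
  traj[[compartment]]
}

#' Calibrate the depot outflow rate against the intravitreal peak
#'
#' The depot outflow rate `kin` couples the hydrogel's remaining
#' concentration to the entry compartment and has no literature value.
#' It is fixed by requiring the intravitreal model's peak vitreous
#' concentration over the horizon to equal `target_peak` (default
#' 0.34 mg/mL). Because the system is linear in `kin`, the solution is
#' obtained in one step from any trial value:
#' `kin = kin_trial * target_peak / peak(kin_trial)`.
#'
#' The calibrated value is shared by all four routes (the same depot is
#' placed at each site), so the other routes' peaks and crossing times
#' are genuine predictions.
#'
#' @param params An `ocular_params` (the `kin` slot is ignored).
#' @param target_peak Target peak vitreous concentration, mg/mL, `> 0`.
#' @param release_fit A [log_release_fit()] for the depot input.
#' @param horizon Horizon over which the peak is taken, hours.
#' @param kin_trial Trial value used for the linear scaling step.
#' @return The calibrated `kin` in hr^-1 (numeric scalar).
#' @export
calibrate_kin <- function(params, target_peak = 0.34,
                          release_fit = default_release_fit(),
                          horizon = 1500, kin_trial = 1e-3) {
  validate_parameters(params)
  if (!is.numeric(target_peak) || length(target_peak) != 1L ||
      !is.finite(target_peak) || target_peak <= 0)
    stop("'target_peak' must be a positive number", call. = FALSE)
  stopifnot(is.numeric(kin_trial), kin_trial > 0)
  sys <- build_model("intravitreal", set_kin(params, kin_trial),
                     release_fit = release_fit)
  traj <- simulate_system(sys, horizon = horizon)
  peak <- find_peak(traj, "vitreous")$c_peak
  if (!is.finite(peak) || peak <= 0)
    stop("trial simulation produced no vitreous exposure; cannot calibrate",
         call. = FALSE)
  kin_trial * target_peak / peak
}

#' Read or write simulated trajectories
#'
#' CSV with header `time_h` followed by one column per compartment
#' (mg/mL).
#'
#' @param traj A `pk_trajectory`.
#' @param path File path.
#' @param route Route label to attach when reading.
#' @return `read_trajectory()` returns a `pk_trajectory`; the writer
#'   returns the path invisibly.
#' @name trajectory_io
NULL

#' @rdname trajectory_io
#' @export
write_trajectory <- function(traj, path) {
  if (!inherits(traj, "pk_trajectory"))
    stop("'traj' must be a pk_trajectory", call. = FALSE)
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' @rdname trajectory_io
#' @export
read_trajectory <- function(path, route = "unknown") {
  df <- utils::read.csv(path)
  if (names(df)[1L] != "time_h")
    stop("expected first CSV column 'time_h' in ", path, call. = FALSE)
  structure(df, class = c("pk_trajectory", "data.frame"), route = route,
            params_fingerprint = NA_character_)
}
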