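#' Simulate all routes and summarise vitreous exposure
#'
#' For each requested route: calibrates the depot outflow rate `kin` once
#' (against the intravitreal peak), simulates the route over the horizon,
#' and reports the peak vitreous concentration, time to peak, and the
#' first upward crossing time of each therapeutic threshold. Times are
#' reported at 0.1 h resolution. When `out_dir` is given, per-route
#' trajectory CSVs, a threshold-event CSV and the summary CSV are written
#' there (re-running with the same configuration reproduces them
#' byte-for-byte); `overlay_plot = TRUE` additionally writes a PDF
#' overlay of the vitreous series.
#'
#' @param routes Character vector of routes, or `"all"` (default).
#' @param params An `ocular_params`; if its `kin` is unset it is
#'   calibrated via [calibrate_kin()] with `target_peak`.
#' @param release_fit A [log_release_fit()] for the depot input.
#' @param horizon Simulation horizon in hours; default 1500.
#' @param thresholds Threshold concentrations in mg/mL, all `> 0`;
#'   default `c(0.007, 0.024)` (minimum therapeutic and optimal-dosing
#'   levels for vancomycin in the vitreous).
#' @param target_peak Calibration target for the intravitreal vitreous
#'   peak, mg/mL; default 0.34.
#' @param precorneal_loss Passed to [build_model()] for the topical route.
#' @param out_dir Optional output directory (created if missing).
#' @param overlay_plot Write `vitreous_overlay.pdf` into `out_dir`.
#' @param verbose Log the calibrated `kin`, parameter fingerprint and
#'   solver tolerances via [message()].
#' @return A data frame with one row per route: `route`,
#'   `peak_vitreous_mg_ml`, `t_peak_h`, and one `time_to_<level>_h`
#'   column per threshold (`NA` when never reached). The calibrated
#'   `kin` is attached as attribute `"kin"` and the trajectories as
#'   attribute `"trajectories"`.
#' @export
#' @examples
#' \donttest{
#' run_report(horizon = 1500)
#' }
run_report <- function(routes = "all", params = default_parameters(),
                       release_fit = default_release_fit(),
                       horizon = 1500, thresholds = c(0.007, 0.024),
                       target_peak = 0.34,
                       precorneal_loss = c("systemic", "tear_turnover"),
                       out_dir = NULL, overlay_plot = FALSE,
                       verbose = FALSE) {
  if (identical(routes, "all")) routes <- vitreokin::routes()
  bad <- setdiff(routes, vitreokin::routes())
  if (length(bad))
    stop("unknown route(s): ", paste(bad, collapse = ", "), call. = FALSE)
  stopifnot(is.numeric(horizon), length(horizon) == 1L, horizon > 0)
  if (!is.numeric(thresholds) || !length(thresholds) || any(thresholds <= 0))
    stop("'thresholds' must be positive concentrations (mg/mL)",
         call. = FALSE)
  precorneal_loss <- match.arg(precorneal_loss)
  validate_parameters(params)
  if (!is.finite(params$kin))
    params <- set_kin(params, calibrate_kin(params, target_peak = target_peak,
                                            release_fit = release_fit,
                                            horizon = horizon))
  if (verbose)
    message(sprintf("kin = %.6g hr^-1; tolerances rel 1e-8 / abs 1e-10; params: %s",
                    params$kin, params_fingerprint(params)))

  trajs <- list()
  rows <- vector("list", length(routes))
  events <- list()
  for (i in seq_along(routes)) {
    r <- routes[i]
    sys <- build_model(r, params, release_fit = release_fit,
                       precorneal_loss = precorneal_loss)
    traj <- simulate_system(sys, horizon = horizon)
    trajs[[r]] <- traj
    pk <- find_peak(traj, "vitreous")
    row <- data.frame(route = r,
                      peak_vitreous_mg_ml = pk$c_peak,
                      t_peak_h = round(pk$t_peak, 1))
    for (lv in thresholds) {
      ev <- find_threshold_crossing(traj, "vitreous", lv)
      col <- sprintf("time_to_%g_h", lv)
      row[[col]] <- if (is.na(ev$crossing_time)) NA_real_
                    else round(ev$crossing_time, 1)
      events[[length(events) + 1L]] <- data.frame(
        route = r, compartment = "vitreous", level_mg_ml = lv,
        crossing_time_h = if (is.na(ev$crossing_time)) NA_real_
                          else round(ev$crossing_time, 1))
    }
    rows[[i]] <- row
  }
  summary <- do.call(rbind, rows)
  rownames(summary) <- NULL

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
      stop("could not create output directory '", out_dir, "'",
           call. = FALSE)
    for (r in names(trajs))
      write_trajectory(trajs[[r]], file.path(out_dir,
                                             paste0("trajectory_", r, ".csv")))
    utils::write.csv(do.call(rbind, events),
                     file.path(out_dir, "events.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(summary, file.path(out_dir, "summary.csv"),
                     row.names = FALSE, quote = FALSE)
    if (overlay_plot) {
      grDevices::pdf(file.path(out_dir, "vitreous_overlay.pdf"),
                     width = 7, height = 5)
      on.exit(grDevices::dev.off(), add = TRUE)
      plot_vitreous_overlay(trajs, thresholds = thresholds)
    }
  }
  structure(summary, kin = params$kin, trajectories = trajs)
}

#' Overlay plot of vitreous concentration for several routes
#'
#' Base-graphics overlay of the vitreous concentration versus time, one
#' line per route, with optional horizontal threshold lines.
#'
#' @param trajectories Named list of `pk_trajectory` objects (names are
#'   used in the legend), e.g. the `"trajectories"` attribute of
#'   [run_report()].
#' @param thresholds Optional numeric vector of threshold levels (mg/mL)
#'   drawn as dashed horizontal lines.
#' @param log_time Plot time on a log axis (the early transients and the
#'   slow topical build-up then both resolve).
#' @return Invisibly, `NULL`. Called for its side effect.
#' @export
plot_vitreous_overlay <- function(trajectories, thresholds = NULL,
                                  log_time = FALSE) {
  stopifnot(is.list(trajectories), length(trajectories) > 0)
  cols <- grDevices::hcl.colors(max(4L, length(trajectories)), "Dark 2")
  ymax <- max(vapply(trajectories, function(tr) max(tr$vitreous),
                     numeric(1)))
  first <- trajectories[[1L]]
  graphics::plot(first$time_h, first$vitreous, type = "n",
                 xlab = "time (h)", ylab = "vitreous concentration (mg/mL)",
                 ylim = c(0, 1.05 * ymax),
                 log = if (log_time) "x" else "")
  for (i in seq_along(trajectories)) {
    tr <- trajectories[[i]]
    graphics::lines(tr$time_h, tr$vitreous, col = cols[i], lwd = 2)
  }
  if (!is.null(thresholds))
    graphics::abline(h = thresholds, lty = 2, col = "grey40")
  graphics::legend("topright", legend = names(trajectories),
                   col = cols[seq_along(trajectories)], lwd = 2, bty = "n")
  invisible(NULL)
}

#' Load a run configuration from YAML
#'
#' Reads a YAML mapping with any of the keys `routes`, `horizon`,
#' `thresholds`, `target_peak`, `precorneal_loss`, `out_dir`, `seed` and
#' `params` (a nested mapping of rate-constant overrides, keyed as in
#' [read_parameters()]); missing keys take the [run_report()] defaults.
#' Field-by-field validation errors are collected and reported together.
#'
#' @param path Path to the YAML file.
#' @return A named list suitable for `do.call(run_report, ...)` (the
#'   `seed` element, if any, is set before the call by the caller).
#' @export
load_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cfg <- list()
  problems <- character()
  if (!is.null(y$routes)) cfg$routes <- as.character(y$routes)
  if (!is.null(y$horizon)) {
    cfg$horizon <- as.numeric(y$horizon)
    if (!is.finite(cfg$horizon) || cfg$horizon <= 0)
      problems <- c(problems, "horizon: must be a positive number of hours")
  }
  if (!is.null(y$thresholds)) {
    cfg$thresholds <- as.numeric(unlist(y$thresholds))
    if (any(!is.finite(cfg$thresholds)) || any(cfg$thresholds <= 0))
      problems <- c(problems, "thresholds: must be positive mg/mL values")
  }
  if (!is.null(y$target_peak)) {
    cfg$target_peak <- as.numeric(y$target_peak)
    if (!is.finite(cfg$target_peak) || cfg$target_peak <= 0)
      problems <- c(problems, "target_peak: must be a positive mg/mL value")
  }
  if (!is.null(y$precorneal_loss)) {
    cfg$precorneal_loss <- as.character(y$precorneal_loss)
    if (!cfg$precorneal_loss %in% c("systemic", "tear_turnover"))
      problems <- c(problems,
                    "precorneal_loss: must be 'systemic' or 'tear_turnover'")
  }
  if (!is.null(y$out_dir)) cfg$out_dir <- as.character(y$out_dir)
  if (!is.null(y$params)) {
    p <- default_parameters()
    for (nm in names(y$params)) {
      v <- as.numeric(y$params[[nm]])
      if (nm %in% names(p$permeation)) p$permeation[[nm]] <- v
      else if (nm %in% names(p$elimination)) p$elimination[[nm]] <- v
      else if (nm == "tear_turnover") p$tear_turnover <- v
      else if (nm == "kin") p$kin <- v
      else problems <- c(problems,
                         paste0("params.", nm, ": unknown rate constant"))
    }
    cfg$params <- p
  }
  if (!is.null(y$seed)) attr(cfg, "seed") <- as.integer(y$seed)
  if (length(problems))
    stop("invalid run configuration in ", path, ":\n  ",
         paste(problems, collapse = "\n  "), call. = FALSE)
  cfg
}
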