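#' Literature rate constants for the ocular compartment models
#'
#' Returns the canonical set of first-order rate constants (all hr^-1)
#' used by the four route models. Permeation constants govern entry into
#' the named tissue; elimination constants are first-order losses.
#' Backflow between compartments is fixed at zero throughout.
#'
#' `tear_turnover` (9.6 hr^-1, i.e. ~16% of the tear film per minute) is
#' carried for reference and can be bound to the precorneal loss term of
#' the topical model via [build_model()]. `kin`, the outflow rate coupling
#' the depot's remaining concentration to the entry compartment, has no
#' literature value and is left unset until [calibrate_kin()].
#'
#' @return An object of class `ocular_params`: a list with elements
#'   `permeation` (named numeric, hr^-1), `elimination` (named numeric,
#'   hr^-1), `tear_turnover` and `kin`.
#' @export
#' @examples
#' p <- default_parameters()
#' p$permeation[["sclera"]]       # 0.05472
#' p$elimination[["vitreous_out"]] # 0.008208
default_parameters <- function() {
  structure(
    list(
      permeation = c(
        cornea          = 0.0216,
        conjunctiva     = 0.0018,
        aqueous_chamber = 0.0189,
        iris_ciliary    = 3.6,
        sclera          = 0.05472,
        choroid         = 1.782,
        retina          = 1.782,
        vitreous_humor  = 0.0234,
        rpe             = 0.000936),
      elimination = c(
        vitreous_out = 0.008208,
        systemic     = 0.0329),
      tear_turnover = 9.6,
      kin = NA_real_),
    class = "ocular_params")
}

validate_parameters <- function(params, require_kin = FALSE) {
  if (!inherits(params, "ocular_params"))
    stop("'params' must be an ocular_params object", call. = FALSE)
  need <- names(default_parameters()$permeation)
  if (!all(need %in% names(params$permeation)))
    stop("missing permeation rates: ",
         paste(setdiff(need, names(params$permeation)), collapse = ", "),
         call. = FALSE)
  if (!all(c("vitreous_out", "systemic") %in% names(params$elimination)))
    stop("missing elimination rates", call. = FALSE)
  rates <- c(params$permeation, params$elimination, params$tear_turnover)
  if (any(!is.finite(rates)) || any(rates < 0))
    stop("all rate constants must be finite and non-negative", call. = FALSE)
  if (require_kin &&
      (!is.numeric(params$kin) || !is.finite(params$kin) || params$kin < 0))
    stop("'kin' is not set; calibrate it with calibrate_kin() or supply ",
         "a value via set_kin()", call. = FALSE)
  invisible(params)
}

#' Set the depot outflow rate
#'
#' @param params An `ocular_params` object.
#' @param kin Depot outflow rate, hr^-1, `>= 0`.
#' @return The parameter set with `kin` set.
#' @seealso [calibrate_kin()]
#' @export
set_kin <- function(params, kin) {
  validate_parameters(params)
  stopifnot(is.numeric(kin), length(kin) == 1L)
  if (!is.finite(kin) || kin < 0)
    stop("'kin' must be a non-negative finite number", call. = FALSE)
  params$kin <- as.numeric(kin)
  params
}

#' @export
print.ocular_params <- function(x, ...) {
  cat("Ocular rate constants (hr^-1)\n  permeation:\n")
  for (nm in names(x$permeation))
    cat(sprintf("    %-16s %g\n", nm, x$permeation[[nm]]))
  cat("  elimination:\n")
  for (nm in names(x$elimination))
    cat(sprintf("    %-16s %g\n", nm, x$elimination[[nm]]))
  cat(sprintf("  tear_turnover    %g\n", x$tear_turnover))
  cat(sprintf("  kin              %s\n",
              if (is.finite(x$kin)) format(x$kin) else "<unset>"))
  invisible(x)
}

# Compact identifier used to stamp trajectories with the parameters that
# produced them.
params_fingerprint <- function(params) {
  vals <- c(params$permeation, params$elimination,
            tear_turnover = params$tear_turnover, kin = params$kin)
  paste0(names(vals), "=", formatC(vals, format = "g", digits = 15),
         collapse = ";")
}

#' Read or write a parameter set as YAML
#'
#' Flat YAML mapping with one key per rate constant (`cornea`,
#' `conjunctiva`, `aqueous_chamber`, `iris_ciliary`, `sclera`, `choroid`,
#' `retina`, `vitreous_humor`, `rpe`, `vitreous_out`, `systemic`,
#' `tear_turnover`, `kin`).
#'
#' @param params An `ocular_params` object.
#' @param path File path.
#' @return `read_parameters()` returns an `ocular_params`; the writer
#'   returns the path invisibly.
#' @name parameters_io
NULL

#' @rdname parameters_io
#' @export
write_parameters <- function(params, path) {
  validate_parameters(params)
  y <- c(as.list(params$permeation), as.list(params$elimination),
         list(tear_turnover = params$tear_turnover,
              kin = if (is.finite(params$kin)) params$kin else NULL))
  yaml::write_yaml(y, path)
  invisible(path)
}

#' @rdname parameters_io
#' @export
read_parameters <- function(path) {
  y <- yaml::read_yaml(path)
  p <- default_parameters()
  for (nm in names(p$permeation))
    if (!is.null(y[[nm]])) p$permeation[[nm]] <- as.numeric(y[[nm]])
  for (nm in names(p$elimination))
    if (!is.null(y[[nm]])) p$elimination[[nm]] <- as.numeric(y[[nm]])
  if (!is.null(y$tear_turnover)) p$tear_turnover <- as.numeric(y$tear_turnover)
  if (!is.null(y$kin)) p$kin <- as.numeric(y$kin)
  validate_parameters(p)
}
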