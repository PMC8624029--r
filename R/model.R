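#' Administration routes
#'
#' @return Character vector of the four supported route names.
#' @export
routes <- function() {
  c("topical", "subconjunctival", "intravitreal", "subretinal")
}

#' Construct a compartment system directly
#'
#' Low-level constructor for a linear compartment graph with a
#' time-varying depot input. [build_model()] is the usual entry point;
#' this constructor exists for custom topologies (e.g. closed-form test
#' systems) and for perturbation studies.
#'
#' @param route Route label; one of [routes()] or `"custom"`.
#' @param compartments Character vector of unique compartment names.
#' @param transfers Data frame with columns `source`, `target`,
#'   `rate_per_hr` (and optionally logical `backflow`); all rates `>= 0`.
#' @param eliminations Named numeric vector of first-order loss rates
#'   (hr^-1); names must be compartments. Compartments without losses may
#'   be omitted.
#' @param input_compartment Name of the compartment receiving the depot
#'   inflow `kin * C_H(t)`.
#' @param kin Depot outflow rate, hr^-1.
#' @param release_fit A [log_release_fit()] supplying `C_H(t)`.
#' @return An object of class `compartment_system`.
#' @export
compartment_system <- function(route, compartments, transfers, eliminations,
                               input_compartment, kin,
                               release_fit = default_release_fit()) {
  stopifnot(is.character(compartments), length(compartments) > 0L)
  if (anyDuplicated(compartments))
    stop("compartment names must be unique", call. = FALSE)
  stopifnot(is.data.frame(transfers))
  if (nrow(transfers) > 0 &&
      !all(c("source", "target", "rate_per_hr") %in% names(transfers)))
    stop("'transfers' needs columns source, target, rate_per_hr",
         call. = FALSE)
  if (is.null(transfers$backflow)) transfers$backflow <- rep(FALSE, nrow(transfers))
  if (nrow(transfers) > 0) {
    bad <- setdiff(unique(c(transfers$source, transfers$target)), compartments)
    if (length(bad))
      stop("transfer references unknown compartments: ",
           paste(bad, collapse = ", "), call. = FALSE)
    if (any(!is.finite(transfers$rate_per_hr)) || any(transfers$rate_per_hr < 0))
      stop("transfer rates must be finite and non-negative", call. = FALSE)
  }
  elim <- stats::setNames(numeric(length(compartments)), compartments)
  if (length(eliminations)) {
    if (is.null(names(eliminations)) ||
        !all(names(eliminations) %in% compartments))
      stop("'eliminations' must be named by compartment", call. = FALSE)
    if (any(!is.finite(eliminations)) || any(eliminations < 0))
      stop("elimination rates must be finite and non-negative", call. = FALSE)
    elim[names(eliminations)] <- eliminations
  }
  if (!input_compartment %in% compartments)
    stop("'input_compartment' is not a compartment", call. = FALSE)
  if (!is.numeric(kin) || length(kin) != 1L || !is.finite(kin) || kin < 0)
    stop("'kin' must be a non-negative finite number", call. = FALSE)
  if (!inherits(release_fit, "log_release_fit"))
    stop("'release_fit' must be a log_release_fit", call. = FALSE)
  sys <- structure(
    list(route = route, compartments = compartments,
         transfers = transfers[, c("source", "target", "rate_per_hr", "backflow")],
         eliminations = elim, input_compartment = input_compartment,
         kin = as.numeric(kin), release_fit = release_fit),
    class = "compartment_system")
  if (route %in% routes() && !has_path(sys, input_compartment, "vitreous"))
    stop("no directed path from the input compartment to the vitreous",
         call. = FALSE)
  sys
}

# breadth-first reachability over positive-rate edges
has_path <- function(system, from, to) {
  if (from == to) return(TRUE)
  tr <- system$transfers[system$transfers$rate_per_hr > 0, , drop = FALSE]
  seen <- from
  repeat {
    nxt <- unique(tr$target[tr$source %in% seen])
    nxt <- setdiff(nxt, seen)
    if (!length(nxt)) return(FALSE)
    if (to %in% nxt) return(TRUE)
    seen <- c(seen, nxt)
  }
}

#' Build a route-specific ocular compartment model
#'
#' Constructs the linear compartmental ODE system for one administration
#' route, with rate constants drawn from `params` under a single uniform
#' rule: the transfer rate from a compartment into tissue Y is the
#' permeation constant "across Y". Exits *from* the vitreous (intravitreal
#' route) are governed by the vitreous-humor permeation constant.
#' Backflow edges are carried in the transfer table with rate zero.
#'
#' Route topologies (losses in parentheses):
#' \describe{
#'   \item{subconjunctival}{depot -> subconjunctival (systemic) -> sclera
#'     -> choroid (systemic) -> retina -> vitreous (vitreous_out); 5
#'     compartments.}
#'   \item{topical}{depot -> precorneal (loss, see `precorneal_loss`),
#'     then in parallel cornea -> anterior chamber -> vitreous and
#'     conjunctiva -> sclera -> choroid (systemic) -> retina -> vitreous
#'     (vitreous_out); 8 compartments.}
#'   \item{intravitreal}{depot -> vitreous (systemic), vitreous -> retina
#'     (systemic) and vitreous -> aqueous chamber (iris/ciliary outflow);
#'     3 compartments.}
#'   \item{subretinal}{depot -> subretinal space (systemic), then retina
#'     -> vitreous (vitreous_out) and RPE -> choroid (systemic) -> sclera;
#'     6 compartments.}
#' }
#'
#' @param route One of [routes()].
#' @param params An `ocular_params` with `kin` set (see [calibrate_kin()]).
#' @param release_fit A [log_release_fit()] for the depot input.
#' @param precorneal_loss Binding for the topical tear-side loss term:
#'   `"systemic"` (default; the systemic absorption constant, the same
#'   binding used for every other unspecified loss term) or
#'   `"tear_turnover"` (tear-film turnover, 9.6 hr^-1, under which
#'   essentially no drug survives the precorneal compartment).
#' @return A [compartment_system()].
#' @export
#' @examples
#' p <- set_kin(default_parameters(), 1e-3)
#' build_model("subconjunctival", p)
build_model <- function(route, params,
                        release_fit = default_release_fit(),
                        precorneal_loss = c("systemic", "tear_turnover")) {
  if (!is.character(route) || length(route) != 1L || !route %in% routes())
    stop("unknown route '", paste(route, collapse = ","),
         "'; expected one of: ", paste(routes(), collapse = ", "),
         call. = FALSE)
  validate_parameters(params, require_kin = TRUE)
  precorneal_loss <- match.arg(precorneal_loss)
  perm <- params$permeation
  elim <- params$elimination
  edge <- function(src, dst, rate) data.frame(source = src, target = dst,
                                              rate_per_hr = rate,
                                              backflow = FALSE)
  topo <- switch(route,
    subconjunctival = list(
      compartments = c("subconjunctival", "sclera", "choroid", "retina",
                       "vitreous"),
      forward = rbind(
        edge("subconjunctival", "sclera",  perm[["sclera"]]),
        edge("sclera",          "choroid", perm[["choroid"]]),
        edge("choroid",         "retina",  perm[["retina"]]),
        edge("retina",          "vitreous", perm[["vitreous_humor"]])),
      eliminations = c(subconjunctival = elim[["systemic"]],
                       choroid = elim[["systemic"]],
                       vitreous = elim[["vitreous_out"]]),
      input = "subconjunctival"),
    topical = list(
      compartments = c("precorneal", "cornea", "anterior_chamber",
                       "conjunctiva", "sclera", "choroid", "retina",
                       "vitreous"),
      forward = rbind(
        edge("precorneal", "cornea",           perm[["cornea"]]),
        edge("cornea",     "anterior_chamber", perm[["aqueous_chamber"]]),
        edge("anterior_chamber", "vitreous",   perm[["vitreous_humor"]]),
        edge("precorneal", "conjunctiva",      perm[["conjunctiva"]]),
        edge("conjunctiva", "sclera",          perm[["sclera"]]),
        edge("sclera",      "choroid",         perm[["choroid"]]),
        edge("choroid",     "retina",          perm[["retina"]]),
        edge("retina",      "vitreous",        perm[["vitreous_humor"]])),
      eliminations = c(
        precorneal = if (precorneal_loss == "systemic") elim[["systemic"]]
                     else params$tear_turnover,
        choroid = elim[["systemic"]],
        vitreous = elim[["vitreous_out"]]),
      input = "precorneal"),
    intravitreal = list(
      compartments = c("vitreous", "retina", "aqueous_chamber"),
      forward = rbind(
        edge("vitreous", "retina",          perm[["vitreous_humor"]]),
        edge("vitreous", "aqueous_chamber", perm[["vitreous_humor"]])),
      eliminations = c(vitreous = elim[["systemic"]],
                       retina = elim[["systemic"]],
                       aqueous_chamber = perm[["iris_ciliary"]]),
      input = "vitreous"),
    subretinal = list(
      compartments = c("subretinal", "retina", "vitreous", "rpe",
                       "choroid", "sclera"),
      forward = rbind(
        edge("subretinal", "retina",   perm[["retina"]]),
        edge("retina",     "vitreous", perm[["vitreous_humor"]]),
        edge("subretinal", "rpe",      perm[["rpe"]]),
        edge("rpe",        "choroid",  perm[["choroid"]]),
        edge("choroid",    "sclera",   perm[["sclera"]])),
      eliminations = c(subretinal = elim[["systemic"]],
                       choroid = elim[["systemic"]],
                       vitreous = elim[["vitreous_out"]]),
      input = "subretinal"))
  backward <- data.frame(source = topo$forward$target,
                         target = topo$forward$source,
                         rate_per_hr = 0, backflow = TRUE)
  compartment_system(route = route,
                     compartments = topo$compartments,
                     transfers = rbind(topo$forward, backward),
                     eliminations = topo$eliminations,
                     input_compartment = topo$input,
                     kin = params$kin,
                     release_fit = release_fit)
}

# System matrix A of dC/dt = A C + kin * C_H(t) e_input.
transfer_matrix <- function(system) {
  n <- length(system$compartments)
  A <- matrix(0, n, n, dimnames = list(system$compartments,
                                       system$compartments))
  tr <- system$transfers
  for (i in seq_len(nrow(tr))) {
    s <- tr$source[i]; d <- tr$target[i]; k <- tr$rate_per_hr[i]
    A[d, s] <- A[d, s] + k
    A[s, s] <- A[s, s] - k
  }
  diag(A) <- diag(A) - system$eliminations[system$compartments]
  A
}

#' Right-hand side of the compartmental ODE system
#'
#' Derivative of each compartment concentration: inflows minus outflows,
#' with the input compartment receiving `kin * C_H(t)`. Exposed for
#' inspection and for fixed-step integrators; [simulate_system()] uses the
#' same arithmetic.
#'
#' @param system A [compartment_system()].
#' @param t Time in hours, `>= 0`.
#' @param state Named or unnamed numeric vector of concentrations, one per
#'   compartment (in `system$compartments` order when unnamed).
#' @return Named numeric vector of derivatives, mg/mL/hr.
#' @export
rhs <- function(system, t, state) {
  if (!inherits(system, "compartment_system"))
    stop("'system' must be a compartment_system", call. = FALSE)
  if (length(state) != length(system$compartments))
    stop("'state' has length ", length(state), " but the system has ",
         length(system$compartments), " compartments", call. = FALSE)
  stopifnot(is.numeric(t), length(t) == 1L, t >= 0)
  if (!is.null(names(state))) state <- state[system$compartments]
  A <- transfer_matrix(system)
  d <- as.vector(A %*% as.numeric(state))
  names(d) <- system$compartments
  d[system$input_compartment] <- d[system$input_compartment] +
    system$kin * hydrogel_concentration(t, system$release_fit)
  d
}

#' @export
print.compartment_system <- function(x, ...) {
  fwd <- x$transfers[!x$transfers$backflow, , drop = FALSE]
  cat(sprintf("Compartment system (%s route): %d compartments, input into '%s', kin = %g hr^-1\n",
              x$route, length(x$compartments), x$input_compartment, x$kin))
  for (i in seq_len(nrow(fwd)))
    cat(sprintf("  %s -> %s @ %g\n", fwd$source[i], fwd$target[i],
                fwd$rate_per_hr[i]))
  loss <- x$eliminations[x$eliminations > 0]
  if (length(loss))
    cat("  losses:", paste(sprintf("%s @ %g", names(loss), loss),
                           collapse = ", "), "\n")
  invisible(x)
}

#' Export the transfer graph as an edge list
#'
#' Writes `source,target,rate_per_hr` CSV (forward and zero-rate backflow
#' edges) for inspection.
#'
#' @param system A [compartment_system()].
#' @param path File path.
#' @return The path, invisibly.
#' @export
write_edge_list <- function(system, path) {
  if (!inherits(system, "compartment_system"))
    stop("'system' must be a compartment_system", call. = FALSE)
  utils::write.csv(system$transfers[, c("source", "target", "rate_per_hr")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
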