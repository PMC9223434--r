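#' Simulation settings
#'
#' Collects the numerical settings shared by every simulation in an analysis:
#' the horizon `T` over which responses are integrated, the output grid on
#' which all trajectories are evaluated (shared between nominal and altered
#' runs so pointwise differences need no interpolation), and solver
#' tolerances.
#'
#' @param horizon End time of the simulation, in the model's time units.
#' @param grid Either a single integer giving the number of equally spaced
#'   output points on `[0, horizon]` (default 1000), or an explicit strictly
#'   increasing time vector starting at 0 and ending at `horizon`.
#' @param rtol,atol Relative and absolute solver tolerances.
#' @param stiff If `TRUE` (default) use a stiff-capable integrator
#'   (`deSolve`'s `lsoda`, which switches between stiff and non-stiff
#'   methods automatically); otherwise a non-stiff Runge-Kutta pair.
#'
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(horizon = 48)
#' @export
sim_config <- function(horizon, grid = 1000L, rtol = 1e-6, atol = 1e-9,
                       stiff = TRUE) {
  if (!is.numeric(horizon) || length(horizon) != 1L || !is.finite(horizon) ||
      horizon <= 0) {
    abort_validation("`horizon` must be a single positive number.")
  }
  if (rtol <= 0 || atol <= 0) {
    abort_validation("Solver tolerances must be positive.")
  }
  if (length(grid) == 1L) {
    if (grid < 2) abort_validation("`grid` needs at least 2 output points.")
    times <- seq(0, horizon, length.out = as.integer(grid))
  } else {
    times <- as.numeric(grid)
    if (is.unsorted(times, strictly = TRUE) ||
        abs(times[1L]) > 0 ||
        abs(times[length(times)] - horizon) > 1e-10 * max(1, horizon)) {
      abort_validation(
        "An explicit grid must be strictly increasing, start at 0 and end at `horizon`."
      )
    }
    times[length(times)] <- horizon
  }
  structure(
    list(horizon = horizon, times = times, rtol = rtol, atol = atol,
         stiff = isTRUE(stiff)),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> horizon =", x$horizon,
      "| grid points =", length(x$times),
      "| rtol =", x$rtol, "| atol =", x$atol,
      "| solver =", if (x$stiff) "lsoda (stiff-capable)" else "rk45", "\n")
  invisible(x)
}

#' Simulate an ODE model on a fixed output grid
#'
#' Integrates the model from its initial state and returns the solution of
#' every state variable on the configured output grid as a tibble. The same
#' call is used for the nominal simulation and for each altered-parameter
#' simulation of a sensitivity analysis, guaranteeing a shared time grid.
#'
#' @param model An [ode_model()].
#' @param params Named numeric vector of parameter values covering every model
#'   parameter, or `NULL` (default) for the nominal values. Partial vectors
#'   override the nominal values for the named entries only.
#' @param config A [sim_config()].
#'
#' @return A tibble of class `aucsens_trajectory` with a `time` column and one
#'   column per state, carrying the model name and the parameter values used
#'   as attributes (`model_name`, `params_used`, `horizon`).
#' @examples
#' m <- make_linear_chain(k = 1, d = 0.5)
#' traj <- simulate_model(m, config = sim_config(horizon = 10))
#' tail(traj, 2)
#' @export
simulate_model <- function(model, params = NULL, config) {
  stopifnot(inherits(model, "ode_model"))
  if (!inherits(config, "sim_config")) {
    abort_validation("`config` must be a sim_config object.")
  }
  full <- model$nominal_params
  if (!is.null(params)) {
    if (is.null(names(params)) || !all(names(params) %in% model$param_names)) {
      abort_validation(sprintf(
        "Unknown parameter(s): %s.",
        paste(setdiff(names(params), model$param_names), collapse = ", ")
      ))
    }
    full[names(params)] <- params
  }
  if (any(!is.finite(full))) {
    abort_validation("All parameter values must be finite.")
  }

  rhs <- model$rhs
  excitation <- model$excitation
  state_names <- model$state_names
  derivs <- function(t, y, p) {
    names(y) <- state_names
    list(rhs(t, y, full, excitation(t)))
  }
  method <- if (config$stiff) "lsoda" else "ode45"
  out <- tryCatch(
    suppressWarnings(deSolve::ode(
      y = unname(model$initial_state), times = config$times, func = derivs,
      parms = NULL, method = method, rtol = config$rtol, atol = config$atol
    )),
    error = function(e) e
  )
  fail <- function(reason) {
    abort(
      sprintf(
        "Integration of model '%s' failed (%s) for parameters: %s.",
        model$name, reason,
        paste(sprintf("%s=%.6g", names(full), full), collapse = ", ")
      ),
      class = "aucsens_integration_error",
      params = full
    )
  }
  if (inherits(out, "error")) fail(conditionMessage(out))
  istate <- attr(out, "istate")
  if (!is.null(istate) && istate[1L] < 0) fail("solver did not converge")
  if (nrow(out) < length(config$times)) fail("integration stopped early")
  states <- out[, -1L, drop = FALSE]
  if (any(!is.finite(states))) fail("non-finite state values")

  traj <- tibble::as_tibble(as.data.frame(unclass(out)))
  names(traj) <- c("time", state_names)
  attr(traj, "model_name") <- model$name
  attr(traj, "params_used") <- full
  attr(traj, "horizon") <- config$horizon
  class(traj) <- c("aucsens_trajectory", class(traj))
  traj
}

#' Area under a trajectory curve
#'
#' Time integral \eqn{\int_0^T x(t)\,dt} of one state variable of a simulated
#' trajectory, approximated by the composite trapezoid rule on the output
#' grid. This is the response summary underlying every sensitivity index in
#' the package.
#'
#' @param traj A trajectory from [simulate_model()] (or any data frame with a
#'   `time` column).
#' @param variable State name to integrate; defaults to the model output
#'   stored with the trajectory when available, otherwise the first state.
#' @param horizon Upper integration limit `T`; defaults to the last grid
#'   time. Must not exceed it, and is expected to fall on a grid point.
#' @return A single number.
#' @examples
#' m <- make_linear_chain(k = 1, d = 0.5)
#' traj <- simulate_model(m, config = sim_config(horizon = 10))
#' auc(traj) # close to 16.027
#' @export
auc <- function(traj, variable = NULL, horizon = NULL) {
  if (!is.data.frame(traj) || !"time" %in% names(traj)) {
    abort_validation("`traj` must be a trajectory with a `time` column.")
  }
  variable <- variable %||% attr(traj, "output_variable") %||%
    setdiff(names(traj), "time")[1L]
  if (!variable %in% names(traj)) {
    abort_validation(sprintf("Unknown variable '%s' in trajectory.", variable))
  }
  times <- traj$time
  horizon <- horizon %||% times[length(times)]
  if (horizon > times[length(times)] + 1e-9 * max(1, horizon)) {
    abort_validation("`horizon` exceeds the simulated time range.")
  }
  keep <- times <= horizon + 1e-9 * max(1, horizon)
  pracma::trapz(times[keep], traj[[variable]][keep])
}

#' Count interior local maxima of a trajectory variable
#'
#' Used to characterise qualitative dynamics of the demonstration models: an
#' oscillatory response shows two or more interior peaks over the horizon
#' while a monotone or single-pulse response shows at most one. Plateau peaks
#' (flat tops) are counted once; tiny numerical wiggles below `tol` relative
#' to the signal range are ignored.
#'
#' @param traj Trajectory from [simulate_model()].
#' @param variable State name; defaults to the first state column.
#' @param tol Relative noise floor for peak detection.
#' @return Integer count of local maxima strictly inside the time range.
#' @export
count_local_maxima <- function(traj, variable = NULL, tol = 1e-6) {
  variable <- variable %||% setdiff(names(traj), "time")[1L]
  if (!variable %in% names(traj)) {
    abort_validation(sprintf("Unknown variable '%s' in trajectory.", variable))
  }
  x <- traj[[variable]]
  rng <- diff(range(x))
  if (rng <= 0) return(0L)
  d <- diff(x)
  d[abs(d) < tol * rng] <- 0
  s <- sign(d)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(s[-length(s)] > 0 & s[-1L] < 0)
}

#' Write a trajectory to CSV
#'
#' Plain CSV export with the time column first and one column per state.
#'
#' @param traj Trajectory from [simulate_model()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
export_trajectory <- function(traj, path) {
  write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}
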