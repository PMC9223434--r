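#' Define an ODE pathway model
#'
#' An `ode_model` bundles everything needed to simulate a signaling-pathway
#' model written as a system of ordinary differential equations
#' \eqn{dX/dt = F(X, P, u)}: named states with initial conditions, named
#' kinetic parameters with nominal values, the right-hand-side function `F`,
#' an optional time-dependent excitation `u` (an external stimulus such as an
#' irradiation pulse or a cytokine dose), and the single state variable that
#' represents the system output in sensitivity analyses.
#'
#' @param name Model name (used in trajectories, reports and the model
#'   registry).
#' @param initial_state Named numeric vector of non-negative initial
#'   concentrations; the names define the model's state variables and their
#'   order.
#' @param parameters Named numeric vector of nominal kinetic parameter values;
#'   every value must be finite.
#' @param rhs Function `(t, state, params, input)` returning the derivative of
#'   each state as a numeric vector in state order. `state` and `params`
#'   arrive as named numeric vectors and `input` is the excitation evaluated
#'   at `t`.
#' @param output Name of the state variable whose response is analysed (the
#'   system output \eqn{x_i}).
#' @param excitation Function of time returning the excitation value, or
#'   `NULL` for a constant zero input. See [step_excitation()] for
#'   piecewise-constant stimuli.
#' @param non_ranked Character vector of parameters excluded from sensitivity
#'   rankings (structural constants such as Michaelis-Menten or saturation
#'   coefficients, which do not correspond to a druggable process).
#'
#' @return An object of class `ode_model`.
#' @examples
#' decay <- ode_model(
#'   "decay",
#'   initial_state = c(x = 2),
#'   parameters = c(d = 1),
#'   rhs = function(t, state, params, input) -params[["d"]] * state[["x"]],
#'   output = "x"
#' )
#' decay
#' @export
ode_model <- function(name, initial_state, parameters, rhs, output,
                      excitation = NULL, non_ranked = character()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort_validation("`name` must be a non-empty string.")
  }
  if (is.null(names(initial_state)) || any(!nzchar(names(initial_state)))) {
    abort_validation("`initial_state` must be a fully named numeric vector.")
  }
  if (anyDuplicated(names(initial_state))) {
    abort_validation("State names must be unique.")
  }
  if (any(!is.finite(initial_state)) || any(initial_state < 0)) {
    abort_validation("Initial state values must be finite and non-negative.")
  }
  if (is.null(names(parameters)) || any(!nzchar(names(parameters)))) {
    abort_validation("`parameters` must be a fully named numeric vector.")
  }
  if (anyDuplicated(names(parameters))) {
    abort_validation("Parameter names must be unique.")
  }
  if (any(!is.finite(parameters))) {
    abort_validation("Every nominal parameter value must be finite.")
  }
  if (!is.function(rhs)) {
    abort_validation("`rhs` must be a function(t, state, params, input).")
  }
  if (!is.character(output) || length(output) != 1L ||
      !output %in% names(initial_state)) {
    abort_validation(sprintf(
      "`output` must be one of the state names: %s.",
      paste(names(initial_state), collapse = ", ")
    ))
  }
  if (!all(non_ranked %in% names(parameters))) {
    bad <- setdiff(non_ranked, names(parameters))
    abort_validation(sprintf(
      "`non_ranked` names not present in parameters: %s.",
      paste(bad, collapse = ", ")
    ))
  }
  if (is.null(excitation)) excitation <- function(t) 0
  if (!is.function(excitation)) {
    abort_validation("`excitation` must be NULL or a function of time.")
  }
  structure(
    list(
      name = name,
      state_names = names(initial_state),
      param_names = names(parameters),
      nominal_params = parameters,
      rhs = rhs,
      initial_state = initial_state,
      excitation = excitation,
      output_variable = output,
      non_ranked_params = non_ranked
    ),
    class = "ode_model"
  )
}

#' @export
print.ode_model <- function(x, ...) {
  cat("<ode_model> ", x$name, "\n", sep = "")
  cat("  states (", length(x$state_names), "): ",
      paste(x$state_names, collapse = ", "), "\n", sep = "")
  cat("  parameters (", length(x$param_names), "): ",
      paste(x$param_names, collapse = ", "), "\n", sep = "")
  cat("  output: ", x$output_variable, "\n", sep = "")
  if (length(x$non_ranked_params)) {
    cat("  not ranked: ", paste(x$non_ranked_params, collapse = ", "),
        "\n", sep = "")
  }
  invisible(x)
}

#' Parameters eligible for sensitivity ranking
#'
#' All model parameters minus the declared non-ranked constants.
#'
#' @param model An [ode_model()].
#' @return Character vector of rankable parameter names.
#' @export
ranked_params <- function(model) {
  stopifnot(inherits(model, "ode_model"))
  setdiff(model$param_names, model$non_ranked_params)
}

#' Piecewise-constant excitation
#'
#' Builds a right-continuous step function of time, the usual description of
#' an on/off stimulus (e.g. an irradiation window or sustained cytokine
#' exposure).
#'
#' @param times Increasing numeric vector of switch times; the first value is
#'   the time the first level takes effect.
#' @param values Numeric vector of levels, same length as `times`. Before
#'   `times[1]` the excitation is 0.
#' @return A function of time.
#' @examples
#' u <- step_excitation(c(0, 10), c(1, 0)) # stimulus on during [0, 10)
#' u(5); u(12)
#' @export
step_excitation <- function(times, values) {
  if (length(times) != length(values) || length(times) == 0L) {
    abort_validation("`times` and `values` must be non-empty and equal length.")
  }
  if (is.unsorted(times, strictly = TRUE)) {
    abort_validation("`times` must be strictly increasing.")
  }
  force(times); force(values)
  function(t) {
    i <- findInterval(t, times)
    ifelse(i == 0, 0, values[pmax(i, 1L)])
  }
}
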