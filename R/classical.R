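#' Local sensitivity function of the output with respect to one parameter
#'
#' Classical local sensitivity analysis works with the sensitivity function
#' \eqn{s_j(t) = \partial x_i(t) / \partial p_j} evaluated along the nominal
#' trajectory. It is estimated here by central finite differences on the
#' parameter: the model is simulated at \eqn{p_j(1 \pm h)} and
#' \eqn{s_j(t) \approx [x(p(1+h), t) - x(p(1-h), t)] / (2 h p_j)}, which is
#' second-order accurate in `h` for smooth solutions.
#'
#' @param model An [ode_model()].
#' @param config A [sim_config()].
#' @param param Parameter name; its nominal value must be nonzero.
#' @param rel_step Relative step `h` in (0, 0.5); default 1e-3.
#' @param normalized If `TRUE`, return the fully relative sensitivity
#'   \eqn{s_j(t)\, p_j / x_{\mathrm{nom}}(t)}, set to `NA` where the nominal
#'   output is below the numerical floor.
#' @return A tibble of class `sensitivity_function` with columns `time` and
#'   `sensitivity`, plus attributes `param`, `normalized`, `rel_step`.
#' @examples
#' m <- ode_model("decay", c(x = 1), c(d = 1),
#'                function(t, s, p, u) -p[["d"]] * s[["x"]], output = "x")
#' sf <- sensitivity_function(m, sim_config(horizon = 1, grid = 101), "d")
#' sf[101, ] # close to -exp(-1)
#' @export
sensitivity_function <- function(model, config, param, rel_step = 1e-3,
                                 normalized = FALSE) {
  stopifnot(inherits(model, "ode_model"))
  if (!param %in% model$param_names) {
    abort_validation(sprintf("Unknown parameter '%s'.", param))
  }
  if (rel_step <= 0 || rel_step >= 0.5) {
    abort_validation("`rel_step` must lie in (0, 0.5).")
  }
  p_nom <- model$nominal_params[[param]]
  if (p_nom == 0) {
    abort(
      sprintf("Parameter '%s' has a zero nominal value and cannot be perturbed relatively.", param),
      class = "aucsens_unrankable_error"
    )
  }
  up <- simulate_model(model, setNames(p_nom * (1 + rel_step), param), config)
  dn <- simulate_model(model, setNames(p_nom * (1 - rel_step), param), config)
  out_var <- model$output_variable
  s <- (up[[out_var]] - dn[[out_var]]) / (2 * rel_step * p_nom)
  if (normalized) {
    nom <- simulate_model(model, config = config)
    x <- nom[[out_var]]
    floor_val <- 1e-12 * max(1, abs(x))
    s <- ifelse(x > floor_val, s * p_nom / x, NA_real_)
  }
  res <- tibble::tibble(time = up$time, sensitivity = s)
  attr(res, "param") <- param
  attr(res, "normalized") <- normalized
  attr(res, "rel_step") <- rel_step
  attr(res, "model_name") <- model$name
  class(res) <- c("sensitivity_function", class(res))
  res
}

#' Classical sensitivity-function ranking
#'
#' The comparison baseline: each rankable parameter is scored by the area
#' under the curve of its sensitivity function,
#' \eqn{R_{\mathrm{cl},j} = p_j \int_0^T |s_j(t)|\,dt} (semi-relative — the
#' derivative is scaled by the nominal parameter value so scores are
#' comparable across parameters of different units; `scale = "absolute"`
#' drops the \eqn{p_j} factor). The absolute value inside the integral
#' follows the usual convention for this baseline, which is exactly why it
#' cannot distinguish parameters whose alteration suppresses the output from
#' those whose alteration amplifies it — the contrast the randomized ranking
#' of [rank_parameters()] is designed to provide.
#'
#' @inheritParams sensitivity_function
#' @param scale `"semi"` (default, multiply by the nominal parameter value)
#'   or `"absolute"`.
#' @return An object of class `classical_ranking`: a list with `ranking` (a
#'   tibble of parameter, R_cl, unrankable, sorted by R_cl descending, ties
#'   by name) and metadata. Supports [tidy()], [glance()] and [autoplot()].
#' @examples
#' m <- make_linear_chain(k = 1, d = 0.5)
#' tidy(rank_classical(m, sim_config(horizon = 10, grid = 200)))
#' @export
rank_classical <- function(model, config, rel_step = 1e-3,
                           scale = c("semi", "absolute")) {
  stopifnot(inherits(model, "ode_model"))
  scale <- match.arg(scale)
  params <- ranked_params(model)
  if (!length(params)) abort_validation("Model has no rankable parameters.")
  rows <- purrr::map(params, function(p) {
    sf <- tryCatch(
      sensitivity_function(model, config, p, rel_step = rel_step),
      aucsens_unrankable_error = function(e) NULL,
      aucsens_integration_error = function(e) NULL
    )
    if (is.null(sf)) {
      return(tibble::tibble(parameter = p, R_cl = NA_real_, unrankable = TRUE))
    }
    fac <- if (scale == "semi") abs(model$nominal_params[[p]]) else 1
    tibble::tibble(
      parameter = p,
      R_cl = fac * pracma::trapz(sf$time, abs(sf$sensitivity)),
      unrankable = FALSE
    )
  })
  ranking <- dplyr::bind_rows(rows) |>
    dplyr::arrange(.data$unrankable, dplyr::desc(.data$R_cl), .data$parameter)
  structure(
    list(
      ranking = ranking,
      model_name = model$name,
      output_variable = model$output_variable,
      horizon = config$horizon,
      rel_step = rel_step,
      scale = scale
    ),
    class = "classical_ranking"
  )
}

#' @export
print.classical_ranking <- function(x, ...) {
  cat(sprintf(
    "<classical_ranking> model '%s', output '%s', horizon %g, rel_step %g (%s scale)\n",
    x$model_name, x$output_variable, x$horizon, x$rel_step, x$scale
  ))
  print(x$ranking, ...)
  invisible(x)
}

#' @rdname rank_classical
#' @param x,object A `classical_ranking`.
#' @param ... Unused.
#' @method tidy classical_ranking
#' @export
tidy.classical_ranking <- function(x, ...) x$ranking

#' @rdname rank_classical
#' @method glance classical_ranking
#' @export
glance.classical_ranking <- function(x, ...) {
  tibble::tibble(
    model = x$model_name,
    output_variable = x$output_variable,
    horizon = x$horizon,
    n_parameters = nrow(x$ranking),
    n_unrankable = sum(x$ranking$unrankable),
    rel_step = x$rel_step,
    scale = x$scale
  )
}

#' @rdname rank_classical
#' @method autoplot classical_ranking
#' @export
autoplot.classical_ranking <- function(object, ...) {
  df <- dplyr::filter(object$ranking, !.data$unrankable) |>
    dplyr::mutate(parameter = factor(.data$parameter, levels = .data$parameter))
  ggplot2::ggplot(df, ggplot2::aes(.data$parameter, .data$R_cl)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "parameter (ranked)", y = "AUC of |sensitivity function|",
      title = sprintf("Classical sensitivity ranking: %s", object$model_name),
      subtitle = "unsigned index: cannot separate suppressing from amplifying parameters"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
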