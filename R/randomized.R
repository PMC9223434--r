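#' Pointwise response difference between altered and nominal trajectories
#'
#' Computes \eqn{\Delta x_i(p_j, t) = x_i(p_j, t) - x_{i,\mathrm{nom}}(t)},
#' the change in the output variable caused by altering one parameter, on the
#' shared output grid.
#'
#' @param traj_altered,traj_nominal Trajectories from [simulate_model()] on
#'   the same time grid.
#' @param variable State name of the system output.
#' @return Numeric vector, altered minus nominal, one value per grid point.
#' @export
delta_response <- function(traj_altered, traj_nominal, variable) {
  for (tr in list(traj_altered, traj_nominal)) {
    if (!is.data.frame(tr) || !"time" %in% names(tr)) {
      abort_validation("Both arguments must be trajectories with a `time` column.")
    }
    if (!variable %in% names(tr)) {
      abort_validation(sprintf("Variable '%s' missing from a trajectory.", variable))
    }
  }
  if (nrow(traj_altered) != nrow(traj_nominal) ||
      max(abs(traj_altered$time - traj_nominal$time)) > 1e-9) {
    abort_validation("Trajectories must share the same time grid.")
  }
  traj_altered[[variable]] - traj_nominal[[variable]]
}

#' Signed AUC-ratio sensitivity index
#'
#' The per-simulation index
#' \deqn{S_j = \frac{\int_0^T \Delta x_i(p_j, t)\,dt}
#'                  {\int_0^T x_{i,\mathrm{nom}}(t)\,dt},}
#' the area under the response-difference curve normalised by the area under
#' the nominal response. The sign carries the drug-action interpretation:
#' negative values mean the alteration suppresses the output (with \eqn{S =
#' -1} the complete suppression, the output identically zero), positive
#' values mean amplification, with no upper bound. The integral is taken of
#' the signed difference, not of \eqn{|\Delta x|} or \eqn{(\Delta x)^2},
#' precisely so that this direction information survives.
#'
#' @param delta Response difference from [delta_response()].
#' @param traj_nominal Nominal trajectory (defines the grid and denominator).
#' @param variable Output state name; defaults to the first state column.
#' @param horizon Upper integration limit; defaults to the end of the grid.
#' @return A single signed number.
#' @examples
#' m <- make_linear_chain(k = 1, d = 0.5)
#' cfg <- sim_config(horizon = 10)
#' nom <- simulate_model(m, config = cfg)
#' alt <- simulate_model(m, params = c(k = 0.15 * 1), config = cfg)
#' sensitivity_index(delta_response(alt, nom, "x"), nom, "x") # about -0.85
#' @export
sensitivity_index <- function(delta, traj_nominal, variable = NULL,
                              horizon = NULL) {
  variable <- variable %||% setdiff(names(traj_nominal), "time")[1L]
  if (length(delta) != nrow(traj_nominal)) {
    abort_validation("`delta` length must match the nominal grid.")
  }
  horizon <- horizon %||% traj_nominal$time[nrow(traj_nominal)]
  denom <- auc(traj_nominal, variable, horizon)
  floor_val <- 1e-12 * max(1, horizon)
  if (!is.finite(denom) || denom <= floor_val) {
    abort(
      sprintf(
        paste0("Nominal AUC of output '%s' is %.3g, at or below the numerical ",
               "floor: the output never rises above zero under nominal ",
               "conditions, so the sensitivity index is undefined."),
        variable, denom
      ),
      class = "aucsens_undefined_index"
    )
  }
  keep <- traj_nominal$time <= horizon + 1e-9 * max(1, horizon)
  num <- pracma::trapz(traj_nominal$time[keep], delta[keep])
  num / denom
}

#' Display value of the population-mean index
#'
#' Rankings are plotted on a logarithmic axis, so the population-mean index
#' `A` is shifted by one: `A + 1` is non-negative whenever `A >= -1` (which
#' holds for non-negative outputs). Values above 1 mean the alteration
#' amplifies the output, values below 1 mean suppression, and 1 itself is the
#' no-effect threshold line.
#'
#' @param A Numeric vector of population-mean indices.
#' @param tol Tolerance below \eqn{-1} before an error is raised; values of
#'   `A` below \eqn{-1} beyond this signal non-physical negative trajectories.
#' @return `A + 1`.
#' @export
display_value <- function(A, tol = 1e-8) {
  bad <- is.finite(A) & (A + 1 < -tol)
  if (any(bad)) {
    abort(
      sprintf("A + 1 is negative beyond tolerance (min A = %.6g); the output trajectory must have gone negative.",
              min(A[bad])),
      class = "aucsens_numerical_anomaly"
    )
  }
  A + 1
}

#' Classify a parameter by the sign of its population-mean index
#'
#' @param A Numeric vector of population-mean indices.
#' @param neutral_band Half-width of the no-effect band around zero; indices
#'   within `[-neutral_band, neutral_band]` are called neutral. Default 0.01.
#' @return Character vector with values `"amplifying"`, `"suppressing"` or
#'   `"neutral"` (`NA` for `NA` input).
#' @export
classify_parameter <- function(A, neutral_band = 0.01) {
  if (neutral_band < 0) abort_validation("`neutral_band` must be >= 0.")
  dplyr::case_when(
    is.na(A) ~ NA_character_,
    A > neutral_band ~ "amplifying",
    A < -neutral_band ~ "suppressing",
    TRUE ~ "neutral"
  )
}

derive_seeds <- function(seed, k) {
  withr::with_seed(as.integer(seed), sample.int(2147483646L, k))
}

run_altered <- function(model, config, param, alpha, nominal_value) {
  tryCatch(
    simulate_model(model, params = setNames(alpha * nominal_value, param),
                   config = config),
    aucsens_integration_error = function(e) NULL
  )
}

#' Randomized OAT sensitivity ranking
#'
#' The package's main analysis. One nominal simulation is run and its output
#' AUC taken as the reference. Then, one parameter at a time, `n` alteration
#' factors \eqn{\alpha} are drawn from `dist`, the model is re-simulated with
#' \eqn{p_j = \alpha\, p_{j,\mathrm{nom}}} (all other parameters nominal),
#' and the signed index \eqn{S_j} is computed for every draw. The ranking
#' score for parameter \eqn{j} is the population mean
#' \eqn{A_j = \bar\mu(S_j)}, which averages the heterogeneous per-cell drug
#' effects; its sign separates parameters whose alteration amplifies the
#' output from those whose alteration suppresses it — the property a
#' drug-target search needs and an unsigned local ranking cannot provide.
#'
#' Altered simulations that fail to integrate (extreme draws can stiffen the
#' system) are dropped and counted in `failed_runs`; a parameter losing more
#' than 10\% of its draws is reported with a warning. Parameters with a zero
#' nominal value cannot be altered multiplicatively and appear in the table
#' as unrankable rather than being silently omitted, as does any parameter
#' whose draws all fail.
#'
#' @param model An [ode_model()]; parameters listed in its
#'   `non_ranked_params` are excluded.
#' @param config A [sim_config()] shared by nominal and altered runs.
#' @param dist An [alteration_dist()]; default is the 85\%-mean-reduction
#'   log-normal law.
#' @param n Draws per parameter (default 1000, the ensemble size used
#'   throughout the package).
#' @param seed Master seed; per-parameter substreams are derived from it
#'   deterministically, so results are reproducible and independent of any
#'   execution order.
#' @param neutral_band Passed to [classify_parameter()].
#' @param sort_by `"abs"` (default) ranks by `|A|` descending so strong
#'   amplifiers and strong suppressors both rank high; `"signed"` ranks by
#'   `A` descending. Ties break by parameter name.
#'
#' @return An object of class `oat_ranking`: a list with `ranking` (tibble of
#'   parameter, A, display_value, classification, n_effective, failed_runs,
#'   unrankable), `samples` (tibble of parameter, alpha, S, R — one row per
#'   successful altered simulation, where R is the un-normalised AUC of the
#'   response difference), and run metadata. Supports [tidy()], [glance()],
#'   [autoplot()] and `print()`.
#' @examples
#' m <- make_linear_chain(k = 1, d = 0.5)
#' r <- rank_parameters(m, sim_config(horizon = 10, grid = 200), n = 50, seed = 1)
#' tidy(r)
#' @export
rank_parameters <- function(model, config, dist = alteration_dist(),
                            n = 1000, seed = 1, neutral_band = 0.01,
                            sort_by = c("abs", "signed")) {
  stopifnot(inherits(model, "ode_model"), inherits(dist, "alteration_dist"))
  sort_by <- match.arg(sort_by)
  if (n < 1) abort_validation("`n` must be at least 1.")
  n <- as.integer(n)

  params <- ranked_params(model)
  if (!length(params)) abort_validation("Model has no rankable parameters.")
  nominal <- simulate_model(model, config = config)
  out_var <- model$output_variable
  nominal_auc <- auc(nominal, out_var, config$horizon)
  # fail fast if the index is undefined for this output
  sensitivity_index(rep(0, nrow(nominal)), nominal, out_var, config$horizon)

  sub_seeds <- derive_seeds(seed, length(params))
  per_param <- purrr::map2(params, sub_seeds, function(p, s) {
    p_nom <- model$nominal_params[[p]]
    if (p_nom == 0) {
      return(list(
        row = tibble::tibble(
          parameter = p, A = NA_real_, n_effective = 0L, failed_runs = n,
          unrankable = TRUE
        ),
        samples = tibble::tibble(parameter = character(), alpha = double(),
                                 S = double(), R = double())
      ))
    }
    alphas <- sample_alpha(dist, n, s)
    sims <- purrr::map(alphas, run_altered, model = model, config = config,
                       param = p, nominal_value = p_nom)
    ok <- !purrr::map_lgl(sims, is.null)
    S <- R <- rep(NA_real_, sum(ok))
    keep_t <- nominal$time <= config$horizon + 1e-9 * max(1, config$horizon)
    i <- 0L
    for (sim in sims[ok]) {
      i <- i + 1L
      d <- delta_response(sim, nominal, out_var)
      R[i] <- pracma::trapz(nominal$time[keep_t], d[keep_t])
      S[i] <- R[i] / nominal_auc
    }
    failed <- n - sum(ok)
    if (failed > 0.1 * n) {
      warn(sprintf(
        "Parameter '%s': %d of %d altered simulations failed to integrate.",
        p, failed, n
      ))
    }
    list(
      row = tibble::tibble(
        parameter = p,
        A = if (sum(ok)) mean(S) else NA_real_,
        n_effective = sum(ok),
        failed_runs = failed,
        unrankable = sum(ok) == 0L
      ),
      samples = tibble::tibble(parameter = p, alpha = alphas[ok], S = S, R = R)
    )
  })

  ranking <- dplyr::bind_rows(purrr::map(per_param, "row")) |>
    dplyr::mutate(
      display_value = display_value(.data$A),
      classification = classify_parameter(.data$A, neutral_band)
    ) |>
    dplyr::arrange(
      .data$unrankable,
      if (sort_by == "abs") dplyr::desc(abs(.data$A)) else dplyr::desc(.data$A),
      .data$parameter
    ) |>
    dplyr::select("parameter", "A", "display_value", "classification",
                  "n_effective", "failed_runs", "unrankable")

  structure(
    list(
      ranking = ranking,
      samples = dplyr::bind_rows(purrr::map(per_param, "samples")),
      nominal = nominal,
      model_name = model$name,
      output_variable = out_var,
      horizon = config$horizon,
      nominal_auc = nominal_auc,
      distribution = dist,
      n = n,
      seed = as.integer(seed),
      neutral_band = neutral_band,
      sort_by = sort_by
    ),
    class = "oat_ranking"
  )
}

#' @export
print.oat_ranking <- function(x, ...) {
  cat(sprintf(
    "<oat_ranking> model '%s', output '%s', horizon %g, n = %d per parameter, seed %d\n",
    x$model_name, x$output_variable, x$horizon, x$n, x$seed
  ))
  print(x$ranking, ...)
  invisible(x)
}

#' @rdname rank_parameters
#' @param x An `oat_ranking` object.
#' @param ... Unused.
#' @method tidy oat_ranking
#' @export
tidy.oat_ranking <- function(x, ...) x$ranking

#' @rdname rank_parameters
#' @method glance oat_ranking
#' @export
glance.oat_ranking <- function(x, ...) {
  tibble::tibble(
    model = x$model_name,
    output_variable = x$output_variable,
    horizon = x$horizon,
    n_parameters = nrow(x$ranking),
    n_per_parameter = x$n,
    total_failed = sum(x$ranking$failed_runs),
    n_unrankable = sum(x$ranking$unrankable),
    nominal_auc = x$nominal_auc,
    seed = x$seed
  )
}

#' @rdname rank_parameters
#' @param object An `oat_ranking` object.
#' @param floor Smallest display value drawn on the log axis; complete
#'   suppression (display value 0) is clipped to this axis floor.
#' @method autoplot oat_ranking
#' @export
autoplot.oat_ranking <- function(object, floor = 1e-3, ...) {
  df <- dplyr::filter(object$ranking, !.data$unrankable) |>
    dplyr::mutate(
      parameter = factor(.data$parameter, levels = .data$parameter),
      shown = pmax(.data$display_value, floor)
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$parameter, y = .data$shown)) +
    ggplot2::geom_hline(yintercept = 1, colour = "red") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(
      x = "parameter (ranked)", y = "A + 1 (log scale)",
      title = sprintf("Randomized OAT sensitivity ranking: %s", object$model_name),
      subtitle = "above the red line: alteration amplifies the output; below: suppresses"
    ) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Population ensemble of altered-output trajectories
#'
#' Emulates a heterogeneous cell population under a drug aimed at one
#' process: `n` alteration factors are drawn, the model is re-simulated once
#' per draw with the targeted parameter(s) scaled, and the output variable is
#' collected for every run together with its pointwise population mean.
#' Passing several parameter names applies the same draw to each of them
#' simultaneously — a manual utility for drugs known to hit one molecule
#' involved in several processes (e.g. an Mdm2-binding drug slowing the
#' degradation of both p53 forms at once); the ranking itself remains
#' strictly one-at-a-time.
#'
#' @inheritParams rank_parameters
#' @param param Character vector of one (typical) or more parameter names to
#'   scale by each draw.
#' @return An object of class `oat_ensemble`: list with `runs` (long tibble:
#'   run, alpha, time, value), `mean_trajectory` (tibble: time, value),
#'   `nominal` (tibble: time, value), counts and metadata. Supports
#'   [autoplot()].
#' @export
population_ensemble <- function(model, config, param,
                                dist = alteration_dist(), n = 1000,
                                seed = 1) {
  stopifnot(inherits(model, "ode_model"))
  if (!all(param %in% model$param_names)) {
    abort_validation(sprintf(
      "Unknown parameter(s): %s.",
      paste(setdiff(param, model$param_names), collapse = ", ")
    ))
  }
  p_nom <- model$nominal_params[param]
  if (any(p_nom == 0)) {
    abort_validation("Parameters with zero nominal value cannot be scaled.")
  }
  out_var <- model$output_variable
  nominal <- simulate_model(model, config = config)
  alphas <- sample_alpha(dist, n, seed)
  runs <- purrr::imap(alphas, function(a, i) {
    sim <- tryCatch(
      simulate_model(model, params = setNames(a * p_nom, param), config = config),
      aucsens_integration_error = function(e) NULL
    )
    if (is.null(sim)) return(NULL)
    tibble::tibble(run = i, alpha = a, time = sim$time, value = sim[[out_var]])
  })
  ok <- !purrr::map_lgl(runs, is.null)
  if (!any(ok)) {
    abort(
      sprintf("All %d altered simulations failed for parameter(s) %s.",
              n, paste(param, collapse = ", ")),
      class = "aucsens_integration_error"
    )
  }
  runs <- dplyr::bind_rows(runs[ok])
  mean_traj <- runs |>
    dplyr::summarise(value = mean(.data$value), .by = "time")
  structure(
    list(
      runs = runs,
      mean_trajectory = mean_traj,
      nominal = tibble::tibble(time = nominal$time, value = nominal[[out_var]]),
      param = param,
      n = as.integer(n),
      n_effective = sum(ok),
      failed_runs = as.integer(n - sum(ok)),
      seed = as.integer(seed),
      model_name = model$name,
      output_variable = out_var,
      distribution = dist
    ),
    class = "oat_ensemble"
  )
}

#' @export
print.oat_ensemble <- function(x, ...) {
  cat(sprintf(
    "<oat_ensemble> model '%s', parameter(s) %s altered, %d/%d runs (%d failed), output '%s'\n",
    x$model_name, paste(x$param, collapse = "+"), x$n_effective, x$n,
    x$failed_runs, x$output_variable
  ))
  invisible(x)
}

#' @rdname population_ensemble
#' @param object An `oat_ensemble`.
#' @param max_shown Number of individual runs drawn (default 100); the
#'   population mean and the nominal response are always drawn.
#' @param ... Unused.
#' @method autoplot oat_ensemble
#' @export
autoplot.oat_ensemble <- function(object, max_shown = 100, ...) {
  shown_ids <- head(unique(object$runs$run), max_shown)
  shown <- dplyr::filter(object$runs, .data$run %in% shown_ids)
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = shown,
      ggplot2::aes(.data$time, .data$value, group = .data$run),
      colour = "grey70", linewidth = 0.2
    ) +
    ggplot2::geom_line(
      data = object$mean_trajectory,
      ggplot2::aes(.data$time, .data$value), colour = "black", linewidth = 0.8
    ) +
    ggplot2::labs(
      x = "time", y = object$output_variable,
      title = sprintf("Population ensemble: %s altered (%s)",
                      paste(object$param, collapse = "+"), object$model_name),
      subtitle = sprintf("%d of %d runs shown (grey), population mean in black",
                         length(shown_ids), object$n_effective)
    ) +
    ggplot2::theme_minimal()
}
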