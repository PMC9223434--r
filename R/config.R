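config_field_error <- function(path, msg) {
  abort_config(sprintf("Configuration error at `%s`: %s", path, msg))
}

known_config_keys <- c(
  "model", "name", "states", "equations", "parameters", "output",
  "exclude", "horizon", "grid", "rtol", "atol", "stiff",
  "distribution", "n_samples", "seed", "neutral_band", "classical",
  "rel_step", "include_samples"
)

#' Load a model and analysis configuration from YAML or JSON
#'
#' A configuration document names either a registered demonstration model
#' (`model:` key, optionally with `parameters:` overrides) or a fully custom
#' model defined inline by `name:`, `states:` (map state name to initial
#' value), `parameters:` (map name to nominal value), `equations:` (map state
#' name to an R expression string over the state names, parameter names, `t`
#' and the excitation `u`) and `output:`. Simulation settings (`horizon:` is
#' required; `grid:`, `rtol:`, `atol:`, `stiff:` optional) and analysis
#' settings (`distribution:`, `n_samples:`, `seed:`, `neutral_band:`,
#' `exclude:`, `classical:`, `rel_step:`, `include_samples:`) complete the
#' document. Unknown keys are rejected so typos fail loudly.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list with elements `model` (an [ode_model()]), `config` (a
#'   [sim_config()]) and `analysis` (distribution, n, seed, neutral band,
#'   and report options).
#' @export
load_model_config <- function(path) {
  if (!file.exists(path)) abort_config(sprintf("No such file: %s", path))
  doc <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  if (!is.list(doc)) abort_config("Configuration must be a mapping.")
  unknown <- setdiff(names(doc), known_config_keys)
  if (length(unknown)) {
    config_field_error(unknown[1L], "unknown key.")
  }

  if (is.null(doc$horizon)) config_field_error("horizon", "required key is missing.")
  if (!is.numeric(doc$horizon) || doc$horizon <= 0) {
    config_field_error("horizon", "must be a positive number.")
  }

  model <- if (!is.null(doc$model)) {
    if (!is.null(doc$states) || !is.null(doc$equations)) {
      config_field_error("model", "give either a registered model name or inline states/equations, not both.")
    }
    pars <- if (!is.null(doc$parameters)) unlist(doc$parameters) else NULL
    tryCatch(demo_model(doc$model, parameters = pars),
             aucsens_validation_error = function(e) {
               config_field_error("parameters", conditionMessage(e))
             })
  } else {
    build_inline_model(doc)
  }

  if (!is.null(doc$output)) {
    if (!doc$output %in% model$state_names) {
      config_field_error("output", sprintf(
        "'%s' is not a state of the model (states: %s).",
        doc$output, paste(model$state_names, collapse = ", ")
      ))
    }
    model$output_variable <- doc$output
  }
  if (!is.null(doc$exclude)) {
    extra <- unlist(doc$exclude)
    if (!all(extra %in% model$param_names)) {
      config_field_error("exclude", sprintf(
        "unknown parameter(s): %s.",
        paste(setdiff(extra, model$param_names), collapse = ", ")
      ))
    }
    model$non_ranked_params <- union(model$non_ranked_params, extra)
  }

  cfg <- tryCatch(
    sim_config(
      horizon = doc$horizon,
      grid = doc$grid %||% 1000L,
      rtol = doc$rtol %||% 1e-6,
      atol = doc$atol %||% 1e-9,
      stiff = doc$stiff %||% TRUE
    ),
    aucsens_validation_error = function(e) config_field_error("grid", conditionMessage(e))
  )

  dist <- parse_distribution(doc$distribution)
  analysis <- list(
    distribution = dist,
    n = as.integer(doc$n_samples %||% 1000L),
    seed = as.integer(doc$seed %||% 1L),
    neutral_band = doc$neutral_band %||% 0.01,
    classical = isTRUE(doc$classical),
    rel_step = doc$rel_step %||% 1e-3,
    include_samples = isTRUE(doc$include_samples)
  )
  if (analysis$n < 1) config_field_error("n_samples", "must be at least 1.")
  list(model = model, config = cfg, analysis = analysis)
}

parse_distribution <- function(spec) {
  if (is.null(spec)) return(alteration_dist())
  if (!is.list(spec)) config_field_error("distribution", "must be a mapping.")
  unknown <- setdiff(names(spec), c("kind", "meanlog", "sdlog", "value", "mode"))
  if (length(unknown)) {
    config_field_error(paste0("distribution.", unknown[1L]), "unknown key.")
  }
  tryCatch(
    alteration_dist(
      kind = spec$kind %||% "lognormal",
      meanlog = spec$meanlog %||% -2.08,
      sdlog = spec$sdlog %||% 0.61,
      value = spec$value %||% 1,
      mode = spec$mode %||% "reduction"
    ),
    error = function(e) config_field_error("distribution", conditionMessage(e))
  )
}

build_inline_model <- function(doc) {
  for (key in c("name", "states", "equations", "parameters", "output")) {
    if (is.null(doc[[key]])) {
      config_field_error(key, "required for an inline model definition.")
    }
  }
  states <- unlist(doc$states)
  params <- unlist(doc$parameters)
  eqs <- doc$equations
  if (!setequal(names(eqs), names(states))) {
    config_field_error("equations", sprintf(
      "must define exactly one equation per state; states are %s.",
      paste(names(states), collapse = ", ")
    ))
  }
  exprs <- lapply(names(states), function(s) {
    tryCatch(parse(text = eqs[[s]])[[1L]],
             error = function(e) config_field_error(
               paste0("equations.", s), conditionMessage(e)))
  })
  state_names <- names(states)
  rhs <- function(t, state, params, input) {
    env <- c(as.list(state), as.list(params), list(t = t, u = input))
    vapply(exprs, function(e) eval(e, env), numeric(1))
  }
  ode_model(doc$name, initial_state = states, parameters = params,
            rhs = rhs, output = doc$output)
}
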