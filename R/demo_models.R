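#' Production-degradation toy model
#'
#' The analytic oracle used throughout the package's tests:
#' \eqn{dx/dt = k - d\,x}, \eqn{x(0) = 0}, output `x`. Its solution
#' \eqn{x(t) = (k/d)(1 - e^{-dt})} is linear in the production rate `k`, so
#' scaling `k` by a factor \eqn{\alpha} scales the whole trajectory — and its
#' AUC — by \eqn{\alpha}, giving the exact identity \eqn{S = \alpha - 1} for
#' the production parameter. With \eqn{\alpha = 0} the output is identically
#' zero and \eqn{S = -1}, the complete-suppression floor of the index.
#'
#' @param k Production rate (> 0).
#' @param d Degradation rate (> 0).
#' @return An [ode_model()] named `"linear_chain"`.
#' @examples
#' m <- make_linear_chain()
#' auc(simulate_model(m, config = sim_config(horizon = 10))) # about 16.027
#' @export
make_linear_chain <- function(k = 1, d = 0.5) {
  if (k <= 0 || d <= 0) abort_validation("`k` and `d` must be positive.")
  ode_model(
    "linear_chain",
    initial_state = c(x = 0),
    parameters = c(k = k, d = d),
    rhs = function(t, state, params, input) {
      params[["k"]] - params[["d"]] * state[["x"]]
    },
    output = "x"
  )
}

#' Illustrative negative-feedback oscillator
#'
#' A minimal three-state surrogate with the loop topology of the p53/Mdm2
#' module: a protein `P` (the output, standing in for phospho-p53) is
#' produced constitutively and degraded by its inhibitor protein `M`
#' (Mdm2-like); `P` activates transcription of the inhibitor's mRNA `R`
#' through a Hill function; `R` is translated into `M`. The transcription and
#' translation stages delay the negative feedback enough for the response to
#' oscillate under the default parameters. These equations are synthetic and
#' illustrative only — they are not any published p53 model; they merely
#' reproduce the qualitative feature that matters for exercising the method
#' (an oscillatory output controlled by a delayed negative feedback loop).
#'
#' Reducing the inhibitor's transcription (`s0`) or translation (`t0`) rate
#' weakens the feedback and raises the output — the analogue of the
#' amplifying targets in an oscillatory pathway. The Hill constant `K` and
#' coefficient `h` are structural constants and are excluded from rankings.
#'
#' Default parameters (time in hours, concentrations in arbitrary units):
#' `p0 = 1` (output production), `s0 = 1` (inhibitor transcription),
#' `t0 = 1` (inhibitor translation), `d4 = 2` (inhibitor-mediated output
#' degradation), `d7 = 0.3` (mRNA turnover), `d0 = 0.3` (inhibitor
#' turnover), `K = 0.5`, `h = 4`. They were frozen after a one-off
#' calibration run (`scripts/calibrate_demo_models.R`) confirming at least
#' two output peaks over a 100-hour horizon and the expected effect
#' directions.
#'
#' @param parameters Optional named numeric vector overriding any subset of
#'   the defaults.
#' @return An [ode_model()] named `"feedback_oscillator"` with output `P`.
#' @export
make_negative_feedback_oscillator <- function(parameters = NULL) {
  defaults <- c(p0 = 1, s0 = 1, t0 = 1, d4 = 2, d7 = 0.3, d0 = 0.3,
                K = 0.5, h = 4)
  pars <- override_params(defaults, parameters)
  ode_model(
    "feedback_oscillator",
    initial_state = c(P = 0, R = 0, M = 0),
    parameters = pars,
    rhs = function(t, state, params, input) {
      P <- state[["P"]]; R <- state[["R"]]; M <- state[["M"]]
      hill <- P^params[["h"]] / (params[["K"]]^params[["h"]] + P^params[["h"]])
      c(
        params[["p0"]] - params[["d4"]] * M * P,
        params[["s0"]] * hill - params[["d7"]] * R,
        params[["t0"]] * R - params[["d0"]] * M
      )
    },
    output = "P",
    non_ranked = c("K", "h")
  )
}

#' Illustrative signaling cascade
#'
#' A three-stage surrogate with the shape of a cytokine-activated cascade
#' (receptor/kinase activation, effector phosphorylation with a saturable
#' step, target-gene transcript): a constant stimulus `u = 1` activates
#' `act`, which drives `phos` through Michaelis-Menten kinetics, which in
#' turn drives the transcript `tr` — the output, standing in for a target
#' mRNA such as IRF1's. The response is aperiodic: every stage relaxes
#' monotonically to a steady state. These equations are synthetic and
#' illustrative, not any published JAK/STAT model.
#'
#' Reducing the first activation rate `k_act` throttles the whole cascade and
#' suppresses the output; reducing the transcript degradation rate `d_tr`
#' stabilises the output and amplifies it — the two effect directions a
#' drug-target ranking must separate. The saturation constant `K_sat` is a
#' structural constant excluded from rankings.
#'
#' Defaults: `k_act = 0.5`, `d_act = 0.2`, `k_phos = 1`, `d_phos = 0.2`,
#' `k_tr = 0.5`, `d_tr = 0.1`, `K_sat = 1` (time in hours).
#'
#' @param parameters Optional named numeric vector overriding any subset of
#'   the defaults.
#' @return An [ode_model()] named `"cascade"` with output `tr`.
#' @export
make_cascade <- function(parameters = NULL) {
  defaults <- c(k_act = 0.5, d_act = 0.2, k_phos = 1, d_phos = 0.2,
                k_tr = 0.5, d_tr = 0.1, K_sat = 1)
  pars <- override_params(defaults, parameters)
  ode_model(
    "cascade",
    initial_state = c(act = 0, phos = 0, tr = 0),
    parameters = pars,
    rhs = function(t, state, params, input) {
      act <- state[["act"]]; phos <- state[["phos"]]; tr <- state[["tr"]]
      c(
        params[["k_act"]] * input - params[["d_act"]] * act,
        params[["k_phos"]] * act / (params[["K_sat"]] + act) -
          params[["d_phos"]] * phos,
        params[["k_tr"]] * phos - params[["d_tr"]] * tr
      )
    },
    output = "tr",
    excitation = function(t) 1,
    non_ranked = "K_sat"
  )
}

override_params <- function(defaults, parameters) {
  if (is.null(parameters)) return(defaults)
  if (is.null(names(parameters)) ||
      !all(names(parameters) %in% names(defaults))) {
    abort_validation(sprintf(
      "Unknown parameter(s): %s.",
      paste(setdiff(names(parameters), names(defaults)), collapse = ", ")
    ))
  }
  defaults[names(parameters)] <- parameters
  defaults
}

demo_registry <- list(
  linear_chain = function() make_linear_chain(),
  feedback_oscillator = function() make_negative_feedback_oscillator(),
  cascade = function() make_cascade()
)

#' Look up a bundled demonstration model by name
#'
#' @param name One of `"linear_chain"`, `"feedback_oscillator"`,
#'   `"cascade"`.
#' @param parameters Optional named overrides of nominal parameter values.
#' @return An [ode_model()].
#' @export
demo_model <- function(name, parameters = NULL) {
  if (!name %in% names(demo_registry)) {
    abort_config(sprintf(
      "Unknown model '%s'; registered demo models are: %s.",
      name, paste(names(demo_registry), collapse = ", ")
    ))
  }
  model <- demo_registry[[name]]()
  if (!is.null(parameters)) {
    pars <- override_params(model$nominal_params, parameters)
    model$nominal_params <- pars
  }
  model
}

#' Parameter inventories of the two case-study pathway models
#'
#' Returns the published parameter inventory of one of the two case-study
#' models — the p53/Mdm2 regulatory module (35 ranked kinetic parameters plus
#' 3 excluded structural constants: `h0`, `NSAT` and `dDAM`) or the IFN-beta
#' JAK/STAT pathway (48 ranked kinetic parameters plus the 2 excluded
#' saturation constants `ks1_phos_sat` and `ks2_phos_sat`). The inventories
#' name and describe each parameter and record whether it takes part in
#' sensitivity rankings; they do not carry nominal values or equations, which
#' belong to the original model publications.
#'
#' @param label `"p53"` or `"jakstat"`.
#' @return A tibble with columns `index`, `name`, `description`, `ranked`,
#'   carrying the label as attribute `model_label`.
#' @examples
#' inv <- load_parameter_inventory("p53")
#' sum(inv$ranked) # 35
#' @export
load_parameter_inventory <- function(label) {
  if (!label %in% c("p53", "jakstat")) {
    abort_validation("`label` must be 'p53' or 'jakstat'.")
  }
  path <- system.file("extdata", paste0(label, "_parameters.csv"),
                      package = "aucsens", mustWork = TRUE)
  inv <- tibble::as_tibble(utils::read.csv(path, stringsAsFactors = FALSE))
  inv$ranked <- as.logical(inv$ranked)
  if (anyDuplicated(inv$name) || !identical(inv$index, seq_len(nrow(inv)))) {
    abort_validation("Corrupt inventory fixture: indices must be contiguous and names unique.")
  }
  attr(inv, "model_label") <- label
  inv
}
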