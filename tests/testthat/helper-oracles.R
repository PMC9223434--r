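# Closed-form oracles and small model factories shared across tests.

# dx/dt = -d x, x(0) = x0: solution, its d-derivative, and the AUC of |ds/dd|
decay_solution <- function(t, d, x0) x0 * exp(-d * t)
decay_sens_d <- function(t, d, x0) -t * x0 * exp(-d * t)
decay_sens_auc <- function(d, x0, T) x0 / d^2 * (1 - exp(-d * T) * (1 + d * T))

# dx/dt = k - d x, x(0) = 0: solution and its time integral on [0, T]
proddeg_solution <- function(t, k, d) (k / d) * (1 - exp(-d * t))
proddeg_auc <- function(k, d, T) k * T / d - (k / d^2) * (1 - exp(-d * T))

make_decay <- function(d = 1, x0 = 1, extra_params = NULL) {
  ode_model(
    "decay",
    initial_state = c(x = x0),
    parameters = c(c(d = d), extra_params),
    rhs = function(t, state, params, input) -params[["d"]] * state[["x"]],
    output = "x"
  )
}

# linear chain with only the production parameter ranked (S = alpha - 1 exactly)
make_chain_k_only <- function(k = 1, d = 0.5) {
  m <- make_linear_chain(k = k, d = d)
  m$non_ranked_params <- "d"
  m
}

# random saturating production-degradation model; F >= 0 at x = 0, so the
# output stays non-negative for any non-negative parameter alteration
random_toy_model <- function() {
  pars <- c(k = runif(1, 0.2, 2), c = runif(1, 0, 2), d = runif(1, 0.1, 1.5))
  ode_model(
    "random_toy",
    initial_state = c(x = runif(1, 0, 1)),
    parameters = pars,
    rhs = function(t, state, params, input) {
      params[["k"]] / (1 + params[["c"]] * state[["x"]]) -
        params[["d"]] * state[["x"]]
    },
    output = "x"
  )
}

write_chain_config <- function(path, n = 200, seed = 7, horizon = 10,
                               grid = 200, extra = list()) {
  doc <- c(
    list(model = "linear_chain", horizon = horizon, grid = grid,
         n_samples = n, seed = seed),
    extra
  )
  yaml::write_yaml(doc, path)
  path
}
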