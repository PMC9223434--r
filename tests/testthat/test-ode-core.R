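test_that("simulation reproduces closed-form solutions of the toy models", {
  # exponential decay
  decay <- make_decay(d = 1, x0 = 2)
  traj <- simulate_model(decay, config = sim_config(horizon = 1, grid = 101))
  expect_equal(traj$x[101], 2 * exp(-1), tolerance = 1e-6)

  # zero derivative: constant trajectory
  flat <- ode_model("flat", c(x = 5), c(dummy = 1),
                    function(t, s, p, u) 0, output = "x")
  traj <- simulate_model(flat, config = sim_config(horizon = 3, grid = 31))
  expect_equal(traj$x, rep(5, 31))

  # production-degradation
  m <- make_linear_chain(k = 1, d = 0.5)
  traj <- simulate_model(m, config = sim_config(horizon = 10))
  expect_equal(traj$x[nrow(traj)], proddeg_solution(10, 1, 0.5),
               tolerance = 1e-6)
  expect_equal(traj$time[1], 0)
  expect_equal(traj$time[nrow(traj)], 10)
})

test_that("trapezoid AUC matches analytic integrals and converges on refinement", {
  flat <- ode_model("flat", c(x = 5), c(dummy = 1),
                    function(t, s, p, u) 0, output = "x")
  traj <- simulate_model(flat, config = sim_config(horizon = 4, grid = 50))
  expect_equal(auc(traj, "x"), 5 * 4, tolerance = 1e-12)

  zero <- ode_model("zero", c(x = 0), c(dummy = 1),
                    function(t, s, p, u) 0, output = "x")
  expect_equal(auc(simulate_model(zero, config = sim_config(4, 20)), "x"), 0)

  m <- make_linear_chain(k = 1, d = 0.5)
  analytic <- proddeg_auc(1, 0.5, 10)
  errs <- vapply(c(50, 200, 1000), function(g) {
    abs(auc(simulate_model(m, config = sim_config(10, grid = g)), "x") - analytic)
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
  expect_lt(errs[3] / analytic, 1e-4)

  expect_error(auc(simulate_model(m, config = sim_config(10)), "nope"),
               class = "aucsens_validation_error")
  expect_error(auc(simulate_model(m, config = sim_config(10)), "x", horizon = 11),
               class = "aucsens_validation_error")
})

test_that("simulation is deterministic and preserves non-negativity on demo models", {
  cfg <- sim_config(horizon = 100, grid = 500)
  for (name in c("linear_chain", "feedback_oscillator", "cascade")) {
    model <- demo_model(name)
    t1 <- simulate_model(model, config = cfg)
    t2 <- simulate_model(model, config = cfg)
    expect_equal(as.data.frame(t1), as.data.frame(t2), tolerance = 1e-12)
    states <- as.matrix(t1[, -1])
    expect_gt(min(states), -cfg$atol * 10)
  }
})

test_that("invalid models, parameters and configs are rejected with clear errors", {
  expect_error(ode_model("m", c(x = -1), c(k = 1), function(t, s, p, u) 0, "x"),
               class = "aucsens_validation_error")
  expect_error(ode_model("m", c(x = 1, x = 2), c(k = 1),
                         function(t, s, p, u) c(0, 0), "x"),
               class = "aucsens_validation_error")
  expect_error(ode_model("m", c(x = 1), c(k = NA_real_),
                         function(t, s, p, u) 0, "x"),
               class = "aucsens_validation_error")
  expect_error(ode_model("m", c(x = 1), c(k = 1), function(t, s, p, u) 0, "y"),
               class = "aucsens_validation_error")
  expect_error(ode_model("m", c(x = 1), c(k = 1), function(t, s, p, u) 0, "x",
                         non_ranked = "zz"),
               class = "aucsens_validation_error")

  m <- make_linear_chain()
  expect_error(simulate_model(m, params = c(zz = 1), config = sim_config(1)),
               class = "aucsens_validation_error")
  expect_error(sim_config(horizon = -1), class = "aucsens_validation_error")
  expect_error(sim_config(1, rtol = 0), class = "aucsens_validation_error")
  expect_error(sim_config(1, grid = c(0, 0.5, 0.4, 1)),
               class = "aucsens_validation_error")
})

test_that("a finite-time blow-up raises an integration error naming the parameters", {
  bomb <- ode_model("bomb", c(x = 1), c(g = 1),
                    function(t, s, p, u) p[["g"]] * s[["x"]]^2, output = "x")
  err <- expect_error(
    simulate_model(bomb, config = sim_config(horizon = 2, grid = 100)),
    class = "aucsens_integration_error"
  )
  expect_match(conditionMessage(err), "g=1")
})

test_that("piecewise-constant excitation feeds the right-hand side", {
  # dx/dt = u with u = 1 on [0, 1), 0 after: x ramps to 1 then holds
  m <- ode_model(
    "ramp", c(x = 0), c(dummy = 1),
    rhs = function(t, state, params, input) input,
    output = "x",
    excitation = step_excitation(c(0, 1), c(1, 0))
  )
  traj <- simulate_model(m, config = sim_config(horizon = 2, grid = 201))
  expect_equal(traj$x[201], 1, tolerance = 1e-3)
  expect_equal(traj$x[101], 1, tolerance = 1e-3)
  expect_equal(traj$x[51], 0.5, tolerance = 1e-3)
})

test_that("trajectory CSV export round-trips", {
  m <- make_linear_chain()
  traj <- simulate_model(m, config = sim_config(5, grid = 11))
  path <- withr::local_tempfile(fileext = ".csv")
  export_trajectory(traj, path)
  back <- utils::read.csv(path)
  expect_identical(names(back), c("time", "x"))
  expect_equal(back$x, traj$x, tolerance = 1e-12)
})
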