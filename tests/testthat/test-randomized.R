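cfg10 <- sim_config(horizon = 10, grid = 200)

test_that("delta_response is the pointwise altered-minus-nominal difference", {
  m <- make_linear_chain()
  nom <- simulate_model(m, config = cfg10)
  expect_equal(delta_response(nom, nom, "x"), rep(0, nrow(nom)))

  alt2 <- simulate_model(m, params = c(k = 2), config = cfg10)
  expect_equal(delta_response(alt2, nom, "x"), nom$x, tolerance = 1e-5)

  zero <- nom
  zero$x <- 0
  expect_equal(delta_response(zero, nom, "x"), -nom$x)

  other_grid <- simulate_model(m, config = sim_config(10, grid = 100))
  expect_error(delta_response(other_grid, nom, "x"),
               class = "aucsens_validation_error")
})

test_that("the S index hits its limits: 0 when unaltered, -1 at complete suppression", {
  m <- make_linear_chain()
  nom <- simulate_model(m, config = cfg10)
  expect_equal(sensitivity_index(rep(0, nrow(nom)), nom, "x"), 0)
  # production knocked out: output identically zero, S = -1 exactly
  expect_equal(sensitivity_index(-nom$x, nom, "x"), -1)
})

test_that("on the linear oracle S equals alpha - 1 per draw", {
  tight <- sim_config(horizon = 10, grid = 200, rtol = 1e-10, atol = 1e-12)
  m <- make_linear_chain()
  nom <- simulate_model(m, config = tight)
  for (a in c(0, 0.15, 0.5, 1, 2)) {
    alt <- simulate_model(m, params = c(k = a * 1), config = tight)
    s <- sensitivity_index(delta_response(alt, nom, "x"), nom, "x")
    expect_equal(s, a - 1, tolerance = 1e-7)
  }
})

test_that("a nominally silent output makes the index undefined, loudly", {
  silent <- ode_model("silent", c(x = 0, y = 1), c(d = 1),
                      function(t, s, p, u) c(0, -p[["d"]] * s[["y"]]),
                      output = "x")
  nom <- simulate_model(silent, config = cfg10)
  expect_error(sensitivity_index(rep(0, nrow(nom)), nom, "x"),
               class = "aucsens_undefined_index")
  expect_error(rank_parameters(silent, cfg10, n = 2, seed = 1),
               class = "aucsens_undefined_index")
})

test_that("display value shifts A by one and flags non-physical values", {
  expect_equal(display_value(0), 1)
  expect_equal(display_value(-1), 0)
  expect_equal(display_value(9), 10)
  expect_equal(display_value(-1 - 1e-10), -1e-10) # inside tolerance
  expect_error(display_value(-1.5), class = "aucsens_numerical_anomaly")
})

test_that("classification splits on the neutral band", {
  expect_identical(classify_parameter(0.5, 0.01), "amplifying")
  expect_identical(classify_parameter(-0.85, 0.01), "suppressing")
  expect_identical(classify_parameter(0.005, 0.01), "neutral")
  expect_identical(classify_parameter(c(-1, 0, 2)),
                   c("suppressing", "neutral", "amplifying"))
  expect_error(classify_parameter(0, neutral_band = -1),
               class = "aucsens_validation_error")
})

test_that("a degenerate alpha = 1 ranking is the identity null", {
  r <- rank_parameters(make_linear_chain(), cfg10,
                       dist = alteration_dist("degenerate", value = 1),
                       n = 3, seed = 1)
  expect_equal(nrow(r$ranking), 2L)
  expect_true(all(abs(r$ranking$A) < 10 * cfg10$rtol))
  expect_equal(r$ranking$display_value, rep(1, 2), tolerance = 1e-5)
  expect_true(all(r$ranking$classification == "neutral"))
})

test_that("the linear-oracle ranking recovers A = E[alpha] - 1 and its samples match the drawn law", {
  m <- make_chain_k_only()
  r <- rank_parameters(m, cfg10, n = 5000, seed = 21)
  s <- r$samples$S
  a <- r$samples$alpha
  expect_equal(nrow(r$samples), 5000L)
  # per-draw identity, so the empirical S distribution is the alpha - 1 law
  expect_lt(max(abs(s - (a - 1))), 1e-5)
  ks <- suppressWarnings(
    stats::ks.test(s + 1, stats::plnorm, meanlog = -2.08, sdlog = 0.61)
  )
  expect_lt(unname(ks$statistic), 0.02)

  # Monte-Carlo consistency between a small and a large sample
  r200 <- rank_parameters(m, cfg10, n = 200, seed = 22)
  A200 <- r200$ranking$A[r200$ranking$parameter == "k"]
  A5000 <- r$ranking$A[r$ranking$parameter == "k"]
  sem <- sqrt(sd(r200$samples$S)^2 / 200 + sd(s)^2 / 5000)
  expect_lt(abs(A200 - A5000), 3 * sem)
})

test_that("rankings are seed-reproducible, bit-identical alphas included", {
  m <- make_linear_chain()
  r1 <- rank_parameters(m, cfg10, n = 40, seed = 5)
  r2 <- rank_parameters(m, cfg10, n = 40, seed = 5)
  expect_identical(r1$samples$alpha, r2$samples$alpha)
  expect_equal(r1$ranking, r2$ranking)
  r3 <- rank_parameters(m, cfg10, n = 40, seed = 6)
  expect_false(identical(r1$samples$alpha, r3$samples$alpha))
})

test_that("ranking entries are sorted by |A| descending with name tie-breaks", {
  m <- make_linear_chain()
  r <- rank_parameters(m, cfg10, n = 60, seed = 2)
  expect_identical(order(abs(r$ranking$A), decreasing = TRUE),
                   seq_len(nrow(r$ranking)))
  rs <- rank_parameters(m, cfg10, n = 60, seed = 2, sort_by = "signed")
  expect_identical(order(rs$ranking$A, decreasing = TRUE),
                   seq_len(nrow(rs$ranking)))
  # exact ties fall back to lexicographic parameter order
  twin <- ode_model(
    "twin", c(x = 0), c(b = 1, a = 1),
    function(t, s, p, u) p[["a"]] * p[["b"]] - s[["x"]], output = "x"
  )
  rt <- rank_parameters(twin, cfg10,
                        dist = alteration_dist("degenerate", value = 0.5),
                        n = 2, seed = 1)
  expect_identical(rt$ranking$parameter, c("a", "b"))
})

test_that("zero-nominal parameters are reported unrankable, not dropped", {
  m <- ode_model("withzero", c(x = 0), c(k = 1, d = 0.5, dead = 0),
                 function(t, s, p, u) p[["k"]] - p[["d"]] * s[["x"]],
                 output = "x")
  r <- rank_parameters(m, cfg10, n = 20, seed = 3)
  expect_equal(nrow(r$ranking), 3L)
  row <- r$ranking[r$ranking$parameter == "dead", ]
  expect_true(row$unrankable)
  expect_true(is.na(row$A))
  expect_equal(row$n_effective, 0L)
  # unrankable rows sort last
  expect_identical(r$ranking$parameter[3], "dead")
})

test_that("S stays above -1 on non-negative outputs across random toy models", {
  withr::local_seed(99)
  for (i in 1:30) {
    m <- random_toy_model()
    cfg <- sim_config(horizon = 8, grid = 120)
    nom <- simulate_model(m, config = cfg)
    alphas <- rlnorm(2, -2.08, 0.61)
    for (p in ranked_params(m)) {
      for (a in alphas) {
        alt <- simulate_model(
          m, params = setNames(a * m$nominal_params[[p]], p), config = cfg)
        s <- sensitivity_index(delta_response(alt, nom, "x"), nom, "x")
        expect_gte(s, -1 - 1e-9)
      }
    }
  }
})

test_that("population ensembles reduce to the nominal trajectory when alpha = 1", {
  m <- make_linear_chain()
  ens <- population_ensemble(m, cfg10, "k",
                             dist = alteration_dist("degenerate", value = 1),
                             n = 5, seed = 1)
  expect_equal(ens$n_effective, 5L)
  expect_equal(ens$mean_trajectory$value, ens$nominal$value, tolerance = 1e-12)
  wide <- tidyr::pivot_wider(ens$runs[, c("run", "time", "value")],
                             names_from = "run", values_from = "value")
  for (col in as.character(1:5)) {
    expect_equal(wide[[col]], ens$nominal$value, tolerance = 1e-12)
  }
})

test_that("on the linear model the ensemble mean is E[alpha] times the nominal output", {
  m <- make_linear_chain()
  ens <- population_ensemble(m, cfg10, "k", n = 300, seed = 8)
  expected <- mean(ens$runs$alpha[!duplicated(ens$runs$run)]) * ens$nominal$value
  # linearity makes this exact up to solver error, whatever the draws were
  expect_equal(ens$mean_trajectory$value[-1], expected[-1], tolerance = 1e-4)

  ens2 <- population_ensemble(m, cfg10, "k", n = 300, seed = 8)
  expect_identical(ens$runs, ens2$runs)
})

test_that("a simultaneous two-parameter ensemble applies one draw to both", {
  m <- make_linear_chain()
  ens <- population_ensemble(m, cfg10, c("k", "d"),
                             dist = alteration_dist("degenerate", value = 0.5),
                             n = 2, seed = 1)
  # k and d scaled together by 0.5: same steady level k/d, slower approach,
  # so the trajectory is the closed form (k/d)(1 - exp(-0.5 d t))
  expect_equal(ens$mean_trajectory$value,
               proddeg_solution(ens$mean_trajectory$time, 0.5 * 1, 0.5 * 0.5),
               tolerance = 1e-5)
  expect_lt(ens$mean_trajectory$value[50], ens$nominal$value[50])
  expect_error(population_ensemble(m, cfg10, "zz", n = 2, seed = 1),
               class = "aucsens_validation_error")
})
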