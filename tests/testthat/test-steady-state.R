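test_that("steady-state utilization collapses to U without facilitation", {
  p <- tm_params(f = 0, U = 0.3, F = 1.7, D = 0.2)
  ss <- steady_state_response(p, c(2, 20, 200))
  expect_equal(ss$u_inf, rep(0.3, 3), tolerance = 1e-12)
})

test_that("low-frequency limit recovers the single-pulse response", {
  p <- tm_params(f = 0.1, U = 0.2, F = 2, D = 2)
  ss <- steady_state_response(p, 0.001)
  expect_equal(ss$u_inf, p$f + (1 - p$f) * p$U, tolerance = 1e-6)
  expect_equal(ss$R_inf, 1, tolerance = 1e-6)
  expect_equal(ss$I_inf, p$A * (p$f + (1 - p$f) * p$U), tolerance = 1e-6)
  expect_error(steady_state_response(p, -5), "frequency")
})

test_that("closed form equals the long-run discrete map", {
  p <- example_params()
  ss <- steady_state_response(p, 20)
  long <- simulate_discrete(p, stim_train(20, 500))$peaks
  expect_lt(abs(long[500] - ss$I_inf) / abs(ss$I_inf), 1e-8)

  # convergence is geometric: error at pulse 100 already tiny
  expect_lt(abs(long[100] - ss$I_inf) / abs(ss$I_inf), 1e-6)
})

test_that("steady-state cost is the brute-force sum of squared residuals", {
  p <- example_params()
  freqs <- protocol_freqs()
  truth_I <- steady_state_response(p, freqs)$I_inf
  obs <- steady_state_obs(freqs, truth_I)
  expect_equal(steady_state_cost(p, obs), 0)

  # single observation arithmetic
  one <- steady_state_obs(20, steady_state_response(p, 20)$I_inf + 1)
  expect_equal(steady_state_cost(p, one), 1, tolerance = 1e-12)

  # perturbed parameters vs independent summation
  q <- tm_params(p$f + 0.02, p$U - 0.03, p$F * 1.1, p$D * 0.9)
  pred <- steady_state_response(q, freqs)$I_inf
  expect_equal(steady_state_cost(q, obs), sum((truth_I - pred)^2),
               tolerance = 1e-12)

  # cost does not depend on the ordering of frequencies
  sh <- sample(length(freqs))
  obs_shuffled <- steady_state_obs(freqs[sh], truth_I[sh])
  expect_equal(steady_state_cost(q, obs_shuffled), steady_state_cost(q, obs))
})

test_that("analytic steady-state Jacobian matches finite differences", {
  freqs <- protocol_freqs()
  set.seed(11)
  for (p in sample_tm_params(10, seed = 11)) {
    sh <- stpdual:::ss_shape(p, freqs, jacobian = TRUE)
    for (k in seq_along(freqs)) {
      fd <- fd_gradient(function(v) {
        q <- tm_params(v[1], v[2], v[3], v[4], A = p$A, tau_syn = p$tau_syn)
        stpdual:::ss_shape(q, freqs[k])$s
      }, tm_theta(p))
      expect_equal(unname(sh$J[k, ]), fd, tolerance = 1e-6)
    }
  }
})

test_that("profiled amplitude equals its closed form", {
  p <- example_params()
  freqs <- protocol_freqs()
  s <- stpdual:::ss_shape(p, freqs)$s
  y <- 2.5 * s + 0.01 * sin(seq_along(s))
  obs <- steady_state_obs(freqs, y)
  cost <- steady_state_cost(p, obs, profile_A = TRUE)
  expect_equal(attr(cost, "A"), sum(s * y) / sum(s * s), tolerance = 1e-10)
})

test_that("fit from the truth stays at the truth", {
  p <- example_params()
  freqs <- protocol_freqs()
  obs <- steady_state_obs(freqs, steady_state_response(p, freqs)$I_inf)
  fit <- fit_steady_state(obs, init = p)
  expect_lt(fit$cost, 1e-12)
  expect_equal(tm_theta(fit$params), tm_theta(p), tolerance = 1e-6)
  # best-so-far trajectory is non-increasing
  expect_true(all(diff(fit$trajectory) <= 0))
})

test_that("random-start fits reproduce the steady-state curve", {
  p <- example_params()
  freqs <- protocol_freqs()
  obs <- steady_state_obs(freqs, steady_state_response(p, freqs)$I_inf)
  set.seed(3)
  fit <- fit_steady_state(obs, init = random_init(), max_steps = 200)
  expect_lt(fit$cost, 1e-8)
  reproduced <- fit$params$A *
    stpdual:::ss_shape(fit$params, freqs)$s
  expect_equal(reproduced, obs$amplitude, tolerance = 1e-3)
})

test_that("three frequencies leave the steady-state fit non-unique", {
  p <- example_params()
  freqs <- c(10, 20, 130)
  obs <- steady_state_obs(freqs, steady_state_response(p, freqs)$I_inf)
  hits <- list()
  for (s in 1:12) {
    set.seed(s)
    fit <- suppressWarnings(
      fit_steady_state(obs, init = random_init(), max_steps = 300))
    if (fit$cost < 1e-10) hits[[length(hits) + 1]] <- fit$params
  }
  expect_gte(length(hits), 2)
  dmax <- max(vapply(hits, function(a) max(vapply(hits, function(b)
    parameter_distance(a, b), numeric(1))), numeric(1)))
  expect_gt(dmax, 0.05)
})

test_that("frozen parameters are held fixed", {
  p <- example_params()
  freqs <- protocol_freqs()
  obs <- steady_state_obs(freqs, steady_state_response(p, freqs)$I_inf)
  init <- tm_params(0.3, 0.55, 0.2, 0.4)
  fit <- suppressWarnings(
    fit_steady_state(obs, init = init, frozen = "U", max_steps = 100))
  expect_equal(fit$params$U, 0.55)

  expect_warning(
    fit_steady_state(steady_state_obs(c(10, 20, 130),
                                      steady_state_response(p, c(10, 20, 130))$I_inf),
                     init = init),
    "under-determined")
})

test_that("out-of-bounds initial parameters are projected with a warning", {
  p <- example_params()
  freqs <- protocol_freqs()
  obs <- steady_state_obs(freqs, steady_state_response(p, freqs)$I_inf)
  init <- tm_params(0.1, 0.2, 4.9, 0.2)
  init$F <- 7  # outside the fitting bounds but a valid parameter
  expect_warning(fit_steady_state(obs, init = init), "projected")
})
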