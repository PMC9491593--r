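test_that("transient detection follows the relative-change definition", {
  # constant series: every pair settles, least valid index is 2
  expect_identical(detect_transient_length(c(1, 1, 1, 1)), 2L)

  # geometric approach to a plateau, checked against an exhaustive scan
  x <- 1 + 0.9^(1:50)
  expect_identical(detect_transient_length(x, 0.05),
                   brute_force_n_trans(x, 0.05))

  # random jittered series against the same oracle
  set.seed(42)
  for (rep in 1:20) {
    y <- cumprod(stats::runif(30, 0.8, 1.1))
    expect_identical(detect_transient_length(y, 0.05),
                     brute_force_n_trans(y, 0.05))
  }

  # a series that never settles returns its length
  z <- 2^(1:10)
  expect_identical(detect_transient_length(z, 0.05), 10L)

  expect_error(detect_transient_length(1), "at least 2")
})

test_that("transient detection is scale invariant and conservative at zeros", {
  x <- simulate_discrete(example_params(), stim_train(20, 60))$peaks
  n1 <- detect_transient_length(x)
  expect_identical(detect_transient_length(1000 * x), n1)
  expect_identical(detect_transient_length(0.001 * x), n1)

  # zero reference peaks fail the relative comparison
  expect_message(nz <- detect_transient_length(c(0, 0.5, 0.5, 0.5)), "zero")
  expect_identical(nz, 3L)
})

test_that("default transient length is the 15-pulse rule of thumb", {
  cfg <- transient_config()
  expect_identical(cfg$n_trans_default, 15L)
  expect_identical(cfg$n_trans_cap, 20L)
  expect_error(transient_config(change_threshold = 1.5), "change_threshold")
})

test_that("transient cost equals direct arithmetic and the double-sum oracle", {
  # hand-computed mean squared error on a 3-pulse example
  expect_equal(stpdual:::transient_mse(list(c(1, 0.8, 0.7)),
                                       list(c(0.9, 0.8, 0.6)), 3L),
               (0.01 + 0 + 0.01) / 3)

  truth <- example_params()
  freqs <- c(10, 50, 130)
  d <- generate_dataset(truth, freqs, 60, noise_sd_frac = 0.1, seed = 9)
  cfg <- transient_config(penalty_factor = 0)
  cost <- transient_cost(truth, d, cfg)

  # independent brute-force double sum
  total <- 0
  for (s in d$series) {
    nt <- min(brute_force_n_trans(s$peaks, 0.05), 20L)
    pred <- simulate_discrete(truth, stim_train(s$frequency, nt))$peaks
    acc <- 0
    for (n in seq_len(nt)) acc <- acc + (s$peaks[n] - pred[n])^2
    total <- total + acc / nt
  }
  expect_equal(as.numeric(cost), total, tolerance = 1e-12)

  # noiseless data at the generating truth has zero cost
  d0 <- generate_dataset(truth, freqs, 60, noise_sd_frac = 0, seed = 9)
  expect_equal(as.numeric(transient_cost(truth, d0, cfg)), 0)
})

test_that("anchor penalty vanishes at the anchor and dominates for large lambda", {
  truth <- example_params()
  d <- generate_dataset(truth, c(10, 50, 130), 60, 0.05, seed = 2)
  cfg0 <- transient_config(penalty_factor = 5, anchor = truth)
  cfgN <- transient_config(penalty_factor = 0)
  expect_equal(as.numeric(transient_cost(truth, d, cfg0)),
               as.numeric(transient_cost(truth, d, cfgN)))

  # huge lambda pins the fit at the anchor
  init <- tm_params(0.3, 0.4, 0.3, 0.3)
  cfgBig <- transient_config(penalty_factor = 1e6, anchor = init)
  fit <- fit_transient(d, init = init, cfg = cfgBig, max_steps = 200)
  expect_lt(max(abs(tm_theta(fit$params) - tm_theta(init))), 1e-3)
})

test_that("transient fitting from the truth keeps zero cost and records a monotone trajectory", {
  truth <- example_params()
  d <- generate_dataset(truth, protocol_freqs(), 60, 0, seed = 4)
  cfg <- transient_config(penalty_factor = 0)
  fit <- fit_transient(d, init = truth, cfg = cfg, max_steps = 50)
  expect_lt(fit$cost, 1e-20)
  expect_equal(tm_theta(fit$params), tm_theta(truth), tolerance = 1e-6)
  expect_true(all(diff(fit$trajectory) <= 0))

  # warm start from a steady-state fit must not end worse than it began
  obs <- steady_state_obs(d)
  set.seed(8)
  ss <- fit_steady_state(obs, init = random_init())
  init_cost <- as.numeric(transient_cost(ss$params, d, cfg, profile_A = TRUE))
  fit2 <- fit_transient(d, init = ss$params, cfg = cfg, max_steps = 300)
  expect_lte(fit2$cost, init_cost)
})

test_that("series shorter than the transient length are rejected", {
  truth <- example_params()
  d <- generate_dataset(truth, c(10, 50), 60, 0, seed = 1)
  cfg <- transient_config(penalty_factor = 0)
  expect_error(transient_cost(truth, d, cfg, n_trans = c(80L, 80L)),
               "shorter")
})
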