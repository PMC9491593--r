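test_that("parameter validation names the violated bound", {
  expect_error(tm_params(f = -0.1, U = 0.2, F = 0.5, D = 0.2), "f = -0.1")
  expect_error(tm_params(f = 0.1, U = 1.2, F = 0.5, D = 0.2), "U = 1.2")
  expect_error(tm_params(f = 0.1, U = 0.2, F = 0, D = 0.2), "F = 0")
  expect_error(tm_params(f = 0.1, U = 0.2, F = 0.5, D = 0.2, A = -1), "A = -1")
  expect_silent(validate_tm_params(tm_params(0, 0, 1, 1)))
})

test_that("stim_train builds constant-interval pulse times", {
  tr <- stim_train(20, 5)
  expect_equal(tr$pulse_times, (1:5) / 20)
  expect_error(stim_train(0, 5), "frequency")
  expect_length(stim_train(10, 0)$pulse_times, 0)
})

test_that("without facilitation the utilization stays at U", {
  p <- tm_params(f = 0, U = 0.4, F = 1, D = 0.2)
  st <- attr(simulate_discrete(p, stim_train(20, 10)), "states")
  expect_equal(st$u, rep(0.4, 10))
})

test_that("first pulse peak is the closed form A*(f + (1-f)U)", {
  # facilitation-dominated set with U = 0: first peak equals A*f
  p1 <- tm_params(f = 0.1, U = 0, F = 2, D = 0.05)
  expect_equal(simulate_discrete(p1, stim_train(50, 3))$peaks[1], 0.1)
  p2 <- example_params()
  expect_equal(simulate_discrete(p2, stim_train(20, 1))$peaks[1],
               p2$A * (p2$f + (1 - p2$f) * p2$U))
  # empty train gives an empty series
  expect_length(simulate_discrete(p2, stim_train(20, 0))$peaks, 0)
})

test_that("discrete map matches the event-driven continuous solution", {
  p <- example_params()
  for (freq in c(20, 50)) {
    disc <- simulate_discrete(p, stim_train(freq, 30))
    cont <- simulate_continuous(p, (1:30) / freq, dt = 1e-3)
    expect_lt(max(abs(attr(cont, "peaks") - disc$peaks) / abs(disc$peaks)),
              1e-9)
  }
})

test_that("continuous simulation is at equilibrium with no pulses and decays after one", {
  p <- example_params()
  tr0 <- simulate_continuous(p, numeric(0), dt = 1e-3)
  expect_true(all(tr0$current == 0))

  tr1 <- simulate_continuous(p, 0.1, dt = 1e-4, t_end = 0.2)
  pk <- attr(tr1, "peaks")
  after <- tr1$time_s >= 0.1   # pulse samples carry the post-jump value
  expect_equal(tr1$current[after],
               pk * exp(-(tr1$time_s[after] - 0.1) / p$tau_syn),
               tolerance = 1e-12)
  expect_true(all(tr1$current[tr1$time_s < 0.1] == 0))
})

test_that("continuous simulation validates input", {
  p <- example_params()
  expect_error(simulate_continuous(p, c(0.2, 0.1), dt = 1e-3), "increasing")
  expect_warning(simulate_continuous(p, (1:5) / 100, dt = 0.02),
                 "inter-pulse")
})

test_that("peaks scale linearly in A", {
  p <- example_params()
  pA <- tm_params(p$f, p$U, p$F, p$D, A = 3.7, tau_syn = p$tau_syn)
  s1 <- simulate_discrete(p, stim_train(30, 40))$peaks
  sA <- simulate_discrete(pA, stim_train(30, 40))$peaks
  expect_equal(sA, 3.7 * s1, tolerance = 1e-12)
})

test_that("state variables respect their bounds over random parameters", {
  set.seed(5)
  truths <- sample_tm_params(200, seed = 5,
                             ranges = list(f = c(0, 1), U = c(0, 1),
                                           F = c(0.01, 2), D = c(0.01, 2)))
  freqs <- c(1, 7, 33, 90, 200)
  for (p in truths) {
    for (freq in sample(freqs, 2)) {
      st <- attr(simulate_discrete(p, stim_train(freq, 50)), "states")
      lo <- min(p$U, p$f + (1 - p$f) * p$U)
      expect_true(all(st$u >= lo - 1e-12 & st$u <= 1 + 1e-12))
      expect_true(all(st$R >= -1e-12 & st$R <= 1 + 1e-12))
    }
  }
})

test_that("fast recovery limit: R stays near 1 and peaks follow the I-recursion", {
  p <- tm_params(f = 0, U = 0.35, F = 0.5, D = 1e-6)
  st <- attr(simulate_discrete(p, stim_train(10, 30)), "states")
  expect_true(all(abs(st$R - 1) < 1e-9))
  eS <- exp(-1 / (10 * p$tau_syn))
  pred <- Reduce(function(I, n) I * eS + p$A * p$U, seq_len(29),
                 accumulate = TRUE, init = p$A * p$U)
  expect_equal(st$I, pred, tolerance = 1e-12)
})

test_that("rendered traces superpose peak-normalized kernels", {
  # single isolated peak: maximum equals the amplitude at the analytic lag
  ps <- peak_series(1, 2)
  tr <- render_trace(ps, tau_rise = 0.001, tau_decay = 0.01, dt = 1e-5)
  tstar <- 0.001 * 0.01 / (0.01 - 0.001) * log(0.01 / 0.001)
  expect_equal(max(tr$current), 2, tolerance = 1e-4)
  expect_equal(tr$time_s[which.max(tr$current)], 1 + tstar, tolerance = 1e-4)

  # empty series renders silence
  expect_true(all(render_trace(peak_series(10, numeric(0)),
                               0.001, 0.01)$current == 0))

  # overlapping kernels: direct brute-force superposition oracle
  ps2 <- peak_series(200, c(1, 0.6))
  tr2 <- render_trace(ps2, tau_rise = 0.001, tau_decay = 0.01, dt = 1e-5)
  kmax <- (exp(-tstar / 0.01) - exp(-tstar / 0.001))
  oracle <- function(t) {
    v <- 0
    for (k in 1:2) {
      rel <- t - k / 200
      if (rel > 0) v <- v + ps2$peaks[k] *
          (exp(-rel / 0.01) - exp(-rel / 0.001)) / kmax
    }
    v
  }
  probe <- c(0.008, 0.0125, 0.02)
  expect_equal(tr2$current[match(probe, round(tr2$time_s, 10))],
               vapply(probe, oracle, numeric(1)), tolerance = 1e-9)

  expect_error(render_trace(ps, tau_rise = 0.01, tau_decay = 0.01), "tau_rise")
})
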