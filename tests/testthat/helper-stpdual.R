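# Shared helpers for the stpdual test suite.

# The eight-frequency stimulation protocol used throughout the synthetic
# experiments.
protocol_freqs <- function() c(5, 10, 20, 30, 50, 100, 130, 200)

# A representative mixed facilitation/depression parameter set.
example_params <- function() tm_params(f = 0.1, U = 0.2, F = 0.5, D = 0.2)

# Central finite-difference gradient of fn at x (independent oracle for the
# analytic Jacobian).
fd_gradient <- function(fn, x, h = 1e-6) {
  vapply(seq_along(x), function(i) {
    hi <- h * max(1, abs(x[i]))
    xp <- x; xp[i] <- x[i] + hi
    xm <- x; xm[i] <- x[i] - hi
    (fn(xp) - fn(xm)) / (2 * hi)
  }, numeric(1))
}

# Brute-force transient-length scan: smallest n >= 2 such that every
# consecutive pair at indices m >= n satisfies the relative-change
# criterion; series length if none does.
brute_force_n_trans <- function(x, threshold = 0.05) {
  n <- length(x)
  for (cand in 2:n) {
    all_ok <- TRUE
    for (m in cand:n) {
      if (m < 2) next
      if (!(abs(x[m] - x[m - 1]) < threshold * abs(x[m - 1]))) {
        all_ok <- FALSE
        break
      }
    }
    if (all_ok) return(cand)
  }
  n
}

# Relative error vector over the four shape parameters.
rel_errors <- function(est, truth) {
  abs(tm_theta(est) - tm_theta(truth)) / abs(tm_theta(truth))
}
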