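#' Sample random TM parameter sets
#'
#' Reproducible draws of ground-truth parameter sets: `f`, `U` uniform and
#' `F`, `D` log-uniform over their ranges (time constants are naturally
#' scale-distributed).
#'
#' @param n Number of parameter sets, `>= 1`.
#' @param ranges Named list of `(lower, upper)` ranges for `f`, `U`, `F`,
#'   `D`. Defaults: `f, U` in `[0.05, 0.95]`; `F, D` in `[0.05, 1]` s.
#' @param seed Integer seed.
#' @param A,tau_syn Scale parameters given to every draw (excitatory 3 ms
#'   default).
#' @return A list of `n` [tm_params()] objects.
#' @examples
#' sample_tm_params(3, seed = 1)
#' @export
sample_tm_params <- function(n, ranges = default_truth_ranges(), seed = 1L,
                             A = 1, tau_syn = 0.003) {
  if (n < 1) stop("n must be >= 1")
  for (nm in c("f", "U", "F", "D")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2 || r[1] > r[2]) {
      stop("invalid range for ", nm)
    }
  }
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    tm_params(f = stats::runif(1, ranges$f[1], ranges$f[2]),
              U = stats::runif(1, ranges$U[1], ranges$U[2]),
              F = exp(stats::runif(1, log(ranges$F[1]), log(ranges$F[2]))),
              D = exp(stats::runif(1, log(ranges$D[1]), log(ranges$D[2]))),
              A = A, tau_syn = tau_syn)
  })
}

#' Default ground-truth sampling ranges
#' @return Named list of ranges for `f`, `U`, `F`, `D`.
#' @export
default_truth_ranges <- function() {
  list(f = c(0.05, 0.95), U = c(0.05, 0.95), F = c(0.05, 1), D = c(0.05, 1))
}

#' Five canonical short-term-plasticity presets
#'
#' Named parameter sets spanning strong depression to strong facilitation.
#' Depressing presets have `F < D` (utilization recovers faster than
#' resources), facilitating presets `F > D`; the steady-state amplitude at
#' 50 Hz and the high/low-frequency response ratio
#' `I_inf(100 Hz) / I_inf(5 Hz)` are both monotone along the
#' depression-to-facilitation ordering.
#'
#' @return Named list of 5 [tm_params()] objects, ordered from
#'   `strong_depression` to `strong_facilitation`.
#' @export
plasticity_presets <- function() {
  list(
    strong_depression  = tm_params(f = 0.02, U = 0.70, F = 0.05, D = 0.90),
    depression         = tm_params(f = 0.05, U = 0.50, F = 0.10, D = 0.50),
    mixed              = tm_params(f = 0.15, U = 0.25, F = 0.25, D = 0.25),
    facilitation       = tm_params(f = 0.30, U = 0.12, F = 0.50, D = 0.12),
    strong_facilitation = tm_params(f = 0.50, U = 0.05, F = 1.00, D = 0.05)
  )
}

#' Generate a ground-truthed multi-frequency dataset
#'
#' Simulates the discrete TM model at each frequency and adds i.i.d.
#' Gaussian noise with standard deviation `noise_sd_frac` times the maximum
#' absolute clean peak over the whole dataset (the noise conditions used in
#' the synthetic validation are 5% and 20% of the maximum amplitude).
#'
#' @param truth A [tm_params()] ground truth.
#' @param frequencies Distinct stimulation frequencies in Hz.
#' @param n_pulses Pulses per train; scalar or one value per frequency.
#'   At least 20 so each series contains both transient and steady
#'   segments (relaxed only by `protocol = "experimental"` which uses 1-s
#'   trains, i.e. `frequency` pulses at each frequency).
#' @param noise_sd_frac Noise sd as a fraction of the maximum amplitude,
#'   `>= 0`.
#' @param seed Integer seed.
#' @param protocol Optional protocol preset. `"experimental"` reproduces
#'   the in-vitro protocol: 10, 20 and 130 Hz trains of 1 s each.
#' @return An [mf_dataset()] carrying `truth` and the noise metadata.
#' @examples
#' d <- generate_dataset(tm_params(0.1, 0.2, 0.5, 0.2),
#'                       c(5, 10, 20, 30, 50, 100, 130, 200), 100,
#'                       noise_sd_frac = 0.2, seed = 1)
#' d
#' @export
generate_dataset <- function(truth, frequencies, n_pulses = 100,
                             noise_sd_frac = 0, seed = 1L,
                             protocol = NULL) {
  validate_tm_params(truth)
  if (!is.null(protocol) && identical(protocol, "experimental")) {
    frequencies <- c(10, 20, 130)
    n_pulses <- c(10, 20, 130)   # 1-second trains
  } else if (!is.null(protocol)) {
    stop("unknown protocol preset: ", protocol)
  }
  if (noise_sd_frac < 0) stop("noise_sd_frac must be >= 0")
  frequencies <- as.numeric(frequencies)
  if (anyDuplicated(frequencies)) stop("frequencies must be distinct")
  n_pulses <- rep_len(as.integer(n_pulses), length(frequencies))
  if (is.null(protocol) && any(n_pulses < 20)) {
    stop("n_pulses must be >= 20 so trains contain transient and steady segments")
  }
  clean <- Map(function(freq, np) {
    simulate_discrete(truth, stim_train(freq, np))
  }, frequencies, n_pulses)
  max_amp <- max(vapply(clean, function(s) max(abs(s$peaks)), numeric(1)))
  set.seed(seed)
  series <- lapply(clean, function(s) {
    noisy <- s$peaks
    if (noise_sd_frac > 0) {
      noisy <- noisy + stats::rnorm(length(noisy),
                                    sd = noise_sd_frac * max_amp)
    }
    ps <- peak_series(s$frequency, noisy)
    attr(ps, "clean") <- s$peaks
    ps
  })
  mf_dataset(series, truth = truth, noise_sd_frac = noise_sd_frac,
             seed = seed,
             protocol = if (is.null(protocol)) NA_character_ else protocol)
}
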