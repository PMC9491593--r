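#' Tsodyks-Markram model parameters
#'
#' Constructs and validates the parameter vector of the extended
#' four-parameter Tsodyks-Markram (TM) model of short-term synaptic
#' plasticity, plus the two scale parameters that map the dimensionless
#' dynamics onto a postsynaptic current (PSC).
#'
#' The dynamic parameters are \code{f} (magnitude of facilitation), \code{U}
#' (baseline release probability), \code{F} (facilitation time constant,
#' seconds) and \code{D} (depression time constant, seconds). \code{A} is the
#' absolute synaptic efficacy (amplitude units) and \code{tau_syn} the
#' synaptic current decay time constant (seconds); typical values are
#' roughly 3 ms for glutamatergic and 10 ms for GABAergic synapses.
#'
#' @param f Facilitation magnitude, in `[0, 1]`.
#' @param U Baseline release probability, in `[0, 1]`.
#' @param F Facilitation time constant in seconds, `> 0`.
#' @param D Depression time constant in seconds, `> 0`.
#' @param A Absolute synaptic efficacy (PSC amplitude scale), `> 0`.
#' @param tau_syn Synaptic decay time constant in seconds, `> 0`.
#'
#' @return An object of class `"tm_params"`: a named list with the six
#'   fields above.
#' @examples
#' p <- tm_params(f = 0.1, U = 0.2, F = 0.5, D = 0.2)
#' p
#' @export
tm_params <- function(f, U, F, D, A = 1, tau_syn = 0.003) {
  p <- structure(
    list(f = as.numeric(f), U = as.numeric(U), F = as.numeric(F),
         D = as.numeric(D), A = as.numeric(A), tau_syn = as.numeric(tau_syn)),
    class = "tm_params"
  )
  validate_tm_params(p)
  p
}

#' Validate TM parameters
#'
#' Checks the physiological bounds of a [tm_params()] object and stops with
#' an error naming the first violated bound.
#'
#' @param p A `"tm_params"` object (or bare named list with the same fields).
#' @return `p`, invisibly, if valid.
#' @export
validate_tm_params <- function(p) {
  need <- c("f", "U", "F", "D", "A", "tau_syn")
  miss <- setdiff(need, names(p))
  if (length(miss)) {
    stop("tm_params is missing field(s): ", paste(miss, collapse = ", "))
  }
  vals <- unlist(p[need])
  if (any(!is.finite(vals))) {
    stop("tm_params fields must be finite numbers (got non-finite ",
         paste(need[!is.finite(vals)], collapse = ", "), ")")
  }
  chk <- function(ok, what) if (!ok) stop("invalid tm_params: ", what)
  chk(p$f >= 0 && p$f <= 1, sprintf("f = %g violates 0 <= f <= 1", p$f))
  chk(p$U >= 0 && p$U <= 1, sprintf("U = %g violates 0 <= U <= 1", p$U))
  chk(p$F > 0, sprintf("F = %g violates F > 0", p$F))
  chk(p$D > 0, sprintf("D = %g violates D > 0", p$D))
  chk(p$A > 0, sprintf("A = %g violates A > 0", p$A))
  chk(p$tau_syn > 0, sprintf("tau_syn = %g violates tau_syn > 0", p$tau_syn))
  invisible(p)
}

#' @export
print.tm_params <- function(x, ...) {
  cat("TM model parameters\n")
  cat(sprintf("  f = %.4g  U = %.4g  F = %.4g s  D = %.4g s\n",
              x$f, x$U, x$F, x$D))
  cat(sprintf("  A = %.4g  tau_syn = %.4g s\n", x$A, x$tau_syn))
  invisible(x)
}

#' Dynamic parameter vector of a TM parameter set
#'
#' Returns the four shape parameters as the named vector
#' `c(f, U, F, D)` — the vector the fitting costs, distances and
#' comparisons operate on (`A` and `tau_syn` are scale/kinetic constants,
#' not part of it).
#'
#' @param x A [tm_params()] object.
#' @return Named numeric vector of length 4.
#' @export
tm_theta <- function(x) {
  c(f = x$f, U = x$U, F = x$F, D = x$D)
}

# Internal: replace the dynamic parameters of `p` by a named numeric vector.
set_tm <- function(p, v) {
  for (nm in names(v)) p[[nm]] <- unname(v[[nm]])
  p
}

#' Constant-frequency stimulation train
#'
#' Defines a DBS-like pulse train: `n_pulses` pulses at a constant
#' `frequency`, with pulse times `t_n = n / frequency` seconds
#' (`n = 1, ..., n_pulses`).
#'
#' @param frequency Stimulation frequency in Hz, `> 0`.
#' @param n_pulses Number of pulses, `>= 0` (0 gives an empty train).
#' @return An object of class `"stim_train"` with fields `frequency`,
#'   `n_pulses` and `pulse_times`.
#' @examples
#' stim_train(20, 5)$pulse_times
#' @export
stim_train <- function(frequency, n_pulses) {
  if (!is.finite(frequency) || frequency <= 0) {
    stop("stimulation frequency must be > 0 Hz (got ", frequency, ")")
  }
  n_pulses <- as.integer(n_pulses)
  if (is.na(n_pulses) || n_pulses < 0) stop("n_pulses must be >= 0")
  structure(
    list(frequency = as.numeric(frequency), n_pulses = n_pulses,
         pulse_times = if (n_pulses > 0) seq_len(n_pulses) / frequency else numeric(0)),
    class = "stim_train"
  )
}

#' Per-pulse PSC peak series
#'
#' The ordered sequence of postsynaptic-current peak amplitudes `I[n]`
#' elicited by a constant-frequency stimulation train (1-based pulse index).
#'
#' @param frequency Stimulation frequency in Hz.
#' @param peaks Numeric vector of peak amplitudes, one per pulse.
#' @return An object of class `"peak_series"`.
#' @export
peak_series <- function(frequency, peaks) {
  peaks <- as.numeric(peaks)
  if (any(!is.finite(peaks))) stop("peak_series amplitudes must be finite")
  structure(list(frequency = as.numeric(frequency), peaks = peaks),
            class = "peak_series")
}

#' @export
print.peak_series <- function(x, ...) {
  cat(sprintf("PSC peak series: %d pulses at %g Hz\n",
              length(x$peaks), x$frequency))
  print(utils::head(x$peaks, 10))
  if (length(x$peaks) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
length.peak_series <- function(x) length(x$peaks)

#' Multi-frequency PSC dataset
#'
#' A collection of [peak_series()] objects over distinct stimulation
#' frequencies, optionally carrying the generating ground-truth parameters
#' and noise metadata (for synthetic data).
#'
#' @param series List of `"peak_series"` objects with distinct frequencies.
#' @param truth Optional `"tm_params"` ground truth.
#' @param noise_sd_frac Noise standard deviation as a fraction of the maximum
#'   absolute clean amplitude (0 for clean data).
#' @param seed Optional integer seed used to generate the data.
#' @param protocol Optional protocol label.
#' @return An object of class `"mf_dataset"`.
#' @export
mf_dataset <- function(series, truth = NULL, noise_sd_frac = 0,
                       seed = NA_integer_, protocol = NA_character_) {
  if (!length(series)) stop("mf_dataset needs at least one peak series")
  if (!all(vapply(series, inherits, logical(1), "peak_series"))) {
    stop("all elements of `series` must be peak_series objects")
  }
  freqs <- vapply(series, function(s) s$frequency, numeric(1))
  if (anyDuplicated(freqs)) stop("mf_dataset frequencies must be distinct")
  series <- series[order(freqs)]
  names(series) <- sprintf("%g", sort(freqs))
  structure(
    list(series = series, truth = truth, noise_sd_frac = noise_sd_frac,
         seed = seed, protocol = protocol),
    class = "mf_dataset"
  )
}

#' @export
print.mf_dataset <- function(x, ...) {
  freqs <- dataset_frequencies(x)
  np <- vapply(x$series, length, integer(1))
  cat(sprintf("Multi-frequency PSC dataset: %d frequencies (%s Hz), %s pulses\n",
              length(freqs), paste(freqs, collapse = ", "),
              paste(unique(np), collapse = "/")))
  if (!is.null(x$truth)) cat("  ground truth attached\n")
  if (is.finite(x$noise_sd_frac) && x$noise_sd_frac > 0) {
    cat(sprintf("  additive noise sd = %g x max amplitude\n", x$noise_sd_frac))
  }
  invisible(x)
}

#' Frequencies present in a dataset
#' @param data An `"mf_dataset"`.
#' @return Sorted numeric vector of stimulation frequencies (Hz).
#' @export
dataset_frequencies <- function(data) {
  unname(sort(vapply(data$series, function(s) s$frequency, numeric(1))))
}
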