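#' Extract per-pulse PSC peaks from a continuous trace
#'
#' For each stimulation time, measures the extremum of the chosen polarity
#' within `(t_pulse + blank, t_pulse + window]`, relative to the pre-pulse
#' baseline (the last trace sample at or before the pulse). The blanking
#' window excludes the stimulation artifact from the peak search. Returned
#' amplitudes are magnitudes of the selected polarity (positive numbers for
#' well-formed responses of that sign).
#'
#' When kernels overlap (high stimulation frequency relative to the decay
#' time constant) the extracted values are the local extrema of the
#' superposed trace, which differ from the underlying per-pulse amplitudes;
#' this measurement bias is inherent to peak extraction, not an artifact of
#' the implementation.
#'
#' @param trace A data.frame with columns `time_s` and `current` (e.g. from
#'   [render_trace()] or [simulate_continuous()]).
#' @param stim_times Stimulation times in seconds (sorted).
#' @param window Search window length after each pulse, seconds; must be
#'   shorter than the smallest inter-pulse interval.
#' @param sign `+1` to measure positive-going peaks, `-1` negative-going.
#' @param blank Artifact blanking window after each pulse, seconds
#'   (default 1 ms).
#' @return A [peak_series()] (frequency inferred from the median
#'   inter-pulse interval; `NA` for fewer than 2 pulses).
#' @export
extract_peaks <- function(trace, stim_times, window, sign = 1,
                          blank = 0.001) {
  if (!all(c("time_s", "current") %in% names(trace))) {
    stop("`trace` needs columns time_s and current")
  }
  if (!sign %in% c(-1, 1)) stop("`sign` must be +1 or -1")
  stim_times <- as.numeric(stim_times)
  n <- length(stim_times)
  freq <- if (n >= 2) 1 / stats::median(diff(stim_times)) else NA_real_
  if (n == 0) return(peak_series(freq, numeric(0)))
  if (n >= 2 && window >= min(diff(stim_times))) {
    stop("`window` must be shorter than the inter-pulse interval ",
         "(peak windows would overlap)")
  }
  if (min(stim_times) < min(trace$time_s) ||
      max(stim_times) > max(trace$time_s)) {
    stop("trace does not cover all stimulation times")
  }
  t <- trace$time_s; cur <- trace$current
  peaks <- vapply(stim_times, function(tp) {
    base_idx <- max(which(t <= tp))
    baseline <- cur[base_idx]
    in_win <- which(t > tp + blank & t <= tp + window)
    if (!length(in_win)) {
      stop(sprintf("no samples in the peak window after pulse at %g s", tp))
    }
    max(sign * cur[in_win]) - sign * baseline
  }, numeric(1))
  peak_series(freq, peaks)
}

#' Fit a double-exponential PSC kernel to a single response
#'
#' Least-squares fit of `amp * k(t - t0)` where `k` is the peak-normalized
#' double exponential `(exp(-t/tau_decay) - exp(-t/tau_rise)) / k_max`. The
#' response is assumed to start at the segment's first sample. Time
#' constants are searched on a log scale by Nelder-Mead with the amplitude
#' profiled linearly; `tau_rise < tau_decay` is enforced by sorting.
#'
#' @param segment A data.frame with columns `time_s` and `current`
#'   containing one isolated response.
#' @param init Optional numeric `c(tau_rise, tau_decay)` initial guess in
#'   seconds; a heuristic from the peak location is used otherwise.
#' @return A list with `tau_rise`, `tau_decay` (seconds), `amplitude` (the
#'   fitted peak value, signed) and `residual` (root-mean-square residual).
#' @export
fit_psc_kernel <- function(segment, init = NULL) {
  if (!all(c("time_s", "current") %in% names(segment))) {
    stop("`segment` needs columns time_s and current")
  }
  t <- segment$time_s - segment$time_s[1]
  y <- segment$current
  if (max(abs(y)) == 0) stop("segment is flat zero: no response to fit")
  sgn <- sign(y[which.max(abs(y))])
  if (is.null(init)) {
    tpk <- t[which.max(sgn * y)]
    init <- c(max(tpk / 3, 1e-5), max(4 * tpk, 2e-4))
  }
  kshape <- function(tau) {
    k <- (exp(-t / tau[2]) - exp(-t / tau[1])) / kernel_peak_value(tau[1], tau[2])
    k[t <= 0] <- 0
    k
  }
  obj <- function(ltau) {
    tau <- sort(exp(ltau))
    if (tau[1] <= 0 || !all(is.finite(tau)) || tau[2] / tau[1] < 1 + 1e-9) {
      return(1e10)
    }
    k <- kshape(tau)
    a <- sum(k * y) / sum(k * k)
    ss <- sum((y - a * k)^2)
    if (!is.finite(ss)) 1e10 else ss
  }
  res <- stats::optim(log(init), obj, method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-12))
  tau <- sort(exp(res$par))
  k <- kshape(tau)
  a <- sum(k * y) / sum(k * k)
  rms <- sqrt(mean((y - a * k)^2))
  if (res$value >= 1e10 || !is.finite(rms) ||
      rms > 0.9 * stats::sd(y)) {
    stop(sprintf(paste0("kernel fit did not converge ",
                        "(rms residual %.3g vs response sd %.3g)"),
                 rms, stats::sd(y)))
  }
  list(tau_rise = tau[1], tau_decay = tau[2], amplitude = a, residual = rms)
}

#' Steady-state amplitude from the tail of a peak series
#'
#' Mean of the last `k` peaks: the steady-state PSC under constant
#' frequency stimulation can be read off as the time average of the settled
#' response, which also averages out measurement noise.
#'
#' @param peaks A [peak_series()] or numeric vector.
#' @param k Number of trailing peaks to average, `>= 1` (default 10).
#' @return Scalar steady-state amplitude estimate.
#' @export
steady_state_from_peaks <- function(peaks, k = 10) {
  x <- if (inherits(peaks, "peak_series")) peaks$peaks else as.numeric(peaks)
  if (k < 1) stop("k must be >= 1")
  if (length(x) < k) stop("series shorter than k")
  if (length(x) >= 2) {
    # cap detection as in fitting: noisy tails would otherwise inflate it
    nt <- min(suppressMessages(detect_transient_length(x)), 20L)
    if (length(x) < nt + k) {
      warning(sprintf(paste0(
        "series length %d < detected transient length %d + k = %d; ",
        "the tail average may include transient pulses"),
        length(x), nt, nt + k))
    }
  }
  mean(x[(length(x) - k + 1):length(x)])
}
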