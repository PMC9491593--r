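#' Simulate the discrete-time TM model over a pulse train
#'
#' Iterates the discrete per-pulse map of the extended Tsodyks-Markram model
#' at a constant stimulation frequency \eqn{\nu}:
#' \deqn{u[n] = f + (1-f)\,(U + (u[n-1]-U)\,e^{-1/(\nu F)})}
#' \deqn{R[n] = 1 - (1 - R[n-1](1-u[n-1]))\,e^{-1/(\nu D)}}
#' \deqn{I[n] = I[n-1]\,e^{-1/(\nu \tau_{syn})} + A\,u[n]\,R[n]}
#' where `u[n]` is the post-pulse utilization \eqn{u(t_n^+)}, `R[n]` the
#' pre-pulse resource fraction \eqn{R(t_n^-)} and `I[n]` the post-pulse PSC
#' peak \eqn{I(t_n^+)}. Resource depletion at a pulse uses the
#' post-facilitation utilization (the standard TM convention). Initial
#' conditions are \eqn{u(t_1^-) = U}, \eqn{R(t_1^-) = 1}, \eqn{I(t_1^-) = 0},
#' so the first peak is \eqn{I[1] = A\,(f + (1-f)U)}.
#'
#' @param params A [tm_params()] object.
#' @param train A [stim_train()] object.
#' @return A [peak_series()] with one amplitude per pulse. The full state
#'   trajectories are attached as attribute `"states"` (a data.frame with
#'   columns `n`, `u`, `R`, `I`).
#' @examples
#' p <- tm_params(f = 0.1, U = 0.2, F = 0.5, D = 0.2)
#' simulate_discrete(p, stim_train(20, 10))
#' @export
simulate_discrete <- function(params, train) {
  validate_tm_params(params)
  if (!inherits(train, "stim_train")) stop("`train` must be a stim_train")
  n <- train$n_pulses
  if (n == 0L) {
    ps <- peak_series(train$frequency, numeric(0))
    attr(ps, "states") <- data.frame(n = integer(0), u = numeric(0),
                                     R = numeric(0), I = numeric(0))
    return(ps)
  }
  st <- tm_discrete_states(params, train$frequency, n)
  ps <- peak_series(train$frequency, st$I)
  attr(ps, "states") <- st
  ps
}

# Internal workhorse: per-pulse states at constant frequency.
# Returns data.frame(n, u, R, I) where u = u(t_n+), R = R(t_n-), I = I(t_n+).
tm_discrete_states <- function(params, frequency, n_pulses) {
  f <- params$f; U <- params$U; A <- params$A
  eF <- exp(-1 / (frequency * params$F))
  eD <- exp(-1 / (frequency * params$D))
  eS <- exp(-1 / (frequency * params$tau_syn))
  u <- numeric(n_pulses); R <- numeric(n_pulses); I <- numeric(n_pulses)
  u_pre <- U      # u(t_1-)
  R_pre <- 1      # R(t_1-)
  I_cur <- 0      # I(t_1-)
  for (k in seq_len(n_pulses)) {
    u_post <- f + (1 - f) * u_pre
    I_cur <- I_cur * eS + A * u_post * R_pre
    u[k] <- u_post; R[k] <- R_pre; I[k] <- I_cur
    u_pre <- U + (u_post - U) * eF
    R_pre <- 1 + (R_pre * (1 - u_post) - 1) * eD
  }
  data.frame(n = seq_len(n_pulses), u = u, R = R, I = I)
}

#' Simulate the continuous TM model by exact event-driven integration
#'
#' Integrates the three-state continuous TM system exactly between pulses
#' (pure exponential relaxation: `u` toward `U` with time constant `F`, `R`
#' toward 1 with `D`, `I` toward 0 with `tau_syn`) and applies the jump maps
#' at each pulse: \eqn{u^+ = f + (1-f)u^-}, \eqn{R^+ = R^-(1 - u^+)},
#' \eqn{I^+ = I^- + A u^+ R^-}. No numerical ODE solver is involved; the
#' sampling grid only affects the rendered trace, never the peak values,
#' which are computed event-driven and match [simulate_discrete()] exactly
#' for constant-interval trains.
#'
#' @param params A [tm_params()] object.
#' @param stim_times Sorted vector of pulse times in seconds (may be
#'   irregular).
#' @param dt Sampling interval of the returned trace, seconds.
#' @param t_end End of the trace; default extends `10 * tau_syn` past the
#'   last pulse.
#' @return A data.frame of class `"tm_trace"` with columns `time_s` and
#'   `current`, with attributes `stim_times` and `peaks` (the exact
#'   post-pulse peak values \eqn{I(t_n^+)}).
#' @examples
#' p <- tm_params(f = 0.1, U = 0.2, F = 0.5, D = 0.2)
#' tr <- simulate_continuous(p, stim_times = (1:5) / 20, dt = 1e-3)
#' head(attr(tr, "peaks"))
#' @export
simulate_continuous <- function(params, stim_times, dt,
                                t_end = NULL) {
  validate_tm_params(params)
  if (!is.finite(dt) || dt <= 0) stop("dt must be > 0")
  stim_times <- as.numeric(stim_times)
  if (is.unsorted(stim_times, strictly = TRUE) && length(stim_times) > 1) {
    stop("stim_times must be strictly increasing")
  }
  n <- length(stim_times)
  if (n > 1 && dt > min(diff(stim_times))) {
    warning("dt is larger than the smallest inter-pulse interval; ",
            "the sampled trace under-resolves pulses (peaks remain exact)")
  }
  if (is.null(t_end)) {
    t_end <- if (n > 0) stim_times[n] + 10 * params$tau_syn else 10 * params$tau_syn
  }

  # Event-driven pass: state just after each pulse.
  f <- params$f; U <- params$U; A <- params$A
  u_post <- numeric(n); I_post <- numeric(n); R_post <- numeric(n)
  u <- U; R <- 1; I <- 0; t_prev <- 0
  for (k in seq_len(n)) {
    gap <- stim_times[k] - t_prev
    u <- U + (u - U) * exp(-gap / params$F)
    R <- 1 + (R - 1) * exp(-gap / params$D)
    I <- I * exp(-gap / params$tau_syn)
    u_new <- f + (1 - f) * u
    I <- I + A * u_new * R
    R <- R * (1 - u_new)
    u <- u_new
    u_post[k] <- u; R_post[k] <- R; I_post[k] <- I
    t_prev <- stim_times[k]
  }

  times <- seq(0, t_end, by = dt)
  # Current at grid points: decay from the preceding pulse (0 before first).
  idx <- findInterval(times, stim_times)
  current <- numeric(length(times))
  hit <- idx > 0
  current[hit] <- I_post[idx[hit]] *
    exp(-(times[hit] - stim_times[idx[hit]]) / params$tau_syn)

  tr <- data.frame(time_s = times, current = current)
  class(tr) <- c("tm_trace", "data.frame")
  attr(tr, "stim_times") <- stim_times
  attr(tr, "peaks") <- I_post
  tr
}

#' Render a PSC trace from a peak series with a double-exponential kernel
#'
#' Superposes one peak-normalized double-exponential kernel per pulse,
#' \deqn{k(t) = (e^{-t/\tau_{decay}} - e^{-t/\tau_{rise}}) / k_{max},}
#' scaled by that pulse's peak amplitude; overlapping kernels add linearly.
#' The normalization makes each isolated kernel's maximum equal to the
#' pulse amplitude; the analytic peak lag is
#' \eqn{t^* = \frac{\tau_r \tau_d}{\tau_d - \tau_r}\ln(\tau_d/\tau_r)}.
#'
#' @param peaks A [peak_series()].
#' @param tau_rise,tau_decay Kernel time constants in seconds,
#'   `0 < tau_rise < tau_decay`.
#' @param dt Sampling interval, seconds.
#' @param t_end Optional trace end time; default `8 * tau_decay` past the
#'   last pulse.
#' @return A `"tm_trace"` data.frame (columns `time_s`, `current`) with
#'   attribute `stim_times`.
#' @export
render_trace <- function(peaks, tau_rise, tau_decay, dt = 1e-4,
                         t_end = NULL) {
  if (!inherits(peaks, "peak_series")) stop("`peaks` must be a peak_series")
  if (!is.finite(tau_rise) || !is.finite(tau_decay) ||
      tau_rise <= 0 || tau_decay <= 0 || tau_rise >= tau_decay) {
    stop("kernel requires 0 < tau_rise < tau_decay (got tau_rise = ",
         tau_rise, ", tau_decay = ", tau_decay, ")")
  }
  n <- length(peaks$peaks)
  stim_times <- if (n > 0) seq_len(n) / peaks$frequency else numeric(0)
  if (is.null(t_end)) {
    t_end <- if (n > 0) stim_times[n] + 8 * tau_decay else 8 * tau_decay
  }
  times <- seq(0, t_end, by = dt)
  current <- numeric(length(times))
  kmax <- kernel_peak_value(tau_rise, tau_decay)
  for (k in seq_len(n)) {
    rel <- times - stim_times[k]
    on <- rel > 0
    current[on] <- current[on] + peaks$peaks[k] *
      (exp(-rel[on] / tau_decay) - exp(-rel[on] / tau_rise)) / kmax
  }
  tr <- data.frame(time_s = times, current = current)
  class(tr) <- c("tm_trace", "data.frame")
  attr(tr, "stim_times") <- stim_times
  tr
}

# Peak lag and unnormalized maximum of the double-exponential kernel.
kernel_peak_time <- function(tau_rise, tau_decay) {
  tau_rise * tau_decay / (tau_decay - tau_rise) * log(tau_decay / tau_rise)
}

kernel_peak_value <- function(tau_rise, tau_decay) {
  tstar <- kernel_peak_time(tau_rise, tau_decay)
  exp(-tstar / tau_decay) - exp(-tstar / tau_rise)
}
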