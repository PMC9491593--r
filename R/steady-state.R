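#' Closed-form steady-state response of the discrete TM map
#'
#' At a constant stimulation frequency \eqn{\nu} the per-pulse map has a
#' unique attracting fixed point. Writing \eqn{e_F = e^{-1/(\nu F)}},
#' \eqn{e_D = e^{-1/(\nu D)}} and \eqn{e_S = e^{-1/(\nu \tau_{syn})}}:
#' \deqn{u_\infty = \frac{f + (1-f)\,U\,(1-e_F)}{1 - (1-f)\,e_F}}
#' \deqn{R_\infty = \frac{1-e_D}{1 - (1-u_\infty)\,e_D}}
#' \deqn{I_\infty = \frac{A\,u_\infty R_\infty}{1 - e_S}}
#'
#' @param params A [tm_params()] object.
#' @param frequency Stimulation frequency in Hz (vectorized), `> 0`.
#' @return A data.frame with columns `frequency`, `u_inf`, `R_inf`, `I_inf`.
#' @examples
#' p <- tm_params(f = 0.1, U = 0.2, F = 0.5, D = 0.2)
#' steady_state_response(p, c(5, 10, 20, 50, 100))
#' @export
steady_state_response <- function(params, frequency) {
  validate_tm_params(params)
  frequency <- as.numeric(frequency)
  if (any(!is.finite(frequency)) || any(frequency <= 0)) {
    stop("frequency must be > 0 Hz")
  }
  sh <- ss_shape(params, frequency)
  data.frame(frequency = frequency, u_inf = sh$u_inf, R_inf = sh$R_inf,
             I_inf = params$A * sh$s)
}

# Internal: steady-state "shape" s = u_inf * R_inf / (1 - e_S) (i.e. I_inf
# at A = 1) and its analytic Jacobian with respect to (f, U, F, D).
# Vectorized over frequency; returns list(u_inf, R_inf, s, J) where J is a
# length(frequency) x 4 matrix (columns f, U, F, D).
ss_shape <- function(params, frequency, jacobian = FALSE) {
  f <- params$f; U <- params$U; Fc <- params$F; Dc <- params$D
  nu <- frequency
  eF <- exp(-1 / (nu * Fc))
  eD <- exp(-1 / (nu * Dc))
  eS <- exp(-1 / (nu * params$tau_syn))

  Nu <- f + (1 - f) * U * (1 - eF)
  Du <- 1 - (1 - f) * eF
  u <- Nu / Du

  Nr <- 1 - eD
  Dr <- 1 - (1 - u) * eD
  R <- Nr / Dr

  s <- u * R / (1 - eS)
  out <- list(u_inf = u, R_inf = R, s = s)
  if (!jacobian) return(out)

  # du/dtheta
  du_df <- ((1 - U * (1 - eF)) * Du - Nu * eF) / Du^2
  du_dU <- (1 - f) * (1 - eF) / Du
  deF_dF <- eF / (nu * Fc^2)
  du_deF <- (-(1 - f) * U * Du + Nu * (1 - f)) / Du^2
  du_dF <- du_deF * deF_dF

  # R depends on u and on eD
  dR_du <- -Nr * eD / Dr^2
  deD_dD <- eD / (nu * Dc^2)
  dR_deD <- (-Dr + Nr * (1 - u)) / Dr^2
  dR_dD <- dR_deD * deD_dD

  ds_common <- 1 / (1 - eS)
  ds_df <- (du_df * R + u * dR_du * du_df) * ds_common
  ds_dU <- (du_dU * R + u * dR_du * du_dU) * ds_common
  ds_dF <- (du_dF * R + u * dR_du * du_dF) * ds_common
  ds_dD <- (u * dR_dD) * ds_common

  out$J <- cbind(f = ds_df, U = ds_dU, F = ds_dF, D = ds_dD)
  out
}

#' Steady-state observations
#'
#' Builds the frequency-to-steady-state-amplitude mapping used by the
#' steady-state cost, either directly from numeric vectors or from an
#' [mf_dataset()] (mean of the last `k` peaks of each series, see
#' [steady_state_from_peaks()]).
#'
#' @param x Either an `"mf_dataset"` or a numeric vector of frequencies (Hz).
#' @param amplitude Observed steady-state amplitudes (when `x` is numeric).
#' @param k Number of trailing peaks averaged per series (dataset input).
#' @return A data.frame of class `"ss_obs"` with columns `frequency` and
#'   `amplitude`.
#' @export
steady_state_obs <- function(x, amplitude = NULL, k = 10) {
  if (inherits(x, "mf_dataset")) {
    freq <- dataset_frequencies(x)
    amp <- vapply(x$series, function(s)
      steady_state_from_peaks(s, k = min(k, length(s$peaks))), numeric(1))
    obs <- data.frame(frequency = freq, amplitude = unname(amp[order(freq)]))
  } else {
    freq <- as.numeric(x)
    if (is.null(amplitude) || length(amplitude) != length(freq)) {
      stop("`amplitude` must match `x` in length")
    }
    obs <- data.frame(frequency = freq, amplitude = as.numeric(amplitude))
  }
  if (!nrow(obs)) stop("steady-state observations are empty")
  if (anyDuplicated(obs$frequency)) stop("frequencies must be distinct")
  class(obs) <- c("ss_obs", "data.frame")
  obs
}

#' Steady-state sum-of-squares cost
#'
#' Sum over the observed frequencies of squared residuals between observed
#' steady-state PSC amplitudes and the model's closed-form \eqn{I_\infty}.
#'
#' @param params A [tm_params()] object (its `A` is used as-is unless
#'   `profile_A = TRUE`).
#' @param obs A [steady_state_obs()] data.frame.
#' @param profile_A If `TRUE`, the linear scale `A` is replaced by its
#'   closed-form least-squares optimum before computing the cost; the value
#'   used is attached as attribute `"A"`.
#' @return Nonnegative scalar cost.
#' @export
steady_state_cost <- function(params, obs, profile_A = FALSE) {
  obs <- as_ss_obs(obs)
  sh <- ss_shape(params, obs$frequency)
  y <- obs$amplitude
  A <- if (profile_A) profile_amplitude(sh$s, y) else params$A
  cost <- sum((y - A * sh$s)^2)
  if (profile_A) attr(cost, "A") <- A
  cost
}

as_ss_obs <- function(obs) {
  if (inherits(obs, "ss_obs")) return(obs)
  if (is.data.frame(obs) && all(c("frequency", "amplitude") %in% names(obs))) {
    return(steady_state_obs(obs$frequency, obs$amplitude))
  }
  stop("`obs` must be a steady_state_obs() data.frame")
}

# Closed-form optimal linear scale: argmin_A sum w (y - A s)^2.
profile_amplitude <- function(s, y, w = 1) {
  denom <- sum(w * s * s)
  if (denom <= 0) return(1)
  A <- sum(w * s * y) / denom
  if (!is.finite(A) || A <= 0) A <- .Machine$double.eps
  A
}

#' Default parameter bounds used by all fitters
#'
#' `f, U` in `[1e-4, 1]`; `F, D` in `[1e-3, 5]` seconds. These cover
#' physiological short-term-plasticity ranges while keeping the per-pulse
#' exponentials well-conditioned.
#'
#' @return A named list of length-2 numeric vectors `(lower, upper)` for
#'   `f`, `U`, `F`, `D`.
#' @export
default_bounds <- function() {
  list(f = c(1e-4, 1), U = c(1e-4, 1), F = c(1e-3, 5), D = c(1e-3, 5))
}

# Project a tm_params onto the bounds; warn when anything moved.
project_to_bounds <- function(params, bounds, quiet = FALSE) {
  moved <- character(0)
  for (nm in names(bounds)) {
    lo <- bounds[[nm]][1]; hi <- bounds[[nm]][2]
    v <- params[[nm]]
    if (v < lo || v > hi) {
      params[[nm]] <- min(max(v, lo), hi)
      moved <- c(moved, nm)
    }
  }
  if (length(moved) && !quiet) {
    warning("initial parameters projected onto bounds: ",
            paste(moved, collapse = ", "))
  }
  params
}

#' Fit TM parameters to steady-state observations (trust-region stage)
#'
#' Minimizes the steady-state cost by a bounded trust-region quasi-Newton
#' method ([stats::nlminb()], PORT routines) using the analytic Jacobian of
#' the closed-form response. The linear amplitude `A` is profiled out in
#' closed form at every step, so only the shape parameters
#' `{f, U, F, D}` (minus any `frozen` ones) are searched.
#'
#' @param obs A [steady_state_obs()] data.frame.
#' @param init A [tm_params()] starting point (projected onto bounds with a
#'   warning if outside).
#' @param frozen Character vector of parameter names among
#'   `c("f","U","F","D","A")` held fixed at their `init` values. Freezing
#'   `"A"` disables profiling.
#' @param max_steps Iteration cap for the trust-region loop.
#' @param bounds Parameter bounds, as [default_bounds()].
#' @param allow_underdetermined If `FALSE` (default), a warning is issued
#'   when there are fewer observations than free parameters.
#' @return A list of class `"ss_fit"`: `params` (with profiled `A`),
#'   `cost` (final), `trajectory` (best-so-far cost per objective
#'   evaluation, non-increasing), `frozen`, `convergence`, `iterations`.
#' @examples
#' truth <- tm_params(f = 0.1, U = 0.2, F = 0.5, D = 0.2)
#' obs <- steady_state_obs(c(5, 10, 20, 30, 50, 100, 130, 200),
#'                         steady_state_response(truth,
#'                           c(5, 10, 20, 30, 50, 100, 130, 200))$I_inf)
#' fit <- fit_steady_state(obs, init = truth)
#' fit$cost
#' @export
fit_steady_state <- function(obs, init, frozen = character(),
                             max_steps = 100, bounds = default_bounds(),
                             allow_underdetermined = FALSE) {
  obs <- as_ss_obs(obs)
  validate_tm_params(init)
  if (length(frozen)) {
    frozen <- match.arg(frozen, c("f", "U", "F", "D", "A"),
                        several.ok = TRUE)
  }
  free <- setdiff(c("f", "U", "F", "D"), frozen)
  profile_A <- !("A" %in% frozen)
  n_free <- length(free) + as.integer(profile_A)
  if (nrow(obs) < n_free && !allow_underdetermined) {
    warning(sprintf(paste0(
      "only %d steady-state observations for %d free parameters; ",
      "the fit is under-determined (consider the frozen-U mode)"),
      nrow(obs), n_free))
  }
  init <- project_to_bounds(init, bounds[free])

  y <- obs$amplitude
  freqs <- obs$frequency
  traj <- numeric(0)
  best <- Inf
  cur_A <- init$A

  make_params <- function(v) set_tm(init, stats::setNames(v, free))

  objective <- function(v) {
    p <- make_params(v)
    sh <- ss_shape(p, freqs)
    A <- if (profile_A) profile_amplitude(sh$s, y) else init$A
    cost <- sum((y - A * sh$s)^2)
    if (!is.finite(cost)) stop("steady-state cost is non-finite at f=",
                               p$f, " U=", p$U, " F=", p$F, " D=", p$D)
    best <<- min(best, cost)
    traj <<- c(traj, best)
    cur_A <<- A
    cost
  }
  gradient <- function(v) {
    p <- make_params(v)
    sh <- ss_shape(p, freqs, jacobian = TRUE)
    A <- if (profile_A) profile_amplitude(sh$s, y) else init$A
    r <- y - A * sh$s
    # With A at its profiled optimum the dA/dtheta term vanishes
    # (envelope theorem); with A frozen it is absent anyway.
    g <- -2 * A * drop(crossprod(sh$J[, free, drop = FALSE], r))
    stats::setNames(g, free)
  }

  lower <- vapply(bounds[free], `[`, numeric(1), 1)
  upper <- vapply(bounds[free], `[`, numeric(1), 2)
  start <- vapply(free, function(nm) init[[nm]], numeric(1))

  res <- stats::nlminb(start, objective, gradient = gradient,
                       lower = lower, upper = upper,
                       control = list(iter.max = max_steps,
                                      eval.max = 10 * max_steps))

  params <- make_params(res$par)
  sh <- ss_shape(params, freqs)
  params$A <- if (profile_A) profile_amplitude(sh$s, y) else init$A
  final_cost <- sum((y - params$A * sh$s)^2)

  structure(
    list(params = params, cost = final_cost, trajectory = traj,
         frozen = frozen, convergence = res$convergence,
         iterations = res$iterations, message = res$message),
    class = "ss_fit"
  )
}

#' @export
print.ss_fit <- function(x, ...) {
  cat(sprintf("Steady-state fit: cost = %.4g after %d iterations\n",
              x$cost, x$iterations))
  if (length(x$frozen)) cat("  frozen:", paste(x$frozen, collapse = ", "), "\n")
  print(x$params)
  invisible(x)
}
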