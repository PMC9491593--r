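#' Transient-stage configuration
#'
#' Collects the hyper-parameters of the transient fitting stage: the
#' relative-change threshold that ends the transient segment, the default
#' and cap on the transient length used inside the cost, and the anchor
#' penalty that keeps the derivative-free search near the steady-state
#' estimate.
#'
#' @param change_threshold Relative per-pulse change below which the series
#'   is considered settled (default 0.05, i.e. 5%).
#' @param n_trans_default Transient length used when detection is
#'   unavailable (rule of thumb: 15 pulses).
#' @param n_trans_cap Maximum transient length used inside fitting
#'   (default 20 pulses).
#' @param penalty_factor Nonnegative anchor-penalty weight \eqn{\lambda}.
#' @param anchor Optional [tm_params()] anchor; `NULL` disables the penalty.
#' @return A list of class `"transient_config"`.
#' @export
transient_config <- function(change_threshold = 0.05, n_trans_default = 15,
                             n_trans_cap = 20, penalty_factor = 0.1,
                             anchor = NULL) {
  if (!(change_threshold > 0 && change_threshold < 1)) {
    stop("change_threshold must be in (0, 1)")
  }
  if (n_trans_default < 1 || n_trans_default > n_trans_cap) {
    stop("need 1 <= n_trans_default <= n_trans_cap")
  }
  if (penalty_factor < 0) stop("penalty_factor must be >= 0")
  if (!is.null(anchor)) validate_tm_params(anchor)
  structure(
    list(change_threshold = change_threshold,
         n_trans_default = as.integer(n_trans_default),
         n_trans_cap = as.integer(n_trans_cap),
         penalty_factor = penalty_factor, anchor = anchor),
    class = "transient_config"
  )
}

#' Detect the transient length of a peak series
#'
#' Returns the least pulse index `n` such that for every later pulse
#' `m >= n` the relative change is small:
#' \eqn{|I[m] - I[m-1]| < \mathrm{threshold} \cdot |I[m-1]|}. Consecutive
#' pairs start at index 2, so the smallest possible answer is 2; if even
#' the last pair fails the criterion the series length is returned. The
#' absolute-value form makes the criterion meaningful for depressing
#' (decreasing) series as well.
#'
#' @param peaks A [peak_series()] or bare numeric vector (length >= 2).
#' @param threshold Relative-change threshold (default 0.05).
#' @return Integer transient length `N_trans`.
#' @examples
#' detect_transient_length(c(1, 1, 1, 1))        # 2
#' detect_transient_length(1 + 0.9^(1:50))       # settles once 0.9^n is small
#' @export
detect_transient_length <- function(peaks, threshold = 0.05) {
  x <- if (inherits(peaks, "peak_series")) peaks$peaks else as.numeric(peaks)
  n <- length(x)
  if (n < 2) stop("transient detection needs at least 2 peaks")
  if (any(x == 0)) {
    # a zero reference peak makes the relative criterion fail at that pair
    message("peak series contains zero values; relative-change comparisons ",
            "against them are treated as failing the criterion")
  }
  ok <- abs(diff(x)) < threshold * abs(x[-n])   # ok[m-1] is pair (m-1, m)
  bad <- which(!ok)
  if (!length(bad)) return(2L)
  n_trans <- max(bad) + 2L                      # first index after last failure
  if (n_trans > n) n else as.integer(n_trans)
}

# Internal: per-frequency transient lengths used inside fitting:
# min(detected on the data, cap); falls back to the default when a series
# is too short to detect.
dataset_transient_lengths <- function(data, cfg) {
  vapply(data$series, function(s) {
    nt <- if (length(s$peaks) >= 2) {
      suppressMessages(detect_transient_length(s, cfg$change_threshold))
    } else cfg$n_trans_default
    as.integer(min(nt, cfg$n_trans_cap, length(s$peaks)))
  }, integer(1))
}

# Internal arithmetic kernel: sum over series of mean squared error over the
# first n_trans[i] entries.
transient_mse <- function(obs_list, pred_list, n_trans) {
  total <- 0
  for (i in seq_along(obs_list)) {
    k <- n_trans[i]
    total <- total + mean((obs_list[[i]][seq_len(k)] -
                           pred_list[[i]][seq_len(k)])^2)
  }
  total
}

# Normalized parameter-space penalty: each coordinate scaled by its bound
# range so that f/U and F/D contribute comparably.
anchor_penalty <- function(params, anchor, bounds = default_bounds()) {
  rng <- vapply(bounds, function(b) b[2] - b[1], numeric(1))
  d <- (tm_theta(params) - tm_theta(anchor)) /
    rng[c("f", "U", "F", "D")]
  sum(d^2)
}

#' Transient mean-squared-error cost with anchor penalty
#'
#' Per-frequency mean squared error over the first `N_trans` peaks between
#' the observed series and the discrete TM prediction, summed over
#' frequencies, plus \eqn{\lambda\,\|\theta - \theta_{anchor}\|^2} in a
#' bound-normalized parameter space. `N_trans` is detected per frequency on
#' the data and capped at `cfg$n_trans_cap`.
#'
#' @param params A [tm_params()] candidate.
#' @param data An [mf_dataset()].
#' @param cfg A [transient_config()].
#' @param n_trans Optional precomputed integer vector of transient lengths
#'   (one per series, in `data$series` order); detection is skipped when
#'   supplied.
#' @param profile_A If `TRUE` the linear amplitude is set to its closed-form
#'   optimum for the truncated series (value attached as attribute `"A"`).
#' @return Nonnegative scalar cost.
#' @export
transient_cost <- function(params, data, cfg = transient_config(),
                           n_trans = NULL, profile_A = FALSE) {
  validate_tm_params(params)
  if (!inherits(data, "mf_dataset")) stop("`data` must be an mf_dataset")
  if (is.null(n_trans)) n_trans <- dataset_transient_lengths(data, cfg)
  short <- vapply(data$series, length, integer(1)) < n_trans
  if (any(short)) {
    stop("series at ", paste(names(data$series)[short], collapse = ", "),
         " Hz are shorter than their transient length")
  }
  obs <- vector("list", length(data$series))
  pred <- vector("list", length(data$series))
  for (i in seq_along(data$series)) {
    s <- data$series[[i]]
    k <- n_trans[i]
    obs[[i]] <- s$peaks[seq_len(k)]
    pred[[i]] <- tm_discrete_states(params, s$frequency, k)$I
  }
  A <- params$A
  if (profile_A) {
    # prediction is linear in A; refit the scale on the truncated series
    shape <- unlist(pred) / params$A
    w <- rep(1 / n_trans, times = n_trans)
    A <- profile_amplitude(shape, unlist(obs), w = w)
    pred <- lapply(pred, function(x) x * A / params$A)
  }
  cost <- transient_mse(obs, pred, n_trans)
  if (!is.null(cfg$anchor) && cfg$penalty_factor > 0) {
    cost <- cost + cfg$penalty_factor * anchor_penalty(params, cfg$anchor)
  }
  if (profile_A) attr(cost, "A") <- A
  cost
}

# Shared Nelder-Mead driver for the derivative-free stages. Searches
# (f, U, log F, log D) -- time constants live on decades, so the simplex is
# far better conditioned in log space -- with out-of-bounds proposals
# rejected through a large finite penalty. `cost_fn(params)` returns the
# cost, optionally with the profiled amplitude as attribute "A".
nm_minimize <- function(init, cost_fn, max_steps, bounds) {
  lower <- vapply(bounds, `[`, numeric(1), 1)
  upper <- vapply(bounds, `[`, numeric(1), 2)
  nm_names <- c("f", "U", "F", "D")
  traj <- numeric(0)
  best_cost <- Inf
  best_par <- tm_theta(init)
  best_A <- init$A
  evals <- 0L

  to_raw <- function(v) c(f = v[[1]], U = v[[2]], F = exp(v[[3]]), D = exp(v[[4]]))
  objective <- function(v) {
    evals <<- evals + 1L
    raw <- to_raw(v)
    if (any(raw < lower[nm_names]) || any(raw > upper[nm_names]) ||
        any(!is.finite(raw))) {
      excess <- sum(pmax(lower[nm_names] - raw, 0) +
                      pmax(raw - upper[nm_names], 0), na.rm = TRUE)
      cost <- 1e10 * (1 + min(excess, 1e6))
    } else {
      p <- set_tm(init, raw)
      cost <- cost_fn(p)
      if (!is.finite(cost)) cost <- 1e10
      if (cost < best_cost) {
        best_cost <<- cost
        best_par <<- raw
        a <- attr(cost, "A")
        if (!is.null(a)) best_A <<- a
      }
    }
    traj <<- c(traj, min(best_cost, cost))
    as.numeric(cost)
  }

  start <- c(init$f, init$U, log(init$F), log(init$D))
  objective(start)  # seed best-so-far with the initial point
  res <- stats::optim(start, objective, method = "Nelder-Mead",
                      control = list(maxit = max_steps, reltol = 1e-10))
  restarted <- FALSE
  if (res$convergence == 10 && max_steps > 10) {
    # degenerate simplex: one re-initialization around the best point
    restarted <- TRUE
    jitter <- best_par * (1 + 0.05 * stats::runif(4, -1, 1))
    jitter <- pmin(pmax(jitter, lower[nm_names]), upper[nm_names])
    stats::optim(c(jitter[1], jitter[2], log(jitter[3]), log(jitter[4])),
                 objective, method = "Nelder-Mead",
                 control = list(maxit = max_steps, reltol = 1e-10))
  }
  params <- set_tm(init, best_par)
  params$A <- if (is.finite(best_A)) best_A else init$A
  list(params = params, cost = best_cost, trajectory = cummin(traj),
       evaluations = evals, restarted = restarted)
}

#' Fit TM parameters to the transient response (Nelder-Mead stage)
#'
#' Minimizes [transient_cost()] over the shape parameters `{f, U, F, D}` by
#' the Nelder-Mead simplex method (classical coefficients, via
#' [stats::optim()]; `F` and `D` are searched on a log scale), with the
#' amplitude `A` profiled in closed form at every evaluation unless
#' `profile_A = FALSE`. Out-of-bounds proposals are rejected through a
#' large finite penalty. If the simplex collapses before the budget is
#' spent, one restart is performed around the best point with 5%
#' multiplicative jitter.
#'
#' @param data An [mf_dataset()].
#' @param init A [tm_params()] starting point (projected onto bounds).
#' @param cfg A [transient_config()]; its `anchor`/`penalty_factor` control
#'   the distance penalty.
#' @param max_steps Nelder-Mead iteration cap.
#' @param bounds Parameter bounds, as [default_bounds()].
#' @param profile_A If `TRUE` (default) the amplitude scale is profiled in
#'   closed form at every evaluation; set `FALSE` when `A` is known.
#' @return A list of class `"transient_fit"`: `params`, `cost` (best
#'   penalized cost), `trajectory` (best-so-far cost per function
#'   evaluation, non-increasing), `evaluations`, `restarted`.
#' @export
fit_transient <- function(data, init, cfg = transient_config(),
                          max_steps = 100, bounds = default_bounds(),
                          profile_A = TRUE) {
  validate_tm_params(init)
  if (!inherits(data, "mf_dataset")) stop("`data` must be an mf_dataset")
  init <- project_to_bounds(init, bounds)
  n_trans <- dataset_transient_lengths(data, cfg)

  res <- nm_minimize(init, function(p) {
    transient_cost(p, data, cfg, n_trans = n_trans, profile_A = profile_A)
  }, max_steps = max_steps, bounds = bounds)

  structure(
    list(params = res$params, cost = res$cost, trajectory = res$trajectory,
         evaluations = res$evaluations, restarted = res$restarted,
         n_trans = n_trans),
    class = "transient_fit"
  )
}

#' @export
print.transient_fit <- function(x, ...) {
  cat(sprintf("Transient fit: cost = %.4g after %d evaluations%s\n",
              x$cost, x$evaluations,
              if (x$restarted) " (1 restart)" else ""))
  print(x$params)
  invisible(x)
}
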