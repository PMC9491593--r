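#' Dual-optimization configuration
#'
#' Hyper-parameters of the alternating steady-state/transient optimizer.
#' Defaults follow the qualitative rule that each stage is iteration-capped
#' so neither overfits before the other corrects it: 8 outer rounds with 50
#' trust-region steps and 300 Nelder-Mead iterations per round (the
#' frozen-U mode halves the per-stage caps and doubles the rounds). The
#' anchor penalty defaults to 0 here: with several frequencies of data the
#' alternation itself keeps the transient stage near the steady-state
#' manifold, and a nonzero weight leaves a bias floor on rich data; raise
#' it for scarce or very noisy recordings.
#'
#' @param n_outer Number of alternation rounds, `>= 1`.
#' @param max_steps_steady Trust-region iteration cap per round.
#' @param max_steps_transient Nelder-Mead iteration cap per round.
#' @param penalty_factor Anchor-penalty weight \eqn{\lambda} for the
#'   transient stage.
#' @param transient_profile_A If `TRUE` (default) the amplitude scale is
#'   profiled in the transient stage as well; set `FALSE` (with
#'   `frozen = "A"`) when the absolute synaptic efficacy is known.
#' @param frozen Parameter names frozen during the steady-state stage
#'   (empty by default; `"U"` for the 3-frequency mode).
#' @param bounds Parameter bounds, as [default_bounds()].
#' @param seed Integer seed controlling random initialization and restarts.
#' @param tol Relative combined-cost change below which the outer loop
#'   stops early.
#' @param k_steady Number of trailing peaks averaged to extract the
#'   steady-state observation of each series.
#' @param change_threshold,n_trans_cap Passed to [transient_config()].
#' @return A list of class `"dual_config"`.
#' @export
dual_config <- function(n_outer = 8, max_steps_steady = 50,
                        max_steps_transient = 300, penalty_factor = 0,
                        frozen = character(), bounds = default_bounds(),
                        seed = 1L, tol = 1e-6, k_steady = 10,
                        change_threshold = 0.05, n_trans_cap = 20,
                        transient_profile_A = TRUE) {
  if (n_outer < 1) stop("n_outer must be >= 1")
  if (tol <= 0) stop("tol must be > 0")
  structure(
    list(n_outer = as.integer(n_outer),
         max_steps_steady = as.integer(max_steps_steady),
         max_steps_transient = as.integer(max_steps_transient),
         penalty_factor = penalty_factor, frozen = frozen, bounds = bounds,
         seed = as.integer(seed), tol = tol, k_steady = k_steady,
         change_threshold = change_threshold,
         n_trans_cap = as.integer(n_trans_cap),
         transient_profile_A = transient_profile_A),
    class = "dual_config"
  )
}

#' Draw a random initial parameter set
#'
#' `f`, `U` uniform on `[0.05, 0.95]`; `F`, `D` log-uniform on
#' `[0.01, 2]` seconds (time constants span decades). Uses the current RNG
#' state; seed externally (or through [dual_optimize()]'s config) for
#' reproducibility.
#'
#' @param template A [tm_params()] supplying `A` and `tau_syn` (default
#'   `A = 1`, `tau_syn = 3` ms).
#' @return A [tm_params()] object.
#' @export
random_init <- function(template = tm_params(0.1, 0.2, 0.5, 0.2)) {
  tm_params(f = stats::runif(1, 0.05, 0.95),
            U = stats::runif(1, 0.05, 0.95),
            F = exp(stats::runif(1, log(0.01), log(2))),
            D = exp(stats::runif(1, log(0.01), log(2))),
            A = template$A, tau_syn = template$tau_syn)
}

# Combined stopping metric: steady-state SSE + unpenalized transient MSE.
combined_cost <- function(params, data, obs, tcfg, n_trans) {
  ss <- steady_state_cost(params, obs)
  tcfg$anchor <- NULL
  tr <- transient_cost(params, data, tcfg, n_trans = n_trans)
  ss + tr
}

new_tm_fit <- function(method, params, cost, history, config, extra = list()) {
  structure(
    c(list(method = method, params = params, cost = cost,
           history = history, config = config), extra),
    class = "tm_fit"
  )
}

#' @export
print.tm_fit <- function(x, ...) {
  cat(sprintf("TM fit (%s): final cost = %.6g\n", x$method, x$cost))
  print(x$params)
  cat(sprintf("  history: %d stage records\n", nrow(x$history)))
  invisible(x)
}

history_row <- function(stage, round, iteration, cost, params) {
  data.frame(stage = stage, round = round, iteration = iteration,
             cost = cost, f = params$f, U = params$U, F = params$F,
             D = params$D, A = params$A)
}

#' Dual optimization of TM parameters
#'
#' The headline estimator: alternates (1) a bounded trust-region fit of the
#' closed-form steady-state response to the per-frequency steady-state
#' observations (mean of the last `k_steady` peaks) and (2) a Nelder-Mead
#' fit of the transient response (first `N_trans` peaks per frequency),
#' anchored to the stage-1 output by a distance penalty. Each stage is
#' warm-started by the other; the loop stops early when the relative change
#' of the combined (steady + unpenalized transient) cost drops below
#' `cfg$tol`, and the best-cost parameters over the whole history are
#' returned.
#'
#' @param data An [mf_dataset()] with at least 4 distinct frequencies when
#'   no parameter is frozen (otherwise use [dual_optimize_frozen_u()]).
#' @param cfg A [dual_config()].
#' @param init Optional [tm_params()] start; when `NULL` a random start is
#'   drawn (seeded by `cfg$seed`).
#' @return An object of class `"tm_fit"`: `params` (best over history),
#'   `cost` (its combined cost), `history` (per-stage data.frame with
#'   columns `stage`, `round`, `iteration`, `cost`, `f`, `U`, `F`, `D`,
#'   `A`), `config`, `obs`.
#' @examples
#' truth <- tm_params(f = 0.1, U = 0.2, F = 0.5, D = 0.2)
#' d <- generate_dataset(truth, c(5, 10, 20, 30, 50, 100, 130, 200),
#'                       n_pulses = 100, noise_sd_frac = 0, seed = 1)
#' fit <- dual_optimize(d, dual_config(n_outer = 2, seed = 7))
#' parameter_distance(fit$params, truth)
#' @export
dual_optimize <- function(data, cfg = dual_config(), init = NULL) {
  if (!inherits(data, "mf_dataset")) stop("`data` must be an mf_dataset")
  freqs <- dataset_frequencies(data)
  n_free_ss <- length(setdiff(c("f", "U", "F", "D"), cfg$frozen))
  if (length(freqs) < n_free_ss) {
    stop(sprintf(paste0(
      "only %d distinct frequencies for %d free steady-state parameters; ",
      "use dual_optimize_frozen_u() for under-determined data"),
      length(freqs), n_free_ss))
  }
  set.seed(cfg$seed)
  if (is.null(init)) init <- random_init()
  validate_tm_params(init)
  init <- project_to_bounds(init, cfg$bounds, quiet = TRUE)

  obs <- steady_state_obs(data, k = cfg$k_steady)
  tcfg <- transient_config(change_threshold = cfg$change_threshold,
                           n_trans_cap = cfg$n_trans_cap,
                           penalty_factor = cfg$penalty_factor)
  n_trans <- dataset_transient_lengths(data, tcfg)

  history <- list()
  current <- init
  best_params <- init
  best_cost <- combined_cost(init, data, obs, tcfg, n_trans)
  prev_cost <- best_cost
  history[[1]] <- history_row("init", 0L, 0L, best_cost, init)

  for (round in seq_len(cfg$n_outer)) {
    ssf <- fit_steady_state(obs, init = current, frozen = cfg$frozen,
                            max_steps = cfg$max_steps_steady,
                            bounds = cfg$bounds,
                            allow_underdetermined = length(cfg$frozen) > 0)
    theta_ss <- ssf$params
    cc_ss <- combined_cost(theta_ss, data, obs, tcfg, n_trans)
    history[[length(history) + 1]] <-
      history_row("steady", round, ssf$iterations, cc_ss, theta_ss)
    if (cc_ss < best_cost) { best_cost <- cc_ss; best_params <- theta_ss }

    tcfg$anchor <- theta_ss
    trf <- fit_transient(data, init = theta_ss, cfg = tcfg,
                         max_steps = cfg$max_steps_transient,
                         bounds = cfg$bounds,
                         profile_A = isTRUE(cfg$transient_profile_A))
    current <- trf$params
    cc_tr <- combined_cost(current, data, obs, tcfg, n_trans)
    history[[length(history) + 1]] <-
      history_row("transient", round, trf$evaluations, cc_tr, current)
    if (cc_tr < best_cost) { best_cost <- cc_tr; best_params <- current }

    rel_change <- abs(prev_cost - cc_tr) / max(abs(prev_cost), .Machine$double.eps)
    prev_cost <- cc_tr
    if (rel_change < cfg$tol) break
  }

  new_tm_fit("dual", best_params, best_cost, do.call(rbind, history), cfg,
             extra = list(obs = obs, init = init))
}

#' Dual optimization with frozen baseline release probability
#'
#' Variant of [dual_optimize()] for under-determined datasets (down to 3
#' stimulation frequencies): `U` is frozen during the steady-state stage
#' (still free during the transient stage), the per-stage iteration caps
#' are halved and the number of alternation rounds is doubled relative to
#' `cfg`, trading per-stage progress for more alternations so that neither
#' stage overfits the under-determined problem.
#'
#' @param data An [mf_dataset()] with at least 3 distinct frequencies.
#' @param cfg A [dual_config()]; its step caps/rounds are rescaled as
#'   described.
#' @param init Optional starting [tm_params()].
#' @return A `"tm_fit"`, as [dual_optimize()].
#' @export
dual_optimize_frozen_u <- function(data, cfg = dual_config(), init = NULL) {
  freqs <- dataset_frequencies(data)
  if (length(freqs) < 3) {
    stop("frozen-U mode needs at least 3 distinct frequencies")
  }
  cfg$frozen <- "U"
  cfg$n_outer <- 2L * cfg$n_outer
  cfg$max_steps_steady <- max(1L, cfg$max_steps_steady %/% 2L)
  cfg$max_steps_transient <- max(1L, cfg$max_steps_transient %/% 2L)
  fit <- dual_optimize(data, cfg, init = init)
  fit$method <- "dual-frozen-U"
  fit
}

#' Conventional full-length LMSE baseline
#'
#' The comparison baseline: Nelder-Mead minimization of the mean squared
#' error over the full length of every peak series (no transient
#' truncation, no steady-state stage, no anchor penalty), with the
#' amplitude `A` profiled in closed form.
#'
#' @param data An [mf_dataset()] with nonempty series.
#' @param init A [tm_params()] starting point (e.g. [random_init()]).
#' @param max_steps Nelder-Mead iteration cap (the comparisons in this
#'   package use 300).
#' @param bounds Parameter bounds.
#' @param profile_A If `TRUE` (default) the amplitude scale is profiled in
#'   closed form; set `FALSE` when the absolute efficacy is known.
#' @return A `"tm_fit"` with `history` holding the best-so-far full-series
#'   cost per function evaluation.
#' @export
conventional_lmse <- function(data, init, max_steps = 300,
                              bounds = default_bounds(), profile_A = TRUE) {
  if (!inherits(data, "mf_dataset")) stop("`data` must be an mf_dataset")
  lens <- vapply(data$series, length, integer(1))
  if (any(lens == 0)) stop("conventional_lmse: dataset contains an empty series")
  # full-length fit == transient cost with N_trans = full series length
  cfg <- transient_config(penalty_factor = 0)
  n_trans <- lens
  validate_tm_params(init)
  init <- project_to_bounds(init, bounds, quiet = TRUE)

  res <- nm_minimize(init, function(p) {
    transient_cost(p, data, cfg, n_trans = n_trans, profile_A = profile_A)
  }, max_steps = max_steps, bounds = bounds)

  history <- data.frame(stage = "lmse", round = 1L,
                        iteration = seq_along(res$trajectory),
                        cost = res$trajectory,
                        f = NA_real_, U = NA_real_, F = NA_real_,
                        D = NA_real_, A = NA_real_)
  new_tm_fit("lmse", res$params, res$cost, history,
             list(max_steps = max_steps, bounds = bounds))
}

#' Full-series mean squared error of a parameter set
#'
#' Convenience metric used in the method comparisons: sum over frequencies
#' of the mean squared error between the observed full-length series and
#' the model prediction.
#'
#' @param params A [tm_params()].
#' @param data An [mf_dataset()].
#' @return Nonnegative scalar.
#' @export
full_series_mse <- function(params, data) {
  cfg <- transient_config(penalty_factor = 0)
  as.numeric(transient_cost(params, data, cfg,
                            n_trans = vapply(data$series, length, integer(1))))
}
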