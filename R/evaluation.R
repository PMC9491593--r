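#' Euclidean distance between TM parameter sets
#'
#' L2 norm of the difference of the raw `[f, U, F, D]` vectors (the metric
#' used in the method comparisons). A bound-normalized variant divides each
#' coordinate by its bound range first, making seconds-scaled and
#' probability-scaled parameters commensurable.
#'
#' @param a,b [tm_params()] objects.
#' @param normalize If `TRUE`, scale each coordinate by its
#'   [default_bounds()] range before taking the norm.
#' @return Nonnegative scalar.
#' @examples
#' parameter_distance(tm_params(0.1, 0.2, 0.5, 0.2),
#'                    tm_params(0.1, 0.2, 0.5, 0.3))  # 0.1
#' @export
parameter_distance <- function(a, b, normalize = FALSE) {
  d <- tm_theta(a) - tm_theta(b)
  if (normalize) {
    rng <- vapply(default_bounds(), function(x) x[2] - x[1], numeric(1))
    d <- d / rng[c("f", "U", "F", "D")]
  }
  sqrt(sum(d^2))
}

#' Benchmark the estimation methods on synthetic ground truths
#'
#' For every combination of ground truth, noise level and method
#' (`"steady"` = steady-state-only fit, `"lmse"` = conventional full-length
#' baseline, `"dual"` = dual optimization), runs `n_inits` independently
#' seeded fits from random initial parameter sets and records the final
#' cost, the parameter estimates and the distance to truth. Initial
#' parameter sets are paired across methods (same draws), so method
#' comparisons are paired comparisons. All run seeds are recorded so every
#' number in the table is recomputable.
#'
#' @param truths List of [tm_params()] ground truths (or a single one).
#' @param frequencies Stimulation frequencies of the protocol.
#' @param n_pulses Pulses per train.
#' @param noise_levels Numeric vector of noise fractions (of max amplitude).
#' @param n_inits Number of random initializations per cell, `>= 2`.
#' @param budget Nelder-Mead iteration budget for `"lmse"`, and for the
#'   transient stage total across rounds in `"dual"`.
#' @param seed Master seed; per-run seeds are derived from it.
#' @param methods Subset of `c("steady", "lmse", "dual")`.
#' @param n_outer Outer rounds for the dual method (its transient budget per
#'   round is `budget / n_outer`).
#' @return A list of class `"stp_benchmark"`: `results` (one row per run:
#'   `truth_id`, `noise`, `method`, `init_id`, `seed`, `cost`, `f`, `U`,
#'   `F`, `D`, `A`, `distance`, `full_mse`, `error`), and `summary`
#'   (median and central 68.2% interval of the distance per
#'   truth/noise/method).
#' @export
compare_methods <- function(truths, frequencies = c(5, 10, 20, 30, 50, 100, 130, 200),
                            n_pulses = 100, noise_levels = 0, n_inits = 2,
                            budget = 300, seed = 1L,
                            methods = c("steady", "lmse", "dual"),
                            n_outer = 5) {
  if (inherits(truths, "tm_params")) truths <- list(truths)
  if (n_inits < 2) stop("n_inits must be >= 2")
  methods <- match.arg(methods, c("steady", "lmse", "dual"), several.ok = TRUE)

  set.seed(seed)
  # pre-draw everything deterministic up front
  data_seeds <- matrix(sample.int(2^30, length(truths) * length(noise_levels)),
                       nrow = length(truths))
  init_sets <- replicate(n_inits, random_init(), simplify = FALSE)
  run_seeds <- array(sample.int(2^30, length(truths) * length(noise_levels) *
                                  n_inits),
                     dim = c(length(truths), length(noise_levels), n_inits))

  rows <- list()
  for (ti in seq_along(truths)) {
    truth <- truths[[ti]]
    for (ni in seq_along(noise_levels)) {
      data <- generate_dataset(truth, frequencies, n_pulses,
                               noise_sd_frac = noise_levels[ni],
                               seed = data_seeds[ti, ni])
      obs <- steady_state_obs(data)
      for (ii in seq_len(n_inits)) {
        init <- init_sets[[ii]]
        rs <- run_seeds[ti, ni, ii]
        for (m in methods) {
          row <- data.frame(truth_id = ti, noise = noise_levels[ni],
                            method = m, init_id = ii, seed = rs,
                            cost = NA_real_, f = NA_real_, U = NA_real_,
                            F = NA_real_, D = NA_real_, A = NA_real_,
                            distance = NA_real_, full_mse = NA_real_,
                            error = NA_character_)
          est <- tryCatch({
            set.seed(rs)
            p <- switch(m,
              steady = fit_steady_state(obs, init = init,
                                        max_steps = budget)$params,
              lmse = conventional_lmse(data, init = init,
                                       max_steps = budget)$params,
              dual = dual_optimize(data,
                       dual_config(n_outer = n_outer,
                                   max_steps_transient =
                                     max(1L, budget %/% n_outer),
                                   seed = rs),
                       init = init)$params)
            p
          }, error = function(e) e)
          if (inherits(est, "error")) {
            row$error <- conditionMessage(est)
          } else {
            row$f <- est$f; row$U <- est$U; row$F <- est$F; row$D <- est$D
            row$A <- est$A
            row$distance <- parameter_distance(est, truth)
            row$full_mse <- full_series_mse(est, data)
            row$cost <- row$full_mse
          }
          rows[[length(rows) + 1]] <- row
        }
      }
    }
  }
  results <- do.call(rbind, rows)

  key <- interaction(results$truth_id, results$noise, results$method,
                     drop = TRUE)
  summ <- do.call(rbind, lapply(split(results, key), function(g) {
    d <- g$distance[!is.na(g$distance)]
    data.frame(truth_id = g$truth_id[1], noise = g$noise[1],
               method = g$method[1], n = length(d),
               median_distance = stats::median(d),
               lo_68 = if (length(d)) stats::quantile(d, 0.159, names = FALSE) else NA_real_,
               hi_68 = if (length(d)) stats::quantile(d, 0.841, names = FALSE) else NA_real_,
               median_full_mse = stats::median(g$full_mse, na.rm = TRUE))
  }))
  rownames(summ) <- NULL
  structure(list(results = results, summary = summ,
                 config = list(frequencies = frequencies,
                               n_pulses = n_pulses, budget = budget,
                               seed = seed, n_outer = n_outer)),
            class = "stp_benchmark")
}

#' @export
print.stp_benchmark <- function(x, ...) {
  cat("STP estimation benchmark\n")
  print(x$summary)
  invisible(x)
}
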