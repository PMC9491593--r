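#' Read and write TM parameter files
#'
#' Parameter files are JSON objects with keys `f`, `U`, `F_s`, `D_s`, `A`,
#' `tau_syn_s` (time constants in seconds).
#'
#' @param path File path.
#' @return `read_tm_params()` returns a [tm_params()]; `write_tm_params()`
#'   returns `path` invisibly.
#' @export
read_tm_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("f", "U", "F_s", "D_s")
  if (!all(need %in% names(x))) {
    stop("parameter file must contain keys ", paste(need, collapse = ", "))
  }
  tm_params(f = x$f, U = x$U, F = x$F_s, D = x$D_s,
            A = if (is.null(x$A)) 1 else x$A,
            tau_syn = if (is.null(x$tau_syn_s)) 0.003 else x$tau_syn_s)
}

#' @param params A [tm_params()] object.
#' @rdname read_tm_params
#' @export
write_tm_params <- function(params, path) {
  validate_tm_params(params)
  jsonlite::write_json(
    list(f = params$f, U = params$U, F_s = params$F, D_s = params$D,
         A = params$A, tau_syn_s = params$tau_syn),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read and write peak-series datasets
#'
#' Peak-series files are CSV with header
#' `frequency_hz,pulse_index,amplitude` (1-based pulse index). Clean
#' datasets round-trip bit-exactly (amplitudes are written with full
#' precision).
#'
#' @param path File path.
#' @return `read_peaks()` returns an [mf_dataset()]; `write_peaks()`
#'   returns `path` invisibly.
#' @export
read_peaks <- function(path) {
  df <- utils::read.csv(path, colClasses = c(frequency_hz = "numeric",
                                             pulse_index = "integer",
                                             amplitude = "numeric"))
  need <- c("frequency_hz", "pulse_index", "amplitude")
  if (!all(need %in% names(df))) {
    stop("peak file must have columns ", paste(need, collapse = ", "))
  }
  series <- lapply(split(df, df$frequency_hz), function(g) {
    g <- g[order(g$pulse_index), ]
    if (!identical(g$pulse_index, seq_len(nrow(g)))) {
      stop("pulse_index must be 1..n per frequency (frequency ",
           g$frequency_hz[1], " Hz)")
    }
    peak_series(g$frequency_hz[1], g$amplitude)
  })
  mf_dataset(unname(series))
}

#' @param data An [mf_dataset()].
#' @rdname read_peaks
#' @export
write_peaks <- function(data, path) {
  if (!inherits(data, "mf_dataset")) stop("`data` must be an mf_dataset")
  rows <- do.call(rbind, lapply(data$series, function(s) {
    data.frame(frequency_hz = s$frequency,
               pulse_index = seq_along(s$peaks),
               amplitude = sprintf("%.17g", s$peaks))
  }))
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write continuous PSC traces
#'
#' Trace files are CSV with header `time_s,current`; stimulation times are
#' a one-column CSV with header `stim_time_s`.
#'
#' @param path File path.
#' @return `read_trace()` returns a data.frame with columns `time_s`,
#'   `current`; `read_stim_times()` a numeric vector of seconds.
#' @export
read_trace <- function(path) {
  df <- utils::read.csv(path)
  if (!all(c("time_s", "current") %in% names(df))) {
    stop("trace file must have columns time_s, current")
  }
  df
}

#' @param trace A data.frame with columns `time_s`, `current`.
#' @rdname read_trace
#' @export
write_trace <- function(trace, path) {
  utils::write.csv(trace[, c("time_s", "current")], path, row.names = FALSE)
  invisible(path)
}

#' @rdname read_trace
#' @export
read_stim_times <- function(path) {
  df <- utils::read.csv(path)
  if (!("stim_time_s" %in% names(df))) {
    stop("stimulation-time file must have column stim_time_s")
  }
  sort(as.numeric(df$stim_time_s))
}

#' Read and write steady-state observation files
#'
#' CSV with header `frequency_hz,steady_state_amplitude`.
#'
#' @param path File path.
#' @return `read_ss_obs()` returns a [steady_state_obs()] data.frame.
#' @export
read_ss_obs <- function(path) {
  df <- utils::read.csv(path)
  need <- c("frequency_hz", "steady_state_amplitude")
  if (!all(need %in% names(df))) {
    stop("observations file must have columns ", paste(need, collapse = ", "))
  }
  steady_state_obs(df$frequency_hz, df$steady_state_amplitude)
}

#' @param obs A [steady_state_obs()] data.frame.
#' @rdname read_ss_obs
#' @export
write_ss_obs <- function(obs, path) {
  obs <- as_ss_obs(obs)
  utils::write.csv(data.frame(frequency_hz = obs$frequency,
                              steady_state_amplitude = obs$amplitude),
                   path, row.names = FALSE)
  invisible(path)
}

#' Write a fit result to JSON
#'
#' Serializes the estimated parameters, frozen set, final cost and
#' iteration/stage counts of a fit object.
#'
#' @param fit A `"tm_fit"`, `"ss_fit"` or `"transient_fit"` object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, path) {
  p <- fit$params
  out <- list(
    params = list(f = p$f, U = p$U, F_s = p$F, D_s = p$D, A = p$A,
                  tau_syn_s = p$tau_syn),
    cost = as.numeric(fit$cost),
    frozen = if (!is.null(fit$frozen)) fit$frozen else
      if (!is.null(fit$config$frozen)) fit$config$frozen else character(0),
    method = if (!is.null(fit$method)) fit$method else class(fit)[1],
    iterations = if (!is.null(fit$iterations)) fit$iterations
      else if (!is.null(fit$evaluations)) fit$evaluations
      else if (!is.null(fit$history)) nrow(fit$history) else NA
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
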