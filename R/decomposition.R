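# Pharmacological decomposition of the evoked response: drug-resistant
# component = drug-condition average, drug-sensitive component = control
# minus drug, with per-latency contributions and kinetic parameters.

#' Decompose a control response into drug-resistant and drug-sensitive parts
#'
#' Both averaged traces are baseline-subtracted, then the sensitive trace is
#' the pointwise difference control - drug. By construction
#' `resistant + sensitive == control` exactly.
#'
#' @param control_avg,drug_avg `evoked_average` objects on identical time
#'   grids with identical baseline treatment.
#' @param channel Channel index to decompose.
#' @param baseline_window_ms Baseline window for both traces.
#' @return Object of class `decomposition_result`: list with `time_ms`,
#'   `control_trace`, `resistant_trace`, `sensitive_trace` (uV,
#'   baseline-subtracted), `fs_hz`, `channel`.
#' @export
decompose <- function(control_avg, drug_avg, channel,
                      baseline_window_ms = c(-100, 0)) {
  if (length(control_avg$time_ms) != length(drug_avg$time_ms) ||
      any(abs(control_avg$time_ms - drug_avg$time_ms) > 1e-9))
    stop("decompose: control and drug averages are on different time grids")
  t <- control_avg$time_ms
  bl <- t >= baseline_window_ms[1] & t < baseline_window_ms[2]
  ctrl <- control_avg$data[channel, ] - mean(control_avg$data[channel, bl])
  drug <- drug_avg$data[channel, ] - mean(drug_avg$data[channel, bl])
  structure(list(time_ms = t, control_trace = ctrl, resistant_trace = drug,
                 sensitive_trace = ctrl - drug, fs_hz = control_avg$fs_hz,
                 channel = channel),
            class = "decomposition_result")
}

#' @export
plot.decomposition_result <- function(x, ...) {
  graphics::matplot(x$time_ms,
                    cbind(x$control_trace, x$resistant_trace,
                          x$sensitive_trace),
                    type = "l", lty = 1, col = c("blue", "red", "black"),
                    xlab = "time (ms)", ylab = "LFP (uV)", ...)
  graphics::legend("bottomright", c("control", "resistant", "sensitive"),
                   col = c("blue", "red", "black"), lty = 1, bty = "n")
  graphics::abline(v = 0, h = 0, lty = 3)
  invisible(x)
}

#' Relative component contributions at a latency
#'
#' Resistant percentage is `100 * resistant(t) / control(t)`; the sensitive
#' percentage is its complement, so the two always sum to 100 where defined.
#'
#' @param dec A `decomposition_result`.
#' @param t_ms Latency (ms); vectorized.
#' @return Data frame with `t_ms`, `resistant_pct`, `sensitive_pct`
#'   (NA where the control trace is zero).
#' @export
contribution_at <- function(dec, t_ms) {
  ctrl <- stats::approx(dec$time_ms, dec$control_trace, xout = t_ms)$y
  res <- stats::approx(dec$time_ms, dec$resistant_trace, xout = t_ms)$y
  pct <- 100 * res / ctrl
  pct[ctrl == 0] <- NA_real_
  data.frame(t_ms = t_ms, resistant_pct = pct, sensitive_pct = 100 - pct)
}

#' 20-80\% rise time of a negative-going front
#'
#' Time between the 20\% and 80\% crossings of the peak magnitude on the
#' rising front, with linear sub-sample interpolation.
#'
#' @param trace Numeric trace (negative-going deflection).
#' @param time_ms Matching time grid (ms).
#' @param onset_ms,peak_ms Front boundaries (ms).
#' @return Duration (ms), or `NA` when the crossings do not exist.
#' @export
rise_time_2080 <- function(trace, time_ms, onset_ms, peak_ms) {
  if (peak_ms <= onset_ms) return(NA_real_)
  step <- (time_ms[2] - time_ms[1]) / 20
  tt <- seq(onset_ms, peak_ms, by = step)
  m <- -stats::approx(time_ms, trace, xout = tt)$y
  if (length(m) < 3) return(NA_real_)
  pk <- m[length(m)]
  if (pk <= 0) return(NA_real_)
  cross <- function(level) {
    idx <- which(m >= level)
    if (!length(idx) || idx[1] == 1) return(NA_real_)
    j <- idx[1]
    tt[j - 1] + (level - m[j - 1]) / (m[j] - m[j - 1]) * step
  }
  t20 <- cross(0.2 * pk)
  t80 <- cross(0.8 * pk)
  if (is.na(t20) || is.na(t80)) return(NA_real_)
  t80 - t20
}

#' Fit an exponential decay to a trace segment
#'
#' Least-squares fit of `A * exp(-(t - t_start) / tau)` to the magnitude of
#' the trace inside the fit window, initialized by a log-linear regression
#' and refined by Levenberg-Marquardt nonlinear least squares.
#'
#' @param trace Numeric trace (signed; the magnitude is fitted).
#' @param time_ms Matching time grid (ms).
#' @param fit_window_ms Length-2 window `c(start, end)` (ms); should begin
#'   at or after the (last) peak.
#' @return Object of class `exp_fit`: list with `amplitude_uV`, `tau_ms`,
#'   `fit_window_ms`, `residual_rms`, `ok` (FALSE on a non-decaying or
#'   degenerate window).
#' @export
fit_exponential_decay <- function(trace, time_ms, fit_window_ms) {
  sel <- which(time_ms >= fit_window_ms[1] & time_ms <= fit_window_ms[2])
  fail <- structure(list(amplitude_uV = NA_real_, tau_ms = NA_real_,
                         fit_window_ms = fit_window_ms,
                         residual_rms = NA_real_, ok = FALSE),
                    class = "exp_fit")
  if (length(sel) < 10) return(fail)
  tt <- time_ms[sel] - time_ms[sel[1]]
  m <- abs(trace[sel])
  pos <- m > 0
  if (sum(pos) < 10) return(fail)
  init <- stats::coef(stats::lm(log(m[pos]) ~ tt[pos]))
  if (!is.finite(init[2]) || init[2] >= 0) return(fail)
  df <- data.frame(tt = tt, m = m)
  fit <- tryCatch(
    minpack.lm::nlsLM(m ~ A * exp(-tt / tau), data = df,
                      start = list(A = unname(exp(init[1])),
                                   tau = unname(-1 / init[2])),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) return(fail)
  co <- stats::coef(fit)
  if (!is.finite(co["tau"]) || co["tau"] <= 0) return(fail)
  structure(list(amplitude_uV = unname(co["A"]), tau_ms = unname(co["tau"]),
                 fit_window_ms = fit_window_ms,
                 residual_rms = sqrt(mean(stats::resid(fit)^2)), ok = TRUE),
            class = "exp_fit")
}

#' Find a late second peak of a component trace
#'
#' First local maximum of the trace magnitude after `after_ms` whose
#' topographic prominence exceeds `prominence_frac` of the component's main
#' peak.
#'
#' @param trace Numeric trace (negative-going component).
#' @param time_ms Matching time grid (ms).
#' @param after_ms Earliest admissible latency (ms).
#' @param prominence_frac Prominence criterion (default 0.10).
#' @return Latency in ms, or `NA` when absent.
#' @export
find_second_peak <- function(trace, time_ms, after_ms,
                             prominence_frac = 0.10) {
  m <- -trace
  main_pk <- max(m)
  if (main_pk <= 0) return(NA_real_)
  pk <- .local_maxima(m)
  pk <- pk[time_ms[pk] > after_ms]
  if (!length(pk)) return(NA_real_)
  prom <- .prominence(m, .local_maxima(m))
  prom <- prom[match(pk, .local_maxima(m))]
  pk <- pk[prom >= prominence_frac * main_pk]
  if (!length(pk)) return(NA_real_)
  time_ms[pk[1]]
}

#' Kinetic summary of one decomposed component
#'
#' Convenience wrapper measuring the 20-80\% rise time, time to peak,
#' second-peak latency and exponential decay constant of a component trace.
#' The decay fit window runs from the last detected peak to the point where
#' the magnitude first falls below 5\% of that peak (or the trace end).
#'
#' @param trace Component trace (uV, negative-going).
#' @param time_ms Matching time grid (ms).
#' @param search_window_ms Window holding the response (default
#'   `c(3, 100)`).
#' @param second_peak_after_ms Passed to [find_second_peak()] (default 30).
#' @return List with `onset_ms`, `time_to_peak_ms`, `rise_2080_ms`,
#'   `second_peak_ms`, `decay_fit` (an `exp_fit`).
#' @export
component_kinetics_measured <- function(trace, time_ms,
                                        search_window_ms = c(3, 100),
                                        second_peak_after_ms = 30) {
  fs <- 1000 / (time_ms[2] - time_ms[1])
  fake <- structure(list(data = matrix(trace, nrow = 1), time_ms = time_ms,
                         fs_hz = fs, n_trials = 1, geometry = NULL),
                    class = "evoked_average")
  sep <- detect_sep(fake, 1, search_window_ms,
                    baseline_window_ms = c(time_ms[1], 0))
  if (!sep$responded)
    return(list(onset_ms = NA_real_, time_to_peak_ms = NA_real_,
                rise_2080_ms = NA_real_, second_peak_ms = NA_real_,
                decay_fit = fit_exponential_decay(trace, time_ms, c(0, 0))))
  rise <- rise_time_2080(trace, time_ms, sep$onset_ms, sep$peak_latency_ms)
  p2 <- find_second_peak(trace, time_ms, second_peak_after_ms)
  last_pk <- if (!is.na(p2)) p2 else sep$peak_latency_ms
  m <- -trace
  pk_val <- m[which.min(abs(time_ms - last_pk))]
  after <- which(time_ms > last_pk & m < 0.05 * pk_val)
  fit_end <- if (length(after)) time_ms[after[1]] else time_ms[length(time_ms)]
  fit <- fit_exponential_decay(trace, time_ms, c(last_pk, fit_end))
  list(onset_ms = sep$onset_ms, time_to_peak_ms = sep$peak_latency_ms,
       rise_2080_ms = rise, second_peak_ms = p2, decay_fit = fit)
}
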