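# Sensory-evoked potential (SEP) parameterization on averaged LFP traces.

#' First derivative of a uniformly sampled trace
#'
#' Central differences at interior samples, one-sided at the edges.
#'
#' @param trace Numeric vector.
#' @param fs_hz Sampling rate (Hz).
#' @return Numeric vector of the derivative in (units of `trace`)/ms.
#' @export
first_derivative <- function(trace, fs_hz) {
  n <- length(trace)
  if (n < 3) stop("first_derivative: need at least 3 samples")
  dt <- 1000 / fs_hz  # ms per sample
  d <- numeric(n)
  d[1] <- (trace[2] - trace[1]) / dt
  d[n] <- (trace[n] - trace[n - 1]) / dt
  d[2:(n - 1)] <- (trace[3:n] - trace[1:(n - 2)]) / (2 * dt)
  d
}

#' Detect and parameterize the sensory-evoked potential
#'
#' The SEP is the first LFP trough of the averaged evoked response. The
#' baseline level is the mean over the baseline window; the trough is the
#' first local minimum inside the search window whose depth below baseline
#' exceeds `trough_criterion_sd` baseline SDs; the onset is the
#' intersection of the SEP front with the baseline level, obtained by
#' extrapolating the tangent at the front's steepest point back to the
#' baseline (exact on piecewise-linear fronts, and robust because it uses
#' only the steep high-amplitude part of the front); the maximal slope is
#' the largest magnitude of the first derivative on the falling front.
#'
#' @param avg An `evoked_average` from [average_evoked()].
#' @param channel Channel index to analyze.
#' @param search_window_ms Post-stimulus trough search window (default
#'   `c(3, 50)` ms).
#' @param baseline_window_ms Baseline window (default `c(-100, 0)` ms).
#' @param trough_criterion_sd Depth criterion in baseline SDs (default 4).
#' @param min_depth_frac Additional qualification: the trough must reach at
#'   least this fraction of the deepest excursion below baseline inside the
#'   search window (default 0.25). Guards against micro-troughs on traces
#'   whose baseline is nearly noiseless.
#' @return Object of class `sep_metrics` with fields `onset_ms`,
#'   `peak_latency_ms`, `peak_amplitude_uV` (positive magnitude of the
#'   trough below baseline), `max_slope_uV_per_ms`, `baseline_uV`, and
#'   `responded`.
#' @export
detect_sep <- function(avg, channel, search_window_ms = c(3, 50),
                       baseline_window_ms = c(-100, 0),
                       trough_criterion_sd = 4, min_depth_frac = 0.25) {
  t <- avg$time_ms
  y <- avg$data[channel, ]
  bl <- t >= baseline_window_ms[1] & t < baseline_window_ms[2]
  if (!any(bl)) stop("detect_sep: trace does not cover the baseline window")
  bmean <- mean(y[bl]); bsd <- stats::sd(y[bl])
  sw <- which(t >= search_window_ms[1] & t < search_window_ms[2])
  if (!length(sw)) stop("detect_sep: trace does not cover the search window")
  no_resp <- structure(list(onset_ms = NA_real_, peak_latency_ms = NA_real_,
                            peak_amplitude_uV = NA_real_,
                            max_slope_uV_per_ms = NA_real_,
                            baseline_uV = bmean, responded = FALSE),
                       class = "sep_metrics")
  # troughs: local maxima of the negated trace; allow a trough at the window
  # edge when the trace is still descending at the window end
  mins <- sw[1] - 1L + .local_maxima(-y[sw])
  max_depth <- bmean - min(y[sw])
  deep <- mins[bmean - y[mins] >= trough_criterion_sd * bsd &
                 bmean - y[mins] >= min_depth_frac * max_depth]
  if (!length(deep)) return(no_resp)
  i_tr <- deep[1]
  # onset: extrapolate the steepest front tangent back to the baseline level
  depth_tr <- bmean - y[i_tr]
  m <- bmean - y  # depth below baseline
  i80 <- i_tr
  while (i80 > 1 && m[i80 - 1] > 0.8 * depth_tr) i80 <- i80 - 1L
  i20 <- i80
  while (i20 > 1 && m[i20 - 1] > 0.2 * depth_tr) i20 <- i20 - 1L
  seg <- max(1L, i20 - 1L):i_tr
  dt_ms <- t[2] - t[1]
  onset <- t[seg[1]]
  if (length(seg) >= 3) {
    dy <- first_derivative(y[seg], avg$fs_hz)
    jm <- which.min(dy)   # steepest descent on the front
    if (dy[jm] < 0) {
      onset <- t[seg[jm]] + (bmean - y[seg[jm]]) / dy[jm]
      onset <- min(max(onset, t[1]), t[i_tr])
    }
  } else if (length(seg) == 2 && y[seg[2]] < y[seg[1]]) {
    b <- (y[seg[2]] - y[seg[1]]) / dt_ms
    onset <- t[seg[1]] + (bmean - y[seg[1]]) / b
    onset <- min(max(onset, t[1]), t[i_tr])
  }
  front <- which(t >= onset & t <= t[i_tr])
  slope <- if (length(front) >= 3)
    max(abs(first_derivative(y[front], avg$fs_hz))) else NA_real_
  structure(list(onset_ms = onset,
                 peak_latency_ms = t[i_tr],
                 peak_amplitude_uV = bmean - y[i_tr],
                 max_slope_uV_per_ms = slope,
                 baseline_uV = bmean, responded = TRUE),
            class = "sep_metrics")
}

#' @export
print.sep_metrics <- function(x, ...) {
  if (!x$responded) {
    cat("sep_metrics: no response detected\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("sep_metrics: onset %.2f ms, peak %.1f uV @ %.2f ms, ",
                     "max slope %.1f uV/ms\n"),
              x$onset_ms, x$peak_amplitude_uV, x$peak_latency_ms,
              x$max_slope_uV_per_ms))
  invisible(x)
}

#' Baseline-subtracted LFP value at a fixed latency
#'
#' Linear interpolation between grid samples; the baseline mean over
#' `baseline_window_ms` is subtracted, so the result is a signed deflection.
#'
#' @param avg An `evoked_average`.
#' @param channel Channel index.
#' @param t_ms Latency (ms) inside the averaged window.
#' @param baseline_window_ms Baseline window (default `c(-100, 0)`).
#' @return Signed LFP value (uV).
#' @export
amplitude_at <- function(avg, channel, t_ms, baseline_window_ms = c(-100, 0)) {
  t <- avg$time_ms
  if (any(t_ms < t[1] | t_ms > t[length(t)]))
    stop("amplitude_at: latency outside the averaged window")
  y <- avg$data[channel, ]
  bl <- t >= baseline_window_ms[1] & t < baseline_window_ms[2]
  bmean <- mean(y[bl])
  stats::approx(t, y, xout = t_ms)$y - bmean
}
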