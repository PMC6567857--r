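# Multi-unit activity: adaptive-threshold spike detection, sliding-window
# spike-density estimation, and early-response MUA metrics.

#' Find the quietest segment of a trace
#'
#' Slides a window of `span_ms` over the trace on a coarse grid and returns
#' the start and standard deviation of the lowest-SD segment. Used to set
#' the per-channel detection threshold from the noise floor.
#'
#' @param trace Numeric vector.
#' @param fs_hz Sampling rate (Hz).
#' @param span_ms Segment length (default 1000 ms).
#' @param step_ms Search-grid step (default 100 ms).
#' @return List with `start_ms`, `sd`, and `constant` (TRUE when the
#'   segment SD is zero, i.e. the threshold is undefined).
#' @export
quietest_segment <- function(trace, fs_hz, span_ms = 1000, step_ms = 100) {
  n <- length(trace)
  w <- round(span_ms / 1000 * fs_hz)
  if (n < w) stop("quietest_segment: trace shorter than the segment span")
  starts <- seq(1L, n - w + 1L, by = max(1L, round(step_ms / 1000 * fs_hz)))
  cs <- cumsum(c(0, trace))
  cs2 <- cumsum(c(0, trace^2))
  s1 <- cs[starts + w] - cs[starts]
  s2 <- cs2[starts + w] - cs2[starts]
  v <- pmax(0, (s2 - s1^2 / w) / (w - 1))
  i <- which.min(v)
  sd <- sqrt(v[i])
  list(start_ms = (starts[i] - 1) / fs_hz * 1000, sd = sd, constant = sd == 0)
}

#' Detect multi-unit spikes by adaptive negative threshold
#'
#' Per channel, the threshold is `-threshold_sd` times the SD of the
#' quietest `quiet_span_ms` segment of the band-passed trace. Each
#' suprathreshold (negative) excursion yields exactly one spike timed at its
#' negative extremum; a dead time suppresses re-detection of the same
#' waveform.
#'
#' @param spike_band A band-passed [wideband_recording()] (see
#'   [bandpass_spike()]), at least `quiet_span_ms` long.
#' @param threshold_sd Threshold multiplier (default 5).
#' @param dead_time_ms Minimum separation between spikes (default 1 ms).
#' @param quiet_span_ms,quiet_step_ms Quietest-segment search parameters.
#' @return Object of class `spike_times`: list with `times_ms` (list of
#'   per-channel sorted spike times, absolute recording time in ms),
#'   `threshold_uV`, `noise_sd_uV` per channel.
#' @export
detect_spikes <- function(spike_band, threshold_sd = 5, dead_time_ms = 1,
                          quiet_span_ms = 1000, quiet_step_ms = 100) {
  fs <- spike_band$fs_hz
  if (nrow(spike_band$data) < quiet_span_ms / 1000 * fs)
    stop("detect_spikes: recording shorter than the quiet-segment span")
  nch <- ncol(spike_band$data)
  times <- vector("list", nch)
  thr_v <- numeric(nch)
  sd_v <- numeric(nch)
  for (ch in seq_len(nch)) {
    x <- spike_band$data[, ch]
    q <- quietest_segment(x, fs, quiet_span_ms, quiet_step_ms)
    sd_v[ch] <- q$sd
    if (q$constant) {
      times[[ch]] <- numeric(0)
      thr_v[ch] <- NA_real_
      next
    }
    thr <- -threshold_sd * q$sd
    thr_v[ch] <- thr
    below <- x < thr
    d <- diff(c(FALSE, below, FALSE))
    starts <- which(d == 1L)
    ends <- which(d == -1L) - 1L
    if (!length(starts)) {
      times[[ch]] <- numeric(0)
      next
    }
    ext <- mapply(function(s, e) s - 1L + which.min(x[s:e]), starts, ends)
    t_ms <- spike_band$t0_ms + (ext - 1) / fs * 1000
    # dead time: greedy left-to-right
    keep <- logical(length(t_ms))
    last <- -Inf
    for (i in seq_along(t_ms)) {
      if (t_ms[i] - last >= dead_time_ms) {
        keep[i] <- TRUE
        last <- t_ms[i]
      }
    }
    times[[ch]] <- t_ms[keep]
  }
  structure(list(times_ms = times, threshold_uV = thr_v, noise_sd_uV = sd_v,
                 fs_hz = fs),
            class = "spike_times")
}

#' @export
print.spike_times <- function(x, ...) {
  cat(sprintf("spike_times: %d channels, %d spikes total\n",
              length(x$times_ms), sum(lengths(x$times_ms))))
  invisible(x)
}

#' Continuous spike density around stimuli
#'
#' Sliding-window peristimulus spike density: counts over a `bin_ms` window
#' centered on each grid point (grid step `step_ms`), pooled across trials
#' and the selected channels, divided by `bin_ms * n_trials`. Units are
#' spikes/ms (summed over the selected channels).
#'
#' @param spikes A `spike_times` from [detect_spikes()].
#' @param stim A [stimulus_train()].
#' @param channels Channel indices to pool (nonempty).
#' @param window_ms Peristimulus window `c(pre, post)` (ms).
#' @param bin_ms Sliding-window width (default 1 ms).
#' @param step_ms Grid step (default 0.2 ms).
#' @return Object of class `mua_density`: list with `time_ms`, `density`
#'   (spikes/ms), `n_trials`, `channels`, `bin_ms`, `step_ms`.
#' @export
spike_density <- function(spikes, stim, channels, window_ms = c(-200, 600),
                          bin_ms = 1.0, step_ms = 0.2) {
  if (!length(channels)) stop("spike_density: empty channel set")
  all_t <- sort(unlist(spikes$times_ms[channels], use.names = FALSE))
  rel <- numeric(0)
  for (on in stim$onsets_ms) {
    sel <- all_t >= on + window_ms[1] & all_t < on + window_ms[2]
    rel <- c(rel, all_t[sel] - on)
  }
  rel <- sort(rel)
  grid <- seq(window_ms[1], window_ms[2], by = step_ms)
  n_trials <- length(stim$onsets_ms)
  lo <- findInterval(grid - bin_ms / 2, rel, left.open = TRUE)
  hi <- findInterval(grid + bin_ms / 2, rel, left.open = TRUE)
  dens <- (hi - lo) / (bin_ms * n_trials)
  structure(list(time_ms = grid, density = dens, n_trials = n_trials,
                 channels = channels, bin_ms = bin_ms, step_ms = step_ms),
            class = "mua_density")
}

#' @export
plot.mua_density <- function(x, ...) {
  graphics::plot(x$time_ms, x$density, type = "l", xlab = "time (ms)",
                 ylab = "MUA density (spikes/ms)", ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

# local maxima indices of y (strict rise then fall, plateaus take first point)
.local_maxima <- function(y) {
  d <- diff(y)
  s <- sign(d)
  # collapse zero slopes to the preceding sign so plateaus count once
  for (i in seq_along(s)) if (s[i] == 0 && i > 1) s[i] <- s[i - 1]
  which(diff(s) < 0) + 1L
}

# topographic prominence of peaks at indices pk in trace y; reference peaks
# must be strictly higher, so equal-height twin peaks do not mask each other
.prominence <- function(y, pk) {
  vapply(pk, function(p) {
    higher_l <- pk[pk < p][y[pk[pk < p]] > y[p]]
    higher_r <- pk[pk > p][y[pk[pk > p]] > y[p]]
    lo <- if (length(higher_l)) max(higher_l) else 1L
    hi <- if (length(higher_r)) min(higher_r) else length(y)
    base <- max(min(y[lo:p]), min(y[p:hi]))
    y[p] - base
  }, numeric(1))
}

#' Early-response MUA metrics
#'
#' Extracts onset latency, first-peak latency/density, rising slope and
#' maximal peak from a peristimulus density trace. The first peak is the
#' first local maximum inside the search window exceeding the detection
#' criterion (baseline mean + `onset_criterion_sd` baseline SDs) with
#' topographic prominence of at least a quarter of the tallest qualifying
#' peak; the onset is the density's last crossing of the baseline mean
#' before the first peak (linear sub-step interpolation); the slope is the
#' maximal first derivative on the rising limb.
#'
#' @param d A `mua_density`.
#' @param baseline_window_ms,search_window_ms Half-open windows (ms).
#' @param onset_criterion_sd Criterion multiplier (default 3).
#' @param peak_prominence_frac Prominence criterion for qualifying peaks,
#'   as a fraction of the tallest qualifying peak above baseline
#'   (default 0.15).
#' @return Object of class `mua_metrics` with fields `onset_ms`,
#'   `first_peak_density`, `first_peak_delay_ms`, `rising_slope`,
#'   `max_peak_density`, `max_peak_delay_ms`, `baseline_density`, and
#'   `responded` (FALSE when no peak exceeds the criterion; metric fields
#'   are then NA).
#' @export
mua_metrics <- function(d, baseline_window_ms = c(-200, 0),
                        search_window_ms = c(3, 50),
                        onset_criterion_sd = 3,
                        peak_prominence_frac = 0.15) {
  t <- d$time_ms; y <- d$density
  bl <- t >= baseline_window_ms[1] & t < baseline_window_ms[2]
  if (!any(bl)) stop("mua_metrics: density does not cover the baseline window")
  bmean <- mean(y[bl]); bsd <- stats::sd(y[bl])
  crit <- bmean + onset_criterion_sd * bsd
  sw <- which(t >= search_window_ms[1] & t < search_window_ms[2])
  if (!length(sw)) stop("mua_metrics: density does not cover the search window")
  pk_all <- sw[1] - 1L + .local_maxima(y[sw])
  pk <- pk_all[y[pk_all] > crit]
  no_resp <- structure(list(onset_ms = NA_real_, first_peak_density = NA_real_,
                            first_peak_delay_ms = NA_real_,
                            rising_slope = NA_real_,
                            max_peak_density = NA_real_,
                            max_peak_delay_ms = NA_real_,
                            baseline_density = bmean, responded = FALSE),
                       class = "mua_metrics")
  if (!length(pk)) return(no_resp)
  # merge split tops closer than the bin width (noise on one burst peak)
  min_sep <- d$bin_ms + 0.2
  while (length(pk) >= 2 && any(diff(t[pk]) < min_sep)) {
    j <- which(diff(t[pk]) < min_sep)[1]
    pk <- pk[-(if (y[pk[j]] >= y[pk[j + 1]]) j + 1L else j)]
  }
  prom <- .prominence(y, pk)
  pk <- pk[prom >= peak_prominence_frac * max(y[pk] - bmean)]
  if (!length(pk)) return(no_resp)
  i_first <- pk[1]
  i_max <- sw[which.max(y[sw])]
  # onset: last sustained crossing of the baseline mean before the first
  # peak; isolated single-spike bins (one bin wide) do not stop the
  # backward walk
  debounce <- max(1L, ceiling(1.2 * d$bin_ms / d$step_ms))
  onset <- t[sw[1]]
  j <- i_first - 1L
  while (j >= 1) {
    if (y[j] <= bmean) {
      run_ok <- all(y[(j + 1):min(j + debounce, i_first)] > bmean)
      if (run_ok) break
    }
    j <- j - 1L
  }
  if (j >= 1) {
    onset <- if (y[j + 1] > bmean && y[j + 1] != y[j])
      t[j] + (bmean - y[j]) / (y[j + 1] - y[j]) * d$step_ms
    else t[j]
  }
  rise <- which(t >= onset & t <= t[i_first])
  slope <- if (length(rise) >= 3) {
    dy <- (y[rise][-c(1, 2)] - y[rise][-c(length(rise) - 1, length(rise))]) /
      (2 * d$step_ms)
    max(dy)
  } else NA_real_
  structure(list(onset_ms = onset,
                 first_peak_density = y[i_first],
                 first_peak_delay_ms = t[i_first],
                 rising_slope = slope,
                 max_peak_density = y[i_max],
                 max_peak_delay_ms = t[i_max],
                 baseline_density = bmean, responded = TRUE),
            class = "mua_metrics")
}

#' @export
print.mua_metrics <- function(x, ...) {
  if (!x$responded) {
    cat("mua_metrics: no response detected\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("mua_metrics: onset %.2f ms, first peak %.3f spikes/ms",
                     " @ %.2f ms,\n  slope %.3f spikes/ms^2, max peak %.3f",
                     " spikes/ms @ %.2f ms\n"),
              x$onset_ms, x$first_peak_density, x$first_peak_delay_ms,
              x$rising_slope, x$max_peak_density, x$max_peak_delay_ms))
  invisible(x)
}

#' Oscillation frequency of the early MUA burst
#'
#' Frequency is 1000 / mean inter-peak interval (ms) of successive density
#' peaks inside the early window. Peaks must exceed a topographic-prominence
#' criterion relative to the tallest peak in the window; peak times are
#' refined by 3-point parabolic interpolation for sub-step resolution.
#'
#' @param d A `mua_density`.
#' @param early_window_ms Window containing the burst, e.g.
#'   `c(onset, onset + 15)`.
#' @param prominence_frac Prominence criterion as a fraction of the tallest
#'   peak (default 0.20).
#' @param min_sep_ms Minimum admissible inter-peak separation; closer peaks
#'   are merged, keeping the taller. The default (1.8 ms) corresponds to
#'   the ~600 Hz upper bound of cortical high-frequency oscillations.
#' @return List with `freq_hz` (NA when fewer than 2 peaks qualify),
#'   `peak_times_ms`, `n_peaks`.
#' @export
oscillation_frequency <- function(d, early_window_ms,
                                  prominence_frac = 0.20,
                                  min_sep_ms = 1.8) {
  t <- d$time_ms; y <- d$density
  sw <- which(t >= early_window_ms[1] & t <= early_window_ms[2])
  if (length(sw) < 3) return(list(freq_hz = NA_real_,
                                  peak_times_ms = numeric(0), n_peaks = 0L))
  # search on a slightly padded window so peaks near the window edges keep
  # both flanks, then retain only peaks inside the requested window
  pad <- which(t >= early_window_ms[1] - 2 & t <= early_window_ms[2] + 2)
  pk <- pad[1] - 1L + .local_maxima(y[pad])
  pk <- pk[t[pk] >= early_window_ms[1] & t[pk] <= early_window_ms[2]]
  # merge peaks closer than one oscillation period can be (split tops and
  # count-noise side lobes) before prominence ranking, keeping the taller
  min_sep <- max(min_sep_ms, d$bin_ms + 0.2)
  while (length(pk) >= 2 && any(diff(t[pk]) < min_sep)) {
    j <- which(diff(t[pk]) < min_sep)[1]
    drop <- if (y[pk[j]] >= y[pk[j + 1]]) j + 1L else j
    pk <- pk[-drop]
  }
  if (length(pk)) {
    prom <- .prominence(y, pk)
    pk <- pk[prom >= prominence_frac * max(y[pk])]
  }
  if (length(pk) < 2) return(list(freq_hz = NA_real_,
                                  peak_times_ms = t[pk], n_peaks = length(pk)))
  # parabolic refinement around each peak sample
  pt <- vapply(pk, function(p) {
    if (p <= 1 || p >= length(y)) return(t[p])
    a <- y[p - 1]; b <- y[p]; c <- y[p + 1]
    den <- a - 2 * b + c
    if (den >= 0) return(t[p])
    t[p] + 0.5 * (a - c) / den * d$step_ms
  }, numeric(1))
  list(freq_hz = 1000 / mean(diff(pt)), peak_times_ms = pt,
       n_peaks = length(pt))
}
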