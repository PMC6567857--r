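test_that("quietest segment finds the low-variance span", {
  set.seed(4)
  fs <- 32000
  loud <- rnorm(3 * fs, sd = 10)
  quiet <- rnorm(fs, sd = 1)
  trace <- c(loud[1:(1.5 * fs)], quiet, loud[(1.5 * fs + 1):(3 * fs)])
  q <- quietest_segment(trace, fs)
  expect_equal(q$start_ms, 1500, tolerance = 100)
  expect_equal(q$sd, 1, tolerance = 0.1)

  qz <- quietest_segment(rep(0, fs), fs)
  expect_true(qz$constant)
  expect_equal(qz$sd, 0)

  # homogeneous noise: any span acceptable, sd near the global value
  qh <- quietest_segment(rnorm(4 * fs), fs)
  expect_equal(qh$sd, 1, tolerance = 0.05)

  expect_error(quietest_segment(rnorm(100), fs), "shorter")
})

test_that("spike detection times troughs and obeys threshold monotonicity", {
  set.seed(9)
  fs <- 32000
  geom <- probe_geometry(3, 100)
  n <- 10 * fs
  x <- rnorm(n, sd = 10)
  kern <- lamep:::.spike_kernel(fs)
  t_true <- seq(500, 9500, by = 450)
  amp <- 8 * 10 * sqrt(2 * 4700 / fs)
  for (tt in t_true) {
    i <- round(tt / 1000 * fs) + 1 - (which.min(kern) - 1)
    x[i:(i + length(kern) - 1)] <- x[i:(i + length(kern) - 1)] + amp * kern
  }
  rec <- wideband_recording(cbind(x, 0 * x, 0 * x), fs, geom)
  bp <- bandpass_spike(rec, 300, 5000)
  spk <- detect_spikes(bp)
  expect_equal(length(spk$times_ms[[2]]), 0)  # constant channel flagged
  hits <- vapply(t_true, function(tt) min(abs(spk$times_ms[[1]] - tt)),
                 numeric(1))
  expect_true(all(hits <= 0.5))

  # raising the threshold multiplier never increases the count
  n5 <- length(detect_spikes(bp, threshold_sd = 5)$times_ms[[1]])
  n6 <- length(detect_spikes(bp, threshold_sd = 6)$times_ms[[1]])
  n4 <- length(detect_spikes(bp, threshold_sd = 4)$times_ms[[1]])
  expect_true(n6 <= n5 && n5 <= n4)

  # translation equivariance: shifting the trace shifts every spike time
  shift <- fs %/% 2  # 500 ms
  x2 <- c(rnorm(shift, sd = 10), x)[1:n]
  # same trace content delayed; compare on the overlapping support
  rec2 <- wideband_recording(cbind(x2, 0 * x2, 0 * x2), fs, geom)
  spk2 <- detect_spikes(bandpass_spike(rec2, 300, 5000))
  t1 <- spk$times_ms[[1]]
  t2 <- spk2$times_ms[[1]] - 500
  common <- t1[t1 > 100 & t1 < 9000]
  match_d <- vapply(common, function(tt) min(abs(t2 - tt)), numeric(1))
  expect_true(mean(match_d <= 0.1) > 0.95)

  expect_error(detect_spikes(wideband_recording(matrix(0, 100, 3), fs, geom)),
               "shorter")
})

test_that("spike density follows the sliding-window definition", {
  stim <- stimulus_train(c(1000, 2000), pulse_duration_ms = 10,
                         isi_range_ms = c(1000, 1000))
  spk <- make_spikes(list(c(1010), numeric(0)))
  d <- spike_density(spk, stimulus_train(1000, 10), 1, c(-50, 50))
  near <- abs(d$time_ms - 10) < 0.5
  expect_true(all(d$density[near] == 1.0))
  expect_true(all(d$density[!near & abs(d$time_ms - 10) > 0.6] == 0))

  d0 <- spike_density(make_spikes(list(numeric(0))), stimulus_train(1000, 10),
                      1, c(-50, 50))
  expect_true(all(d0$density == 0))
  expect_error(spike_density(spk, stim, integer(0), c(-50, 50)), "empty")

  # density conservation: step * sum(density) ~ spikes per trial
  set.seed(2)
  times <- sort(runif(400, 900, 1100))
  dcons <- spike_density(make_spikes(list(times)), stimulus_train(1000, 10),
                         1, c(-100, 100))
  total <- dcons$step_ms * sum(dcons$density)
  expect_equal(total, 400, tolerance = 0.01)
})

test_that("constant-rate spikes recover the planted Poisson rate", {
  set.seed(6)
  tg <- seq(0, 99.9, by = 0.1)
  ev <- generate_spike_train(rep(0.05, length(tg)), tg, 500)
  onsets <- 1000 * seq_len(500)
  spk <- make_spikes(list(sort(onsets[ev$trial] + ev$t_ms)))
  d <- spike_density(spk, stimulus_train(onsets, 10), 1, c(10, 90))
  mid <- d$time_ms > 20 & d$time_ms < 80
  expect_equal(mean(d$density[mid]), 0.05, tolerance = 0.1)
})

test_that("MUA metrics extract onset, peaks and slope from the density", {
  # triangular bump peaking exactly on a grid point
  grid <- seq(-200, 100, by = 0.2)
  y <- pmax(0, 1 - abs(grid - 9.4) / 3) * 0.5
  d <- structure(list(time_ms = grid, density = y, n_trials = 100,
                      channels = 1L, bin_ms = 1, step_ms = 0.2),
                 class = "mua_density")
  m <- mua_metrics(d)
  expect_true(m$responded)
  expect_equal(m$first_peak_delay_ms, 9.4)
  expect_equal(m$first_peak_density, 0.5)
  expect_equal(m$max_peak_delay_ms, 9.4)
  expect_equal(m$onset_ms, 6.4, tolerance = 0.25)  # baseline crossing at 9.4 - 3
  expect_equal(m$rising_slope, 0.5 / 3, tolerance = 0.01)

  flat <- d; flat$density <- rep(0, length(grid))
  expect_false(mua_metrics(flat)$responded)

  expect_true(m$onset_ms <= m$first_peak_delay_ms)
  expect_true(m$first_peak_delay_ms <= m$max_peak_delay_ms)
})

test_that("oscillation frequency equals the planted inter-peak interval", {
  grid <- seq(-200, 100, by = 0.2)
  mk_d <- function(centers, amps) {
    y <- rep(0, length(grid))
    for (i in seq_along(centers))
      y <- y + amps[i] * exp(-(grid - centers[i])^2 / (2 * 0.5^2))
    structure(list(time_ms = grid, density = y, n_trials = 100,
                   channels = 1L, bin_ms = 1, step_ms = 0.2),
              class = "mua_density")
  }
  d <- mk_d(c(9.3, 11.8, 14.3, 16.8), c(0.32, 0.56, 0.28, 0.2))
  o <- oscillation_frequency(d, c(8, 18))
  expect_equal(o$n_peaks, 4)
  expect_equal(o$freq_hz, 400, tolerance = 0.01)

  o1 <- oscillation_frequency(mk_d(9.3, 0.5), c(8, 18))
  expect_true(is.na(o1$freq_hz))
  expect_equal(o1$n_peaks, 1)
})
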