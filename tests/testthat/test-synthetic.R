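test_that("component waveform honors amplitude, decay constant and rise time", {
  tg <- seq(0, 600, by = 0.1)
  k <- component_kinetics(7.5, 2.0, 11.1, 100)
  tr <- component_waveform(k, tg)
  expect_true(all(tr[tg <= 7.5] == 0))
  expect_equal(min(tr), -100, tolerance = 1e-6)

  # decay constant: for a slow kernel the trace at peak + tau is close to
  # peak/e (the rise term is negligible there)
  ks <- component_kinetics(8, 3.9, 88.3, 100)
  trs <- component_waveform(ks, tg)
  ip <- which.min(trs)
  v_tau <- -trs[which.min(abs(tg - (tg[ip] + 88.3)))]
  expect_equal(v_tau, 100 / exp(1), tolerance = 0.05)

  # requested 20-80% rise time is realized on the returned trace
  r <- rise_time_2080(tr, tg, 7.5, tg[which.min(tr)])
  expect_equal(r, 2.0, tolerance = 0.11)
  rs <- rise_time_2080(trs, tg, 8, tg[which.min(trs)])
  expect_equal(rs, 3.9, tolerance = 0.11)

  # post-peak decay is exponential with the requested constant
  seg <- tg >= tg[ip] + 30 & tg <= tg[ip] + 200
  fitted <- coef(lm(log(-trs[seg]) ~ tg[seg]))[2]
  expect_equal(-1 / fitted, 88.3, tolerance = 0.01, ignore_attr = TRUE)
})

test_that("fast kernel decays close to baseline within 30 ms of onset", {
  # with rise 2.0 ms and tau 11.1 ms the exact value 30 ms after onset is
  # ~15% of peak; the trace must be at or below that and falling
  tg <- seq(0, 200, by = 0.1)
  tr <- component_waveform(component_kinetics(7.5, 2.0, 11.1, 100), tg)
  frac30 <- -tr[which.min(abs(tg - 37.5))] / 100
  expect_lt(frac30, 0.15)
  expect_lt(-tr[which.min(abs(tg - 60))] / 100, 0.02)
})

test_that("second lobe lands at the configured latency", {
  tg <- seq(0, 600, by = 0.1)
  k <- component_kinetics(8, 3.9, 88.3, 180,
                          second_peak_delay_ms = 46, second_peak_frac = 0.25)
  tr <- component_waveform(k, tg)
  p2 <- find_second_peak(tr, tg, after_ms = 30)
  expect_equal(p2, 46, tolerance = 0.01)
  expect_error(component_kinetics(8, 3.9, 88.3, 180,
                                  second_peak_delay_ms = 46),
               "both")
})

test_that("waveform rejects a grid coarser than the rise time", {
  expect_error(component_waveform(component_kinetics(5, 0.5, 10, 1),
                                  seq(0, 100, by = 1)),
               "resolution")
})

test_that("lfp_from_csd inverts the second-difference operator", {
  geom <- probe_geometry(16, 100)
  # zeros map to zeros
  z <- lfp_from_csd(matrix(0, 14, 5), geom)
  expect_true(all(z == 0))

  # the defining equation holds: -(V[i-1]-2V[i]+V[i+1])/h^2 = C, checked by
  # direct elementwise evaluation (independent of the solver)
  set.seed(42)
  h <- 0.1
  for (rep in 1:20) {
    C <- matrix(rnorm(14 * 7), 14, 7)
    V <- lfp_from_csd(C, geom)
    expect_true(all(V[1, ] == 0) && all(V[16, ] == 0))
    for (i in 2:15) {
      lhs <- -(V[i - 1, ] - 2 * V[i, ] + V[i + 1, ]) / h^2
      expect_lt(max(abs(lhs - C[i - 1, ])), 1e-8)
    }
  }

  # single-channel impulse sink: the potential profile is piecewise linear
  # (tent) in depth on both sides of the source
  C <- matrix(0, 14, 1); C[7, 1] <- 1
  V <- lfp_from_csd(C, geom)[, 1]
  expect_lt(max(abs(diff(diff(V[1:8])))), 1e-9)    # linear above
  expect_lt(max(abs(diff(diff(V[8:16])))), 1e-9)   # linear below
  expect_error(lfp_from_csd(matrix(0, 1, 1), probe_geometry(3)), NA)
})

test_that("spike trains are Poisson with the requested rate and reproducible", {
  tg <- seq(0, 99.9, by = 0.1)
  expect_equal(nrow(generate_spike_train(rep(0, length(tg)), tg, 50)), 0)
  expect_error(generate_spike_train(rep(-1, length(tg)), tg, 1), "negative")

  st <- generate_spike_train(rep(0.01, length(tg)), tg, 1000, seed = 7)
  # expected total = 0.01 spikes/ms * 100 ms * 1000 trials = 1000
  expect_lt(abs(nrow(st) - 1000), 3 * sqrt(1000))
  st2 <- generate_spike_train(rep(0.01, length(tg)), tg, 1000, seed = 7)
  expect_identical(st, st2)
  expect_true(all(st$t_ms >= 0 & st$t_ms < 100))
})

test_that("simulated pair is deterministic and respects the null drug effect", {
  cfg <- quick_sim_config(seed = 5, drug_suppression = 0)
  a <- simulate_pair(cfg)
  b <- simulate_pair(cfg)
  expect_identical(a$control$data, b$control$data)
  # no suppression: the two conditions are bit-identical
  expect_identical(a$control$data, a$drug$data)
  expect_identical(a$truth$spikes_control, a$truth$spikes_drug)
})

test_that("full block leaves only the fast component in the drug LFP", {
  cfg <- quick_sim_config(seed = 5, drug_suppression = 1,
                          noise_sd_uV = 0, lfp_noise_sd_uV = 0,
                          mua_profile = silent_mua_profile())
  sim <- simulate_pair(cfg)
  # drug recording = fast component alone at every channel
  i_on <- round(sim$stim$onsets_ms[1] / 1000 * cfg$fs_hz) + 1
  seg <- i_on:(i_on + nrow(sim$truth$fast_lfp) - 1)
  expect_equal(sim$drug$data[seg, ], sim$truth$fast_lfp, tolerance = 1e-12,
               ignore_attr = TRUE)
  diffmat <- sim$control$data[seg, ] - sim$drug$data[seg, ]
  expect_equal(diffmat, sim$truth$slow_lfp_control, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("ground-truth spike lists match the injected waveform count", {
  cfg <- quick_sim_config(seed = 3)
  sim <- simulate_pair(cfg)
  n_ctrl <- sum(lengths(sim$truth$spikes_control))
  n_drug <- sum(lengths(sim$truth$spikes_drug))
  expect_gt(n_ctrl, n_drug)  # tail thinned away under full suppression
  # every drug spike is one of the control spikes (thinning, shared draws)
  for (ch in seq_along(sim$truth$spikes_drug)) {
    expect_true(all(sim$truth$spikes_drug[[ch]] %in%
                      sim$truth$spikes_control[[ch]]))
  }
  expect_identical(sim$truth$config, cfg)
})

test_that("noiseless control trace peaks where the component mixture predicts", {
  cfg <- quick_sim_config(seed = 2, noise_sd_uV = 0, lfp_noise_sd_uV = 0,
                          mua_profile = silent_mua_profile())
  sim <- simulate_pair(cfg)
  ref <- sim$truth$ref_channel
  mix <- sim$truth$fast_lfp[, ref] + sim$truth$slow_lfp_control[, ref]
  # analytic prediction of the control peak from the two kernels
  tg <- sim$truth$tgrid_ms
  kf <- component_waveform(cfg$fast_kinetics, tg)
  ks <- component_waveform(cfg$slow_kinetics, tg)
  expect_equal(which.min(mix), which.min(kf + ks))
  expect_equal(min(mix), min(kf + ks), tolerance = 1e-9)
})
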