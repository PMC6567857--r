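test_that("subtraction decomposition is exact and additive", {
  tg <- seq(-100, 400, by = 1)
  geom <- probe_geometry(3, 100)
  ctrl_tr <- component_waveform(component_kinetics(7.5, 2, 11.1, 469), tg) +
    component_waveform(component_kinetics(8, 3.9, 88.3, 183, 46, 0.25), tg)
  drug_tr <- component_waveform(component_kinetics(7.5, 2, 11.1, 469), tg)
  ctrl <- make_avg(rbind(ctrl_tr, ctrl_tr, ctrl_tr), tg, geometry = geom)
  drug <- make_avg(rbind(drug_tr, drug_tr, drug_tr), tg, geometry = geom)

  dec <- decompose(ctrl, drug, 2)
  expect_identical(dec$resistant_trace + dec$sensitive_trace,
                   dec$control_trace)
  # sensitive equals the slow component exactly (noiseless, zero baseline)
  slow <- ctrl_tr - drug_tr
  expect_equal(dec$sensitive_trace, slow, tolerance = 1e-12)

  dec0 <- decompose(ctrl, ctrl, 1)
  expect_true(all(dec0$sensitive_trace == 0))

  zero <- make_avg(matrix(0, 3, length(tg)), tg, geometry = geom)
  decf <- decompose(ctrl, zero, 1)
  expect_equal(decf$sensitive_trace, dec$control_trace)

  bad <- make_avg(rbind(drug_tr[-1], drug_tr[-1], drug_tr[-1]), tg[-1],
                  geometry = geom)
  expect_error(decompose(ctrl, bad, 1), "grids")
})

test_that("contributions split the control response and sum to 100", {
  tg <- seq(-100, 400, by = 1)
  dec <- structure(list(time_ms = tg,
                        control_trace = rep(-580, length(tg)),
                        resistant_trace = rep(-400, length(tg)),
                        sensitive_trace = rep(-180, length(tg)),
                        fs_hz = 1000, channel = 1),
                   class = "decomposition_result")
  co <- contribution_at(dec, c(10, 50))
  expect_equal(co$resistant_pct, rep(100 * 400 / 580, 2), tolerance = 1e-9)
  expect_equal(co$resistant_pct + co$sensitive_pct, rep(100, 2))

  dec$resistant_trace <- dec$sensitive_trace <- dec$control_trace / 2
  expect_equal(contribution_at(dec, 20)$resistant_pct, 50)

  dec$control_trace <- rep(0, length(tg))
  expect_true(is.na(contribution_at(dec, 20)$resistant_pct))
})

test_that("20-80% rise time matches closed forms", {
  tg <- seq(0, 50, by = 0.5)
  ramp <- ifelse(tg <= 10, -tg / 10, -1)
  expect_equal(rise_time_2080(ramp, tg, 0, 10), 6.0, tolerance = 1e-6)

  sat <- -(1 - exp(-tg / 5))
  expect_equal(rise_time_2080(sat, tg, 0, 50), 5 * log(4), tolerance = 0.05)

  expect_true(is.na(rise_time_2080(rep(0, length(tg)), tg, 0, 10)))
})

test_that("exponential decay fitting recovers planted constants", {
  tg <- seq(0, 400, by = 1)
  for (tau in c(88.3, 26)) {
    tr <- -120 * exp(-tg / tau)
    f <- fit_exponential_decay(tr, tg, c(0, 350))
    expect_true(f$ok)
    expect_equal(f$tau_ms, tau, tolerance = 1e-3)
    expect_equal(f$amplitude_uV, 120, tolerance = 0.01)
  }

  # 5% noise: median of replicate fits within 5% of truth
  set.seed(17)
  taus <- replicate(40, {
    tr <- -100 * exp(-tg / 88.3) + rnorm(length(tg), sd = 5)
    fit_exponential_decay(tr, tg, c(0, 350))$tau_ms
  })
  expect_equal(median(taus, na.rm = TRUE), 88.3, tolerance = 0.05)

  # non-decaying window flagged
  bad <- fit_exponential_decay(-tg, tg, c(0, 350))
  expect_false(bad$ok)
})

test_that("second-peak search respects the first-event and prominence rules", {
  tg <- seq(0, 200, by = 0.5)
  mono <- -exp(-tg / 50)
  expect_true(is.na(find_second_peak(mono, tg, 30)))

  lobes <- -(exp(-(tg - 40)^2 / 18) * 0.5 + exp(-(tg - 60)^2 / 18) * 0.4 +
               exp(-tg / 30))
  expect_equal(find_second_peak(lobes, tg, 25), 40, tolerance = 0.5)
})

test_that("decomposition commutes with the CSD operator", {
  set.seed(12)
  geom <- probe_geometry(10, 100)
  tg <- seq(-50, 100, by = 1)
  mk <- function() {
    m <- matrix(rnorm(10 * length(tg)), 10)
    make_avg(m, tg, geometry = geom)
  }
  ctrl <- mk(); drug <- mk()
  c1 <- compute_csd(ctrl, c(-50, 0))$data - compute_csd(drug, c(-50, 0))$data
  diffavg <- make_avg(ctrl$data - drug$data, tg, geometry = geom)
  c2 <- compute_csd(diffavg, c(-50, 0))$data
  expect_equal(c1, c2, tolerance = 1e-9)
})

test_that("component kinetics wrapper summarizes a slow component", {
  tg <- seq(-200, 599, by = 1)
  tr <- component_waveform(component_kinetics(8, 3.9, 88.3, 183, 46, 0.25), tg)
  k <- component_kinetics_measured(tr, tg, c(3, 100), 30)
  expect_lt(abs(k$onset_ms - 8), 0.5)
  expect_equal(k$rise_2080_ms, 3.9, tolerance = 0.1)
  expect_equal(k$second_peak_ms, 46, tolerance = 1)
  expect_true(k$decay_fit$ok)
  expect_equal(k$decay_fit$tau_ms, 88.3, tolerance = 0.02)
})
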