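test_that("CSD annihilates depth-affine profiles and matches closed forms", {
  geom <- probe_geometry(16, 100)
  tg <- seq(-100, 100, by = 1)
  nt <- length(tg)
  z <- geom$channel_depths_um

  # linear in depth at every time point -> identically zero
  a <- runif(nt, -2, 2); b <- runif(nt, -50, 50)
  lin <- outer(z, a) + matrix(b, 16, nt, byrow = TRUE)
  csd <- compute_csd(make_avg(lin, tg, geometry = geom), c(-100, 0))
  expect_lt(max(abs(csd$data)), 1e-9)

  # quadratic in depth appearing at stimulus time: constant interior CSD
  # equal to the analytic second difference
  quad <- outer(z^2, as.numeric(tg >= 0))
  csd2 <- compute_csd(make_avg(quad, tg, geometry = geom), c(-100, 0))
  h_mm <- 0.1
  expected <- -2 * 100^2 / h_mm^2   # negated second difference of z^2
  expect_lt(max(abs(csd2$data[, tg >= 0] - expected)), 1e-6)
  expect_lt(max(abs(csd2$data[, tg < 0])), 1e-9)
  expect_equal(nrow(csd2$data), 14)
  expect_equal(csd2$depth_um, z[2:15])
})

test_that("CSD is linear and invariant to adding depth-affine fields", {
  set.seed(3)
  geom <- probe_geometry(8, 100)
  tg <- seq(-50, 50, by = 1)
  nt <- length(tg)
  x <- matrix(rnorm(8 * nt), 8, nt)
  y <- matrix(rnorm(8 * nt), 8, nt)
  f <- function(m) compute_csd(make_avg(m, tg, geometry = geom), c(-50, 0))$data
  expect_equal(f(x + 2 * y), f(x) + 2 * f(y), tolerance = 1e-9)

  aff <- outer(geom$channel_depths_um, rnorm(nt)) +
    matrix(rnorm(nt), 8, nt, byrow = TRUE)
  expect_equal(f(x + aff), f(x), tolerance = 1e-8)
})

test_that("CSD round-trips with the generator's forward model", {
  set.seed(8)
  geom <- probe_geometry(16, 100)
  tg <- seq(-100, 100, by = 1)
  C <- matrix(rnorm(14 * length(tg)), 14)
  C[, tg < 0] <- 0   # quiet baseline so baseline subtraction is a no-op
  V <- lfp_from_csd(C, geom)
  csd <- compute_csd(make_avg(V, tg, geometry = geom), c(-100, 0))
  expect_lt(max(abs(csd$data - C)), 1e-9)
})

test_that("spatial up-interpolation honors the native nodes exactly", {
  geom <- probe_geometry(8, 100)
  tg <- seq(-20, 20, by = 1)
  C <- matrix(rnorm(6 * length(tg)), 6)
  V <- lfp_from_csd(C, geom)
  csd <- compute_csd(make_avg(V, tg, geometry = geom), c(-20, 0))
  up <- interpolate_csd(csd, factor = 4)
  native <- match(csd$depth_um, up$depth_um)
  expect_equal(up$data[native, ], csd$data, ignore_attr = TRUE)
})

test_that("sink onset applies the SEP rule to CSD rows", {
  tg <- seq(-100, 100, by = 1)
  mk_sink <- function(onset, amp = 1) {
    k <- component_waveform(component_kinetics(onset, 2, 11.1, amp), tg)
    k
  }
  row <- mk_sink(7.5, 1000)
  expect_lt(abs(sink_onset(row, tg) - 7.5), 1)
  expect_true(is.na(sink_onset(rep(0, length(tg)), tg)))
  # two sinks: the earliest is returned
  two <- mk_sink(8, 800) + mk_sink(20, 1000)
  expect_lt(abs(sink_onset(two, tg) - 8), 1.5)
})

test_that("layer assignment finds L4 at the earliest deep sink", {
  geom <- probe_geometry(16, 100)
  tg <- seq(-100, 200, by = 1)
  z_int <- geom$channel_depths_um[2:15]
  fast <- component_waveform(component_kinetics(7.5, 2, 11.1, 1), tg)
  slow <- component_waveform(component_kinetics(8.5, 3.9, 88.3, 0.6), tg)
  C <- outer(exp(-(z_int - 620)^2 / (2 * 100^2)), fast) +
    outer(exp(-(z_int - 360)^2 / (2 * 100^2)), slow)
  V <- lfp_from_csd(C * 1e4, geom)
  csd <- compute_csd(make_avg(V, tg, geometry = geom), c(-100, 0))
  lay <- assign_layers(csd)
  expect_equal(lay$l4_channels, c(7, 8))  # 600 and 700 um
  expect_true(abs(lay$depths_um[lay$l23_mid_channel] - 360) <= 100)
  expect_true(all(lay$depths_um[lay$l23_channels] > 100))
  expect_true(all(lay$depths_um[lay$l23_channels] <
                    min(lay$depths_um[lay$l4_channels]) - 100))
  expect_true(length(lay$l23_channels) >= 2 && length(lay$l23_channels) <= 3)

  # MUA onsets can sharpen the choice; equal-latency case stays at 600/700
  on <- rep(NA_real_, 14); on[z_int %in% c(600, 700)] <- 6
  lay2 <- assign_layers(csd, mua_onsets_ms = on)
  expect_equal(lay2$l4_channels, c(7, 8))
})

test_that("degenerate sink geometry raises an assignment error", {
  geom <- probe_geometry(16, 100)
  tg <- seq(-100, 200, by = 1)
  fast <- component_waveform(component_kinetics(7.5, 2, 11.1, 1000), tg)
  C <- matrix(0, 14, length(tg))
  C[1, ] <- fast   # only the most superficial interior channel has a sink
  V <- lfp_from_csd(C, geom)
  csd <- compute_csd(make_avg(V, tg, geometry = geom), c(-100, 0))
  expect_error(assign_layers(csd), "assignment|supragranular|sink")
})

test_that("equal-latency candidate pairs break toward the expected depth", {
  geom <- probe_geometry(16, 100)
  tg <- seq(-100, 200, by = 1)
  z_int <- geom$channel_depths_um[2:15]
  k <- component_waveform(component_kinetics(7.5, 2, 11.1, 1), tg)
  # two identical sinks, centered at 750 (near expected 600) and at 200
  C <- outer(exp(-(z_int - 750)^2 / (2 * 60^2)), k) +
    outer(exp(-(z_int - 200)^2 / (2 * 60^2)), k)
  V <- lfp_from_csd(C * 1e4, geom)
  csd <- compute_csd(make_avg(V, tg, geometry = geom), c(-100, 0))
  lay <- assign_layers(csd)
  expect_true(all(lay$depths_um[lay$l4_channels] %in% c(700, 800)))
})
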