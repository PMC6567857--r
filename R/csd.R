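# One-dimensional current-source-density mapping and layer assignment.

# baseline-to-trough sink amplitude per interior channel
.sink_amplitudes <- function(csd, baseline_window_ms, search_window_ms) {
  t <- csd$time_ms
  sw <- t >= search_window_ms[1] & t < search_window_ms[2]
  bl <- t >= baseline_window_ms[1] & t < baseline_window_ms[2]
  vapply(seq_len(nrow(csd$data)), function(i)
    mean(csd$data[i, bl]) - min(csd$data[i, sw]), numeric(1))
}

#' Compute the current-source-density map
#'
#' Per-channel baseline (mean of the averaged LFP over `baseline_window_ms`)
#' is subtracted first; the CSD at each interior channel is the negated
#' second spatial difference, `-(V[i-1] - 2 V[i] + V[i+1]) / h^2` with `h`
#' the inter-site spacing in mm, so current sinks (local extracellular
#' negativity) appear as negative values. The top and bottom sites are
#' excluded.
#'
#' @param avg An `evoked_average` with >= 3 uniformly spaced channels.
#' @param baseline_window_ms Baseline window (default `c(-1000, 0)` ms;
#'   clipped to the available pre-stimulus span).
#' @param sink_negative If `FALSE`, flips the sign convention.
#' @return Object of class `csd_map`: list with `data` (interior channels x
#'   time), `depth_um`, `time_ms`, `fs_hz`, `baseline_window_ms`.
#' @export
compute_csd <- function(avg, baseline_window_ms = c(-1000, 0),
                        sink_negative = TRUE) {
  geom <- avg$geometry
  n <- nrow(avg$data)
  if (n < 3) stop("compute_csd: need at least 3 channels")
  dz <- diff(geom$channel_depths_um)
  if (max(dz) - min(dz) > 1e-6 * max(dz))
    stop("compute_csd: channel spacing must be uniform")
  t <- avg$time_ms
  bl <- t >= baseline_window_ms[1] & t < baseline_window_ms[2]
  if (!any(bl)) stop("compute_csd: no samples in the baseline window")
  v <- avg$data - rowMeans(avg$data[, bl, drop = FALSE])
  h <- geom$spacing_um / 1000  # mm
  i <- 2:(n - 1)
  csd <- -(v[i - 1, , drop = FALSE] - 2 * v[i, , drop = FALSE] +
             v[i + 1, , drop = FALSE]) / h^2
  if (!sink_negative) csd <- -csd
  structure(list(data = csd, depth_um = geom$channel_depths_um[i],
                 time_ms = t, fs_hz = avg$fs_hz,
                 baseline_window_ms = baseline_window_ms,
                 sink_negative = sink_negative),
            class = "csd_map")
}

#' Spatially up-interpolated CSD map for display
#'
#' Linear interpolation along depth; the original node values are honored
#' exactly. Display helper only - analysis always runs on native channels.
#'
#' @param csd A `csd_map`.
#' @param factor Integer up-sampling factor along depth.
#' @return A `csd_map` with interpolated rows.
#' @export
interpolate_csd <- function(csd, factor = 4) {
  z <- csd$depth_um
  zi <- seq(z[1], z[length(z)], length.out = (length(z) - 1) * factor + 1)
  out <- apply(csd$data, 2, function(col) stats::approx(z, col, xout = zi)$y)
  structure(list(data = out, depth_um = zi, time_ms = csd$time_ms,
                 fs_hz = csd$fs_hz, baseline_window_ms = csd$baseline_window_ms,
                 sink_negative = csd$sink_negative),
            class = "csd_map")
}

#' @export
plot.csd_map <- function(x, xlim = NULL, ...) {
  d <- x$data
  zl <- max(abs(d))
  cols <- grDevices::hcl.colors(65, "RdBu")
  graphics::image(x$time_ms, x$depth_um, t(d), zlim = c(-zl, zl), col = cols,
                  xlab = "time (ms)", ylab = "depth (um)", xlim = xlim,
                  ylim = rev(range(x$depth_um)), ...)
  graphics::abline(v = 0, lty = 3)
  invisible(x)
}

#' Sink onset latency of one CSD row
#'
#' Applies the same back-tracked baseline-crossing rule as [detect_sep()] to
#' the negative-going CSD deflection of a single depth.
#'
#' @param csd_row Numeric vector (one row of a `csd_map`).
#' @param time_ms Matching time grid (ms).
#' @param baseline_window_ms,search_window_ms Analysis windows (ms).
#' @param criterion_sd Depth criterion in baseline SDs (default 4).
#' @return Onset latency in ms, or `NA` when no qualifying sink excursion
#'   exists.
#' @export
sink_onset <- function(csd_row, time_ms, baseline_window_ms = c(-100, 0),
                       search_window_ms = c(3, 50), criterion_sd = 4) {
  fs <- 1000 / (time_ms[2] - time_ms[1])
  fake <- structure(list(data = matrix(csd_row, nrow = 1), time_ms = time_ms,
                         fs_hz = fs, n_trials = 1, geometry = NULL),
                    class = "evoked_average")
  m <- detect_sep(fake, 1, search_window_ms, baseline_window_ms, criterion_sd)
  if (!m$responded) NA_real_ else m$onset_ms
}

#' Assign probe channels to cortical layers
#'
#' L4 is taken as the two adjacent interior channels nearest the expected
#' granular depth carrying the earliest sink onsets (ties broken toward the
#' expected depth); short-latency multi-unit onsets, when supplied, are
#' averaged into the same earliness score. L2/3 comprises the channels
#' deeper than 100 um below the surface and more than 100 um above the
#' shallowest L4 channel.
#'
#' @param csd A `csd_map`.
#' @param mua_onsets_ms Optional per-interior-channel MUA onset latencies
#'   (ms, NA allowed), same order as `csd$depth_um`.
#' @param expected_l4_depth_um Expected granular-layer depth (default 600).
#' @param baseline_window_ms,search_window_ms Windows for [sink_onset()].
#' @param geometry The full [probe_geometry()] (for surface-referenced
#'   depths); defaults to reconstructing depths from the map.
#' @return Object of class `layer_assignment`: list with `l4_channels`,
#'   `l23_channels`, `l23_mid_channel` (all indices into the full channel
#'   set), `depths_um`, `sink_onsets_ms`.
#' @export
assign_layers <- function(csd, mua_onsets_ms = NULL,
                          expected_l4_depth_um = 600,
                          baseline_window_ms = c(-100, 0),
                          search_window_ms = c(3, 50),
                          geometry = NULL) {
  z <- csd$depth_um
  spacing <- z[2] - z[1]
  t <- csd$time_ms
  # sink amplitude per channel; only channels carrying a substantial sink
  # (>= 25% of the map maximum) are latency-ranked, so noise-only channels
  # cannot contaminate the assignment
  amp <- .sink_amplitudes(csd, baseline_window_ms, search_window_ms)
  qualified <- amp >= 0.25 * max(amp)
  onsets <- rep(NA_real_, length(z))
  onsets[qualified] <- vapply(which(qualified), function(i)
    sink_onset(csd$data[i, ], t, baseline_window_ms,
               search_window_ms), numeric(1))
  if (all(is.na(onsets)))
    stop("assign_layers: no sink detected on any channel")
  score <- onsets
  if (!is.null(mua_onsets_ms)) {
    if (length(mua_onsets_ms) != length(z))
      stop("assign_layers: mua_onsets_ms must match the interior channels")
    mo <- mua_onsets_ms
    mo[!qualified] <- NA_real_   # spike latency refines sink channels only
    score <- rowMeans(cbind(onsets, mo), na.rm = TRUE)
    score[is.na(onsets)] <- NA_real_
  }
  # candidate adjacent pairs with defined onsets
  pairs <- which(!is.na(score[-length(score)]) & !is.na(score[-1]))
  if (!length(pairs)) stop("assign_layers: no adjacent channel pair with sinks")
  pair_score <- (score[pairs] + score[pairs + 1]) / 2
  pair_depth <- (z[pairs] + z[pairs + 1]) / 2
  pair_amp <- (amp[pairs] + amp[pairs + 1]) / 2
  best <- which(pair_score <= min(pair_score) + 0.5)  # earliest, 0.5 ms tol
  # ties toward the expected depth, then toward the strongest sink
  o <- order(abs(pair_depth[best] - expected_l4_depth_um), -pair_amp[best])
  i4 <- pairs[best[o[1]]]
  # map interior indices back to full-probe channel indices (+1 offset)
  l4 <- c(i4, i4 + 1L) + 1L
  surface_z <- z[1] - spacing  # depth of the excluded top site
  full_z <- c(surface_z, z, z[length(z)] + spacing)
  l4_top_z <- full_z[l4[1]]
  l23 <- which(full_z - full_z[1] > 100 & full_z < l4_top_z - 100)
  if (!length(l23))
    stop("assign_layers: no supragranular channels left above L4 ",
         sprintf("(L4 starts at %g um)", l4_top_z))
  if (length(l23) > 3) l23 <- l23[(length(l23) - 2):length(l23)]
  mid <- l23[ceiling((length(l23) + 1) / 2)]
  structure(list(l4_channels = l4, l23_channels = l23, l23_mid_channel = mid,
                 depths_um = full_z, sink_onsets_ms = onsets),
            class = "layer_assignment")
}

#' @export
print.layer_assignment <- function(x, ...) {
  cat(sprintf("layer_assignment: L4 channels %s (%s um), L2/3 channels %s (mid %d)\n",
              paste(x$l4_channels, collapse = ","),
              paste(x$depths_um[x$l4_channels], collapse = ","),
              paste(x$l23_channels, collapse = ","),
              x$l23_mid_channel))
  invisible(x)
}
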