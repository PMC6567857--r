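#' Linear probe geometry
#'
#' Describes a linear (laminar) multi-site probe: number of recording sites,
#' inter-site spacing and the cortical depth of every site. Depths are
#' measured in micrometres below the pial surface and increase downward;
#' channel 1 is the most superficial site.
#'
#' @param n_channels Number of recording sites (>= 3).
#' @param spacing_um Inter-site spacing in micrometres (> 0).
#' @param tip_depth_um Depth of the deepest site in micrometres. The site
#'   depths are derived as `tip_depth_um - spacing_um * (n_channels - 1):0`
#'   unless `channel_depths_um` is given explicitly.
#' @param channel_depths_um Optional explicit per-channel depths (strictly
#'   increasing, micrometres).
#'
#' @return An object of class `probe_geometry` with fields `n_channels`,
#'   `spacing_um`, `tip_depth_um`, `channel_depths_um`.
#' @examples
#' probe_geometry(16, 100, 1500)
#' @export
probe_geometry <- function(n_channels = 16, spacing_um = 100,
                           tip_depth_um = spacing_um * (n_channels - 1),
                           channel_depths_um = NULL) {
  n_channels <- as.integer(n_channels)
  if (n_channels < 3) stop("probe_geometry: n_channels must be >= 3")
  if (spacing_um <= 0) stop("probe_geometry: spacing_um must be > 0")
  if (is.null(channel_depths_um)) {
    channel_depths_um <- tip_depth_um - spacing_um * ((n_channels - 1):0)
  }
  if (length(channel_depths_um) != n_channels)
    stop("probe_geometry: one depth per channel required")
  if (any(diff(channel_depths_um) <= 0))
    stop("probe_geometry: channel depths must be strictly increasing (downward)")
  structure(list(n_channels = n_channels, spacing_um = spacing_um,
                 tip_depth_um = channel_depths_um[n_channels],
                 channel_depths_um = as.numeric(channel_depths_um)),
            class = "probe_geometry")
}

#' Wideband multichannel recording
#'
#' Container for a raw extracellular recording: a samples x channels matrix
#' of potentials in microvolts, the sampling rate and the probe geometry.
#'
#' @param data Numeric matrix, samples in rows, channels in columns (uV).
#' @param fs_hz Sampling rate in Hz.
#' @param geometry A [probe_geometry()].
#' @param t0_ms Time of the first sample in milliseconds (default 0).
#' @return Object of class `wideband_recording`.
#' @export
wideband_recording <- function(data, fs_hz, geometry, t0_ms = 0) {
  data <- as.matrix(data)
  if (fs_hz <= 0) stop("wideband_recording: fs_hz must be > 0")
  if (ncol(data) != geometry$n_channels)
    stop("wideband_recording: column count must equal geometry$n_channels")
  if (nrow(data) > 0 && !all(is.finite(data)))
    stop("wideband_recording: data must be finite")
  structure(list(data = data, fs_hz = fs_hz, geometry = geometry,
                 t0_ms = t0_ms),
            class = "wideband_recording")
}

#' @export
print.wideband_recording <- function(x, ...) {
  cat(sprintf("wideband_recording: %d samples x %d channels @ %g Hz (%.2f s)\n",
              nrow(x$data), ncol(x$data), x$fs_hz, nrow(x$data) / x$fs_hz))
  cat(sprintf("  depths %g..%g um, t0 = %g ms\n",
              x$geometry$channel_depths_um[1],
              x$geometry$tip_depth_um, x$t0_ms))
  invisible(x)
}

#' Stimulus train
#'
#' Ordered stimulus-onset times with pulse metadata.
#'
#' @param onsets_ms Strictly increasing onset times (ms).
#' @param pulse_duration_ms Stimulus pulse duration (ms).
#' @param isi_range_ms Length-2 numeric, nominal (min, max) inter-stimulus
#'   interval (ms).
#' @return Object of class `stimulus_train`.
#' @export
stimulus_train <- function(onsets_ms, pulse_duration_ms = 200,
                           isi_range_ms = c(5000, 10000)) {
  onsets_ms <- as.numeric(onsets_ms)
  if (length(onsets_ms) > 1) {
    d <- diff(onsets_ms)
    if (any(d <= 0)) stop("stimulus_train: onsets must be strictly increasing")
    if (any(d < pulse_duration_ms))
      stop("stimulus_train: inter-stimulus interval shorter than pulse duration")
  }
  structure(list(onsets_ms = onsets_ms, pulse_duration_ms = pulse_duration_ms,
                 isi_range_ms = isi_range_ms),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("stimulus_train: %d onsets, pulse %g ms\n",
              length(x$onsets_ms), x$pulse_duration_ms))
  invisible(x)
}

# ---- flat binary recording container -------------------------------------
# <stem>.bin : little-endian, sample-major (all channels of sample i
#              contiguous), float32 or int16 (+ scale_uv_per_count)
# <stem>.meta: plain-text "key: value" sidecar

.meta_required <- c("fs_hz", "n_channels", "dtype", "channel_depths_um")

.write_meta <- function(path, kv) {
  lines <- vapply(names(kv), function(k) paste0(k, ": ", kv[[k]]), "")
  writeLines(lines, path)
}

.read_meta <- function(path) {
  if (!file.exists(path)) stop("missing sidecar file: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^([^:]+):\\s*(.*)$", lines))
  if (any(lengths(m) != 3)) stop("malformed sidecar line in ", path)
  kv <- lapply(m, `[`, 3)
  names(kv) <- trimws(vapply(m, `[`, "", 2))
  kv
}

#' Read a flat binary recording
#'
#' Reads a sample-major little-endian binary file (`float32`, or `int16`
#' with a declared scale in uV per count) together with its plain-text
#' sidecar, and returns the data scaled to microvolts.
#'
#' @param path_data Path to the `.bin` payload.
#' @param path_meta Path to the `.meta` sidecar; defaults to `path_data`
#'   with extension replaced by `.meta`.
#' @return A [wideband_recording()].
#' @export
read_recording <- function(path_data,
                           path_meta = sub("\\.[^.]*$", ".meta", path_data)) {
  kv <- .read_meta(path_meta)
  missing <- setdiff(.meta_required, names(kv))
  if (length(missing))
    stop("sidecar missing required key(s): ", paste(missing, collapse = ", "))
  fs <- as.numeric(kv$fs_hz)
  nch <- as.integer(kv$n_channels)
  dtype <- trimws(kv$dtype)
  depths <- as.numeric(strsplit(kv$channel_depths_um, ",")[[1]])
  if (length(depths) != nch) stop("sidecar depth count != n_channels")
  t0 <- if (!is.null(kv$t0_ms)) as.numeric(kv$t0_ms) else 0
  width <- switch(dtype, float32 = 4L, int16 = 2L,
                  stop("unsupported dtype: ", dtype))
  nbytes <- file.size(path_data)
  if (is.na(nbytes)) stop("missing data file: ", path_data)
  frame <- width * nch
  if (nbytes %% frame != 0)
    stop(sprintf("data size %d bytes is not a multiple of the %d-byte frame",
                 nbytes, frame))
  nsamp <- nbytes %/% frame
  con <- file(path_data, "rb"); on.exit(close(con))
  if (dtype == "float32") {
    raw <- readBin(con, "numeric", n = nsamp * nch, size = 4, endian = "little")
  } else {
    scale <- if (!is.null(kv$scale_uv_per_count))
      as.numeric(kv$scale_uv_per_count) else
      stop("sidecar missing required key(s): scale_uv_per_count")
    raw <- readBin(con, "integer", n = nsamp * nch, size = 2, signed = TRUE,
                   endian = "little") * scale
  }
  # sample-major on disk -> fill a channels x samples matrix, then transpose
  data <- t(matrix(raw, nrow = nch, ncol = nsamp))
  geom <- probe_geometry(nch,
                         spacing_um = if (nch > 1) stats::median(diff(depths)) else 1,
                         channel_depths_um = depths)
  wideband_recording(data, fs, geom, t0_ms = t0)
}

#' Write a flat binary recording
#'
#' Inverse of [read_recording()]; the round trip is bit-exact for the
#' declared sample width (`float32` stores the float32 rounding of the data,
#' `int16` stores `round(uV / scale)` counts).
#'
#' @param rec A [wideband_recording()].
#' @param path_data,path_meta Output paths.
#' @param dtype `"float32"` (default) or `"int16"`.
#' @param scale_uv_per_count Scale used for `int16` storage.
#' @return Invisibly, `path_data`.
#' @export
write_recording <- function(rec, path_data,
                            path_meta = sub("\\.[^.]*$", ".meta", path_data),
                            dtype = c("float32", "int16"),
                            scale_uv_per_count = 0.195) {
  dtype <- match.arg(dtype)
  if (nrow(rec$data) > 0 && !all(is.finite(rec$data)))
    stop("write_recording: data contains non-finite values")
  kv <- list(fs_hz = format(rec$fs_hz, digits = 17),
             n_channels = rec$geometry$n_channels,
             dtype = dtype,
             channel_depths_um = paste(format(rec$geometry$channel_depths_um,
                                              digits = 17, trim = TRUE),
                                       collapse = ","),
             t0_ms = format(rec$t0_ms, digits = 17))
  flat <- as.vector(t(rec$data))  # sample-major
  con <- file(path_data, "wb")
  if (dtype == "float32") {
    writeBin(flat, con, size = 4, endian = "little")
  } else {
    kv$scale_uv_per_count <- format(scale_uv_per_count, digits = 17)
    counts <- as.integer(round(flat / scale_uv_per_count))
    if (length(counts) && max(abs(counts)) > 32767L) {
      close(con)
      stop("write_recording: int16 overflow at this scale")
    }
    writeBin(counts, con, size = 2, endian = "little")
  }
  close(con)
  .write_meta(path_meta, kv)
  invisible(path_data)
}

#' Read a stimulus-onset list
#'
#' One onset time (ms) per line. Onsets are sorted ascending; duplicate
#' times are rejected.
#'
#' @param path Path to the text file.
#' @param pulse_duration_ms,isi_range_ms Metadata passed to
#'   [stimulus_train()].
#' @return A [stimulus_train()].
#' @export
read_stimulus_train <- function(path, pulse_duration_ms = 200,
                                isi_range_ms = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  vals <- suppressWarnings(as.numeric(lines))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("read_stimulus_train: cannot parse line %d: '%s'",
                 bad, lines[bad]))
  }
  vals <- sort(vals)
  if (anyDuplicated(vals))
    stop("read_stimulus_train: duplicate onset time")
  if (is.null(isi_range_ms))
    isi_range_ms <- if (length(vals) > 1) range(diff(vals)) else c(NA_real_, NA_real_)
  stimulus_train(vals, pulse_duration_ms = pulse_duration_ms,
                 isi_range_ms = isi_range_ms)
}

#' Write a stimulus-onset list
#' @param stim A [stimulus_train()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_stimulus_train <- function(stim, path) {
  writeLines(format(stim$onsets_ms, digits = 17, trim = TRUE, scientific = FALSE),
             path)
  invisible(path)
}

# ---- analysis configuration ----------------------------------------------

#' Default analysis configuration
#'
#' Named list of every tunable parameter of the pipeline, with defaults.
#' Times are milliseconds, frequencies Hz, amplitudes microvolts.
#'
#' @param ... Overrides as `name = value` pairs.
#' @return Object of class `analysis_config` (a named list).
#' @details Key parameters: `lfp_rate_hz` LFP sampling rate after
#'   downsampling (1000); `spike_band_hz` band edges for spike detection
#'   (300, 5000); `spike_threshold_sd` threshold multiplier on the noise SD
#'   of the quietest segment (5); `spike_dead_time_ms` refractory dead time
#'   after a detected spike (1); `mua_bin_ms`/`mua_step_ms` sliding-window
#'   spike-density parameters (1, 0.2); `epochs_ms` post-stimulus epoch
#'   boundaries (5, 8, 10, 20, 50, 100); `window_ms` trial-alignment window.
#' @export
analysis_config <- function(...) {
  cfg <- list(
    lfp_rate_hz = 1000,
    spike_band_hz = c(300, 5000),
    spike_threshold_sd = 5,
    spike_dead_time_ms = 1,
    quiet_span_ms = 1000,
    quiet_step_ms = 100,
    window_ms = c(-200, 600),
    baseline_window_ms = c(-200, 0),
    sep_search_ms = c(3, 50),
    sep_trough_criterion_sd = 4,
    csd_baseline_ms = c(-200, 0),
    csd_sink_negative = TRUE,
    mua_bin_ms = 1,
    mua_step_ms = 0.2,
    mua_search_ms = c(3, 50),
    mua_onset_criterion_sd = 3,
    osc_window_ms = 8,
    osc_prominence_frac = 0.20,
    epochs_ms = c(5, 8, 10, 20, 50, 100),
    spont_window_ms = c(-200, 0),
    expected_l4_depth_um = 600,
    second_peak_after_ms = 30,
    second_peak_prominence_frac = 0.10,
    contrib_at_ms = c(10.5, 12.6, 14.3, 17.5, 46),
    firing_probability = 0.2,
    seed = 1L
  )
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config parameter(s): ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  structure(cfg, class = "analysis_config")
}

#' Write an analysis configuration
#'
#' Plain-text `key = value` document; numeric vectors are comma-separated.
#' The round trip through [read_analysis_config()] is lossless.
#'
#' @param cfg An [analysis_config()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_analysis_config <- function(cfg, path) {
  lines <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    paste0(k, " = ", paste(format(v, digits = 17, trim = TRUE), collapse = ","))
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read an analysis configuration
#' @param path Path to a file written by [write_analysis_config()].
#' @return An [analysis_config()].
#' @export
read_analysis_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  m <- regmatches(lines, regexec("^([^=]+)=(.*)$", lines))
  if (any(lengths(m) != 3)) stop("malformed config line in ", path)
  keys <- trimws(vapply(m, `[`, "", 2))
  vals <- lapply(m, function(x) {
    v <- strsplit(trimws(x[3]), ",")[[1]]
    if (all(v %in% c("TRUE", "FALSE"))) return(as.logical(v))
    num <- suppressWarnings(as.numeric(v))
    if (anyNA(num)) v else num
  })
  names(vals) <- keys
  do.call(analysis_config, vals)
}

#' Write a metric table as TSV
#'
#' All result tables are tab-delimited text with a header row.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_table_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a metric table written by [write_table_tsv()]
#' @param path Path to the TSV.
#' @return A data frame.
#' @export
read_table_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", check.names = FALSE)
}
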