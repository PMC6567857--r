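# End-to-end orchestration: preprocess -> layers -> SEP/CSD/MUA -> epochs ->
# decomposition -> report, with a machine-readable run manifest.

# band-pass and threshold-detect spikes on a channel subset, returning a
# full-width spike_times object (undetected channels stay empty/NA)
.detect_on <- function(rec, chans, cfg) {
  sub <- structure(list(data = rec$data[, chans, drop = FALSE],
                        fs_hz = rec$fs_hz,
                        geometry = list(n_channels = length(chans)),
                        t0_ms = rec$t0_ms),
                   class = "wideband_recording")
  bp <- bandpass_spike(sub, cfg$spike_band_hz[1], cfg$spike_band_hz[2])
  detect_spikes(bp, cfg$spike_threshold_sd, cfg$spike_dead_time_ms,
                cfg$quiet_span_ms, cfg$quiet_step_ms)
}

# analyze one condition; layers may be supplied (e.g. reuse control layers)
.analyze_condition <- function(rec, stim, cfg, layers = NULL) {
  lfp <- downsample_lfp(rec, cfg$lfp_rate_hz)
  stack <- align_trials(lfp, stim, cfg$window_ms)
  avg <- average_evoked(stack)
  csd <- compute_csd(avg, cfg$csd_baseline_ms,
                     sink_negative = isTRUE(cfg$csd_sink_negative))
  nch <- rec$geometry$n_channels
  interior <- 2:(nch - 1)
  # spike detection is restricted to channels carrying a qualified sink
  # (>= 25% of the map maximum) plus any already-assigned layer channels;
  # the remaining sites contribute no MUA to any downstream stage
  amp <- .sink_amplitudes(csd, cfg$baseline_window_ms, cfg$sep_search_ms)
  det_ch <- which(amp >= 0.25 * max(amp)) + 1L
  if (!is.null(layers))
    det_ch <- sort(union(det_ch, c(layers$l23_channels, layers$l4_channels)))
  det <- .detect_on(rec, det_ch, cfg)
  spikes <- structure(list(times_ms = rep(list(numeric(0)), nch),
                           threshold_uV = rep(NA_real_, nch),
                           noise_sd_uV = rep(NA_real_, nch),
                           fs_hz = rec$fs_hz),
                      class = "spike_times")
  spikes$times_ms[det_ch] <- det$times_ms
  spikes$threshold_uV[det_ch] <- det$threshold_uV
  spikes$noise_sd_uV[det_ch] <- det$noise_sd_uV
  # per-channel onset screening uses a stricter criterion (5 SD) than the
  # layer-pooled metrics so spontaneous-only channels rarely pass
  ch_onsets <- vapply(interior, function(ch) {
    if (!(ch %in% det_ch)) return(NA_real_)
    d <- spike_density(spikes, stim, ch, cfg$window_ms,
                       cfg$mua_bin_ms, cfg$mua_step_ms)
    m <- mua_metrics(d, cfg$baseline_window_ms, cfg$mua_search_ms,
                     max(5, cfg$mua_onset_criterion_sd))
    if (m$responded) m$onset_ms else NA_real_
  }, numeric(1))
  if (is.null(layers))
    layers <- assign_layers(csd, ch_onsets, cfg$expected_l4_depth_um,
                            cfg$baseline_window_ms, cfg$sep_search_ms)
  need <- setdiff(c(layers$l23_channels, layers$l4_channels), det_ch)
  if (length(need)) {
    extra <- .detect_on(rec, need, cfg)
    spikes$times_ms[need] <- extra$times_ms
    spikes$threshold_uV[need] <- extra$threshold_uV
    spikes$noise_sd_uV[need] <- extra$noise_sd_uV
  }
  layer_results <- lapply(list(l23 = layers$l23_channels,
                               l4 = layers$l4_channels), function(chs) {
    d <- spike_density(spikes, stim, chs, cfg$window_ms,
                       cfg$mua_bin_ms, cfg$mua_step_ms)
    m <- mua_metrics(d, cfg$baseline_window_ms, cfg$mua_search_ms,
                     cfg$mua_onset_criterion_sd)
    osc <- if (m$responded)
      oscillation_frequency(d, c(m$onset_ms, m$onset_ms + cfg$osc_window_ms),
                            cfg$osc_prominence_frac)
    else list(freq_hz = NA_real_, n_peaks = 0L)
    er <- epoch_rates(spikes, stim, chs, epoch_definition(cfg$epochs_ms),
                      cfg$spont_window_ms)
    list(density = d, metrics = m, osc = osc, epochs = er)
  })
  sep <- detect_sep(avg, layers$l23_mid_channel, cfg$sep_search_ms,
                    cfg$baseline_window_ms, cfg$sep_trough_criterion_sd)
  amp50 <- amplitude_at(avg, layers$l23_mid_channel, 50,
                        cfg$baseline_window_ms)
  list(avg = avg, csd = csd, spikes = spikes, layers = layers,
       channel_onsets = ch_onsets, sep = sep, amp50 = amp50,
       l23 = layer_results$l23, l4 = layer_results$l4)
}

.mua_row <- function(cond, layer, lr) {
  m <- lr$metrics
  data.frame(condition = cond, layer = layer, onset_ms = m$onset_ms,
             first_peak_density = m$first_peak_density,
             first_peak_delay_ms = m$first_peak_delay_ms,
             rising_slope = m$rising_slope,
             max_peak_density = m$max_peak_density,
             max_peak_delay_ms = m$max_peak_delay_ms,
             oscillation_freq_hz = lr$osc$freq_hz)
}

#' Run the full laminar analysis pipeline on one recording pair
#'
#' Orchestrates preprocessing, layer assignment (on the control condition,
#' reused for the drug condition), SEP/CSD/MUA parameterization, epoch
#' rates and decrements, and control-minus-drug decomposition, writing the
#' seven result tables plus a JSON run manifest to `out_dir`.
#'
#' @param config An [analysis_config()].
#' @param control_rec,drug_rec [wideband_recording()]s (or paths to `.bin`
#'   files readable with [read_recording()]). `drug_rec` may be `NULL`,
#'   in which case drug-dependent stages are skipped.
#' @param stim A [stimulus_train()] or path to an onset list.
#' @param out_dir Output directory (created if needed).
#' @return The run manifest (list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(config, control_rec, stim, drug_rec = NULL,
                         out_dir = ".") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  digests <- list()
  if (is.character(control_rec)) {
    digests$control <- unname(tools::md5sum(control_rec))
    control_rec <- read_recording(control_rec)
  }
  if (is.character(drug_rec)) {
    digests$drug <- unname(tools::md5sum(drug_rec))
    drug_rec <- read_recording(drug_rec)
  }
  if (is.character(stim)) {
    digests$stim <- unname(tools::md5sum(stim))
    stim <- read_stimulus_train(stim)
  }
  t_start <- Sys.time()
  stage <- "control analysis"
  res <- tryCatch({
    ctrl <- .analyze_condition(control_rec, stim, config)
    drug <- NULL
    if (!is.null(drug_rec)) {
      stage <- "drug analysis"
      drug <- .analyze_condition(drug_rec, stim, config,
                                 layers = ctrl$layers)
    }
    list(ctrl = ctrl, drug = drug)
  }, error = function(e) stop(sprintf("pipeline stage '%s' failed: %s",
                                      stage, conditionMessage(e)), call. = FALSE))
  ctrl <- res$ctrl; drug <- res$drug

  paths <- list()
  tab <- function(name, df) {
    p <- file.path(out_dir, name)
    write_table_tsv(df, p)
    paths[[name]] <<- p
  }

  sep_df <- data.frame(condition = "control", onset_ms = ctrl$sep$onset_ms,
                       peak_latency_ms = ctrl$sep$peak_latency_ms,
                       peak_amplitude_uV = ctrl$sep$peak_amplitude_uV,
                       max_slope_uV_per_ms = ctrl$sep$max_slope_uV_per_ms,
                       amplitude_at_50ms_uV = ctrl$amp50)
  if (!is.null(drug))
    sep_df <- rbind(sep_df,
                    data.frame(condition = "drug", onset_ms = drug$sep$onset_ms,
                               peak_latency_ms = drug$sep$peak_latency_ms,
                               peak_amplitude_uV = drug$sep$peak_amplitude_uV,
                               max_slope_uV_per_ms = drug$sep$max_slope_uV_per_ms,
                               amplitude_at_50ms_uV = drug$amp50))
  tab("sep.tsv", sep_df)

  csd_df <- data.frame(depth_um = ctrl$csd$depth_um, ctrl$csd$data,
                       check.names = FALSE)
  names(csd_df)[-1] <- sprintf("t%.1f", ctrl$csd$time_ms)
  tab("csd.tsv", csd_df)

  lay <- ctrl$layers
  role <- rep("other", length(lay$depths_um))
  role[lay$l4_channels] <- "L4"
  role[lay$l23_channels] <- "L2/3"
  role[lay$l23_mid_channel] <- "L2/3-mid"
  tab("layers.tsv",
      data.frame(channel = seq_along(lay$depths_um),
                 depth_um = lay$depths_um, role = role,
                 sink_onset_ms = c(NA, lay$sink_onsets_ms, NA),
                 mua_onset_ms = c(NA, ctrl$channel_onsets, NA)))

  mua_df <- rbind(.mua_row("control", "L2/3", ctrl$l23),
                  .mua_row("control", "L4", ctrl$l4))
  if (!is.null(drug))
    mua_df <- rbind(mua_df, .mua_row("drug", "L2/3", drug$l23),
                    .mua_row("drug", "L4", drug$l4))
  tab("mua.tsv", mua_df)

  ep <- function(cond, layer, er)
    data.frame(condition = cond, layer = layer, epoch = er$epoch,
               rate_hz = er$rate_hz, raw_rate_hz = er$raw_rate_hz,
               spont_rate_hz = attr(er, "spont_rate_hz"))
  ep_df <- rbind(ep("control", "L2/3", ctrl$l23$epochs),
                 ep("control", "L4", ctrl$l4$epochs))
  if (!is.null(drug))
    ep_df <- rbind(ep_df, ep("drug", "L2/3", drug$l23$epochs),
                   ep("drug", "L4", drug$l4$epochs))
  tab("epochs.tsv", ep_df)

  if (!is.null(drug)) {
    st_df <- rbind(
      data.frame(layer = "L2/3", epoch = ctrl$l23$epochs$epoch,
                 control_rate_hz = ctrl$l23$epochs$rate_hz,
                 drug_rate_hz = drug$l23$epochs$rate_hz,
                 decrement = decrement(ctrl$l23$epochs$rate_hz,
                                       drug$l23$epochs$rate_hz)),
      data.frame(layer = "L4", epoch = ctrl$l4$epochs$epoch,
                 control_rate_hz = ctrl$l4$epochs$rate_hz,
                 drug_rate_hz = drug$l4$epochs$rate_hz,
                 decrement = decrement(ctrl$l4$epochs$rate_hz,
                                       drug$l4$epochs$rate_hz)))
    tab("stats.tsv", st_df)

    dec <- decompose(ctrl$avg, drug$avg, lay$l23_mid_channel,
                     config$baseline_window_ms)
    tab("decomp.tsv",
        data.frame(time_ms = dec$time_ms, control_uV = dec$control_trace,
                   resistant_uV = dec$resistant_trace,
                   sensitive_uV = dec$sensitive_trace))
    kin <- list(
      resistant = component_kinetics_measured(dec$resistant_trace, dec$time_ms,
                                              config$sep_search_ms,
                                              config$second_peak_after_ms),
      sensitive = component_kinetics_measured(dec$sensitive_trace, dec$time_ms,
                                              c(config$sep_search_ms[1], 100),
                                              config$second_peak_after_ms))
    contrib <- contribution_at(dec, config$contrib_at_ms)
  } else {
    kin <- NULL
    contrib <- NULL
  }

  manifest <- list(
    package = "lamep",
    version = as.character(utils::packageVersion("lamep")),
    seed = config$seed,
    config = unclass(config),
    input_digests = digests,
    outputs = paths,
    kinetics = if (!is.null(kin)) lapply(kin, function(k)
      list(onset_ms = k$onset_ms, time_to_peak_ms = k$time_to_peak_ms,
           rise_2080_ms = k$rise_2080_ms, second_peak_ms = k$second_peak_ms,
           decay_tau_ms = k$decay_fit$tau_ms)),
    contributions = contrib,
    started = format(t_start, "%Y-%m-%dT%H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(manifest)
}

#' Render a human-readable report from a run manifest
#'
#' @param manifest A manifest list from [run_pipeline()] or the path to a
#'   `manifest.json`.
#' @param path Optional output path for the markdown report.
#' @return The report as a character vector of lines, invisibly when
#'   `path` is given.
#' @export
make_report <- function(manifest, path = NULL) {
  if (is.character(manifest))
    manifest <- jsonlite::read_json(manifest, simplifyVector = TRUE)
  need <- c("sep.tsv", "mua.tsv", "epochs.tsv")
  missing <- need[!vapply(need, function(n)
    !is.null(manifest$outputs[[n]]) && file.exists(manifest$outputs[[n]]),
    logical(1))]
  if (length(missing))
    stop("make_report: missing result table(s): ",
         paste(missing, collapse = ", "))
  rd <- function(n) read_table_tsv(manifest$outputs[[n]])
  fmt_tab <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], function(x) signif(x, 4))
    c(paste(names(df), collapse = " | "),
      paste(rep("---", ncol(df)), collapse = " | "),
      apply(df, 1, paste, collapse = " | "))
  }
  lines <- c(sprintf("# Laminar evoked-response analysis (lamep %s)",
                     manifest$version),
             sprintf("Seed: %s", manifest$seed), "",
             "## SEP metrics (L2/3 mid channel)", fmt_tab(rd("sep.tsv")), "",
             "## MUA metrics", fmt_tab(rd("mua.tsv")), "",
             "## Epoch rates (baseline-corrected, spikes/s per channel)",
             fmt_tab(rd("epochs.tsv")))
  if (!is.null(manifest$outputs[["stats.tsv"]]) &&
      file.exists(manifest$outputs[["stats.tsv"]])) {
    lines <- c(lines, "", "## Drug decrement per epoch",
               fmt_tab(rd("stats.tsv")))
  }
  if (!is.null(manifest$kinetics)) {
    k <- manifest$kinetics
    lines <- c(lines, "", "## Component kinetics",
               sprintf("- resistant: rise(20-80) %.2f ms, peak %.1f ms, decay tau %.1f ms",
                       k$resistant$rise_2080_ms, k$resistant$time_to_peak_ms,
                       k$resistant$decay_tau_ms),
               sprintf("- sensitive: rise(20-80) %.2f ms, peak %.1f ms, decay tau %.1f ms, second peak %s ms",
                       k$sensitive$rise_2080_ms, k$sensitive$time_to_peak_ms,
                       k$sensitive$decay_tau_ms,
                       format(k$sensitive$second_peak_ms)))
  }
  if (!is.null(manifest$contributions)) {
    lines <- c(lines, "", "## Component contributions",
               fmt_tab(as.data.frame(manifest$contributions)))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}

#' Per-epoch paired signed-rank test over a group of animals
#'
#' @param control_mat,drug_mat Numeric matrices, animals x epochs, of
#'   baseline-corrected epoch rates (columns matched).
#' @return Data frame with `epoch` (column name), mean `decrement`,
#'   `p_value` and `n_effective` per epoch.
#' @export
epoch_group_test <- function(control_mat, drug_mat) {
  stopifnot(all(dim(control_mat) == dim(drug_mat)))
  out <- lapply(seq_len(ncol(control_mat)), function(j) {
    tst <- signed_rank_test(control_mat[, j], drug_mat[, j])
    data.frame(epoch = colnames(control_mat)[j] %||% as.character(j),
               decrement = mean(decrement(control_mat[, j], drug_mat[, j]),
                                na.rm = TRUE),
               p_value = tst$p_value, n_effective = tst$n_effective)
  })
  do.call(rbind, out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
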