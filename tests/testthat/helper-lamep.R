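# shared test utilities

# wrap a single trace (or channels x time matrix) as an evoked_average
make_avg <- function(traces, time_ms, fs_hz = 1000 / (time_ms[2] - time_ms[1]),
                     geometry = NULL) {
  if (is.null(dim(traces))) traces <- matrix(traces, nrow = 1)
  structure(list(data = traces, time_ms = time_ms, fs_hz = fs_hz,
                 n_trials = 1L, geometry = geometry),
            class = "evoked_average")
}

# spike_times object from a list of per-channel time vectors
make_spikes <- function(times_list, fs_hz = 32000) {
  structure(list(times_ms = times_list,
                 threshold_uV = rep(NA_real_, length(times_list)),
                 noise_sd_uV = rep(NA_real_, length(times_list)),
                 fs_hz = fs_hz),
            class = "spike_times")
}

# small, fast simulation: fewer trials, short ISI
quick_sim_config <- function(...) {
  simulation_config(n_trials = 10, isi_range_ms = c(750, 800),
                    response_span_ms = 500, ...)
}

# noiseless, spikeless configuration (pure LFP components)
silent_mua_profile <- function() {
  list(baseline_rate_hz = 0, l23_first_peak_ms = 9.3,
       l23_peak_densities = numeric(0), l4_first_peak_ms = 7.5,
       l4_peak_densities = numeric(0), osc_freq_hz = 398,
       burst_sigma_ms = 0.5, late_tail_gain = 0, l4_tail_gain = 0,
       tail_start_ms = 11)
}
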