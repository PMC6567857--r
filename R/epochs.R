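# Epoch-based quantification of drug effects and matched-samples testing.

#' Epoch definition
#'
#' Named half-open post-stimulus intervals. The default set is the classic
#' staging of the whisker-evoked cortical response: 5-8, 8-10, 10-20, 20-50
#' and 50-100 ms.
#'
#' @param boundaries_ms Increasing numeric vector of epoch boundaries (ms);
#'   epoch k is `[boundaries[k], boundaries[k+1])`.
#' @return Object of class `epoch_definition`: data frame with `name`,
#'   `start_ms`, `end_ms`.
#' @export
epoch_definition <- function(boundaries_ms = c(5, 8, 10, 20, 50, 100)) {
  if (any(diff(boundaries_ms) <= 0))
    stop("epoch_definition: boundaries must be strictly increasing")
  k <- length(boundaries_ms) - 1
  out <- data.frame(name = paste0(boundaries_ms[-(k + 1)], "-",
                                  boundaries_ms[-1], "ms"),
                    start_ms = boundaries_ms[-(k + 1)],
                    end_ms = boundaries_ms[-1])
  class(out) <- c("epoch_definition", "data.frame")
  out
}

#' Baseline-corrected mean firing rate per epoch
#'
#' For each epoch, the rate is the spike count inside the epoch pooled over
#' trials and channels, divided by `trials x channels x duration`, minus the
#' spontaneous rate computed with the same normalization over the
#' pre-stimulus window. Units are spikes/s per channel.
#'
#' @param spikes A `spike_times` from [detect_spikes()].
#' @param stim A [stimulus_train()].
#' @param channels Channel indices to pool.
#' @param epochs An [epoch_definition()].
#' @param spont_window_ms Pre-stimulus window `c(pre, 0)` for the
#'   spontaneous rate (default `c(-1000, 0)`).
#' @return Object of class `epoch_rates`: data frame with `epoch`,
#'   `rate_hz` (corrected), `raw_rate_hz`, plus attributes `spont_rate_hz`,
#'   `n_trials`, `n_channels`.
#' @export
epoch_rates <- function(spikes, stim, channels,
                        epochs = epoch_definition(),
                        spont_window_ms = c(-1000, 0)) {
  if (spont_window_ms[2] > min(epochs$start_ms))
    stop("epoch_rates: spontaneous window must precede the epochs")
  all_t <- sort(unlist(spikes$times_ms[channels], use.names = FALSE))
  n_tr <- length(stim$onsets_ms)
  n_ch <- length(channels)
  count_in <- function(a, b) {  # pooled count in [onset+a, onset+b)
    sum(vapply(stim$onsets_ms, function(on)
      sum(all_t >= on + a & all_t < on + b), numeric(1)))
  }
  spont_dur_s <- diff(spont_window_ms) / 1000
  spont <- count_in(spont_window_ms[1], spont_window_ms[2]) /
    (n_tr * n_ch * spont_dur_s)
  raw <- mapply(function(a, b) count_in(a, b) / (n_tr * n_ch * (b - a) / 1000),
                epochs$start_ms, epochs$end_ms)
  out <- data.frame(epoch = epochs$name, rate_hz = raw - spont,
                    raw_rate_hz = raw)
  attr(out, "spont_rate_hz") <- spont
  attr(out, "n_trials") <- n_tr
  attr(out, "n_channels") <- n_ch
  class(out) <- c("epoch_rates", "data.frame")
  out
}

#' Normalized drug decrement
#'
#' `(control - drug) / control`. Values above 1 arise when the
#' baseline-corrected drug rate falls below zero (activity suppressed below
#' the spontaneous level).
#'
#' @param control_rate,drug_rate Baseline-corrected rates (same units).
#' @return The decrement fraction; `NA` when the control rate is zero.
#' @export
decrement <- function(control_rate, drug_rate) {
  out <- (control_rate - drug_rate) / control_rate
  out[control_rate == 0] <- NA_real_
  out
}

# exact null distribution of the signed-rank statistic by convolution over
# doubled ranks (average ranks for ties are multiples of 1/2)
.signed_rank_exact_p <- function(r, w_obs) {
  r2 <- as.integer(round(2 * r))
  total <- sum(r2)
  # f[j+1] = number of sign assignments with doubled statistic == j
  f <- numeric(total + 1)
  f[1] <- 1
  for (x in r2) {
    g <- f
    g[(x + 1):(total + 1)] <- g[(x + 1):(total + 1)] + f[1:(total + 1 - x)]
    f <- g
  }
  w2 <- round(2 * w_obs)
  n_assign <- 2^length(r)
  p_ge <- sum(f[(w2 + 1):(total + 1)]) / n_assign
  p_le <- sum(f[1:(w2 + 1)]) / n_assign
  min(1, 2 * min(p_ge, p_le))
}

#' Two-sided Wilcoxon signed-rank test for matched samples
#'
#' Zero differences are dropped (Wilcoxon's rule); tied absolute
#' differences receive average ranks. For `n_effective <= exact_max` the
#' two-sided p-value is computed from the exact null distribution over all
#' sign assignments (handles ties exactly); above that, a normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Paired numeric vectors of equal length.
#' @param exact_max Largest `n_effective` for the exact computation
#'   (default 25).
#' @return Object of class `signed_rank_result`: list with `statistic`
#'   (sum of positive-difference ranks), `p_value`, `n_effective`,
#'   `method`.
#' @export
signed_rank_test <- function(x, y, exact_max = 25) {
  if (length(x) != length(y)) stop("signed_rank_test: unequal lengths")
  if (!length(x)) stop("signed_rank_test: empty input")
  d <- x - y
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) {
    warning("signed_rank_test: all differences zero")
    return(structure(list(statistic = 0, p_value = 1, n_effective = 0L,
                          method = "degenerate"),
                     class = "signed_rank_result"))
  }
  r <- rank(abs(d))
  w <- sum(r[d > 0])
  if (n <= exact_max) {
    p <- .signed_rank_exact_p(r, w)
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    method <- "normal approximation"
  }
  structure(list(statistic = w, p_value = p, n_effective = n, method = method),
            class = "signed_rank_result")
}

#' @export
print.signed_rank_result <- function(x, ...) {
  cat(sprintf("signed-rank test (%s): W = %g, n = %d, p = %.4g\n",
              x$method, x$statistic, x$n_effective, x$p_value))
  invisible(x)
}

#' Estimate the number of sampled neurons
#'
#' Divides the mean number of evoked spikes per response by the assumed
#' per-neuron firing probability during the response.
#'
#' @param spikes_per_response Mean evoked spike count per stimulus.
#' @param firing_probability Assumed per-neuron firing probability in
#'   `(0, 1]` (default 0.2).
#' @return Estimated neuron count.
#' @export
estimate_sampled_neurons <- function(spikes_per_response,
                                     firing_probability = 0.2) {
  if (firing_probability <= 0 || firing_probability > 1)
    stop("estimate_sampled_neurons: firing_probability must be in (0, 1]")
  spikes_per_response / firing_probability
}
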