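# Optogenetic unit-response analysis: peri-stimulus time histograms in
# 100-ms z-scored bins, a baseline-stability discard rule, per-trial firing
# rate changes for burst stimulation, one-sample t-tests per unit, and
# Benjamini-Hochberg correction across units.

#' Construct a stimulation experiment
#'
#' @param spikes named list of per-unit spike-time vectors (seconds).
#' @param single_pulses onset times of the single 10-ms pulses.
#' @param bursts onset times of the 5-pulse 10-Hz bursts.
#' @param baseline_window `c(start, stop)` of the tonic baseline recording
#'   (default the first minute).
#' @param burst_n_pulses,burst_hz,pulse_width burst protocol parameters.
#' @return An object of class `stim_experiment`.
#' @export
stim_experiment <- function(spikes, single_pulses, bursts,
                            baseline_window = c(0, 60),
                            burst_n_pulses = 5, burst_hz = 10,
                            pulse_width = 0.01) {
  if (length(spikes) == 0)
    ek_stop("experiment needs at least one unit", "ek_parameter_error")
  if (is.null(names(spikes)) || any(!nzchar(names(spikes))))
    names(spikes) <- paste0("unit", seq_along(spikes))
  stim_end <- max(c(single_pulses, bursts, baseline_window[2]))
  if (min(c(single_pulses, bursts)) < baseline_window[2])
    ek_stop("baseline window must precede stimulation", "ek_data_error")
  structure(
    list(spikes = spikes, single_pulses = sort(single_pulses),
         bursts = sort(bursts), baseline_window = baseline_window,
         burst_n_pulses = burst_n_pulses, burst_hz = burst_hz,
         pulse_width = pulse_width,
         burst_duration = (burst_n_pulses - 1) / burst_hz + pulse_width),
    class = "stim_experiment")
}

#' @export
print.stim_experiment <- function(x, ...) {
  cat(sprintf(
    "stim_experiment: %d units, %d single pulses, %d bursts (%d pulses at %g Hz)\n",
    length(x$spikes), length(x$single_pulses), length(x$bursts),
    x$burst_n_pulses, x$burst_hz))
  invisible(x)
}

bin_counts <- function(spikes, from, to, bin) {
  edges <- seq(from, to, by = bin)
  if (length(edges) < 2) return(integer(0))
  tabulate(findInterval(spikes[spikes >= from & spikes < to], edges),
           nbins = length(edges) - 1)
}

#' Peri-stimulus time histogram in z-scored bins
#'
#' Counts spikes in 100-ms bins around each event, converts to rates, and
#' z-scores each trial's bins against the pooled pre-stimulus (lag < 0) bin
#' rates of that unit; the z-binned rows are then averaged across trials.
#'
#' @param spikes spike times of one unit (seconds).
#' @param events stimulus onset times (seconds).
#' @param bin bin width in seconds (default 0.1).
#' @param window `c(pre, post)` seconds around each event (pre negative).
#' @return List with `lags` (bin left edges, s), `z` (trial-averaged
#'   z-scored rates), `rate` (trial-averaged raw rates, Hz), `per_trial`
#'   (trials x bins rate matrix), `baseline_mean`, `baseline_sd` (Hz).
#' @export
psth_z <- function(spikes, events, bin = 0.1, window = c(-1, 1)) {
  if (length(events) == 0)
    ek_stop("psth needs at least one event", "ek_parameter_error")
  nb <- round((window[2] - window[1]) / bin)
  if (abs(nb * bin - (window[2] - window[1])) > 1e-9)
    ek_stop("bin width must divide the window", "ek_parameter_error")
  lags <- window[1] + bin * (seq_len(nb) - 1)
  per_trial <- t(vapply(events, function(ev)
    bin_counts(spikes, ev + window[1], ev + window[2] + 1e-12, bin) / bin,
    numeric(nb)))
  pre_idx <- lags < 0
  pre_rates <- as.numeric(per_trial[, pre_idx])
  m <- mean(pre_rates)
  s <- stats::sd(pre_rates)
  if (!is.finite(s) || s == 0)
    ek_stop("silent baseline: zero pre-stimulus variance in PSTH",
            "ek_data_error")
  z <- colMeans((per_trial - m) / s)
  list(lags = lags, z = z, rate = colMeans(per_trial),
       per_trial = per_trial, baseline_mean = m, baseline_sd = s)
}

# per-trial pre-stimulus rates (Hz) over `pre_window` seconds before each
# trial onset
pre_trial_rates <- function(spikes, onsets, pre_window = 1) {
  vapply(onsets, function(on)
    sum(spikes >= on - pre_window & spikes < on) / pre_window, numeric(1))
}

#' Baseline-stability discard rule
#'
#' A unit is discarded if its per-trial pre-stimulus firing rate changes by
#' more than 5x across trials (max/min ratio > 5; a mix of zero and nonzero
#' pre-trial rates is treated as an infinite ratio and discarded).
#'
#' @param spikes spike times of one unit.
#' @param onsets trial onset times used for the pre-stimulus windows.
#' @param pre_window length (s) of the pre-stimulus window per trial.
#' @param max_ratio maximum allowed max/min ratio (default 5).
#' @return List with `keep` (logical) and `rates` (per-trial Hz).
#' @export
stability_filter <- function(spikes, onsets, pre_window = 1, max_ratio = 5) {
  r <- pre_trial_rates(spikes, onsets, pre_window)
  mx <- max(r); mn <- min(r)
  keep <- if (mx == 0) TRUE          # uniformly silent: no rate *change*
  else if (mn == 0) FALSE            # zero to nonzero: unbounded change
  else mx / mn <= max_ratio
  list(keep = keep, rates = r)
}

#' Per-trial firing-rate changes for burst stimulation
#'
#' For each burst trial: rate in the response window (burst onset to last
#' pulse offset + 100 ms) minus the rate in that trial's own pre-stimulus
#' window.
#'
#' @param spikes spike times of one unit.
#' @param bursts burst onset times.
#' @param burst_duration onset-to-last-pulse-offset duration (s); 0.41 s for
#'   the default 5-pulse 10-Hz 10-ms protocol.
#' @param response_pad extra time after burst offset included in the
#'   response window (default 0.1 s).
#' @param pre_window pre-stimulus window length per trial (default 1 s).
#' @return Numeric vector of per-trial rate changes (Hz).
#' @export
trial_rate_changes <- function(spikes, bursts, burst_duration = 0.41,
                               response_pad = 0.1, pre_window = 1) {
  if (length(bursts) == 0)
    ek_stop("no burst trials supplied", "ek_parameter_error")
  resp_len <- burst_duration + response_pad
  resp <- vapply(bursts, function(on)
    sum(spikes >= on & spikes < on + resp_len) / resp_len, numeric(1))
  pre <- pre_trial_rates(spikes, bursts, pre_window)
  resp - pre
}

# one-sample t-test p-value with the degenerate zero-variance rule:
# identical nonzero changes are treated as maximal evidence (p = 0),
# identical zero changes as no evidence (p = 1)
one_sample_p <- function(x) {
  if (stats::sd(x) == 0) return(list(t = NA_real_,
                                     p = if (mean(x) != 0) 0 else 1))
  ht <- stats::t.test(x, mu = 0)
  list(t = unname(ht$statistic), p = ht$p.value)
}

#' Classify unit responses to burst stimulation
#'
#' For every unit passing the baseline-stability filter, the 6 per-trial
#' burst rate changes are tested against zero with a one-sample t-test; the
#' p-values are Benjamini-Hochberg adjusted across units. A unit is
#' `inhibited` if adjusted p < `fdr_level` and the mean change is negative,
#' `excited` if positive, otherwise `nonresponsive`; units failing the
#' stability filter are `discarded_unstable`.
#'
#' @param experiment a `stim_experiment`.
#' @param config a `session_config` (uses `thresholds$fdr_level` and
#'   `thresholds$stability_ratio`).
#' @param response_pad,pre_window see [trial_rate_changes()].
#' @return A data.frame (class `unit_results`) with one row per unit:
#'   `unit`, `mean_change`, `t_stat`, `p_raw`, `p_adj`, `class`.
#' @export
classify_units <- function(experiment, config = default_config(),
                           response_pad = 0.1, pre_window = 1) {
  th <- config$thresholds
  units <- names(experiment$spikes)
  res <- data.frame(unit = units, mean_change = NA_real_,
                    t_stat = NA_real_, p_raw = NA_real_, p_adj = NA_real_,
                    class = "discarded_unstable", stringsAsFactors = FALSE)
  changes_list <- vector("list", length(units))
  for (i in seq_along(units)) {
    sp <- experiment$spikes[[i]]
    stab <- stability_filter(sp, experiment$bursts, pre_window,
                             th$stability_ratio)
    if (!stab$keep) next
    ch <- trial_rate_changes(sp, experiment$bursts,
                             experiment$burst_duration, response_pad,
                             pre_window)
    changes_list[[i]] <- ch
    ts <- one_sample_p(ch)
    res$mean_change[i] <- mean(ch)
    res$t_stat[i] <- ts$t
    res$p_raw[i] <- ts$p
    res$class[i] <- "pending"
  }
  kept <- res$class == "pending"
  if (!any(kept))
    ek_stop("no unit passed the stability filter", "ek_data_error")
  res$p_adj[kept] <- stats::p.adjust(res$p_raw[kept], method = "BH")
  sig <- kept & res$p_adj < th$fdr_level
  res$class[kept] <- "nonresponsive"
  res$class[sig & res$mean_change < 0] <- "inhibited"
  res$class[sig & res$mean_change > 0] <- "excited"
  attr(res, "changes") <- changes_list
  class(res) <- c("unit_results", "data.frame")
  res
}

#' @export
print.unit_results <- function(x, ...) {
  tab <- table(factor(x$class, levels = c("inhibited", "excited",
                                          "nonresponsive",
                                          "discarded_unstable")))
  cat(sprintf(
    "unit_results: %d units | inhibited %d, excited %d, nonresponsive %d, discarded %d\n",
    nrow(x), tab["inhibited"], tab["excited"], tab["nonresponsive"],
    tab["discarded_unstable"]))
  invisible(x)
}

#' Latency of the first significant inhibition bin
#'
#' Scans post-stimulus PSTH bins and returns the lag of the first bin whose
#' trial-averaged z-score falls below `-z_crit / sqrt(n_trials)` (the
#' standard error of a mean of unit-variance bins), or `NA` if none does.
#'
#' @param psth a [psth_z()] result.
#' @param z_crit significance cutoff in standard-error units (default 1.96).
#' @return Latency in seconds (left edge of the first significant bin).
#' @export
inhibition_latency <- function(psth, z_crit = 1.96) {
  n_trials <- nrow(psth$per_trial)
  crit <- z_crit / sqrt(n_trials)
  post <- psth$lags >= 0
  hit <- which(post & psth$z < -crit)
  if (length(hit) == 0) return(NA_real_)
  psth$lags[min(hit)]
}
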