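# Photometry processing chain. The canonical order is:
#   decimate -> resample -> interpolate_artifacts -> lowpass ->
#   bleach_correct -> motion_correct -> rolling_zscore
# Each step records itself in the `steps` provenance attribute so a processed
# trace carries its own history.

add_step <- function(x, name, ...) {
  params <- list(...)
  steps <- attr(x, "steps")
  attr(x, "steps") <- c(steps, list(c(list(step = name), params)))
  x
}

#' Decimate a raw session by block averaging
#'
#' Reduces the acquisition-rate recording by averaging consecutive blocks of
#' `factor` samples in both channels (the block average acts as the
#' anti-alias smoother). Block time stamps are the block-mean times.
#'
#' @param session a `photometry_session`.
#' @param factor integer decimation factor (default 100).
#' @return A decimated `photometry_session`.
#' @export
decimate_raw <- function(session, factor = 100) {
  n <- length(session$time)
  if (factor < 1 || factor != round(factor))
    ek_stop("decimation factor must be a positive integer",
            "ek_parameter_error")
  if (factor >= n)
    ek_stop(sprintf("decimation factor %d >= channel length %d",
                    factor, n), "ek_parameter_error")
  if (factor == 1) return(session)
  nb <- n %/% factor
  idx <- rep(seq_len(nb), each = factor)
  keep <- seq_len(nb * factor)
  blk <- function(v) as.numeric(tapply(v[keep], idx, mean))
  out <- photometry_session(blk(session$time), blk(session$signal),
                            blk(session$reference))
  add_step(out, "decimate", factor = factor)
}

#' Resample a session onto a uniform grid
#'
#' Linear interpolation of both channels onto a uniform grid at `rate` Hz
#' spanning the original time range.
#'
#' @param session a `photometry_session`.
#' @param rate target rate in Hz (default 100).
#' @return A uniformly sampled `photometry_session`.
#' @export
resample_uniform <- function(session, rate = 100) {
  if (!is.finite(rate) || rate <= 0)
    ek_stop("resampling rate must be positive", "ek_parameter_error")
  if (length(session$time) < 2)
    ek_stop("need >= 2 samples to resample", "ek_data_error")
  t0 <- session$time[1]
  t1 <- session$time[length(session$time)]
  grid <- t0 + seq(0, floor((t1 - t0) * rate)) / rate
  out <- photometry_session(
    grid,
    stats::approx(session$time, session$signal, xout = grid)$y,
    stats::approx(session$time, session$reference, xout = grid)$y)
  out$native_rate <- rate
  attr(out, "steps") <- attr(session, "steps")
  add_step(out, "resample", rate = rate)
}

#' Replace user-specified artifact regions by linear interpolation
#'
#' Samples with time in any half-open region `[start, stop)` are replaced by
#' the straight line joining the nearest samples outside the region.
#'
#' @param y numeric trace.
#' @param time sample times (seconds).
#' @param regions list of length-2 numeric vectors `c(start, stop)`.
#' @return The trace with regions linearly interpolated.
#' @export
interpolate_artifacts <- function(y, time, regions = list()) {
  if (length(regions) == 0) return(y)
  span <- range(time)
  for (r in regions) {
    if (length(r) != 2 || r[1] >= r[2])
      ek_stop(sprintf("invalid artifact region [%s]",
                      paste(r, collapse = ", ")), "ek_parameter_error")
    if (r[1] < span[1] || r[2] > span[2] + 1e-9)
      ek_stop(sprintf("artifact region [%g, %g) outside trace span [%g, %g]",
                      r[1], r[2], span[1], span[2]), "ek_parameter_error")
    inside <- time >= r[1] & time < r[2]
    if (!any(inside)) next
    lo <- max(which(!inside & time < r[1]), 1L)
    hi_c <- which(!inside & time >= r[2])
    hi <- if (length(hi_c)) min(hi_c) else length(y)
    y[inside] <- stats::approx(time[c(lo, hi)], y[c(lo, hi)],
                               xout = time[inside], rule = 2)$y
  }
  y
}

#' Zero-phase low-pass filter
#'
#' 4th-order Butterworth applied forward and backward (zero phase).
#'
#' @param y numeric trace on a uniform grid.
#' @param rate sampling rate in Hz.
#' @param cutoff cutoff frequency in Hz (default 2).
#' @return The filtered trace.
#' @export
lowpass <- function(y, rate, cutoff = 2) {
  nyq <- rate / 2
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= nyq)
    ek_stop(sprintf("low-pass cutoff %g Hz must lie in (0, Nyquist=%g)",
                    cutoff, nyq), "ek_parameter_error")
  bf <- signal::butter(4, cutoff / nyq, type = "low")
  # reflect-pad around the edge values to suppress filter edge transients
  n <- length(y)
  pad <- min(n - 1, ceiling(3 * rate / cutoff))
  head_ref <- 2 * y[1] - y[(pad + 1):2]
  tail_ref <- 2 * y[n] - y[(n - 1):(n - pad)]
  yf <- signal::filtfilt(bf, c(head_ref, y, tail_ref))
  as.numeric(yf[(pad + 1):(pad + n)])
}

#' Fit and subtract an exponential photobleaching trend
#'
#' Least-squares fit of `a * exp(-t / tau) + c`; the fitted curve is
#' subtracted. A near-constant input is handled as the degenerate case
#' (subtract the mean).
#'
#' @param y numeric trace.
#' @param time sample times (seconds).
#' @return The detrended trace, with the fit stored in attribute
#'   `bleach_fit`.
#' @export
bleach_correct <- function(y, time) {
  if (diff(range(time)) < 10)
    ek_stop("bleach correction needs >= 10 s of data", "ek_data_error")
  s <- stats::sd(y)
  if (s < 1e-12 * (abs(mean(y)) + 1)) {
    out <- y - mean(y)
    attr(out, "bleach_fit") <- list(a = 0, tau = Inf, c = mean(y))
    return(out)
  }
  t0 <- time - time[1]
  span <- diff(range(t0))
  start <- list(a = y[1] - y[length(y)], tau = span / 3,
                c = y[length(y)])
  if (abs(start$a) < 1e-12) start$a <- s
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a * exp(-t0 / tau) + c,
                      data = data.frame(y = y, t0 = t0),
                      start = start,
                      lower = c(a = -Inf, tau = 1e-3, c = -Inf),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error"))
    ek_stop(sprintf("exponential bleach fit failed: %s",
                    conditionMessage(fit)), "ek_fit_error")
  cf <- stats::coef(fit)
  out <- y - stats::predict(fit)
  attr(out, "bleach_fit") <- as.list(cf)
  out
}

#' Remove shared motion artifacts using the isosbestic reference
#'
#' The 405 nm reference is regressed onto the 465 nm signal with a
#' polynomial fit (degree 1 by default) and the fitted reference component
#' is subtracted from the signal.
#'
#' @param y signal trace.
#' @param ref reference trace on the same grid.
#' @param degree polynomial degree of the fit (default 1).
#' @return The motion-corrected trace, with the fit coefficients in
#'   attribute `motion_fit`.
#' @export
motion_correct <- function(y, ref, degree = 1) {
  if (length(y) != length(ref))
    ek_stop("signal and reference must share one grid", "ek_data_error")
  if (stats::sd(ref) < 1e-12 * (abs(mean(ref)) + 1))
    ek_stop("reference channel flat: cannot fit motion model",
            "ek_data_error")
  fit <- stats::lm(y ~ stats::poly(ref, degree, raw = TRUE))
  out <- as.numeric(stats::residuals(fit))
  attr(out, "motion_fit") <- as.numeric(stats::coef(fit))
  out
}

# O(n) rolling mean and sample sd over a centered window (truncated at the
# edges) via prefix sums.
rolling_stats <- function(y, half) {
  n <- length(y)
  cs <- cumsum(c(0, y))
  cs2 <- cumsum(c(0, y * y))
  i <- seq_len(n)
  lo <- pmax(i - half, 1L)
  hi <- pmin(i + half, n)
  cnt <- hi - lo + 1
  s <- cs[hi + 1] - cs[lo]
  s2 <- cs2[hi + 1] - cs2[lo]
  m <- s / cnt
  v <- (s2 - s * s / cnt) / (cnt - 1)
  v[v < 0] <- 0
  list(mean = m, sd = sqrt(v), count = cnt)
}

#' Moving-window z-score normalization
#'
#' Normalizes a trace as `(f - f0) / f1` where `f0` and `f1` are the mean
#' and standard deviation within a centered moving window (60 s by default;
#' edge windows are truncated).
#'
#' @param y numeric trace on a uniform grid.
#' @param rate sampling rate in Hz.
#' @param window window length in seconds (default 60).
#' @return Numeric z-score trace with attributes `f0` and `f1`.
#' @export
rolling_zscore <- function(y, rate, window = 60) {
  n <- length(y)
  if (n / rate < window)
    ek_stop(sprintf("trace duration %.1f s shorter than z-score window %g s",
                    n / rate, window), "ek_data_error")
  half <- floor(window * rate / 2)
  rs <- rolling_stats(y, half)
  if (any(rs$sd <= 0))
    ek_stop("zero-variance window in rolling z-score", "ek_data_error")
  z <- (y - rs$mean) / rs$sd
  attr(z, "f0") <- rs$mean
  attr(z, "f1") <- rs$sd
  z
}

#' Run the full photometry processing chain
#'
#' Applies, in order: decimation (optional), resampling to the target rate,
#' artifact-region interpolation, zero-phase low-pass filtering, exponential
#' bleach correction (each channel), isosbestic motion correction, and
#' moving-window z-score normalization. Provenance of every step with its
#' parameters is stored in the result.
#'
#' @param session a `photometry_session`.
#' @param config a `session_config` (see [default_config()]).
#' @param artifact_regions list of `c(start, stop)` second pairs to
#'   interpolate over.
#' @param decimate_factor optional decimation factor applied before
#'   resampling; `NULL` (default) skips decimation.
#' @param motion boolean, apply isosbestic motion correction (default TRUE;
#'   exposed so the contribution of the reference channel can be measured).
#' @return An object of class `processed_trace` with elements `time`
#'   (uniform grid, seconds), `z` (z-scored activity), `f0`, `f1`, and
#'   `steps` (provenance).
#' @export
process_photometry <- function(session, config = default_config(),
                               artifact_regions = list(),
                               decimate_factor = NULL, motion = TRUE) {
  steps <- list()
  log_step <- function(name, ...) steps[[length(steps) + 1L]] <<-
      c(list(step = name), list(...))

  if (!is.null(decimate_factor)) {
    session <- decimate_raw(session, decimate_factor)
    log_step("decimate", factor = decimate_factor)
  }
  rate <- config$sample_rate_target
  session <- resample_uniform(session, rate)
  log_step("resample", rate = rate)

  sig <- interpolate_artifacts(session$signal, session$time,
                               artifact_regions)
  ref <- interpolate_artifacts(session$reference, session$time,
                               artifact_regions)
  log_step("interpolate_artifacts", n_regions = length(artifact_regions))

  sig <- lowpass(sig, rate, config$lowpass_cutoff)
  ref <- lowpass(ref, rate, config$lowpass_cutoff)
  log_step("lowpass", cutoff = config$lowpass_cutoff)

  sig <- bleach_correct(sig, session$time)
  ref <- bleach_correct(ref, session$time)
  log_step("bleach_correct")

  if (motion) {
    sig <- motion_correct(sig, ref, degree = config$motion_poly_degree)
    log_step("motion_correct", degree = config$motion_poly_degree)
  }

  z <- rolling_zscore(as.numeric(sig), rate, config$zscore_window)
  log_step("rolling_zscore", window = config$zscore_window)

  structure(
    list(time = session$time, z = as.numeric(z),
         f0 = attr(z, "f0"), f1 = attr(z, "f1"),
         rate = rate, steps = steps),
    class = "processed_trace")
}

#' @export
print.processed_trace <- function(x, ...) {
  cat(sprintf("processed_trace: %d samples at %g Hz (%.1f s), steps: %s\n",
              length(x$time), x$rate, diff(range(x$time)),
              paste(vapply(x$steps, `[[`, "", "step"), collapse = " -> ")))
  invisible(x)
}

#' Mean z-score over an epoch (the epoch "AUC")
#'
#' The epoch statistic is the time-normalized area under the z-score curve,
#' i.e. the mean z over the half-open interval `[start, stop)`.
#'
#' @param trace a `processed_trace`.
#' @param start,stop epoch bounds in seconds.
#' @return Scalar mean z.
#' @export
epoch_auc <- function(trace, start, stop) {
  if (!is.finite(start) || !is.finite(stop) || stop <= start)
    ek_stop("epoch must satisfy stop > start", "ek_parameter_error")
  inside <- trace$time >= start & trace$time < stop
  if (!any(inside))
    ek_stop(sprintf("epoch [%g, %g) contains no samples", start, stop),
            "ek_parameter_error")
  mean(trace$z[inside])
}

#' Event-triggered averaging of a processed trace
#'
#' Extracts z-score snippets around each behavior-initiation onset, averages
#' them, and computes the baseline (mean over lags −5 to −3 s of the
#' averaged trace) and the baseline-corrected extremum (max or min over lags
#' 0 to 3 s minus the baseline). Onsets too close to the trace edge are
#' dropped with a warning.
#'
#' @param trace a `processed_trace`.
#' @param onsets behavior initiation times (seconds).
#' @param pre,post seconds before / after the onset (default 5 each).
#' @param polarity `"max"` (activation analyses) or `"min"` (suppression).
#' @param baseline_window lags (s) over which the baseline is averaged.
#' @param extremum_window lags (s) searched for the extremum.
#' @return An object of class `event_triggered` with `lags`, `mean_trace`,
#'   `per_event` (events x lags matrix), `baseline`, `corrected_extremum`,
#'   `n_events`.
#' @export
event_triggered <- function(trace, onsets, pre = 5, post = 5,
                            polarity = c("max", "min"),
                            baseline_window = c(-5, -3),
                            extremum_window = c(0, 3)) {
  polarity <- match.arg(polarity)
  if (length(onsets) == 0)
    ek_stop("no onsets supplied", "ek_parameter_error")
  dt <- 1 / trace$rate
  nlag <- round(pre / dt)
  plag <- round(post / dt)
  lags <- seq(-nlag, plag) * dt
  t0 <- trace$time[1]
  n <- length(trace$z)
  rows <- list()
  dropped <- 0
  for (on in onsets) {
    ci <- round((on - t0) / dt) + 1
    lo <- ci - nlag
    hi <- ci + plag
    if (lo < 1 || hi > n) {
      dropped <- dropped + 1
      next
    }
    rows[[length(rows) + 1L]] <- trace$z[lo:hi]
  }
  if (dropped > 0)
    ek_warn(sprintf("%d onset(s) dropped: closer than %g/%g s to trace edge",
                    dropped, pre, post), "ek_dropped_events")
  if (length(rows) == 0)
    ek_stop("all onsets too close to trace edges", "ek_data_error")
  per_event <- do.call(rbind, rows)
  mean_trace <- colMeans(per_event)
  bl_idx <- lags >= baseline_window[1] & lags <= baseline_window[2]
  ex_idx <- lags >= extremum_window[1] & lags <= extremum_window[2]
  baseline <- mean(mean_trace[bl_idx])
  extremum <- if (polarity == "max") max(mean_trace[ex_idx]) else
    min(mean_trace[ex_idx])
  structure(
    list(lags = lags, mean_trace = mean_trace, per_event = per_event,
         baseline = baseline, corrected_extremum = extremum - baseline,
         polarity = polarity, n_events = nrow(per_event)),
    class = "event_triggered")
}

#' @export
print.event_triggered <- function(x, ...) {
  cat(sprintf(
    "event_triggered: %d events, baseline %.3f z, corrected %s %.3f z\n",
    x$n_events, x$baseline, x$polarity, x$corrected_extremum))
  invisible(x)
}
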