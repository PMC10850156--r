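test_that("decimation block-averages both channels consistently", {
  t <- seq(0, 0.9999, by = 1e-4) # 10 kHz, 10 000 samples
  s <- photometry_session(t, sin(2 * pi * t), cos(2 * pi * t))
  d <- decimate_raw(s, 100)
  expect_length(d$time, 100)
  expect_equal(d$native_rate, 100, tolerance = 1e-6)

  # identity at factor 1; constants stay constant
  expect_identical(decimate_raw(s, 1), s)
  sc <- photometry_session(t, rep(2, length(t)), rep(3, length(t)))
  dc <- decimate_raw(sc, 100)
  expect_equal(dc$signal, rep(2, 100))
  expect_equal(dc$reference, rep(3, 100))

  expect_error(decimate_raw(s, length(t)), class = "ek_parameter_error")
})

test_that("resampling yields an exact uniform grid and preserves ramps", {
  set.seed(1)
  t <- sort(runif(500, 0, 5)) # jittered sample times
  t[1] <- 0; t[500] <- 5
  s <- photometry_session(t, 3 * t + 1, -2 * t) # linear channels
  r <- resample_uniform(s, 100)
  expect_equal(diff(r$time), rep(0.01, length(r$time) - 1))
  expect_equal(r$signal, 3 * r$time + 1, tolerance = 1e-12)
  expect_equal(r$reference, -2 * r$time, tolerance = 1e-12)
  expect_error(resample_uniform(s, 0), class = "ek_parameter_error")
})

test_that("artifact regions are replaced by the boundary-joining line", {
  t <- seq(0, 9.99, by = 0.01)
  y <- 2 * t + 1
  spiky <- y
  spiky[t >= 4 & t < 5] <- 100
  out <- interpolate_artifacts(spiky, t, list(c(4, 5)))
  expect_equal(out, y, tolerance = 1e-9) # back on the ramp line
  expect_identical(interpolate_artifacts(y, t, list()), y)
  expect_error(interpolate_artifacts(y, t, list(c(9, 11))),
               class = "ek_parameter_error")
})

test_that("low-pass filter has the required response at 0.1 and 20 Hz", {
  rate <- 100
  t <- seq(0, 60, by = 1 / rate)
  amp_ratio <- function(freq) {
    y <- sin(2 * pi * freq * t)
    yf <- lowpass(y, rate, 2)
    # amplitude by quadrature regression at the known frequency
    fit <- lm(yf ~ sin(2 * pi * freq * t) + cos(2 * pi * freq * t) - 1)
    sqrt(sum(coef(fit)^2))
  }
  expect_gte(amp_ratio(0.1), 0.95)
  expect_lte(amp_ratio(20), 0.10)
  # DC passes unchanged (to filter numerical precision)
  expect_equal(lowpass(rep(4, 1000), rate, 2), rep(4, 1000),
               tolerance = 1e-3)
  expect_error(lowpass(rnorm(100), rate, 60), class = "ek_parameter_error")
})

test_that("bleach correction removes exponential trends and keeps signals", {
  t <- seq(0, 300, by = 0.01)
  y <- 5 * exp(-t / 80) + 2
  out <- bleach_correct(y, t)
  expect_lt(max(abs(out)), 1e-6 * 5)

  # constant input: degenerate case, output ~0
  expect_equal(as.numeric(bleach_correct(rep(7, length(t)), t)),
               rep(0, length(t)), tolerance = 1e-9)

  # a 1 Hz sinusoid riding on the bleach survives within 5% amplitude
  y2 <- y + 0.5 * sin(2 * pi * 1 * t)
  out2 <- bleach_correct(y2, t)
  fit <- lm(out2 ~ sin(2 * pi * t) + cos(2 * pi * t) - 1)
  expect_equal(sqrt(sum(coef(fit)^2)), 0.5, tolerance = 0.05)

  expect_error(bleach_correct(rnorm(100), seq(0, 0.99, by = 0.01)),
               class = "ek_data_error")
})

test_that("motion correction suppresses the shared artifact, keeps transients", {
  expect_error(motion_correct(rnorm(100), rep(1, 100)),
               class = "ek_data_error")

  # identical channels leave (numerically) nothing behind
  set.seed(2)
  y <- cumsum(rnorm(2000)) / 10
  expect_lt(sd(motion_correct(y, y)), 1e-10)

  # generator ground truth: artifact at 0.8 gain in the reference
  cfg <- default_config()
  g <- gen_photometry(cfg, seed = 11, duration = 300, n_events = 10,
                      n_artifacts = 10, noise_sd = 0.1,
                      ref_background_sd = 0.1)
  s <- resample_uniform(g$session, 100)
  sig <- bleach_correct(lowpass(s$signal, 100, 2), s$time)
  ref <- bleach_correct(lowpass(s$reference, 100, 2), s$time)
  corr <- motion_correct(as.numeric(sig), as.numeric(ref))
  art_mask <- rep(FALSE, length(s$time))
  for (at in g$truth$artifact_times)
    art_mask <- art_mask | (s$time >= at - 0.5 & s$time < at + 0.5)
  p_before <- mean(sig[art_mask]^2)
  p_after <- mean(corr[art_mask]^2)
  expect_lt(p_after / p_before, 0.10)
  # transient peaks survive within 10%
  idx <- round(g$truth$event_schedule$start * 100) + 47 # kernel peak lag
  expect_equal(mean(corr[idx]) / mean(sig[idx]), 1, tolerance = 0.1)
})

test_that("rolling z-score matches the brute-force windowed computation", {
  rate <- 100
  set.seed(3)
  y <- rnorm(60 * rate) + sin(seq_len(60 * rate) / 500) # 1-min trace
  z <- rolling_zscore(y, rate, window = 10)
  expect_equal(as.numeric(z), brute_rolling_zscore(y, rate, 10),
               tolerance = 1e-10)

  # white noise: windowed mean ~0, sd ~1 at 10-min duration
  y <- rnorm(600 * rate)
  z <- rolling_zscore(y, rate, 60)
  expect_lt(abs(mean(z)), 0.05)
  expect_equal(sd(z), 1, tolerance = 0.05)

  # a linear ramp normalizes to a bounded, trend-free series
  zr <- as.numeric(rolling_zscore(seq(0, 10, length.out = 6000), rate, 10))
  expect_lt(max(abs(zr)), 2)
  mid <- zr[1000:5000]
  expect_lt(abs(coef(lm(mid ~ seq_along(mid)))[2]), 1e-6)

  expect_error(rolling_zscore(rep(1, 6000), rate, 10),
               class = "ek_data_error")
})

test_that("epoch AUC is the sample mean over the half-open interval", {
  tr <- make_trace(rep(1, 1000))
  expect_equal(epoch_auc(tr, 0, 5), 1.0)
  tr2 <- make_trace(c(rep(1, 500), rep(-1, 500)))
  expect_equal(epoch_auc(tr2, 0, 10), 0.0)
  expect_error(epoch_auc(tr, 5, 5), class = "ek_parameter_error")

  set.seed(4)
  tr3 <- make_trace(rnorm(2000))
  for (i in 1:100) {
    a <- runif(1, 0, 15)
    b <- a + runif(1, 0.1, 4)
    b <- min(b, 19.99)
    inside <- tr3$time >= a & tr3$time < b
    expect_equal(epoch_auc(tr3, a, b), mean(tr3$z[inside]))
  }
})

test_that("event-triggered averaging implements baseline and corrected extremum", {
  # flat zero trace: everything zero
  tr <- make_trace(rep(0, 3000))
  et <- event_triggered(tr, c(10, 15, 20))
  expect_equal(et$baseline, 0)
  expect_equal(et$corrected_extremum, 0)

  # single onset: mean trace is that snippet
  set.seed(5)
  tr <- make_trace(rnorm(3000))
  et1 <- event_triggered(tr, 12)
  i0 <- round(12 * 100) + 1
  expect_equal(et1$mean_trace, tr$z[(i0 - 500):(i0 + 500)])
  expect_equal(et1$n_events, 1)

  # a known square bump: baseline from [-5,-3], extremum from [0,3]
  z <- rep(0, 3000)
  tl <- (seq_along(z) - 1) / 100
  z[tl >= 15 & tl < 16] <- 2       # bump after the onset at t=14
  z[tl >= 9 & tl < 11.5] <- 0.5    # lifts the baseline window [9,11]
  et2 <- event_triggered(make_trace(z), 14, polarity = "max")
  expect_equal(et2$baseline, 0.5, tolerance = 0.02)
  expect_equal(et2$corrected_extremum, 1.5, tolerance = 0.02)
  et3 <- event_triggered(make_trace(-z), 14, polarity = "min")
  expect_equal(et3$corrected_extremum, -1.5, tolerance = 0.02)

  # edge onsets are dropped with a warning; all-dropped is an error
  expect_warning(event_triggered(tr, c(2, 15)), class = "ek_dropped_events")
  expect_error(suppressWarnings(event_triggered(tr, 2)),
               class = "ek_data_error")
  expect_error(event_triggered(tr, numeric(0)),
               class = "ek_parameter_error")
})

test_that("the full chain records provenance in the prescribed order", {
  cfg <- default_config()
  g <- gen_photometry(cfg, seed = 6, duration = 150, n_events = 5,
                      n_artifacts = 3)
  tr <- process_photometry(g$session, cfg,
                           artifact_regions = list(c(100, 101)),
                           decimate_factor = 2)
  expect_equal(vapply(tr$steps, `[[`, "", "step"),
               c("decimate", "resample", "interpolate_artifacts",
                 "lowpass", "bleach_correct", "motion_correct",
                 "rolling_zscore"))
  expect_equal(diff(tr$time), rep(0.01, length(tr$time) - 1))
})
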