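# Synthetic-data generators. Each generator emulates one raw-data modality
# of the experiment and returns both the dataset and a `ground_truth` list
# whose fields map one-to-one onto generator parameters, so pipeline output
# can be compared against truth without re-derivation. Every generator
# requires an explicit seed and is fully deterministic given (config, seed).

require_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    ek_stop("an explicit integer seed is required for reproducibility",
            "ek_parameter_error")
  set.seed(as.integer(seed))
}

# unit-sd slow background: white noise smoothed with a 0.25-s Gaussian
# kernel, rescaled to sd 1 (band-limited well below the 2 Hz low-pass)
slow_noise <- function(n, rate, sd_target = 1, kernel_sd = 0.25) {
  if (sd_target == 0) return(numeric(n))
  w <- stats::rnorm(n + 4 * ceiling(kernel_sd * rate))
  sm <- gauss_smooth(w, rate, 4 * kernel_sd)[seq_len(n)]
  sm <- sm - mean(sm)
  sm / stats::sd(sm) * sd_target
}

# double-exponential calcium transient kernel (rise 0.2 s, decay 1.5 s,
# GCaMP6s-like), normalized to unit peak
transient_kernel <- function(rate, rise = 0.2, decay = 1.5, span = 10) {
  t <- seq(0, span, by = 1 / rate)
  k <- exp(-t / decay) - exp(-t / rise)
  k / max(k)
}

#' Generate a two-channel photometry session with known ground truth
#'
#' The 465 nm signal is an exponential photobleaching baseline plus a
#' band-limited background fluctuation (unit sd), event-locked calcium
#' transients (double-exponential kernel, rise 0.2 s / decay 1.5 s),
#' shared motion artifacts (Gaussian bumps), and white measurement noise.
#' `transient_amplitude` is expressed in the z units of the moving-window
#' normalization: because the transients themselves contribute to the
#' windowed sd, the generator solves for the raw peak scale whose expected
#' normalized peak equals the nominal amplitude (the scale used is returned
#' as `truth$raw_peak_scale`).
#' The 405 nm reference carries its own bleaching baseline, the SAME
#' artifact waveform scaled by `ref_artifact_gain`, its own (smaller)
#' background and noise, and NO transients. Artifacts are placed away from
#' transients so each effect is separately measurable.
#'
#' @param config a `session_config`; `sample_rate_target` sets the native
#'   rate of the generated recording.
#' @param seed integer seed (required).
#' @param duration session length in seconds (default 600, the 10-min test).
#' @param n_events number of behavior-locked transients (default 20).
#' @param transient_amplitude transient peak in moving-window z units.
#' @param bleach_tau photobleaching time constant in seconds (default 300).
#' @param n_artifacts number of shared motion artifacts.
#' @param artifact_amplitude artifact bump peak, background-sd units.
#' @param ref_artifact_gain artifact gain in the reference channel.
#' @param background_sd signal-channel slow background sd (default 1; this
#'   sd is the reference scale for `transient_amplitude` and
#'   `artifact_amplitude`).
#' @param ref_background_sd reference-channel slow background sd.
#' @param noise_sd white measurement noise sd (both channels).
#' @return List with `session` (a `photometry_session`) and `truth`
#'   (`ground_truth` list: `event_schedule`, `transient_amplitude`,
#'   `bleach_tau`, `artifact_times`, gains and noise levels).
#' @export
gen_photometry <- function(config = default_config(), seed,
                           duration = 600, n_events = 20,
                           transient_amplitude = 2, bleach_tau = 300,
                           n_artifacts = 15, artifact_amplitude = 8,
                           ref_artifact_gain = 0.8, background_sd = 1,
                           ref_background_sd = 0.2, noise_sd = 0.5) {
  require_seed(seed)
  if (duration < 2 * config$zscore_window)
    ek_stop("session duration must be >= 2x the z-score window",
            "ek_parameter_error")
  rate <- config$sample_rate_target
  n <- duration * rate
  t <- (seq_len(n) - 1) / rate

  # event onsets: spaced >= 12 s, clear of the trace edges
  lo <- config$thresholds$event_pre + 2
  hi <- duration - config$thresholds$event_post - 2
  onsets <- numeric(0)
  if (n_events > 0) {
    cand <- sort(stats::runif(n_events * 20, lo, hi))
    for (cc in cand) {
      if (length(onsets) == n_events) break
      if (length(onsets) == 0 || cc - onsets[length(onsets)] >= 12)
        onsets <- c(onsets, cc)
    }
    if (length(onsets) < n_events)
      ek_stop("could not place the requested number of events", "ek_data_error")
  }

  # artifact times: clear of edges and of any event by >= 6 s
  artifact_times <- numeric(0)
  if (n_artifacts > 0) {
    cand <- stats::runif(n_artifacts * 50, 5, duration - 5)
    for (cc in cand) {
      if (length(artifact_times) == n_artifacts) break
      if ((length(onsets) == 0 || min(abs(cc - onsets)) >= 6) &&
          (length(artifact_times) == 0 ||
           min(abs(cc - artifact_times)) >= 3))
        artifact_times <- c(artifact_times, cc)
    }
    artifact_times <- sort(artifact_times)
    if (length(artifact_times) < n_artifacts)
      ek_stop("could not place the requested number of artifacts",
              "ek_data_error")
  }

  # Unit-peak transient field. The pipeline's z unit is the moving-window
  # standard deviation, which the transients themselves contribute to; to
  # make "amplitude in z units" well defined, solve for the raw peak scale
  # s such that the expected windowed-sd-normalized peak equals the nominal
  # amplitude: s / sqrt(bg_var + s^2 * v) = A, with v the windowed variance
  # of the unit-amplitude transient field at the event peaks (known exactly
  # from the schedule).
  kern <- transient_kernel(rate)
  tau <- numeric(n)
  for (on in onsets) {
    i0 <- round(on * rate) + 1
    idx <- i0:min(n, i0 + length(kern) - 1)
    tau[idx] <- tau[idx] + kern[seq_along(idx)]
  }
  scale <- 0
  if (length(onsets) > 0 && transient_amplitude > 0) {
    half <- floor(config$zscore_window * rate / 2)
    rs <- rolling_stats(tau, half)
    peak_idx <- pmin(n, round(onsets * rate) + which.max(kern))
    v <- mean(rs$sd[peak_idx]^2) / max(background_sd^2, 1e-12)
    if (transient_amplitude^2 * v >= 1)
      ek_stop("transient amplitude too large for this event density and z-score window",
              "ek_parameter_error")
    scale <- transient_amplitude * background_sd /
      sqrt(1 - transient_amplitude^2 * v)
  }
  transients <- scale * tau

  artifact <- numeric(n)
  for (at in artifact_times)
    artifact <- artifact +
      artifact_amplitude * background_sd * exp(-(t - at)^2 / (2 * 0.15^2))

  bg_sig <- slow_noise(n, rate, background_sd)
  bg_ref <- slow_noise(n, rate, ref_background_sd)

  sig <- 100 * exp(-t / bleach_tau) + 50 + bg_sig + transients +
    artifact + stats::rnorm(n, sd = noise_sd)
  ref <- 80 * exp(-t / (bleach_tau * 1.2)) + 40 + bg_ref +
    ref_artifact_gain * artifact + stats::rnorm(n, sd = noise_sd)

  truth <- list(
    event_schedule = event_table(data.frame(
      behavior = rep("transient", length(onsets)), start = onsets,
      stop = onsets)),
    transient_amplitude = transient_amplitude,
    raw_peak_scale = scale,
    bleach_tau = bleach_tau,
    artifact_times = artifact_times,
    artifact_amplitude = artifact_amplitude,
    ref_artifact_gain = ref_artifact_gain,
    noise_sd = noise_sd,
    seed = as.integer(seed))
  list(session = photometry_session(t, sig, ref), truth = truth)
}

default_bout_script <- function() {
  data.frame(
    label = c("locomotion", "immobility", "surveying", "locomotion",
              "pause", "locomotion", "immobility", "surveying",
              "locomotion", "pause"),
    duration = c(30, 30, 12, 30, 10, 30, 25, 12, 30, 10),
    speed = c(10, 0, 0, 12, 1, 9, 0, 0, 11, 1),
    zone = c("wall", "wall", "wall", "center", "center", "wall", "wall",
             "center", "center", "center"),
    stringsAsFactors = FALSE)
}

#' Generate an arena trajectory from a scripted bout sequence
#'
#' Realizes an x,y path from a script of labeled bouts, each with a target
#' speed and zone. Immobility bouts are stationary with per-frame motion
#' below 1%; surveying and pause bouts are (near-)stationary but with
#' visible body motion; locomotion bouts move at the target speed either
#' along the walls (`zone = "wall"`, thigmotactic) or on an inner circuit
#' (`zone = "center"`). The scripted ethogram is returned as ground truth.
#'
#' @param config a `session_config`; `frame_rate` and `arena_size` must be
#'   set.
#' @param seed integer seed (required; a clean script uses no randomness
#'   beyond none, but determinism is part of the generator contract).
#' @param script data.frame with columns `label`, `duration` (s), `speed`
#'   (cm/s) and optionally `zone` (`"wall"` or `"center"`).
#' @param jitter_sd positional jitter sd in cm (default 0: clean
#'   trajectories for classifier-recovery tests).
#' @return List with `trajectory` and `truth` (scripted `ethogram` event
#'   table plus the script itself).
#' @export
gen_tracking <- function(config, seed, script = default_bout_script(),
                         jitter_sd = 0) {
  require_seed(seed)
  if (!is.finite(config$frame_rate))
    ek_stop("config$frame_rate must be set to generate tracking",
            "ek_config_error")
  fr <- config$frame_rate
  arena <- config$arena_size
  if (is.null(script$zone)) script$zone <- "wall"
  if (any(script$speed / fr > min(arena) / 2))
    ek_stop("scripted speed incompatible with arena size: per-frame step exceeds half the arena",
            "ek_generation_error")

  margin <- 3                       # cm inside the walls for the wall path
  # rectangular wall circuit parameterized by path length, and its nearest
  # point to an arbitrary position
  wall_w <- arena[1] - 2 * margin
  wall_h <- arena[2] - 2 * margin
  wall_path <- function(s) {
    p <- 2 * (wall_w + wall_h)
    s <- s %% p
    if (s < wall_w) c(margin + s, margin)
    else if (s < wall_w + wall_h) c(arena[1] - margin, margin + (s - wall_w))
    else if (s < 2 * wall_w + wall_h)
      c(arena[1] - margin - (s - wall_w - wall_h), arena[2] - margin)
    else c(margin, arena[2] - margin - (s - 2 * wall_w - wall_h))
  }
  wall_entry <- function(pos) {
    cx <- min(max(pos[1], margin), arena[1] - margin)
    cy <- min(max(pos[2], margin), arena[2] - margin)
    d <- c(cy - margin, arena[1] - margin - cx,
           arena[2] - margin - cy, cx - margin) # bottom, right, top, left
    side <- which.min(d)
    s <- switch(side,
                cx - margin,
                wall_w + (cy - margin),
                wall_w + wall_h + (arena[1] - margin - cx),
                2 * wall_w + wall_h + (arena[2] - margin - cy))
    list(point = wall_path(s), s = s)
  }
  circle_path <- function(center, r) function(s)
    c(center[1] + r * cos(s / r), center[2] + r * sin(s / r))
  circle_entry <- function(center, r, pos) {
    ang <- atan2(pos[2] - center[2], pos[1] - center[1])
    if (!is.finite(ang)) ang <- 0
    list(point = c(center[1] + r * cos(ang), center[2] + r * sin(ang)),
         s = r * ang)
  }

  xs <- ys <- motions <- numeric(0)
  labels <- character(0)
  pos <- wall_path(0)
  loco_th <- config$thresholds$locomotion_speed
  for (i in seq_len(nrow(script))) {
    nfr <- round(script$duration[i] * fr)
    sp <- script$speed[i]
    lab <- script$label[i]
    zone <- script$zone[i]
    motion_pct <- switch(lab, immobility = 0.2, surveying = 3,
                         pause = 3, head_dip = 2, 5)
    if (sp > 0) {
      # pick the bout's circuit; slow bouts orbit a small circle in place
      # so the path stays continuous at every bout boundary
      if (sp <= loco_th && !(lab == "locomotion")) {
        r <- 3
        ctr <- pmin(pmax(pos, r + 0.5), arena - r - 0.5)
        pf <- circle_path(ctr, r)
        ent <- circle_entry(ctr, r, pos)
      } else if (zone == "center") {
        r <- min(arena) / 6
        ctr <- arena / 2
        pf <- circle_path(ctr, r)
        ent <- circle_entry(ctr, r, pos)
      } else {
        pf <- wall_path
        ent <- wall_entry(pos)
      }
      on_circuit <- FALSE
      arc <- ent$s
      step_len <- sp / fr
      for (k in seq_len(nfr)) {
        if (!on_circuit) {
          d <- sqrt(sum((ent$point - pos)^2))
          if (d > step_len) {
            pos <- pos + (ent$point - pos) / d * step_len
          } else {
            on_circuit <- TRUE
            arc <- arc + (step_len - d)
            pos <- pf(arc)
          }
        } else {
          arc <- arc + step_len
          pos <- pf(arc)
        }
        xs <- c(xs, pos[1]); ys <- c(ys, pos[2])
      }
    } else {
      xs <- c(xs, rep(pos[1], nfr)); ys <- c(ys, rep(pos[2], nfr))
    }
    motions <- c(motions, rep(motion_pct, nfr))
    labels <- c(labels, rep(lab, nfr))
  }
  n <- length(xs)
  if (jitter_sd > 0) {
    xs <- xs + stats::rnorm(n, sd = jitter_sd)
    ys <- ys + stats::rnorm(n, sd = jitter_sd)
  }
  xs <- pmin(pmax(xs, 0), arena[1])
  ys <- pmin(pmax(ys, 0), arena[2])
  time <- (seq_len(n) - 1) / fr

  rr <- rle(labels)
  ends <- cumsum(rr$lengths)
  starts <- ends - rr$lengths + 1
  truth_etho <- event_table(data.frame(
    behavior = rr$values, start = time[starts],
    stop = time[ends] + 1 / fr))

  traj <- trajectory(seq_len(n) - 1L, time, xs, ys, motions, fr, arena)
  list(trajectory = traj,
       truth = list(ethogram = truth_etho, script = script,
                    jitter_sd = jitter_sd, seed = as.integer(seed)))
}

#' Generate a head-dip schedule with focused-exploration structure
#'
#' Produces head-dip intervals grouped into ground-truth focused
#' exploration episodes (inter-dip gaps below the chaining threshold) and
#' isolated dips (gaps above it).
#'
#' @param seed integer seed (required).
#' @param n_episodes number of multi-dip episodes.
#' @param n_isolated number of isolated dips.
#' @param dips_per_episode dips in each episode (recycled).
#' @param gap_range within-episode end-to-start gap range (s), must stay
#'   below the 5-s chaining rule.
#' @param dip_duration head-dip duration (s).
#' @return List with `dips` (an `event_table`) and `truth`.
#' @export
gen_headdips <- function(seed, n_episodes = 3, n_isolated = 4,
                         dips_per_episode = 3, gap_range = c(1, 4),
                         dip_duration = 1) {
  require_seed(seed)
  t <- 5
  rows <- list()
  episode_id <- integer(0)
  eid <- 0
  per <- rep_len(dips_per_episode, n_episodes)
  for (e in seq_len(n_episodes)) {
    eid <- eid + 1
    for (d in seq_len(per[e])) {
      rows[[length(rows) + 1L]] <- data.frame(
        behavior = "head_dip", start = t, stop = t + dip_duration)
      episode_id <- c(episode_id, eid)
      t <- t + dip_duration + stats::runif(1, gap_range[1], gap_range[2])
    }
    t <- t + 8   # > 5 s: break the chain
  }
  for (d in seq_len(n_isolated)) {
    rows[[length(rows) + 1L]] <- data.frame(
      behavior = "head_dip", start = t, stop = t + dip_duration)
    episode_id <- c(episode_id, 0L)
    t <- t + dip_duration + 8
  }
  dips <- event_table(do.call(rbind, rows))
  list(dips = dips,
       truth = list(episode_id = episode_id, n_episodes = n_episodes,
                    n_isolated = n_isolated, seed = as.integer(seed)))
}

#' Generate an optogenetic stimulation experiment with known responders
#'
#' Each unit fires as a Poisson process at a baseline rate drawn uniformly
#' from `baseline_range` (the tonic range observed in midbrain recordings,
#' 2.2-31.8 Hz). The protocol is a 1-min baseline, then 6 single 10-ms
#' pulses (5 s ITI), then 6 bursts (5 pulses, 10 Hz, 10 ms width, 5 s ITI).
#' Responder units are inhibited by `inhibition_depth` (fraction of the
#' baseline rate removed) in a window starting `inhibition_latency` after
#' each pulse onset; inhibition is realized by exact thinning of the
#' homogeneous train.
#'
#' @param n_units number of units (>= 1).
#' @param config a `session_config`.
#' @param seed integer seed (required).
#' @param responder_flags logical vector (recycled) marking inhibited
#'   units.
#' @param inhibition_depth fraction of baseline rate suppressed, in [0, 1].
#' @param inhibition_latency seconds from pulse onset to inhibition onset.
#' @param inhibition_window inhibition duration after (last) pulse (s).
#' @param baseline_range uniform range for tonic rates (Hz).
#' @param baseline_rates optional explicit per-unit rates (overrides the
#'   range).
#' @return List with `experiment` (a `stim_experiment`) and `truth`
#'   (`responder_flags`, rates, latency, depth).
#' @export
gen_spiketrains <- function(n_units, config = default_config(), seed,
                            responder_flags = FALSE,
                            inhibition_depth = 1,
                            inhibition_latency = 0.02,
                            inhibition_window = 0.5,
                            baseline_range = c(2.2, 31.8),
                            baseline_rates = NULL) {
  require_seed(seed)
  if (n_units < 1)
    ek_stop("n_units must be >= 1", "ek_parameter_error")
  if (inhibition_depth < 0 || inhibition_depth > 1)
    ek_stop("inhibition_depth must lie in [0, 1]", "ek_parameter_error")
  flags <- rep_len(responder_flags, n_units)
  rates <- if (is.null(baseline_rates))
    stats::runif(n_units, baseline_range[1], baseline_range[2])
  else rep_len(baseline_rates, n_units)

  single_pulses <- 65 + 5 * (0:5)
  bursts <- 100 + 5 * (0:5)
  burst_n <- 5; burst_hz <- 10; pw <- 0.01
  burst_dur <- (burst_n - 1) / burst_hz + pw
  t_end <- max(bursts) + 5

  # inhibition windows: per single pulse and per burst (covering the burst)
  inh_windows <- rbind(
    cbind(single_pulses + inhibition_latency,
          single_pulses + inhibition_latency + inhibition_window),
    cbind(bursts + inhibition_latency,
          bursts + burst_dur + inhibition_window))

  spikes <- vector("list", n_units)
  for (u in seq_len(n_units)) {
    nsp <- stats::rpois(1, rates[u] * t_end)
    st <- sort(stats::runif(nsp, 0, t_end))
    if (flags[u] && inhibition_depth > 0 && length(st) > 0) {
      in_win <- rep(FALSE, length(st))
      for (w in seq_len(nrow(inh_windows)))
        in_win <- in_win | (st >= inh_windows[w, 1] & st < inh_windows[w, 2])
      drop <- in_win & stats::runif(length(st)) < inhibition_depth
      st <- st[!drop]
    }
    spikes[[u]] <- st
  }
  names(spikes) <- sprintf("unit%03d", seq_len(n_units))
  exp <- stim_experiment(spikes, single_pulses, bursts,
                         baseline_window = c(0, 60),
                         burst_n_pulses = burst_n, burst_hz = burst_hz,
                         pulse_width = pw)
  list(experiment = exp,
       truth = list(responder_flags = flags, baseline_rates = rates,
                    inhibition_depth = inhibition_depth,
                    inhibition_latency = inhibition_latency,
                    inhibition_window = inhibition_window,
                    seed = as.integer(seed)))
}

#' Generate a puncta-count table with known positive fractions
#'
#' SYP positivity is Bernoulli(`p_syp`); vGLUT2 positivity is
#' Bernoulli(`p_vglut2_given_syp`) for SYP+ cells and
#' Bernoulli(`p_vglut2_given_not_syp`) otherwise. Positive cells receive
#' counts of 4 plus a Poisson(4) excess; negative cells receive counts in
#' 0-3.
#'
#' @param n_cells number of cells.
#' @param p_syp,p_vglut2_given_syp,p_vglut2_given_not_syp probabilities in
#'   [0, 1].
#' @param seed integer seed (required).
#' @return List with `puncta` (data.frame `cell_id`, `syp_count`,
#'   `vglut2_count`) and `truth` (the per-cell labels and probabilities).
#' @export
gen_puncta <- function(n_cells, p_syp = 0.4, p_vglut2_given_syp = 0.8,
                       p_vglut2_given_not_syp = 0.5, seed) {
  require_seed(seed)
  probs <- c(p_syp, p_vglut2_given_syp, p_vglut2_given_not_syp)
  if (any(probs < 0) || any(probs > 1))
    ek_stop("probabilities must lie in [0, 1]", "ek_parameter_error")
  is_syp <- stats::runif(n_cells) < p_syp
  is_vglut2 <- ifelse(is_syp,
                      stats::runif(n_cells) < p_vglut2_given_syp,
                      stats::runif(n_cells) < p_vglut2_given_not_syp)
  pos_count <- function(pos) {
    cnt <- integer(length(pos))
    cnt[pos] <- 4L + stats::rpois(sum(pos), 4)
    cnt[!pos] <- sample(0:3, sum(!pos), replace = TRUE,
                        prob = c(0.4, 0.3, 0.2, 0.1))
    cnt
  }
  puncta <- data.frame(
    cell_id = sprintf("cell%04d", seq_len(n_cells)),
    syp_count = pos_count(is_syp),
    vglut2_count = pos_count(is_vglut2),
    stringsAsFactors = FALSE)
  list(puncta = puncta,
       truth = list(is_syp = is_syp, is_vglut2 = is_vglut2,
                    p_syp = p_syp,
                    p_vglut2_given_syp = p_vglut2_given_syp,
                    p_vglut2_given_not_syp = p_vglut2_given_not_syp,
                    seed = as.integer(seed)))
}
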