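# Behavioral-state classification from arena tracking. All thresholds are
# taken from the config `thresholds` block; comparisons are strict in the
# direction written there (< 6 cm/s for immobility, > 6 cm/s for locomotion)
# so exactly-threshold frames fall to the residual "surveying" category.
# Intervals are half-open [start, stop): a run of frames i..j spans
# [time[i], time[j] + 1/frame_rate).

# maximal runs of TRUE; returns data.frame(first, last) of frame indices
runs_of <- function(mask) {
  r <- rle(mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  data.frame(first = starts[r$values], last = ends[r$values])
}

run_interval <- function(traj, first, last) {
  dt <- 1 / traj$frame_rate
  data.frame(start = traj$time[first], stop = traj$time[last] + dt)
}

# Gaussian smoothing of a series with a given window (s); kernel sd is
# window/4 so +/-2 sd spans the window; edge-normalized.
gauss_smooth <- function(v, frame_rate, window) {
  if (window <= 0) return(v)
  sd_s <- window / 4
  half <- max(1L, ceiling(2 * sd_s * frame_rate))
  k <- stats::dnorm(seq(-half, half), sd = sd_s * frame_rate)
  n <- length(v)
  num <- stats::filter(c(rep(0, half), v, rep(0, half)), k, sides = 2)
  den <- stats::filter(c(rep(0, half), rep(1, n), rep(0, half)), k,
                       sides = 2)
  as.numeric(num[(half + 1):(half + n)] / den[(half + 1):(half + n)])
}

#' Instantaneous speed from tracked position
#'
#' Positions are Gaussian-smoothed (1-s window by default), then speed is
#' the frame-to-frame displacement times the frame rate. The first frame
#' repeats the second so the series has one speed per frame.
#'
#' @param traj a `trajectory`.
#' @param smooth_window smoothing window in seconds; 0 gives the raw
#'   finite-difference speed.
#' @return List with `speed` (cm/s per frame) and the smoothed `x`, `y`.
#' @export
velocity <- function(traj, smooth_window = 1) {
  if (length(traj$x) < 2)
    ek_stop("velocity needs >= 2 frames", "ek_data_error")
  xs <- gauss_smooth(traj$x, traj$frame_rate, smooth_window)
  ys <- gauss_smooth(traj$y, traj$frame_rate, smooth_window)
  disp <- sqrt(diff(xs)^2 + diff(ys)^2)
  sp <- c(disp[1], disp) * traj$frame_rate
  list(speed = sp, x = xs, y = ys)
}

#' Detect immobility bouts
#'
#' Maximal runs of frames with speed below the immobility speed cutoff AND
#' per-frame motion below the motion cutoff; a run is kept only if it is
#' longer than `immobility_min_frames` frames (strictly more than 15 by
#' default).
#'
#' @param traj a `trajectory`.
#' @param config a `session_config`.
#' @param vel optional precomputed [velocity()] result.
#' @return data.frame of bout intervals (`start`, `stop`, seconds).
#' @export
detect_immobility <- function(traj, config = default_config(), vel = NULL) {
  th <- config$thresholds
  if (is.null(vel)) vel <- velocity(traj)
  mask <- vel$speed < th$immobility_speed & traj$motion < th$immobility_motion
  rr <- runs_of(mask)
  rr <- rr[rr$last - rr$first + 1 > th$immobility_min_frames, , drop = FALSE]
  if (nrow(rr) == 0) return(data.frame(start = numeric(0), stop = numeric(0)))
  run_interval(traj, rr$first, rr$last)
}

#' Detect locomotion bouts and locomotor distance
#'
#' Maximal runs of frames with speed above the locomotion cutoff; runs whose
#' path length is below the minimum distance (100 mm) are discarded. A
#' continuous run counts as a single bout. Distance is the summed path
#' length over surviving runs.
#'
#' @inheritParams detect_immobility
#' @return List with `bouts` (data.frame `start`, `stop`, `distance`) and
#'   total `distance` (cm).
#' @export
detect_locomotion <- function(traj, config = default_config(), vel = NULL) {
  th <- config$thresholds
  if (is.null(vel)) vel <- velocity(traj)
  mask <- vel$speed > th$locomotion_speed
  rr <- runs_of(mask)
  step <- sqrt(diff(vel$x)^2 + diff(vel$y)^2) # length n-1; step i = i -> i+1
  keep <- logical(nrow(rr))
  dist <- numeric(nrow(rr))
  for (i in seq_len(nrow(rr))) {
    f <- rr$first[i]; l <- rr$last[i]
    d <- if (l > f) sum(step[f:(l - 1)]) else 0
    dist[i] <- d
    keep[i] <- d >= th$locomotion_min_distance
  }
  rr <- rr[keep, , drop = FALSE]
  dist <- dist[keep]
  bouts <- if (nrow(rr) == 0)
    data.frame(start = numeric(0), stop = numeric(0), distance = numeric(0))
  else cbind(run_interval(traj, rr$first, rr$last), distance = dist)
  list(bouts = bouts, distance = sum(dist))
}

#' Detect pauses and locomotion-initiation times
#'
#' Pauses are maximal runs of frames with speed below the pause cutoff
#' (3 cm/s) lasting at least the minimum duration (1 s); locomotion
#' initiations are aligned at pause termination.
#'
#' @inheritParams detect_immobility
#' @return List with `pauses` (interval data.frame) and `initiations`
#'   (numeric vector of pause end times, seconds).
#' @export
detect_pauses <- function(traj, config = default_config(), vel = NULL) {
  th <- config$thresholds
  if (is.null(vel)) vel <- velocity(traj)
  mask <- vel$speed < th$pause_speed
  rr <- runs_of(mask)
  dur <- (rr$last - rr$first + 1) / traj$frame_rate
  rr <- rr[dur >= th$pause_min_duration, , drop = FALSE]
  if (nrow(rr) == 0)
    return(list(pauses = data.frame(start = numeric(0), stop = numeric(0)),
                initiations = numeric(0)))
  iv <- run_interval(traj, rr$first, rr$last)
  list(pauses = iv, initiations = iv$stop)
}

# TRUE for frames inside the central zone (complement of the peripheral
# thigmotactic band).
in_center <- function(x, y, arena, fraction = 0.25, mode = c("linear", "area")) {
  mode <- match.arg(mode)
  band <- if (mode == "linear") {
    # outer band covering `fraction` of the linear extent per axis:
    # band width = fraction/2 of the side at each wall
    fraction / 2 * arena
  } else {
    # band width such that the band covers `fraction` of the arena area
    arena / 2 * (1 - sqrt(1 - fraction))
  }
  x >= band[1] & x <= arena[1] - band[1] &
    y >= band[2] & y <= arena[2] - band[2]
}

#' Center-zone and thigmotaxis metrics
#'
#' The thigmotactic zone is the peripheral band of the arena (25% by
#' default, interpreted linearly: the band occupies 25% of each side's
#' extent, 12.5% at each wall); the center zone is its complement. Each
#' frame contributes `1/frame_rate` of time to the zone its position falls
#' in, so center time plus thigmotaxis time equals session duration.
#'
#' @inheritParams detect_immobility
#' @return List with `center_time`, `thigmo_time` (s), `center_distance`,
#'   `thigmo_distance` (cm), and `thigmo_intervals` (data.frame).
#' @export
zone_metrics <- function(traj, config = default_config(), vel = NULL) {
  th <- config$thresholds
  if (is.null(vel)) vel <- velocity(traj)
  ctr <- in_center(traj$x, traj$y, traj$arena, th$zone_fraction,
                   th$zone_mode)
  dt <- 1 / traj$frame_rate
  step <- c(sqrt(diff(vel$x)^2 + diff(vel$y)^2), 0) # step leaving frame i
  rr <- runs_of(!ctr)
  thig <- if (nrow(rr) == 0)
    data.frame(start = numeric(0), stop = numeric(0))
  else run_interval(traj, rr$first, rr$last)
  list(center_time = sum(ctr) * dt,
       thigmo_time = sum(!ctr) * dt,
       center_distance = sum(step[ctr]),
       thigmo_distance = sum(step[!ctr]),
       thigmo_intervals = thig)
}

#' Chain head-dips into focused-exploration episodes
#'
#' Two or more successive head-dips with an end-to-start gap of at most
#' `focused_gap` seconds (5 s) are merged transitively into one episode
#' spanning from the first dip's start to the last dip's end. Dips that do
#' not chain are isolated head-dips; every input dip belongs to exactly one
#' category.
#'
#' @param dips an `event_table` (or data.frame) of head-dip intervals.
#' @param max_gap maximum end-to-start gap (s).
#' @return List with `episodes` (data.frame `start`, `stop`, `n_dips`) and
#'   `isolated` (the dip rows that chained with nothing).
#' @export
detect_focused_exploration <- function(dips, max_gap = 5) {
  dips <- dips[order(dips$start), , drop = FALSE]
  n <- nrow(dips)
  if (n == 0)
    return(list(episodes = data.frame(start = numeric(0), stop = numeric(0),
                                      n_dips = integer(0)),
                isolated = dips))
  gaps <- if (n > 1) dips$start[-1] - dips$stop[-n] else numeric(0)
  grp <- cumsum(c(1, as.integer(gaps > max_gap)))
  episodes <- list()
  iso <- integer(0)
  for (g in unique(grp)) {
    idx <- which(grp == g)
    if (length(idx) >= 2) {
      episodes[[length(episodes) + 1L]] <- data.frame(
        start = dips$start[idx[1]], stop = dips$stop[idx[length(idx)]],
        n_dips = length(idx))
    } else {
      iso <- c(iso, idx)
    }
  }
  ep <- if (length(episodes)) do.call(rbind, episodes) else
    data.frame(start = numeric(0), stop = numeric(0), n_dips = integer(0))
  list(episodes = ep, isolated = dips[iso, , drop = FALSE])
}

#' Build a behavioral ethogram
#'
#' Assigns every frame exactly one of the five open-field states. Precedence:
#' manually scored grooming/rearing events win over everything, then
#' immobility, then locomotion; frames matching nothing are surveying (the
#' residual category: the animal is neither immobile nor locomoting).
#'
#' @param traj a `trajectory`.
#' @param manual_events an `event_table` whose `behavior` column may contain
#'   `grooming` and `rearing` intervals; may be empty or `NULL`.
#' @param config a `session_config`.
#' @return An object of class `ethogram`: a data.frame of labeled intervals
#'   (`behavior`, `start`, `stop`) with the per-frame label vector in
#'   attribute `frame_labels`.
#' @export
build_ethogram <- function(traj, manual_events = NULL,
                           config = default_config()) {
  n <- length(traj$frame)
  if (n == 0) ek_stop("empty trajectory", "ek_empty_error")
  vel <- velocity(traj)
  lab <- rep("surveying", n)

  loco <- detect_locomotion(traj, config, vel)
  for (i in seq_len(nrow(loco$bouts)))
    lab[traj$time >= loco$bouts$start[i] & traj$time < loco$bouts$stop[i]] <-
      "locomotion"

  immo <- detect_immobility(traj, config, vel)
  for (i in seq_len(nrow(immo)))
    lab[traj$time >= immo$start[i] & traj$time < immo$stop[i]] <-
      "immobility"

  if (!is.null(manual_events) && nrow(manual_events) > 0) {
    man <- manual_events[manual_events$behavior %in% c("grooming", "rearing"), ,
                         drop = FALSE]
    for (i in seq_len(nrow(man)))
      lab[traj$time >= man$start[i] & traj$time < man$stop[i]] <-
        man$behavior[i]
  }

  rr <- rle(lab)
  ends <- cumsum(rr$lengths)
  starts <- ends - rr$lengths + 1
  iv <- run_interval(traj, starts, ends)
  etho <- data.frame(behavior = rr$values, start = iv$start, stop = iv$stop,
                     stringsAsFactors = FALSE)
  attr(etho, "frame_labels") <- lab
  class(etho) <- c("ethogram", "data.frame")
  etho
}

# length of intersection of [a1,a2) with [b1,b2)
overlap_len <- function(a1, a2, b1, b2) pmax(0, pmin(a2, b2) - pmax(a1, b1))

#' Per-epoch behavioral metrics with baseline (Pre) normalization
#'
#' Splits the session into the configured epoch design (e.g. Pre/ON/OFF
#' repeated, 3-min epochs, half-open intervals), computes per-epoch metrics,
#' averages repetitions of the same label, and normalizes each label's
#' metrics to the Pre baseline (subtraction by default; `mode = "ratio"`
#' divides instead).
#'
#' @param etho an `ethogram` (or `NULL` to skip state durations).
#' @param traj a `trajectory`.
#' @param dips an `event_table` of head-dip intervals (or `NULL`).
#' @param config a `session_config`; `epoch_design` and `epoch_length`
#'   define the epochs, starting at the first tracked frame.
#' @param mode baseline normalization: `"subtract"` or `"ratio"`.
#' @return List with `per_epoch` (data.frame, one row per epoch instance),
#'   `by_label` (repetitions averaged), and `normalized` (`by_label` after
#'   Pre-correction).
#' @export
epoch_metrics <- function(etho, traj, dips = NULL,
                          config = default_config(),
                          mode = c("subtract", "ratio")) {
  mode <- match.arg(mode)
  t0 <- traj$time[1]
  len <- config$epoch_length
  design <- config$epoch_design
  t_end <- traj$time[length(traj$time)] + 1 / traj$frame_rate
  if (t0 + length(design) * len > t_end + 1e-9)
    ek_stop(sprintf(
      "epoch design (%d x %g s) extends past session end (%.1f s)",
      length(design), len, t_end - t0), "ek_parameter_error")
  vel <- velocity(traj)
  loco <- detect_locomotion(traj, config, vel)
  zones_ctr <- in_center(traj$x, traj$y, traj$arena,
                         config$thresholds$zone_fraction,
                         config$thresholds$zone_mode)
  dt <- 1 / traj$frame_rate
  step <- c(sqrt(diff(vel$x)^2 + diff(vel$y)^2), 0)
  in_loco <- rep(FALSE, length(traj$time))
  for (i in seq_len(nrow(loco$bouts)))
    in_loco[traj$time >= loco$bouts$start[i] &
              traj$time < loco$bouts$stop[i]] <- TRUE

  states <- c("immobility", "grooming", "surveying", "rearing", "locomotion")
  rows <- list()
  for (k in seq_along(design)) {
    a <- t0 + (k - 1) * len
    b <- a + len
    infr <- traj$time >= a & traj$time < b
    row <- list(epoch = k, label = design[k], start = a, stop = b)
    for (s in states) {
      row[[paste0("dur_", s)]] <- if (is.null(etho)) NA_real_ else
        sum(overlap_len(etho$start[etho$behavior == s],
                        etho$stop[etho$behavior == s], a, b))
    }
    row$loco_bouts <- sum(loco$bouts$start >= a & loco$bouts$start < b)
    row$loco_distance <- sum(step[infr & in_loco])
    row$mean_speed <- mean(vel$speed[infr])
    row$center_time <- sum(zones_ctr & infr) * dt
    row$center_distance <- sum(step[zones_ctr & infr])
    if (!is.null(dips) && nrow(dips) > 0) {
      row$headdip_count <- sum(dips$start >= a & dips$start < b)
      row$headdip_duration <- sum(overlap_len(dips$start, dips$stop, a, b))
    } else {
      row$headdip_count <- 0
      row$headdip_duration <- 0
    }
    rows[[k]] <- as.data.frame(row, stringsAsFactors = FALSE)
  }
  per_epoch <- do.call(rbind, rows)

  metric_cols <- setdiff(names(per_epoch), c("epoch", "label", "start", "stop"))
  by_label <- stats::aggregate(per_epoch[metric_cols],
                               by = list(label = per_epoch$label), mean)
  if (!"Pre" %in% by_label$label)
    ek_stop("epoch design has no Pre epoch to normalize to",
            "ek_parameter_error")
  pre <- by_label[by_label$label == "Pre", metric_cols]
  normalized <- by_label
  for (cc in metric_cols) {
    normalized[[cc]] <- if (mode == "subtract")
      by_label[[cc]] - pre[[cc]]
    else by_label[[cc]] / ifelse(pre[[cc]] == 0, NA_real_, pre[[cc]])
  }
  list(per_epoch = per_epoch, by_label = by_label, normalized = normalized,
       mode = mode)
}
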