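# Readers and writers for the delimited-text formats the pipeline consumes:
# two-channel photometry traces, arena tracking, BORIS-style event logs,
# spike/stimulus time lists, and per-cell puncta tables. All tables are
# comma- or tab-delimited with a header row. Times are seconds everywhere;
# intervals are half-open [start, stop).

read_delim_checked <- function(path, required, what = "table") {
  if (!file.exists(path))
    ek_stop(sprintf("file not found: %s", path), "ek_io_error")
  if (file.size(path) == 0)
    ek_stop(sprintf("empty input: %s", path), "ek_empty_error")
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0)
    ek_stop(sprintf("empty input: %s has a header but no rows", path),
            "ek_empty_error")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0)
    ek_stop(sprintf("%s %s is missing required column(s): %s",
                    what, path, paste(missing, collapse = ", ")),
            "ek_format_error")
  df
}

# print doubles with enough digits that read.table restores them exactly
full_precision <- function(df) {
  for (nm in names(df))
    if (is.double(df[[nm]])) df[[nm]] <- sprintf("%.17g", df[[nm]])
  df
}

#' Construct a photometry session
#'
#' A two-channel recording: the calcium-dependent 465 nm signal and the
#' calcium-independent (isosbestic) 405 nm reference on one shared time base.
#'
#' @param time sample times in seconds, strictly increasing.
#' @param signal 465 nm channel, arbitrary units.
#' @param reference 405 nm channel, arbitrary units.
#' @return An object of class `photometry_session`.
#' @export
photometry_session <- function(time, signal, reference) {
  if (length(time) != length(signal) || length(time) != length(reference))
    ek_stop("time, signal and reference must have equal length",
            "ek_data_error")
  if (length(time) < 2 || any(diff(time) <= 0))
    ek_stop("time must be strictly increasing with >= 2 samples",
            "ek_data_error")
  structure(
    list(time = as.numeric(time), signal = as.numeric(signal),
         reference = as.numeric(reference),
         native_rate = 1 / stats::median(diff(time))),
    class = "photometry_session")
}

#' @export
print.photometry_session <- function(x, ...) {
  cat(sprintf("photometry_session: %d samples, %.1f s, ~%.1f Hz\n",
              length(x$time), diff(range(x$time)), x$native_rate))
  invisible(x)
}

#' Read a two-channel photometry recording
#'
#' Expects a delimited text file with columns `time`, `signal_465`, `ref_405`.
#'
#' @param path input file.
#' @return A `photometry_session`.
#' @export
read_photometry <- function(path) {
  df <- read_delim_checked(path, c("time", "signal_465", "ref_405"),
                           "photometry file")
  if (any(diff(df$time) <= 0))
    ek_stop(sprintf("photometry file %s: time is not strictly increasing",
                    path), "ek_data_error")
  photometry_session(df$time, df$signal_465, df$ref_405)
}

#' Write a photometry session
#'
#' @param session a `photometry_session`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_photometry <- function(session, path) {
  utils::write.csv(
    full_precision(data.frame(time = session$time,
                              signal_465 = session$signal,
                              ref_405 = session$reference)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a behavioral event log
#'
#' Accepts both dialects of a BORIS-style export: interval rows with columns
#' `behavior`, `start`, `stop`; or point rows with columns `behavior`, `time`,
#' `type` where `type` is `START` or `STOP` and rows are paired per behavior
#' label. Either way the result is a normalized interval table sorted by
#' start, with half-open `[start, stop)` semantics.
#'
#' @param path input file.
#' @return A data.frame with columns `behavior`, `start`, `stop`.
#' @export
read_events <- function(path) {
  if (!file.exists(path))
    ek_stop(sprintf("file not found: %s", path), "ek_io_error")
  if (file.size(path) == 0)
    ek_stop(sprintf("empty input: %s", path), "ek_empty_error")
  first <- readLines(path, n = 1L, warn = FALSE)
  sep <- if (grepl("\t", first)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0)
    ek_stop(sprintf("empty input: %s has a header but no rows", path),
            "ek_empty_error")
  if (all(c("start", "stop") %in% names(df))) {
    ev <- data.frame(behavior = as.character(df$behavior),
                     start = as.numeric(df$start),
                     stop = as.numeric(df$stop),
                     stringsAsFactors = FALSE)
  } else if (all(c("time", "type") %in% names(df))) {
    ev <- pair_point_events(df, path)
  } else {
    ek_stop(sprintf(
      "event file %s needs columns (behavior,start,stop) or (behavior,time,type)",
      path), "ek_format_error")
  }
  event_table(ev)
}

pair_point_events <- function(df, path) {
  df <- df[order(df$time), , drop = FALSE]
  out <- list()
  open <- list() # per-label stack of open START times
  for (i in seq_len(nrow(df))) {
    lab <- as.character(df$behavior[i])
    ty <- toupper(as.character(df$type[i]))
    if (ty == "START") {
      open[[lab]] <- c(open[[lab]], df$time[i])
    } else if (ty == "STOP") {
      if (is.null(open[[lab]]) || length(open[[lab]]) == 0)
        ek_stop(sprintf("%s: STOP without matching START for '%s' at t=%g s",
                        path, lab, df$time[i]), "ek_pairing_error")
      st <- open[[lab]][length(open[[lab]])]
      open[[lab]] <- open[[lab]][-length(open[[lab]])]
      out[[length(out) + 1L]] <- data.frame(
        behavior = lab, start = st, stop = df$time[i],
        stringsAsFactors = FALSE)
    } else {
      ek_stop(sprintf("%s: unknown event type '%s' (expected START/STOP)",
                      path, ty), "ek_format_error")
    }
  }
  dangling <- names(open)[vapply(open, length, integer(1)) > 0]
  if (length(dangling) > 0)
    ek_stop(sprintf("%s: START without matching STOP for: %s",
                    path, paste(dangling, collapse = ", ")),
            "ek_pairing_error")
  do.call(rbind, out)
}

#' Construct / validate an event interval table
#'
#' @param df data.frame with columns `behavior`, `start`, `stop` (seconds).
#' @return The table sorted by `start`, class `event_table`.
#' @export
event_table <- function(df) {
  if (!all(c("behavior", "start", "stop") %in% names(df)))
    ek_stop("event table needs columns behavior, start, stop",
            "ek_format_error")
  if (any(df$stop < df$start))
    ek_stop("event table has stop < start", "ek_data_error")
  if (any(df$start < 0))
    ek_stop("event table has negative times", "ek_data_error")
  df <- df[order(df$start), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_table", "data.frame")
  df
}

#' Write an event interval table
#' @param events an `event_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_events <- function(events, path) {
  utils::write.csv(full_precision(as.data.frame(events)), path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Construct a tracking trajectory
#'
#' @param frame integer frame indices (consecutive).
#' @param time seconds.
#' @param x,y position in cm.
#' @param motion per-frame body-change percentage from the tracker.
#' @param frame_rate acquisition rate in Hz (required; the tracker's export
#'   does not always carry it, so it is an explicit argument).
#' @param arena arena side lengths in cm, length-2 numeric.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(frame, time, x, y, motion, frame_rate, arena) {
  n <- length(frame)
  if (n == 0) ek_stop("empty trajectory", "ek_empty_error")
  if (any(lengths(list(time, x, y, motion)) != n))
    ek_stop("trajectory columns must have equal length", "ek_data_error")
  if (missing(frame_rate) || is.null(frame_rate) || !is.finite(frame_rate))
    ek_stop("frame_rate is required for a trajectory", "ek_config_error")
  if (missing(arena) || length(arena) != 2)
    ek_stop("arena must be a length-2 numeric (cm x cm)", "ek_config_error")
  if (any(diff(frame) != 1))
    ek_stop("frames must be consecutive", "ek_data_error")
  structure(
    list(frame = as.integer(frame), time = as.numeric(time),
         x = as.numeric(x), y = as.numeric(y), motion = as.numeric(motion),
         frame_rate = frame_rate, arena = as.numeric(arena)),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("trajectory: %d frames at %g Hz, arena %g x %g cm\n",
              length(x$frame), x$frame_rate, x$arena[1], x$arena[2]))
  invisible(x)
}

#' Read a tracking table
#'
#' Expects columns `frame`, `time`, `x`, `y`, `motion`.
#'
#' @param path input file.
#' @param frame_rate Hz; if `NULL`, inferred from the median time step.
#' @param arena arena side lengths in cm.
#' @return A `trajectory`.
#' @export
read_tracking <- function(path, frame_rate = NULL, arena = c(50, 50)) {
  df <- read_delim_checked(path, c("frame", "time", "x", "y", "motion"),
                           "tracking file")
  if (is.null(frame_rate)) frame_rate <- 1 / stats::median(diff(df$time))
  trajectory(df$frame, df$time, df$x, df$y, df$motion, frame_rate, arena)
}

#' Write a tracking table
#' @param traj a `trajectory`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tracking <- function(traj, path) {
  utils::write.csv(
    full_precision(data.frame(frame = traj$frame, time = traj$time,
                              x = traj$x, y = traj$y,
                              motion = traj$motion)),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read sorted spike times
#'
#' Expects columns `unit`, `spike_time`; returns a named list of per-unit
#' spike-time vectors (sorted).
#'
#' @param path input file.
#' @return Named list of numeric vectors.
#' @export
read_spikes <- function(path) {
  df <- read_delim_checked(path, c("unit", "spike_time"), "spike file")
  sp <- split(as.numeric(df$spike_time), as.character(df$unit))
  lapply(sp, sort)
}

#' Write spike times
#' @param spikes named list of per-unit spike-time vectors.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_spikes <- function(spikes, path) {
  df <- data.frame(
    unit = rep(names(spikes), lengths(spikes)),
    spike_time = unlist(spikes, use.names = FALSE))
  utils::write.csv(full_precision(df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read optogenetic stimulus timestamps
#'
#' Expects columns `type` (`single` or `burst`) and `time` (onset seconds).
#'
#' @param path input file.
#' @return List with elements `single_pulses` and `bursts`.
#' @export
read_stim <- function(path) {
  df <- read_delim_checked(path, c("type", "time"), "stimulus file")
  list(single_pulses = sort(df$time[df$type == "single"]),
       bursts = sort(df$time[df$type == "burst"]))
}

#' Write optogenetic stimulus timestamps
#' @param stim list with `single_pulses`, `bursts`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stim <- function(stim, path) {
  df <- data.frame(
    type = c(rep("single", length(stim$single_pulses)),
             rep("burst", length(stim$bursts))),
    time = c(stim$single_pulses, stim$bursts))
  utils::write.csv(full_precision(df), path, row.names = FALSE,
                   quote = FALSE)
  invisible(path)
}

#' Read a per-cell puncta-count table
#'
#' Expects columns `cell_id`, `syp_count`, `vglut2_count`.
#'
#' @param path input file.
#' @return A data.frame with integer counts.
#' @export
read_puncta <- function(path) {
  df <- read_delim_checked(path, c("cell_id", "syp_count", "vglut2_count"),
                           "puncta file")
  if (any(df$syp_count < 0) || any(df$vglut2_count < 0) ||
      any(df$syp_count != round(df$syp_count)) ||
      any(df$vglut2_count != round(df$vglut2_count)))
    ek_stop("puncta counts must be non-negative integers", "ek_data_error")
  df$syp_count <- as.integer(df$syp_count)
  df$vglut2_count <- as.integer(df$vglut2_count)
  df
}

#' Write a puncta-count table
#' @param puncta data.frame with `cell_id`, `syp_count`, `vglut2_count`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_puncta <- function(puncta, path) {
  utils::write.csv(puncta, path, row.names = FALSE)
  invisible(path)
}

#' Write a results table plus a JSON summary
#'
#' @param table a data.frame of per-row results.
#' @param summary a named list of scalar summaries.
#' @param csv_path,json_path output paths.
#' @return A list of the two paths, invisibly.
#' @export
write_results <- function(table, summary, csv_path, json_path) {
  utils::write.csv(table, csv_path, row.names = FALSE)
  jsonlite::write_json(summary, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null", na = "null")
  invisible(list(csv = csv_path, json = json_path))
}
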