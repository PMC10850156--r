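#' @keywords internal
"_PACKAGE"

# Structured error helper: all package errors carry class "ek_error" plus a
# specific subclass so callers (and tests) can distinguish failure modes.
ek_stop <- function(msg, class) {
  stop(structure(
    class = c(class, "ek_error", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

ek_warn <- function(msg, class = "ek_warning") {
  warning(structure(
    class = c(class, "ek_warning", "warning", "condition"),
    list(message = msg, call = sys.call(-1))
  ))
}

#' Default session configuration
#'
#' Returns the full set of analysis constants used throughout the pipeline:
#' photometry processing rates and windows, the epoch design, and every
#' behavioral / electrophysiological / histological threshold. All values are
#' overridable; the defaults are the conventional values for this class of
#' experiment (3-min Pre/ON/OFF epochs, 100 Hz processing rate, 2 Hz low-pass,
#' 60-s z-score window, 6 cm/s immobility and locomotion speed cutoffs,
#' 3 cm/s pause cutoff, 5-s focused-exploration gap, 4-puncta positivity,
#' 5x baseline-stability discard rule, 0.05 FDR level).
#'
#' The tracking `frame_rate` has no sensible universal default and is `NA`
#' until set; readers and detectors that need it refuse to run while it is
#' missing.
#'
#' @param ... named overrides, e.g. `frame_rate = 30` or
#'   `thresholds = list(pause_speed = 2.5)` (threshold overrides are merged
#'   into the default block, not replacing it).
#' @return A nested list of class `session_config`.
#' @export
#' @examples
#' cfg <- default_config(frame_rate = 30)
#' cfg$thresholds$immobility_speed
default_config <- function(...) {
  cfg <- list(
    sample_rate_target = 100,    # Hz, uniform grid after resampling
    lowpass_cutoff     = 2,      # Hz
    zscore_window      = 60,     # s, moving-window normalization
    epoch_length       = 180,    # s (3-min epochs)
    epoch_design       = c("Pre", "ON", "OFF", "ON", "OFF"),
    frame_rate         = NA_real_, # Hz, tracking; must be supplied
    arena_size         = c(50, 50), # cm, open field; hole-board is 45.5
    motion_poly_degree = 1,      # polynomial degree for 405->465 fit
    rng_seed           = NA_integer_,
    thresholds = list(
      immobility_speed        = 6,    # cm/s, strict <
      immobility_motion       = 1,    # % body change, strict <
      immobility_min_frames   = 15,   # bout kept only if run length > 15
      locomotion_speed        = 6,    # cm/s, strict >
      locomotion_min_distance = 10,   # cm (100 mm rule)
      pause_speed             = 3,    # cm/s, strict <
      pause_min_duration      = 1,    # s, >=
      focused_gap             = 5,    # s, max end-to-start inter-dip gap
      zone_fraction           = 0.25, # peripheral thigmotactic zone
      zone_mode               = "linear",
      puncta_threshold        = 4,    # >= puncta marks a positive cell
      stability_ratio         = 5,    # max/min pre-stimulus rate across trials
      fdr_level               = 0.05,
      event_pre               = 5,    # s before behavior initiation
      event_post              = 5,    # s after
      baseline_window         = c(-5, -3), # s, lags for baseline mean
      extremum_window         = c(0, 3)    # s, lags for corrected max/min
    )
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (nm == "thresholds") {
      for (tn in names(dots$thresholds)) cfg$thresholds[[tn]] <- dots$thresholds[[tn]]
    } else {
      cfg[[nm]] <- dots[[nm]]
    }
  }
  validate_config(cfg)
  class(cfg) <- c("session_config", "list")
  cfg
}

validate_config <- function(cfg) {
  durs <- c(cfg$sample_rate_target, cfg$lowpass_cutoff, cfg$zscore_window,
            cfg$epoch_length)
  if (any(!is.finite(durs)) || any(durs <= 0))
    ek_stop("all rates and durations must be positive", "ek_config_error")
  if (length(cfg$epoch_design) == 0 || any(!nzchar(cfg$epoch_design)))
    ek_stop("epoch_design labels must be nonempty", "ek_config_error")
  th <- cfg$thresholds
  num <- unlist(th[vapply(th, is.numeric, logical(1))])
  if (any(!is.finite(num)))
    ek_stop("thresholds must be finite numbers", "ek_config_error")
  invisible(cfg)
}

#' Read a configuration file
#'
#' Loads a YAML configuration document and merges it over [default_config()],
#' so a file only needs to state the values it changes.
#'
#' @param path path to a YAML file.
#' @return A `session_config` list.
#' @export
read_config <- function(path) {
  if (!file.exists(path))
    ek_stop(sprintf("config file not found: %s", path), "ek_io_error")
  user <- yaml::read_yaml(path)
  if (is.null(user)) ek_stop(sprintf("empty input: %s", path), "ek_empty_error")
  do.call(default_config, user)
}

#' Write a configuration file
#'
#' @param cfg a `session_config` list.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}
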