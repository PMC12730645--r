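#' I-VT detection and windowing configuration
#'
#' @param v0 velocity threshold (deg/s); samples at or below it are
#'   fixation, strictly above it saccade. Default 45 deg/s.
#' @param min_fixation_ms minimum fixation duration (ms); shorter fixation
#'   runs are relabelled saccade. Default 55 ms.
#' @param window_s,step_s sliding-window length and step (s); default 5 s
#'   windows every 1 s.
#' @return an object of class `ivt_config`.
#' @export
ivt_config <- function(v0 = 45, min_fixation_ms = 55, window_s = 5, step_s = 1) {
  if (!is_number(v0) || v0 <= 0) stopf("v0 must be > 0")
  if (!is_number(min_fixation_ms) || min_fixation_ms < 0)
    stopf("min_fixation_ms must be >= 0")
  if (!is_number(step_s) || step_s <= 0 || !is_number(window_s) ||
      window_s < step_s)
    stopf("window_s >= step_s > 0 is required")
  structure(list(v0 = v0, min_fixation_ms = min_fixation_ms,
                 window_s = window_s, step_s = step_s),
            class = "ivt_config")
}

#' Per-sample angular velocities
#'
#' Forward-difference speed between consecutive samples,
#' `v_i = sqrt(dx^2 + dy^2) / dt` with `dt = 1 / rate_hz`; velocity `i`
#' belongs to the transition from sample `i` to `i + 1`.
#'
#' @param rec a `gaze_recording` with at least 2 samples.
#' @return numeric vector of length `n_samples - 1` (deg/s).
#' @export
sample_velocities <- function(rec) {
  n <- length(rec$x)
  if (n < 2) stopf("at least 2 samples are required to compute velocities")
  sqrt(diff(rec$x)^2 + diff(rec$y)^2) * rec$rate_hz
}

#' Classify velocities into fixation/saccade samples
#'
#' @param velocities numeric velocities (deg/s).
#' @param cfg an [ivt_config()].
#' @return character vector, `"fixation"` where `v <= v0` else `"saccade"`.
#' @export
classify_samples <- function(velocities, cfg = ivt_config()) {
  ifelse(velocities <= cfg$v0, "fixation", "saccade")
}

#' Segment per-sample labels into ocular events
#'
#' Maximal runs of identical labels become events; fixation runs shorter
#' than `min_fixation_ms` are relabelled saccade and merged with adjacent
#' saccade runs. Events tile the velocity-index range without gaps; the
#' range `start_idx:(end_idx - 1)` (half-open) indexes velocities, so the
#' event spans samples `start_idx .. end_idx`.
#'
#' @param labels character label vector from [classify_samples()].
#' @param rate_hz sampling rate (Hz).
#' @param cfg an [ivt_config()].
#' @return data frame with `kind`, `start_idx`, `end_idx`, `duration_ms`.
#' @export
segment_events <- function(labels, rate_hz, cfg = ivt_config()) {
  if (!length(labels)) stopf("labels must be non-empty")
  r <- rle(labels)
  short <- r$values == "fixation" &
    r$lengths / rate_hz * 1000 < cfg$min_fixation_ms
  r$values[short] <- "saccade"
  labels2 <- inverse.rle(r)
  r <- rle(labels2)
  ends <- cumsum(r$lengths)
  data.frame(kind = r$values,
             start_idx = c(1L, head(ends, -1L) + 1L),
             end_idx = ends + 1L,
             duration_ms = r$lengths / rate_hz * 1000,
             stringsAsFactors = FALSE)
}

#' Detect ocular events in a recording
#'
#' Convenience wrapper: velocities, I-VT classification, run segmentation,
#' and per-event kinematics (straight-line displacement between event start
#' and end positions; mean of per-sample velocities within the event).
#'
#' @param rec a preprocessed `gaze_recording`.
#' @param cfg an [ivt_config()].
#' @return data frame of events with `kind`, `start_idx`, `end_idx`,
#'   `duration_ms`, `distance_deg`, `mean_speed`.
#' @export
detect_events <- function(rec, cfg = ivt_config()) {
  v <- sample_velocities(rec)
  ev <- segment_events(classify_samples(v, cfg), rec$rate_hz, cfg)
  cs <- c(0, cumsum(v))
  ev$distance_deg <- sqrt((rec$x[ev$end_idx] - rec$x[ev$start_idx])^2 +
                          (rec$y[ev$end_idx] - rec$y[ev$start_idx])^2)
  ev$mean_speed <- (cs[ev$end_idx] - cs[ev$start_idx]) /
    (ev$end_idx - ev$start_idx)
  ev
}

#' Sliding-window sample ranges
#'
#' Windows of `window_s * rate_hz` samples starting every
#' `step_s * rate_hz` samples; a trailing partial window is dropped.
#'
#' @param n_samples recording length in samples.
#' @param rate_hz sampling rate (Hz).
#' @param cfg an [ivt_config()].
#' @return integer matrix with columns `start`, `end` (half-open sample
#'   ranges, 1-based).
#' @export
window_slices <- function(n_samples, rate_hz, cfg = ivt_config()) {
  w <- round(cfg$window_s * rate_hz)
  s <- round(cfg$step_s * rate_hz)
  if (n_samples < w)
    stopf("recording (%d samples) is shorter than one %g s window",
          n_samples, cfg$window_s)
  starts <- seq.int(1L, n_samples - w + 1L, by = s)
  cbind(start = as.integer(starts), end = as.integer(starts + w))
}
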