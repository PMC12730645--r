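#' Class-conditional ocular statistics profile
#'
#' Bundles the per-class distribution parameters the synthetic gaze
#' generator draws from. Classes with higher arousal are typically given a
#' larger pupil diameter and shorter/longer fixations; the defaults in
#' [default_class_profiles()] encode such a three-class gradient.
#'
#' @param class_id integer class index, `0 .. C-1`.
#' @param pupil_mean,pupil_sd per-sample pupil diameter mean and noise sd (mm).
#' @param fixation_dur_mean,fixation_dur_sd fixation duration mean and sd (ms);
#'   the mean must exceed 55 ms so planted fixations survive the I-VT minimum
#'   duration rule.
#' @param saccade_amp_mean,saccade_amp_sd saccade amplitude mean and sd (deg).
#' @param saccade_peak_speed constant saccade velocity (deg/s); must clearly
#'   exceed the I-VT velocity threshold used downstream.
#' @param blink_rate blink events per minute (confidence-dropout gaps).
#' @return an object of class `class_profile`.
#' @seealso [generate_trial()], [generator_spec()]
#' @export
class_profile <- function(class_id, pupil_mean, pupil_sd = 0.2,
                          fixation_dur_mean = 300, fixation_dur_sd = 50,
                          saccade_amp_mean = 5, saccade_amp_sd = 1.5,
                          saccade_peak_speed = 300, blink_rate = 12) {
  if (!is_count(class_id, min = 0L)) stopf("class_id must be a non-negative integer")
  sds <- c(pupil_sd, fixation_dur_sd, saccade_amp_sd)
  if (any(!is.finite(sds)) || any(sds < 0)) stopf("standard deviations must be >= 0")
  if (!is_number(fixation_dur_mean) || fixation_dur_mean <= 55)
    stopf("fixation_dur_mean must exceed 55 ms (the I-VT minimum fixation duration)")
  if (!is_number(saccade_peak_speed) || saccade_peak_speed <= 0)
    stopf("saccade_peak_speed must be positive")
  structure(list(
    class_id = as.integer(class_id), pupil_mean = pupil_mean, pupil_sd = pupil_sd,
    fixation_dur_mean = fixation_dur_mean, fixation_dur_sd = fixation_dur_sd,
    saccade_amp_mean = saccade_amp_mean, saccade_amp_sd = saccade_amp_sd,
    saccade_peak_speed = saccade_peak_speed, blink_rate = blink_rate
  ), class = "class_profile")
}

#' Default three-class (low/medium/high arousal style) profiles
#'
#' Pupil means 3.0/3.5/4.0 mm (per-sample sd 0.2 mm) and fixation-duration
#' means 250/400/600 ms define the benchmark separation; saccade amplitude,
#' peak speed and blink rate follow a matching gradient.
#'
#' @return list of three [class_profile()] objects.
#' @export
default_class_profiles <- function() {
  list(
    class_profile(0L, pupil_mean = 3.0, pupil_sd = 0.2,
                  fixation_dur_mean = 250, fixation_dur_sd = 50,
                  saccade_amp_mean = 4, saccade_amp_sd = 1.5,
                  saccade_peak_speed = 250, blink_rate = 10),
    class_profile(1L, pupil_mean = 3.5, pupil_sd = 0.2,
                  fixation_dur_mean = 400, fixation_dur_sd = 50,
                  saccade_amp_mean = 5, saccade_amp_sd = 1.5,
                  saccade_peak_speed = 300, blink_rate = 12),
    class_profile(2L, pupil_mean = 4.0, pupil_sd = 0.2,
                  fixation_dur_mean = 600, fixation_dur_sd = 50,
                  saccade_amp_mean = 6, saccade_amp_sd = 1.5,
                  saccade_peak_speed = 350, blink_rate = 15)
  )
}

#' Synthetic dataset specification
#'
#' @param n_subjects number of subjects.
#' @param trials_per_subject_per_class trials per subject per class.
#' @param duration_s trial duration (s).
#' @param rate_hz sampling rate (Hz).
#' @param profiles list of [class_profile()] objects, one per class.
#' @param subject_pupil_sd between-subject pupil baseline sd (mm).
#' @param dropout_prob fraction of samples given a sub-threshold confidence.
#' @param blinks logical; plant blink gaps at each profile's `blink_rate`.
#' @param seed integer RNG seed.
#' @return an object of class `generator_spec`.
#' @export
generator_spec <- function(n_subjects = 10, trials_per_subject_per_class = 4,
                           duration_s = 60, rate_hz = 240,
                           profiles = default_class_profiles(),
                           subject_pupil_sd = 0.15, dropout_prob = 0.02,
                           blinks = TRUE, seed = 1L) {
  if (!is_count(n_subjects)) stopf("n_subjects must be a positive integer")
  if (!is_count(trials_per_subject_per_class))
    stopf("trials_per_subject_per_class must be a positive integer")
  if (!is_number(duration_s) || duration_s <= 0) stopf("duration_s must be > 0")
  if (!is_number(rate_hz) || rate_hz <= 0) stopf("rate_hz must be > 0")
  if (!length(profiles)) stopf("profiles must be non-empty")
  if (!all(vapply(profiles, inherits, logical(1), "class_profile")))
    stopf("profiles must be class_profile objects")
  if (!is_number(dropout_prob) || dropout_prob < 0 || dropout_prob > 1)
    stopf("dropout_prob must lie in [0, 1]")
  if (!is_number(subject_pupil_sd) || subject_pupil_sd < 0)
    stopf("subject_pupil_sd must be >= 0")
  structure(list(
    n_subjects = as.integer(n_subjects),
    trials_per_subject_per_class = as.integer(trials_per_subject_per_class),
    duration_s = duration_s, rate_hz = rate_hz, profiles = profiles,
    subject_pupil_sd = subject_pupil_sd, dropout_prob = dropout_prob,
    blinks = isTRUE(blinks), seed = as.integer(seed)
  ), class = "generator_spec")
}

new_gaze_recording <- function(time, x, y, pupil, confidence, rate_hz,
                               subject_id = NA_character_,
                               trial_id = NA_character_,
                               label = NA_integer_, events = NULL) {
  n <- length(time)
  if (!all(lengths(list(x, y, pupil, confidence)) == n))
    stopf("all gaze channels must have equal length")
  structure(list(
    time = time, x = x, y = y, pupil = pupil, confidence = confidence,
    rate_hz = rate_hz, subject_id = subject_id, trial_id = trial_id,
    label = label, events = events
  ), class = "gaze_recording")
}

#' @export
print.gaze_recording <- function(x, ...) {
  cat(sprintf("<gaze_recording> %d samples @ %g Hz (%.1f s)\n",
              length(x$time), x$rate_hz, length(x$time) / x$rate_hz))
  cat(sprintf("  subject %s, trial %s, label %s\n",
              x$subject_id, x$trial_id,
              ifelse(is.na(x$label), "<none>", x$label)))
  if (!is.null(x$events))
    cat(sprintf("  %d ground-truth events (%d fixations)\n",
                nrow(x$events), sum(x$events$kind == "fixation")))
  invisible(x)
}

#' Generate one synthetic gaze trial
#'
#' Builds a uniformly sampled gaze/pupil/confidence series that alternates
#' fixation plateaus (position held, bounded Gaussian jitter) with
#' constant-velocity saccade ramps whose per-sample speed strictly exceeds
#' the I-VT threshold, so the planted event segmentation is exactly
#' recoverable. The pupil channel is `profile$pupil_mean + subject_offset`
#' plus Gaussian per-sample noise; blink gaps and random dropouts carry a
#' sub-threshold confidence (pupil set to the sentinel `-1` inside blinks).
#'
#' Fixation durations are drawn from the profile's Gaussian truncated below
#' at 70 ms so every planted fixation survives the 55 ms I-VT minimum;
#' positional jitter is clamped so per-sample velocity inside a fixation can
#' never reach `v_threshold`.
#'
#' @param profile a [class_profile()].
#' @param subject_offset subject pupil baseline offset (mm).
#' @param duration_s,rate_hz trial duration (s) and sampling rate (Hz).
#' @param seed optional integer seed (uses the current RNG stream if `NULL`).
#' @param v_threshold I-VT velocity threshold (deg/s) the construction must
#'   respect.
#' @param jitter_sd fixational jitter sd (deg).
#' @param dropout_prob fraction of samples with confidence below 0.95.
#' @param blinks logical; plant blink gaps at `profile$blink_rate`.
#' @return a `gaze_recording` with a `events` data frame of ground-truth
#'   segments (`kind`, half-open velocity-index range `start_idx`/`end_idx`).
#' @export
generate_trial <- function(profile, subject_offset = 0, duration_s = 60,
                           rate_hz = 240, seed = NULL, v_threshold = 45,
                           jitter_sd = 0.01, dropout_prob = 0, blinks = TRUE) {
  if (!inherits(profile, "class_profile")) stopf("profile must be a class_profile")
  if (!is_number(duration_s) || duration_s <= 0) stopf("duration_s must be > 0")
  if (!is_number(rate_hz) || rate_hz <= 0) stopf("rate_hz must be > 0")
  n <- round(duration_s * rate_hz)
  if (n < 2) stopf("duration_s * rate_hz must be at least 2")
  if (profile$saccade_peak_speed <= v_threshold + 0.2 * rate_hz)
    stopf("saccade_peak_speed too close to the velocity threshold at this rate")
  if (!is.null(seed)) set.seed(seed)

  n_steps <- n - 1L                      # velocity (transition) positions
  min_fix_steps <- ceiling(0.070 * rate_hz)   # 70 ms floor, above 55 ms rule

  # plan the step-kind sequence: alternating fixation / saccade runs
  kind <- character(0)
  sacc_len <- numeric(0)                 # planned amplitude per saccade run
  repeat {
    f <- max(min_fix_steps,
             round(rnorm(1, profile$fixation_dur_mean,
                         profile$fixation_dur_sd) / 1000 * rate_hz))
    kind <- c(kind, rep("fixation", f))
    if (length(kind) >= n_steps) break
    amp <- max(0.5, rnorm(1, profile$saccade_amp_mean, profile$saccade_amp_sd))
    s <- max(1L, round(amp / profile$saccade_peak_speed * rate_hz))
    kind <- c(kind, rep("saccade", s))
    sacc_len <- c(sacc_len, s)
    if (length(kind) >= n_steps) break
  }
  kind <- kind[seq_len(n_steps)]
  # a truncated trailing fixation shorter than the I-VT minimum would be
  # relabelled by the detector; fold it into the preceding saccade instead
  r <- rle(kind)
  k <- length(r$values)
  if (k >= 2 && r$values[k] == "fixation" &&
      r$lengths[k] < ceiling(profile_min_fix_ms() / 1000 * rate_hz)) {
    r$values[k] <- "saccade"
    kind <- inverse.rle(r)
  }

  # walk the plan into positions; saccades move at constant speed toward a
  # direction re-drawn per saccade (biased back toward centre when far out)
  step_disp <- profile$saccade_peak_speed / rate_hz
  x <- numeric(n); y <- numeric(n)
  px <- 0; py <- 0
  theta <- runif(1, 0, 2 * pi)
  in_sacc <- FALSE
  for (i in seq_len(n_steps)) {
    if (kind[i] == "saccade") {
      if (!in_sacc) {
        theta <- if (sqrt(px^2 + py^2) > 15)
          atan2(-py, -px) + rnorm(1, 0, 0.3) else runif(1, 0, 2 * pi)
        in_sacc <- TRUE
      }
      px <- px + step_disp * cos(theta)
      py <- py + step_disp * sin(theta)
    } else in_sacc <- FALSE
    x[i + 1L] <- px
    y[i + 1L] <- py
  }
  # bounded jitter: per-axis clamp keeps every intra-fixation step strictly
  # below the velocity threshold
  clamp <- min(4 * jitter_sd, 0.9 * v_threshold / rate_hz / (2 * sqrt(2)))
  jx <- pmin(pmax(rnorm(n, 0, jitter_sd), -clamp), clamp)
  jy <- pmin(pmax(rnorm(n, 0, jitter_sd), -clamp), clamp)
  x <- x + jx
  y <- y + jy

  pupil <- rnorm(n, profile$pupil_mean + subject_offset, profile$pupil_sd)
  confidence <- runif(n, 0.96, 1)

  if (dropout_prob > 0) {
    bad <- runif(n) < dropout_prob
    confidence[bad] <- runif(sum(bad), 0, 0.5)
  }
  if (blinks && profile$blink_rate > 0) {
    n_blinks <- rpois(1, profile$blink_rate * duration_s / 60)
    if (n_blinks > 0) {
      starts <- sort(sample.int(n, n_blinks))
      lens <- pmax(1L, round(runif(n_blinks, 0.10, 0.30) * rate_hz))
      for (b in seq_len(n_blinks)) {
        idx <- starts[b]:min(n, starts[b] + lens[b] - 1L)
        confidence[idx] <- 0
        pupil[idx] <- -1          # blink sentinel; removed by cleaning
      }
    }
  }

  r <- rle(kind)
  ends <- cumsum(r$lengths)
  events <- data.frame(
    kind = r$values,
    start_idx = c(1L, head(ends, -1L) + 1L),
    end_idx = ends + 1L,                    # half-open over velocity indices
    duration_ms = r$lengths / rate_hz * 1000,
    stringsAsFactors = FALSE
  )

  new_gaze_recording(
    time = (seq_len(n) - 1L) / rate_hz, x = x, y = y, pupil = pupil,
    confidence = confidence, rate_hz = rate_hz,
    label = profile$class_id, events = events
  )
}

profile_min_fix_ms <- function() 55

#' Generate a labelled synthetic gaze dataset
#'
#' Draws one pupil baseline offset per subject, then
#' `n_subjects * trials_per_subject_per_class * C` trials with ground-truth
#' event segments and class labels attached.
#'
#' @param spec a [generator_spec()].
#' @return an object of class `gaze_dataset`: list with `recordings` (list of
#'   `gaze_recording`), `subject_offsets`, and the `spec`.
#' @export
generate_gaze_dataset <- function(spec) {
  if (!inherits(spec, "generator_spec")) stopf("spec must be a generator_spec")
  set.seed(spec$seed)
  offsets <- rnorm(spec$n_subjects, 0, spec$subject_pupil_sd)
  recs <- vector("list",
                 spec$n_subjects * spec$trials_per_subject_per_class *
                   length(spec$profiles))
  i <- 0L
  for (s in seq_len(spec$n_subjects)) {
    for (p in spec$profiles) {
      for (tr in seq_len(spec$trials_per_subject_per_class)) {
        i <- i + 1L
        rec <- generate_trial(
          p, subject_offset = offsets[s], duration_s = spec$duration_s,
          rate_hz = spec$rate_hz, dropout_prob = spec$dropout_prob,
          blinks = spec$blinks
        )
        rec$subject_id <- sprintf("S%02d", s)
        rec$trial_id <- sprintf("S%02d_C%d_T%02d", s, p$class_id, tr)
        recs[[i]] <- rec
      }
    }
  }
  structure(list(recordings = recs, subject_offsets = offsets, spec = spec),
            class = "gaze_dataset")
}

#' @export
print.gaze_dataset <- function(x, ...) {
  labs <- vapply(x$recordings, function(r) r$label, integer(1))
  cat(sprintf("<gaze_dataset> %d recordings, %d subjects, %d classes\n",
              length(x$recordings), x$spec$n_subjects, length(unique(labs))))
  print(table(label = labs))
  invisible(x)
}

#' Write a gaze recording as CSV plus a JSON sidecar
#'
#' The CSV holds columns `time_s, x_deg, y_deg, pupil_mm, confidence`; the
#' sidecar (same path with extension `.json`) carries the label, subject and
#' trial identifiers and the ground-truth event list when present.
#'
#' @param rec a `gaze_recording`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_gaze_csv <- function(rec, path) {
  df <- data.frame(time_s = rec$time, x_deg = rec$x, y_deg = rec$y,
                   pupil_mm = rec$pupil, confidence = rec$confidence)
  write.csv(df, path, row.names = FALSE)
  meta <- list(subject_id = rec$subject_id, trial_id = rec$trial_id,
               label = rec$label, rate_hz = rec$rate_hz)
  if (!is.null(rec$events)) meta$events <- rec$events
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA, dataframe = "columns")
  invisible(path)
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)
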