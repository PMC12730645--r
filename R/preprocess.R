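#' Read a gaze recording from CSV
#'
#' Expects columns `time_s, x_deg, y_deg, pupil_mm, confidence`. The
#' sampling rate is taken from `rate_hz` when supplied, otherwise inferred
#' as the reciprocal of the median time spacing. A JSON sidecar (same path,
#' `.json` extension) written by [write_gaze_csv()] is picked up
#' automatically for label/subject/trial metadata.
#'
#' @param path CSV path.
#' @param rate_hz optional known sampling rate (Hz).
#' @return a `gaze_recording`.
#' @export
read_gaze_csv <- function(path, rate_hz = NULL) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.csv(path)
  required <- c("time_s", "x_deg", "y_deg", "pupil_mm", "confidence")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stopf("gaze CSV %s is missing column(s): %s", path,
          paste(missing, collapse = ", "))
  if (nrow(df) >= 2 && any(diff(df$time_s) <= 0))
    stopf("gaze CSV %s has non-monotone time_s", path)
  if (is.null(rate_hz)) {
    if (nrow(df) < 2) stopf("cannot infer sampling rate from %d row(s)", nrow(df))
    rate_hz <- 1 / median(diff(df$time_s))
  }
  rec <- new_gaze_recording(df$time_s, df$x_deg, df$y_deg, df$pupil_mm,
                            df$confidence, rate_hz = rate_hz)
  sc <- sidecar_path(path)
  if (file.exists(sc)) {
    meta <- jsonlite::read_json(sc, simplifyVector = TRUE)
    rec$subject_id <- meta$subject_id %||% NA_character_
    rec$trial_id <- meta$trial_id %||% NA_character_
    rec$label <- if (is.null(meta$label)) NA_integer_ else as.integer(meta$label)
    if (!is.null(meta$events)) rec$events <- as.data.frame(meta$events)
  }
  rec
}

#' Screen a recording by observed valid duration
#'
#' A trial is dropped when its missing duration exceeds half of the expected
#' experiment length. Observed valid duration counts samples whose
#' confidence reaches `confidence_threshold`.
#'
#' @param rec a `gaze_recording`.
#' @param expected_s expected full-trial duration (s).
#' @param confidence_threshold per-sample validity cutoff.
#' @return list with `keep` (logical), `observed_s`, `missing_s` and
#'   `missing_fraction`.
#' @export
screen_duration <- function(rec, expected_s, confidence_threshold = 0.95) {
  if (!is_number(expected_s) || expected_s <= 0) stopf("expected_s must be > 0")
  observed <- sum(rec$confidence >= confidence_threshold) / rec$rate_hz
  missing <- expected_s - observed
  list(keep = !(missing > expected_s / 2),
       observed_s = observed, missing_s = missing,
       missing_fraction = missing / expected_s)
}

#' Mask low-confidence samples and refill by linear interpolation
#'
#' Samples with confidence below `threshold` are invalidated in the x, y and
#' pupil channels and refilled by linear interpolation between the nearest
#' valid neighbours; leading/trailing invalid runs take the nearest valid
#' value. Series length and the time grid are unchanged.
#'
#' @param rec a `gaze_recording`.
#' @param threshold confidence cutoff in (0, 1]; default 0.95.
#' @return the cleaned `gaze_recording`.
#' @export
clean_confidence <- function(rec, threshold = 0.95) {
  if (!is_number(threshold) || threshold <= 0 || threshold > 1)
    stopf("threshold must lie in (0, 1]")
  good <- rec$confidence >= threshold
  if (!any(good))
    stopf("unrecoverable trial: no sample reaches confidence %g", threshold)
  if (all(good)) return(rec)
  n <- length(good)
  refill <- function(v) {
    if (sum(good) == 1L) return(rep(v[good], n))
    approx(x = which(good), y = v[good], xout = seq_len(n),
           method = "linear", rule = 2)$y
  }
  rec$x <- refill(rec$x)
  rec$y <- refill(rec$y)
  rec$pupil <- refill(rec$pupil)
  rec
}

# running median with shrinking symmetric windows at the edges
run_median_shrink <- function(v, k) {
  n <- length(v)
  if (k == 1L || n == 1L) return(v)
  if (k >= 2 * n) k <- if (n %% 2L == 1L) 2L * n - 1L else 2L * n - 3L
  half <- (k - 1L) %/% 2L
  out <- if (n >= k) as.numeric(stats::runmed(v, k, endrule = "keep")) else v
  edge <- seq_len(min(half, n))
  for (i in edge) {
    h <- min(half, i - 1L, n - i)
    out[i] <- median(v[(i - h):(i + h)])
    j <- n - i + 1L
    h <- min(half, j - 1L, n - j)
    out[j] <- median(v[(j - h):(j + h)])
  }
  out
}

#' Median-filter the gaze and pupil channels
#'
#' Applies a running median of odd width `kernel` independently to x, y and
#' pupil; window shrinks symmetrically at the edges; confidence untouched.
#'
#' @param rec a `gaze_recording`.
#' @param kernel odd window width in samples (default 5).
#' @return the filtered `gaze_recording`.
#' @export
median_filter <- function(rec, kernel = 5L) {
  if (!is_count(kernel) || kernel %% 2L == 0L)
    stopf("kernel must be an odd positive integer")
  kernel <- as.integer(kernel)
  rec$x <- run_median_shrink(rec$x, kernel)
  rec$y <- run_median_shrink(rec$y, kernel)
  rec$pupil <- run_median_shrink(rec$pupil, kernel)
  rec
}

#' Full preprocessing chain for one recording
#'
#' Optional duration screening, then confidence cleaning with linear
#' interpolation, then median filtering.
#'
#' @param rec a `gaze_recording`.
#' @param confidence_threshold per-sample validity cutoff (default 0.95).
#' @param median_kernel odd median-filter width (default 5 samples).
#' @param expected_s expected trial duration for screening; `NULL` skips the
#'   screen.
#' @return the preprocessed `gaze_recording`, or `NULL` when screened out.
#' @export
preprocess_gaze <- function(rec, confidence_threshold = 0.95,
                            median_kernel = 5L, expected_s = NULL) {
  if (!is.null(expected_s)) {
    dec <- screen_duration(rec, expected_s, confidence_threshold)
    if (!dec$keep) return(NULL)
  }
  rec <- clean_confidence(rec, confidence_threshold)
  median_filter(rec, median_kernel)
}
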