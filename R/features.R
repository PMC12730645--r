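FEATURE_FAMILIES <- c("pupil", "fix_dur", "sacc_dur", "sacc_speed", "sacc_dist")
FEATURE_STATS <- c("mean", "kurt", "skew", "var", "cv")

feature_names_25 <- function() {
  as.vector(t(outer(FEATURE_FAMILIES, FEATURE_STATS, paste, sep = "_")))
}

# five moment statistics of one parameter family; conventions: population
# variance, Fisher excess kurtosis, adjusted Fisher-Pearson skewness (0 when
# n < 3), CV = sd/|mean| (0 when |mean| ~ 0); empty family -> all zeros
family_stats <- function(v) {
  n <- length(v)
  if (n == 0L) return(c(0, 0, 0, 0, 0))
  m <- mean(v)
  va <- mean((v - m)^2)
  s <- sqrt(va)
  kurt <- if (n >= 2L && va > 1e-24) mean((v - m)^4) / va^2 - 3 else 0
  skew <- if (n >= 3L && va > 1e-24)
    sqrt(n * (n - 1)) / (n - 2) * mean((v - m)^3) / s^3 else 0
  cv <- if (abs(m) > 1e-12) s / abs(m) else 0
  c(m, kurt, skew, va, cv)
}

#' Per-window feature vector
#'
#' Computes the 25 raw features of one window: for each of the five
#' parameter families -- pupil diameter (per sample within the window),
#' fixation duration, saccade duration, saccade mean speed and saccade
#' distance (per event overlapping the window) -- the mean, kurtosis,
#' skewness, variance and coefficient of variation. Events that straddle a
#' window boundary are clipped to the intersection (duration, displacement
#' and speed recomputed over the clipped span). Families without events in
#' the window yield zeros.
#'
#' @param rec a preprocessed `gaze_recording`.
#' @param events event table from [detect_events()].
#' @param slice length-2 integer vector (half-open sample range) or one row
#'   of [window_slices()].
#' @param velocities optional precomputed [sample_velocities()] result.
#' @return named numeric vector of length 25.
#' @export
window_statistics <- function(rec, events, slice, velocities = NULL) {
  a <- slice[[1]]; b <- slice[[2]]             # samples a .. b-1
  if (a < 1 || b - 1L > length(rec$x)) stopf("slice is outside the recording")
  if (is.null(velocities)) velocities <- sample_velocities(rec)
  cs <- c(0, cumsum(velocities))
  # velocity indices inside the window: a .. b-2
  os <- pmax(events$start_idx, a)
  oe <- pmin(events$end_idx, b - 1L)
  keep <- oe > os
  ev <- events[keep, , drop = FALSE]
  os <- os[keep]; oe <- oe[keep]
  dur <- (oe - os) / rec$rate_hz * 1000
  dist <- sqrt((rec$x[oe] - rec$x[os])^2 + (rec$y[oe] - rec$y[os])^2)
  speed <- (cs[oe] - cs[os]) / (oe - os)
  fix <- ev$kind == "fixation"
  out <- c(family_stats(rec$pupil[a:(b - 1L)]),
           family_stats(dur[fix]),
           family_stats(dur[!fix]),
           family_stats(speed[!fix]),
           family_stats(dist[!fix]))
  names(out) <- feature_names_25()
  out
}

new_window_features <- function(values, feature_names, window_starts,
                                label = NA_integer_,
                                subject_id = NA_character_,
                                trial_id = NA_character_) {
  stopifnot(ncol(values) == length(feature_names))
  colnames(values) <- feature_names
  structure(list(values = values, feature_names = feature_names,
                 window_starts = window_starts, label = label,
                 subject_id = subject_id, trial_id = trial_id),
            class = "window_features")
}

#' @export
print.window_features <- function(x, ...) {
  cat(sprintf("<window_features> %d windows x %d features (trial %s, label %s)\n",
              nrow(x$values), ncol(x$values), x$trial_id,
              ifelse(is.na(x$label), "<none>", x$label)))
  invisible(x)
}

#' Extract the per-window feature matrix of a recording
#'
#' Stacks the [window_statistics()] vectors of every sliding window in
#' chronological order into a `K x 25` matrix with feature names and window
#' start times attached.
#'
#' @param rec a preprocessed `gaze_recording`.
#' @param cfg an [ivt_config()].
#' @return a `window_features` object.
#' @export
extract_feature_matrix <- function(rec, cfg = ivt_config()) {
  v <- sample_velocities(rec)
  events <- detect_events(rec, cfg)
  slices <- window_slices(length(rec$x), rec$rate_hz, cfg)
  vals <- matrix(0, nrow(slices), 25L)
  for (i in seq_len(nrow(slices)))
    vals[i, ] <- window_statistics(rec, events, slices[i, ], velocities = v)
  if (any(!is.finite(vals))) stopf("non-finite window feature encountered")
  new_window_features(vals, feature_names_25(),
                      window_starts = (slices[, "start"] - 1L) / rec$rate_hz,
                      label = rec$label, subject_id = rec$subject_id,
                      trial_id = rec$trial_id)
}

#' Rolling temporal feature doubling
#'
#' For each feature column computes the trailing rolling mean over `roll_w`
#' windows (an expanding prefix where fewer windows are available) and
#' concatenates the rolled columns after the originals, doubling the feature
#' dimension while leaving the number of windows unchanged. A `[1000, 13]`
#' matrix becomes `[1000, 26]`.
#'
#' @param fm a `window_features` object or plain numeric matrix.
#' @param roll_w rolling window length in windows (default 5).
#' @return same type as `fm`, with `2 L` columns (`*_rollmean` appended).
#' @export
rolling_temporal_features <- function(fm, roll_w = 5L) {
  if (!is_count(roll_w)) stopf("roll_w must be a positive integer")
  mat <- if (inherits(fm, "window_features")) fm$values else fm
  rolled <- apply(mat, 2L, rolling_mean_trailing, w = roll_w)
  if (!is.matrix(rolled)) rolled <- matrix(rolled, nrow = nrow(mat))
  nms <- colnames(mat) %||% paste0("f", seq_len(ncol(mat)))
  out <- cbind(mat, rolled)
  colnames(out) <- c(nms, paste0(nms, "_rollmean"))
  if (inherits(fm, "window_features")) {
    fm$values <- out
    fm$feature_names <- colnames(out)
    fm
  } else out
}

#' Pool per-trial window features into one table
#'
#' @param dataset a `gaze_dataset`, or list of `gaze_recording`s, or list of
#'   `window_features`.
#' @param cfg an [ivt_config()].
#' @param preprocess logical; run [preprocess_gaze()] per recording first.
#' @param ... passed to [preprocess_gaze()].
#' @return data frame with columns `subject_id`, `trial_id`,
#'   `window_start_s`, `label` and one column per feature.
#' @export
features_table <- function(dataset, cfg = ivt_config(), preprocess = TRUE, ...) {
  recs <- if (inherits(dataset, "gaze_dataset")) dataset$recordings else dataset
  rows <- lapply(recs, function(r) {
    fm <- if (inherits(r, "window_features")) r else {
      if (preprocess) r <- preprocess_gaze(r, ...)
      if (is.null(r)) return(NULL)
      extract_feature_matrix(r, cfg)
    }
    cbind(data.frame(subject_id = fm$subject_id, trial_id = fm$trial_id,
                     window_start_s = fm$window_starts, label = fm$label,
                     stringsAsFactors = FALSE),
          as.data.frame(fm$values))
  })
  do.call(rbind, rows)
}

#' One-way ANOVA feature screening over pairwise class contrasts
#'
#' For every feature column, a one-way ANOVA F test is run for each
#' pairwise class contrast; a feature is retained when it is significant
#' (`p < alpha`) in at least `min_contrasts` contrasts. Constant-within-pair
#' features yield an undefined test and count as not significant.
#'
#' @param x numeric matrix or data frame of features (rows = samples).
#' @param y class labels (factor or coercible).
#' @param alpha significance level (default 0.05).
#' @param min_contrasts minimum number of significant contrasts for
#'   retention (default 1).
#' @return an object of class `anova_selection`: list with logical `mask`,
#'   the `pvalues` matrix (features x contrasts), `alpha`, `min_contrasts`.
#' @export
anova_select <- function(x, y, alpha = 0.05, min_contrasts = 1L) {
  x <- as.matrix(x)
  y <- factor(y)
  if (nlevels(y) < 2L) stopf("at least 2 classes are required")
  if (any(table(y) < 2L)) stopf("every class needs at least 2 samples")
  if (!is_number(alpha) || alpha < 0 || alpha > 1) stopf("alpha must be in [0, 1]")
  pairs <- combn(levels(y), 2L)
  pv <- matrix(NA_real_, ncol(x), ncol(pairs))
  rownames(pv) <- colnames(x) %||% paste0("f", seq_len(ncol(x)))
  colnames(pv) <- apply(pairs, 2L, paste, collapse = "-")
  for (p in seq_len(ncol(pairs))) {
    sel <- y %in% pairs[, p]
    g <- droplevels(y[sel])
    for (f in seq_len(ncol(x))) {
      pv[f, p] <- tryCatch(
        oneway.test(x[sel, f] ~ g, var.equal = TRUE)$p.value,
        error = function(e) NA_real_)
    }
  }
  nsig <- rowSums(pv < alpha, na.rm = TRUE)
  structure(list(mask = nsig >= min_contrasts, pvalues = pv,
                 alpha = alpha, min_contrasts = as.integer(min_contrasts)),
            class = "anova_selection")
}

#' @export
print.anova_selection <- function(x, ...) {
  cat(sprintf("<anova_selection> %d / %d features retained (p < %g in >= %d contrast(s))\n",
              sum(x$mask), length(x$mask), x$alpha, x$min_contrasts))
  invisible(x)
}
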