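test_that("velocities follow the forward-difference formula", {
  rec <- toy_recording()
  rec$x <- c(0, 1, 1); rec$y <- c(0, 0, 0)
  rec$time <- (0:2) / 240; rec$rate_hz <- 240
  rec$pupil <- rep(3, 3); rec$confidence <- rep(1, 3)
  v <- sample_velocities(rec)
  expect_equal(v, c(240, 0))

  rec$x <- c(0, 3); rec$y <- c(0, 4); rec$rate_hz <- 1
  rec$time <- 0:1; rec$pupil <- rep(3, 2); rec$confidence <- rep(1, 2)
  expect_equal(sample_velocities(rec), 5)

  rec$x <- rep(1, 5); rec$y <- rep(2, 5); rec$time <- 0:4
  rec$pupil <- rep(3, 5); rec$confidence <- rep(1, 5)
  expect_equal(sample_velocities(rec), rep(0, 4))

  rec$x <- 1; rec$y <- 1; rec$time <- 0
  rec$pupil <- 3; rec$confidence <- 1
  expect_error(sample_velocities(rec), "2 samples")
})

test_that("I-VT boundary: at the threshold is fixation, above is saccade", {
  cfg <- ivt_config(v0 = 45)
  expect_identical(classify_samples(c(45, 45.01, 0), cfg),
                   c("fixation", "saccade", "fixation"))
})

test_that("event segmentation merges sub-minimum fixations into saccades", {
  cfg <- ivt_config()
  # 24 fixation labels at 240 Hz: one fixation of 100 ms
  ev <- segment_events(rep("fixation", 24), 240, cfg)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$duration_ms, 100)
  expect_identical(ev$kind, "fixation")

  # 10 fixation labels (41.7 ms < 55 ms) flanked by saccades: single saccade
  labs <- c(rep("saccade", 5), rep("fixation", 10), rep("saccade", 5))
  ev2 <- segment_events(labs, 240, cfg)
  expect_equal(nrow(ev2), 1L)
  expect_identical(ev2$kind, "saccade")
  expect_equal(ev2$start_idx, 1L)
  expect_equal(ev2$end_idx, 21L)

  ev3 <- segment_events(rep("saccade", 30), 240, cfg)
  expect_equal(nrow(ev3), 1L)
  expect_identical(ev3$kind, "saccade")
})

test_that("events tile the velocity range without gaps or overlaps", {
  set.seed(7)
  for (rep_i in 1:5) {
    labs <- sample(c("fixation", "saccade"), 500, replace = TRUE,
                   prob = c(0.8, 0.2))
    ev <- segment_events(labs, 240, ivt_config())
    expect_equal(ev$start_idx[1], 1L)
    expect_equal(ev$end_idx[nrow(ev)], 501L)
    if (nrow(ev) > 1)
      expect_equal(ev$start_idx[-1], ev$end_idx[-nrow(ev)])
    expect_equal(sum(ev$end_idx - ev$start_idx), 500L)
  }
})

test_that("window slicing matches direct enumeration", {
  cfg <- ivt_config(window_s = 5, step_s = 1)
  sl <- window_slices(14400, 240, cfg)
  expect_equal(nrow(sl), 56L)
  # enumeration oracle: every full 1200-sample window starting on the grid
  starts <- seq(1, 14400, by = 240)
  expect_equal(sl[, "start"], as.integer(starts[starts + 1200 - 1 <= 14400]))
  expect_true(all(sl[, "end"] - sl[, "start"] == 1200L))

  expect_equal(nrow(window_slices(1200, 240, cfg)), 1L)
  tile <- window_slices(3000, 100, ivt_config(window_s = 5, step_s = 5))
  expect_equal(nrow(tile), 6L)
  expect_equal(tile[-1, "start"], tile[-nrow(tile), "end"])
  expect_error(window_slices(1199, 240, cfg), "shorter")
})

test_that("window statistics match brute-force recomputation", {
  p <- default_class_profiles()[[2]]
  rec <- generate_trial(p, duration_s = 20, rate_hz = 240, seed = 31,
                        dropout_prob = 0, blinks = FALSE)
  cfg <- ivt_config()
  events <- detect_events(rec, cfg)
  v <- sample_velocities(rec)
  slices <- window_slices(length(rec$x), rec$rate_hz, cfg)
  for (i in c(1L, 7L, nrow(slices))) {
    a <- slices[i, "start"]; b <- slices[i, "end"]
    got <- window_statistics(rec, events, slices[i, ], velocities = v)
    # brute force: clip events to the window, recompute family values
    vals <- list(pupil = rec$pupil[a:(b - 1)])
    fix_d <- c(); sac_d <- c(); sac_s <- c(); sac_a <- c()
    for (e in seq_len(nrow(events))) {
      os <- max(events$start_idx[e], a)
      oe <- min(events$end_idx[e], b - 1L)
      if (oe <= os) next
      dur <- (oe - os) / rec$rate_hz * 1000
      if (events$kind[e] == "fixation") fix_d <- c(fix_d, dur) else {
        sac_d <- c(sac_d, dur)
        sac_s <- c(sac_s, mean(v[os:(oe - 1)]))
        sac_a <- c(sac_a, sqrt((rec$x[oe] - rec$x[os])^2 +
                               (rec$y[oe] - rec$y[os])^2))
      }
    }
    want <- c(ref_family_stats(vals$pupil), ref_family_stats(fix_d),
              ref_family_stats(sac_d), ref_family_stats(sac_s),
              ref_family_stats(sac_a))
    expect_equal(unname(got), want, tolerance = 1e-9)
  }
})

test_that("window statistics handle degenerate windows by the zero rule", {
  rec <- toy_recording(fix1 = 1200L, sacc = 6L, fix2 = 60L)
  cfg <- ivt_config()
  events <- detect_events(rec, cfg)
  # first window: pure fixation, no saccade: 15 saccade-family zeros
  f <- window_statistics(rec, events, c(1L, 1201L))
  expect_equal(unname(f[11:25]), rep(0, 15))
  # constant pupil: mean is the constant, var and cv are 0
  expect_equal(unname(f["pupil_mean"]), 3.5)
  expect_equal(unname(f["pupil_var"]), 0)
  expect_equal(unname(f["pupil_cv"]), 0)
})

test_that("fixation-duration stats use the population variance convention", {
  # two fixations of 100 ms and 300 ms: mean 200 ms, population var 10000
  rec <- toy_recording(fix1 = 24L, sacc = 6L, fix2 = 72L)
  events <- detect_events(rec, ivt_config())
  f <- window_statistics(rec, events, c(1L, length(rec$x) + 1L))
  expect_equal(unname(f["fix_dur_mean"]), 200)
  expect_equal(unname(f["fix_dur_var"]), 10000)
})

test_that("feature matrix extraction is deterministic with stable shape", {
  p <- default_class_profiles()[[1]]
  rec <- generate_trial(p, duration_s = 12, rate_hz = 120, seed = 77,
                        dropout_prob = 0, blinks = FALSE)
  fm <- extract_feature_matrix(rec, ivt_config())
  expect_equal(dim(fm$values), c(8L, 25L))
  expect_true(all(is.finite(fm$values)))
  expect_identical(fm$feature_names, colnames(fm$values))
  fm2 <- extract_feature_matrix(rec, ivt_config())
  expect_identical(fm$values, fm2$values)
  # single-window recording
  short <- generate_trial(p, duration_s = 5, rate_hz = 120, seed = 78,
                          dropout_prob = 0, blinks = FALSE)
  expect_equal(nrow(extract_feature_matrix(short, ivt_config())$values), 1L)
})

test_that("rolling doubling appends causal means and passes originals through", {
  set.seed(12)
  m <- matrix(rnorm(1000 * 13), 1000, 13)
  out <- rolling_temporal_features(m, roll_w = 5)
  expect_equal(dim(out), c(1000L, 26L))
  expect_identical(unname(out[, 1:13]), unname(m))
  # direct check of the trailing mean with expanding prefix
  expect_equal(unname(out[1, 14]), m[1, 1])
  expect_equal(unname(out[3, 14]), mean(m[1:3, 1]))
  expect_equal(unname(out[10, 14]), mean(m[6:10, 1]))
  # roll_w = 1 is the identity on the rolled half
  one <- rolling_temporal_features(m, roll_w = 1)
  expect_equal(unname(one[, 14:26]), unname(m), tolerance = 1e-12)
  # constant column stays constant
  cm <- matrix(5, 20, 1)
  expect_equal(unname(rolling_temporal_features(cm, roll_w = 4)[, 2]),
               rep(5, 20))
})

test_that("noise-free synthetic trials are recovered exactly by I-VT", {
  for (cls in 1:3) {
    p <- default_class_profiles()[[cls]]
    rec <- generate_trial(p, duration_s = 30, rate_hz = 240, seed = 100 + cls,
                          dropout_prob = 0, blinks = FALSE)
    ev <- detect_events(rec, ivt_config())
    n <- length(rec$x) - 1L
    expect_identical(event_sample_labels(ev, n),
                     event_sample_labels(rec$events, n))
  }
})

test_that("ANOVA screening keeps separated features and rejects alpha = 0", {
  set.seed(5)
  n <- 200
  y <- rep(0:1, each = n)
  x <- cbind(strong = c(rnorm(n, 0), rnorm(n, 10)),   # 10 pooled sd apart
             null1 = rnorm(2 * n), null2 = rnorm(2 * n))
  sel <- anova_select(x, y, alpha = 0.05)
  expect_true(sel$mask[["strong"]])
  expect_equal(dim(sel$pvalues), c(3L, 1L))
  none <- anova_select(x, y, alpha = 0)
  expect_false(any(none$mask))
  expect_error(anova_select(x, c(0, rep(1, 2 * n - 1))), "at least 2")
})

test_that("features_table pools trials with metadata columns", {
  spec <- generator_spec(n_subjects = 2, trials_per_subject_per_class = 1,
                         duration_s = 6, rate_hz = 120, dropout_prob = 0,
                         blinks = FALSE, seed = 6)
  ds <- generate_gaze_dataset(spec)
  tab <- features_table(ds)
  expect_equal(nrow(tab), 6L * 2L)      # 2 windows per 6 s trial, 6 trials
  expect_true(all(c("subject_id", "trial_id", "window_start_s", "label")
                  %in% names(tab)))
  expect_equal(ncol(tab), 4L + 25L)
})
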