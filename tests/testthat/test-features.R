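test_that("moving average truncates the window at the edges", {
  expect_equal(smooth_series(c(1, 2, 3, 4), 3), c(1.5, 2, 3, 3.5))
  expect_equal(smooth_series(rep(7, 20), 3), rep(7, 20))
  expect_equal(smooth_series(numeric(0), 3), numeric(0))
  expect_equal(smooth_series(5, 3), 5)
  expect_error(smooth_series(1:4, 2), "odd")
  set.seed(1)
  x <- rnorm(500)
  expect_lt(var(smooth_series(x, 3)), var(x))
})

test_that("kinematics: uniform (3,4) px/frame motion gives 12.5 mm/s at 10 px/mm", {
  tr <- straight_track(n = 60, dx = 3, dy = 4)
  p <- feature_params(px_per_mm = 10, fps = 25)
  kin <- kinematics(tr, p)
  sp <- kin$speed_mms[!is.na(kin$speed_mms)]
  expect_equal(sp, rep(12.5, length(sp)))
  av <- kin$angvel_rads[!is.na(kin$angvel_rads)]
  expect_equal(av, rep(0, length(av))) # straight line: zero angular velocity
  # moving down the image (dy > 0) means negative vertical velocity
  vv <- kin$vert_vel_mms[!is.na(kin$vert_vel_mms)]
  expect_true(all(vv < 0))
  expect_error(kinematics(tr[1:2, ], p), "at least")
})

test_that("uniform circular motion recovers angular velocity 2*pi/T", {
  n_per_rev <- 100; fps <- 25; R <- 80
  ang <- 2 * pi * (0:299) / n_per_rev
  tr <- tibble::tibble(track_id = 1L, frame = 0:299,
                       x_px = 200 + R * cos(ang), y_px = 200 + R * sin(ang))
  kin <- kinematics(tr, feature_params(px_per_mm = 8, fps = fps))
  period <- n_per_rev / fps # seconds per revolution
  av <- kin$angvel_rads[!is.na(kin$angvel_rads)]
  expect_equal(mean(abs(av)), 2 * pi / period, tolerance = 1e-6)
})

test_that("plane classification applies the 0.92 / 0.58 thresholds", {
  p <- segmentation_params()
  expect_equal(classify_plane(0.95, p), "transverse")
  expect_equal(classify_plane(0.50, p), "sagittal")
  expect_equal(classify_plane(0.75, p), "unclassified")
  expect_equal(classify_plane(c(0.93, 0.57, 0.92, 0.58), p),
               c("transverse", "sagittal", "unclassified", "unclassified"))
})

test_that("ethogram: a motionless track is all Pause; probabilities partition", {
  still <- straight_track(n = 50, dx = 0, dy = 0)
  p <- feature_params(px_per_mm = 8, fps = 25)
  kin <- kinematics(still, p)
  eth <- ethogram(kin, body_len_mm = 2.5, p)
  expect_equal(unname(eth$probabilities["Pause"]), 1)
  expect_equal(sum(eth$probabilities), 1)
  # partition of unity on arbitrary random tracks
  set.seed(3)
  for (i in 1:5) {
    tr <- tibble::tibble(track_id = 1L, frame = 0:199,
                         x_px = cumsum(rnorm(200, 0, 4)) + 500,
                         y_px = cumsum(rnorm(200, 0, 4)) + 500)
    pr <- ethogram(kinematics(tr, p), 2.5, p)$probabilities
    expect_equal(sum(pr), 1)
    expect_true(all(pr >= 0))
  }
})

test_that("ethogram states agree frame-by-frame with the cascade applied by hand", {
  # 50 frames fast straight swimming, 50 frames standstill
  tr <- tibble::tibble(track_id = 1L, frame = 0:99,
                       x_px = c(seq(0, 49 * 8, by = 8), rep(49 * 8, 50)) + 100,
                       y_px = 100)
  p <- feature_params(px_per_mm = 8, fps = 25)
  kin <- kinematics(tr, p)
  bl <- 2.5
  eth <- ethogram(kin, bl, p)
  # independent hand application of the cascade to the same kinematics
  hand <- character(100)
  for (i in 1:100) {
    s <- kin$speed_mms[i] / bl; a <- abs(kin$angvel_rads[i])
    hand[i] <- if (is.na(s)) NA_character_
      else if (s <= p$pause_speed_max) "Pause"
      else if (!is.na(a) && a >= p$spin_angvel_min) "Spin"
      else if (!is.na(a) && a >= p$turn_angvel_min) "Turn"
      else if (s >= p$run_speed_min) "FwdRun"
      else if (s <= p$slow_speed_max) "FwdSlow"
      else "Fwd"
  }
  expect_identical(eth$states, hand)
  # roughly half running, half paused, up to boundary frames
  expect_equal(unname(eth$probabilities["FwdRun"]), 0.5, tolerance = 0.05)
  expect_equal(unname(eth$probabilities["Pause"]), 0.5, tolerance = 0.05)
})

test_that("natural features of a constant-velocity track are degenerate as expected", {
  tr <- straight_track(n = 120, dx = 2, dy = 0)
  p <- feature_params(px_per_mm = 8, fps = 25, arena_h_px = 300)
  f <- natural_features(tr, p)
  expect_equal(ncol(f) - 1, 21) # 21 features + track_id
  expect_equal(f$sd_speed_mms, 0)
  expect_equal(f$net_gross_ratio, 1)
  expect_equal(f$p_turn, 0)
  expect_equal(f$duration_s, 119 / 25)
  expect_identical(f, natural_features(tr, p)) # deterministic
  # transverse-only circularity: sagittal area missing, not zero
  expect_true(is.na(f$area_sagittal_mm2))
  expect_gt(f$area_transverse_mm2, 0)
})

test_that("speed features are invariant to translation and x-mirroring; vertical features flip", {
  set.seed(11)
  tr <- tibble::tibble(track_id = 1L, frame = 0:199,
                       x_px = cumsum(rnorm(200, 1, 2)) + 500,
                       y_px = cumsum(rnorm(200, -0.5, 2)) + 500)
  tr$area_px <- 300; tr$perimeter_px <- 60
  tr$major_px <- 20; tr$minor_px <- 18; tr$circularity <- 0.95
  p <- feature_params(px_per_mm = 8, fps = 25, arena_h_px = 1000)
  f0 <- natural_features(tr, p)
  shifted <- dplyr::mutate(tr, x_px = x_px + 37, y_px = y_px) # rigid translation
  fs <- natural_features(shifted, p)
  mirrored <- dplyr::mutate(tr, x_px = 1000 - x_px)
  fm <- natural_features(mirrored, p)
  for (col in c("mean_speed_mms", "sd_speed_mms", "mean_angvel_rads",
                "mean_abs_vert_vel_mms", "net_gross_ratio")) {
    expect_equal(fs[[col]], f0[[col]], tolerance = 1e-9)
    expect_equal(fm[[col]], f0[[col]], tolerance = 1e-9)
  }
  # y-mirror flips the sign of signed vertical velocity
  kin0 <- kinematics(tr, p)
  kiny <- kinematics(dplyr::mutate(tr, y_px = 1000 - y_px), p)
  expect_equal(kiny$vert_vel_mms, -kin0$vert_vel_mms, tolerance = 1e-9)
})

test_that("stimulus features recover a clean step response exactly", {
  sch <- stimulus_schedule()
  fps <- 25
  # straight-line track whose step doubles inside every stimulus window
  frames <- 0:(120 * fps - 1)
  t_s <- frames / fps
  stim <- (t_s >= 20 & t_s < 30) | (t_s >= 40 & t_s < 50) |
    (t_s >= 70 & t_s < 80)
  steps <- ifelse(stim, 4, 2)[-1]
  tr <- tibble::tibble(track_id = 1L, frame = frames,
                       x_px = cumsum(c(100, steps)), y_px = 200)
  p <- feature_params(px_per_mm = 8, fps = fps)
  f <- stimulus_features(tr, sch, p)
  expect_equal(ncol(f) - 1, 12) # 12 features + track_id
  for (lab in c("weak_light", "strong_light", "vibration")) {
    expect_equal(f[[paste0(lab, "_response_ratio")]], 2.0)
  }
  # gain 1 (no response): ratio exactly 1
  tr1 <- tibble::tibble(track_id = 1L, frame = frames,
                        x_px = 100 + 2 * frames, y_px = 200)
  f1 <- stimulus_features(tr1, sch, p)
  expect_equal(f1$weak_light_response_ratio, 1.0)
})

test_that("upward drift during light-on shows as positive vertical velocity", {
  sch <- stimulus_schedule()
  cfg <- cohort_config(n_animals = 6, duration_s = 120, arena_w_px = 2000,
                       arena_h_px = 2000, drift_speed = 3, seed = 13)
  tr <- simulate_trajectories(cfg, 10, sch)$trajectories
  p <- feature_params(px_per_mm = cfg$px_per_mm, fps = cfg$fps,
                      arena_h_px = cfg$arena_h_px)
  one <- dplyr::mutate(dplyr::filter(tr, animal_id == 1), track_id = 1L)
  f <- stimulus_features(one, sch, p)
  expect_gt(f$weak_light_vert_vel_mms, 0)
  expect_gt(f$strong_light_vert_vel_mms, 0)
})

test_that("tracks absent from a stimulus window yield missing stimulus fields", {
  sch <- stimulus_schedule()
  # track only covers 0..35 s: vibration fields (70-80 s) must be NA
  tr <- straight_track(n = 35 * 25, dx = 0.5, dy = 0)
  f <- stimulus_features(tr, sch, feature_params(px_per_mm = 8, fps = 25))
  expect_true(is.na(f$vibration_response_ratio))
  expect_false(is.na(f$weak_light_response_ratio))
})

test_that("feature correlation matrix is symmetric with unit diagonal and honest NAs", {
  set.seed(21)
  n <- 400
  feats <- tibble::tibble(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  feats$dup <- feats$a
  feats$const <- 1
  m <- correlation_matrix(feats)
  expect_equal(m, t(m))
  expect_true(all(diag(m) == 1))
  expect_equal(m["a", "dup"], 1)
  expect_true(is.na(m["a", "const"])) # undefined, not zero
  expect_true("const" %in% attr(m, "constant"))
  # independent features: |r| below 3/sqrt(n)
  expect_lt(abs(m["a", "b"]), 3 / sqrt(n))
  expect_lt(abs(m["a", "c"]), 3 / sqrt(n))
  expect_error(correlation_matrix(feats[1, ]), "2 rows")
})

test_that("features are stable across overlapping sub-windows of a stationary track", {
  cfg <- cohort_config(n_animals = 1, duration_s = 60, arena_w_px = 3000,
                       arena_h_px = 3000, seed = 17)
  tr <- simulate_trajectories(cfg, 10)$trajectories
  tr$track_id <- 1L
  tr$major_px <- 20; tr$minor_px <- 18
  tr$area_px <- 300; tr$perimeter_px <- 60; tr$circularity <- 0.95
  p <- feature_params(px_per_mm = cfg$px_per_mm, fps = cfg$fps,
                      arena_h_px = cfg$arena_h_px)
  wins <- list(c(0, 30), c(15, 45), c(30, 60))
  vals <- sapply(wins, function(w) {
    sub <- dplyr::filter(tr, t_s >= w[1], t_s < w[2])
    natural_features(sub, p)$mean_speed_mms
  })
  kin <- kinematics(tr, p)
  sem <- sd(kin$speed_mms, na.rm = TRUE) /
    sqrt(sum(!is.na(kin$speed_mms)) / 2) # halved window
  expect_lt(max(vals) - min(vals), 2 * 3 * sem)
})

test_that("extract_features binds natural and stimulus blocks with metadata", {
  sch <- stimulus_schedule()
  cfg <- tiny_config(n_animals = 2, duration_s = 120, arena_w_px = 2000,
                     arena_h_px = 2000)
  tr <- simulate_trajectories(cfg, 10, sch)$trajectories
  tracks <- dplyr::mutate(tr, track_id = animal_id, area_px = 300,
                          perimeter_px = 60, major_px = 20, minor_px = 18,
                          circularity = 0.95)
  p <- feature_params(px_per_mm = cfg$px_per_mm, fps = cfg$fps,
                      arena_h_px = cfg$arena_h_px)
  f <- extract_features(tracks, p, sch, age_days = 12, cohort = "c1",
                        condition = "control")
  expect_equal(nrow(f), 2)
  expect_equal(ncol(f), 1 + 21 + 12 + 3) # id + natural + stimulus + metadata
  expect_equal(unique(f$age_days), 12)
})
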