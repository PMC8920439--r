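#' Feature-extraction parameters
#'
#' Ethogram speed thresholds are in body lengths per second (BL/s),
#' where a track's body length is its median major-axis length;
#' angular-velocity thresholds are in rad/s. The defaults (pause below
#' 0.2 BL/s, slow below 1 BL/s, run above 2 BL/s, turn above pi/2 rad/s,
#' spin above 2*pi rad/s) were calibrated on synthetic cohorts.
#'
#' @param px_per_mm spatial calibration, pixels per mm.
#' @param fps frames per second.
#' @param window moving-average smoothing window (odd, in time-points);
#'   published value 3.
#' @param arena_h_px arena height, needed for the vertical-position
#'   features (mean height, fraction of time in the upper half).
#' @param pause_speed_max,slow_speed_max,run_speed_min ethogram speed
#'   thresholds, BL/s.
#' @param turn_angvel_min,spin_angvel_min ethogram angular-velocity
#'   thresholds, rad/s.
#' @return a `feature_params` list.
#' @export
feature_params <- function(px_per_mm = 8, fps = 25, window = 3L,
                           arena_h_px = 300,
                           pause_speed_max = 0.2,
                           slow_speed_max = 1,
                           run_speed_min = 2,
                           turn_angvel_min = pi / 2,
                           spin_angvel_min = 2 * pi) {
  stopifnot(
    "window must be odd and >= 1" = window >= 1 && window %% 2 == 1,
    "speed thresholds must satisfy 0 <= pause < slow < run" =
      pause_speed_max >= 0 && pause_speed_max < slow_speed_max &&
      slow_speed_max < run_speed_min,
    "turn_angvel_min must be below spin_angvel_min" =
      turn_angvel_min < spin_angvel_min,
    px_per_mm > 0, fps > 0, arena_h_px > 0
  )
  structure(list(px_per_mm = px_per_mm, fps = fps, window = as.integer(window),
                 arena_h_px = arena_h_px,
                 pause_speed_max = pause_speed_max,
                 slow_speed_max = slow_speed_max,
                 run_speed_min = run_speed_min,
                 turn_angvel_min = turn_angvel_min,
                 spin_angvel_min = spin_angvel_min),
            class = "feature_params")
}

#' Centered moving average with truncated edges
#'
#' A centred moving average over an odd window; at the series edges the
#' window is truncated to the available points, so `smooth_series(c(1, 2,
#' 3, 4), 3)` is `c(1.5, 2, 3, 3.5)`.
#'
#' @param series numeric vector.
#' @param window odd window length in time-points (published value 3).
#' @return smoothed vector of the same length; empty in, empty out.
#' @export
smooth_series <- function(series, window = 3L) {
  stopifnot("window must be odd and >= 1" = window >= 1 && window %% 2 == 1)
  if (length(series) == 0) return(series)
  if (window == 1L || length(series) == 1) return(series)
  as.numeric(zoo::rollapply(zoo::zoo(series), width = window, FUN = mean,
                            align = "center", partial = TRUE))
}

#' Per-frame kinematics of one track
#'
#' Positions are smoothed with the moving average, then differenced.
#' Speed is `|delta position| * fps / px_per_mm` (mm/s); heading comes
#' from the displacement vector; angular velocity is the wrapped heading
#' difference times fps (rad/s); vertical velocity is sign-flipped so
#' upward motion is positive. The first and last displacement samples
#' are reported as `NA`: the truncated smoothing window distorts them
#' even for perfectly uniform motion, so features use interior samples
#' only.
#'
#' @param track tibble for a single track (columns `frame`, `x_px`,
#'   `y_px`).
#' @param params a [feature_params()].
#' @return tibble: `frame`, `t_s`, `x_mm`, `y_mm`, `speed_mms`,
#'   `angvel_rads`, `vert_vel_mms` (NA where undefined).
#' @export
kinematics <- function(track, params = feature_params()) {
  tr <- arrange(as_tibble(track), .data$frame)
  n <- nrow(tr)
  if (n < max(3, params$window)) {
    abort(paste0("kinematics: track has ", n, " frames; need at least ",
                 max(3, params$window)))
  }
  xs <- smooth_series(tr$x_px, params$window)
  ys <- smooth_series(tr$y_px, params$window)
  dx <- diff(xs); dy <- diff(ys)
  step_px <- sqrt(dx^2 + dy^2)
  speed <- c(NA, step_px * params$fps / params$px_per_mm)
  vert <- c(NA, -dy * params$fps / params$px_per_mm)
  heading <- atan2(-dy, dx)
  angvel <- c(NA, NA, wrap_angle(diff(heading)) * params$fps)
  # truncated-window edge samples are biased: blank them
  half <- (params$window - 1L) %/% 2L
  if (half > 0) {
    edge <- c(seq_len(half + 1L), n - seq_len(half) + 1L)
    speed[edge] <- NA; vert[edge] <- NA
    edge_a <- unique(c(seq_len(half + 2L), n - seq_len(half) + 1L))
    angvel[edge_a] <- NA
  }
  tibble(frame = tr$frame, t_s = tr$frame / params$fps,
         x_mm = xs / params$px_per_mm, y_mm = ys / params$px_per_mm,
         speed_mms = speed, angvel_rads = angvel, vert_vel_mms = vert)
}

#' Classify body presentation plane from circularity
#'
#' Blobs with normalized circularity above the transverse threshold
#' (published 0.92) are top views (transverse plane); below the sagittal
#' threshold (published 0.58), side views (sagittal plane); in between,
#' unclassified and excluded from plane-specific size features.
#'
#' @param circ normalized circularity values (vectorized).
#' @param params a [segmentation_params()] carrying the two thresholds.
#' @return character vector: `"transverse"`, `"sagittal"` or
#'   `"unclassified"`.
#' @export
classify_plane <- function(circ, params = segmentation_params()) {
  ifelse(is.na(circ), NA_character_,
  ifelse(circ > params$transverse_circ_threshold, "transverse",
  ifelse(circ < params$sagittal_circ_threshold, "sagittal", "unclassified")))
}

ethogram_states <- c("FwdRun", "Fwd", "FwdSlow", "Turn", "Spin", "Pause")

#' Locomotor-state (ethogram) classification
#'
#' Assigns each frame to one of six locomotor states by a fixed decision
#' cascade on speed (in body lengths per second) and angular velocity:
#' speed at or below the pause threshold -> `Pause`; else |angular
#' velocity| at or above the spin threshold -> `Spin`; else at or above
#' the turn threshold -> `Turn`; else speed at or above the run
#' threshold -> `FwdRun`; speed at or below the slow threshold ->
#' `FwdSlow`; otherwise `Fwd`. Per-state probabilities are the fractions
#' of classified frames, and always sum to 1.
#'
#' @param kin kinematics tibble from [kinematics()].
#' @param body_len_mm body length used for BL/s normalization (per-track
#'   median major axis / px_per_mm).
#' @param params a [feature_params()].
#' @return list with `states` (per-frame character, NA at edges) and
#'   `probabilities` (named numeric over the 6 states, summing to 1).
#' @export
ethogram <- function(kin, body_len_mm, params = feature_params()) {
  stopifnot(body_len_mm > 0)
  bl <- kin$speed_mms / body_len_mm
  av <- abs(kin$angvel_rads)
  st <- ifelse(is.na(bl), NA_character_,
        ifelse(bl <= params$pause_speed_max, "Pause",
        ifelse(!is.na(av) & av >= params$spin_angvel_min, "Spin",
        ifelse(!is.na(av) & av >= params$turn_angvel_min, "Turn",
        ifelse(bl >= params$run_speed_min, "FwdRun",
        ifelse(bl <= params$slow_speed_max, "FwdSlow", "Fwd"))))))
  cl <- st[!is.na(st)]
  probs <- if (length(cl) == 0) {
    setNames(rep(NA_real_, 6), ethogram_states)
  } else {
    tab <- table(factor(cl, levels = ethogram_states))
    setNames(as.numeric(tab) / length(cl), ethogram_states)
  }
  list(states = st, probabilities = probs)
}

#' Natural-swimming feature vector of one track
#'
#' The 21 per-trajectory features of the natural-swimming regime:
#' kinematic summaries (mean/median/SD speed, mean/SD angular velocity,
#' mean absolute vertical velocity), vertical-location summaries (mean
#' height in the arena on a 0-1 scale with up = 1, fraction of time in
#' the upper half), path geometry (net-to-gross displacement ratio, path
#' length, duration), morphology (transverse- and sagittal-plane areas
#' in mm^2 from plane-classified frames, major and minor axes in mm)
#' and the six ethogram state probabilities. Plane-specific sizes are
#' `NA` when no frame classifies into that plane.
#'
#' @param track single-track tibble (tracking-module schema).
#' @param params a [feature_params()].
#' @param seg_params a [segmentation_params()] (plane thresholds).
#' @return one-row tibble of the 21 features plus `track_id`.
#' @export
natural_features <- function(track, params = feature_params(),
                             seg_params = segmentation_params()) {
  tr <- arrange(as_tibble(track), .data$frame)
  kin <- kinematics(tr, params)
  ppm <- params$px_per_mm
  body_len_mm <- median(tr$major_px, na.rm = TRUE) / ppm
  eth <- ethogram(kin, body_len_mm, params)
  plane <- if ("circularity" %in% names(tr)) {
    classify_plane(tr$circularity, seg_params)
  } else rep(NA_character_, nrow(tr))
  mean_or_na <- function(x) if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE)
  sp <- kin$speed_mms; av <- kin$angvel_rads
  net_px <- sqrt((tr$x_px[nrow(tr)] - tr$x_px[1])^2 +
                 (tr$y_px[nrow(tr)] - tr$y_px[1])^2)
  gross_px <- sum(sqrt(diff(tr$x_px)^2 + diff(tr$y_px)^2))
  height <- 1 - tr$y_px / params$arena_h_px # 0 bottom .. 1 top
  tibble(
    track_id = tr$track_id[1] %||% NA_integer_,
    mean_speed_mms = mean_or_na(sp),
    median_speed_mms = median(sp, na.rm = TRUE),
    sd_speed_mms = sd(sp[!is.na(sp)]),
    mean_angvel_rads = mean_or_na(abs(av)),
    sd_angvel_rads = sd(av[!is.na(av)]),
    mean_abs_vert_vel_mms = mean_or_na(abs(kin$vert_vel_mms)),
    mean_vert_pos = mean(height),
    frac_upper_half = mean(height > 0.5),
    net_gross_ratio = if (gross_px > 0) net_px / gross_px else NA_real_,
    area_transverse_mm2 = mean_or_na(tr$area_px[plane == "transverse"]) / ppm^2,
    area_sagittal_mm2 = mean_or_na(tr$area_px[plane == "sagittal"]) / ppm^2,
    major_axis_mm = median(tr$major_px, na.rm = TRUE) / ppm,
    minor_axis_mm = median(tr$minor_px, na.rm = TRUE) / ppm,
    p_fwdrun = eth$probabilities[["FwdRun"]],
    p_fwd = eth$probabilities[["Fwd"]],
    p_fwdslow = eth$probabilities[["FwdSlow"]],
    p_turn = eth$probabilities[["Turn"]],
    p_spin = eth$probabilities[["Spin"]],
    p_pause = eth$probabilities[["Pause"]],
    duration_s = (nrow(tr) - 1) / params$fps,
    path_length_mm = gross_px / ppm
  )
}

#' Stimulus-response feature vector of one track
#'
#' For each scheduled stimulus: mean speed over the 10 s immediately
#' before onset (`pre`), mean speed during the stimulus window (`post`),
#' the response ratio `post/pre`, and the mean signed vertical velocity
#' during the window (positive = upward, the expected sign for
#' phototaxis toward an overhead light). 3 stimuli x 4 quantities = 12
#' features; fields are `NA` where the track does not cover the window.
#'
#' Because positions are smoothed before differencing, the few speed
#' samples whose smoothing window straddles a stimulus onset or offset
#' blend the two regimes; window means therefore exclude a guard of
#' `(window + 1) / 2` frames at each boundary, so a clean step response
#' is recovered exactly.
#'
#' @param track single-track tibble.
#' @param schedule a [stimulus_schedule()].
#' @param params a [feature_params()].
#' @param pre_window_s length of the pre-onset baseline window, seconds.
#' @return one-row tibble of 12 features plus `track_id`.
#' @export
stimulus_features <- function(track, schedule, params = feature_params(),
                              pre_window_s = 10) {
  tr <- arrange(as_tibble(track), .data$frame)
  kin <- kinematics(tr, params)
  guard <- ((params$window - 1) / 2 + 1) / params$fps
  out <- list(track_id = tr$track_id[1] %||% NA_integer_)
  for (i in seq_len(nrow(schedule))) {
    lab <- schedule$stimulus[i]
    on <- schedule$onset_s[i]; off <- schedule$offset_s[i]
    pre_i <- kin$t_s >= on - pre_window_s + guard & kin$t_s < on - guard
    post_i <- kin$t_s >= on + guard & kin$t_s < off - guard
    pre <- if (any(pre_i & !is.na(kin$speed_mms)))
      mean(kin$speed_mms[pre_i], na.rm = TRUE) else NA_real_
    post <- if (any(post_i & !is.na(kin$speed_mms)))
      mean(kin$speed_mms[post_i], na.rm = TRUE) else NA_real_
    vert <- if (any(post_i & !is.na(kin$vert_vel_mms)))
      mean(kin$vert_vel_mms[post_i], na.rm = TRUE) else NA_real_
    out[[paste0(lab, "_pre_speed_mms")]] <- pre
    out[[paste0(lab, "_post_speed_mms")]] <- post
    out[[paste0(lab, "_response_ratio")]] <-
      if (!is.na(pre) && !is.na(post) && pre > 0) post / pre else NA_real_
    out[[paste0(lab, "_vert_vel_mms")]] <- vert
  }
  as_tibble(out)
}

#' Extract the full feature table from a track table
#'
#' Applies [natural_features()] (and, when a schedule is given,
#' [stimulus_features()]) to every track and binds the rows into a
#' feature table, one row per trajectory, with optional metadata
#' columns.
#'
#' @param tracks track tibble (many tracks).
#' @param params a [feature_params()].
#' @param schedule optional [stimulus_schedule()].
#' @param seg_params a [segmentation_params()].
#' @param age_days,cohort,condition metadata recycled onto every row.
#' @return feature tibble, one row per track.
#' @export
extract_features <- function(tracks, params = feature_params(),
                             schedule = NULL,
                             seg_params = segmentation_params(),
                             age_days = NA_real_, cohort = NA_character_,
                             condition = NA_character_) {
  tr <- as_tibble(tracks)
  if (nrow(tr) == 0) return(tibble())
  pieces <- lapply(split(tr, tr$track_id), function(one) {
    nat <- natural_features(one, params, seg_params)
    if (!is.null(schedule)) {
      stim <- stimulus_features(one, schedule, params)
      nat <- bind_cols(nat, select(stim, -"track_id"))
    }
    nat
  })
  out <- bind_rows(pieces)
  mutate(out, age_days = age_days, cohort = cohort, condition = condition)
}

#' Pairwise Pearson correlation matrix of a feature table
#'
#' Correlations use complete pairs. Constant (zero-variance) columns
#' produce `NA` entries (undefined, not zero) and are reported in the
#' `constant` attribute.
#'
#' @param features feature tibble; non-numeric and metadata columns are
#'   dropped.
#' @return symmetric correlation matrix with unit diagonal and attribute
#'   `constant` naming zero-variance columns.
#' @export
correlation_matrix <- function(features) {
  num <- features[vapply(features, is.numeric, logical(1))]
  num <- num[setdiff(names(num), c("track_id", "age_days"))]
  if (nrow(num) < 2) abort("correlation_matrix: need at least 2 rows")
  sds <- vapply(num, function(x) sd(x, na.rm = TRUE), numeric(1))
  const <- names(num)[!is.na(sds) & sds == 0]
  suppressWarnings(m <- cor(as.matrix(num), use = "pairwise.complete.obs"))
  diag(m) <- 1
  attr(m, "constant") <- const
  m
}

#' Read / write feature tables as CSV
#' @param features feature tibble.
#' @param path file path.
#' @return `read_features_csv` returns the feature tibble.
#' @export
write_features_csv <- function(features, path) {
  utils::write.csv(as.data.frame(features), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("feature file not found: ", path))
  as_tibble(utils::read.csv(path))
}
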