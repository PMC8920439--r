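#' Configuration for a synthetic cohort
#'
#' Bundles every parameter of the synthetic cohort generator: arena and
#' camera geometry, kinematics and their age dependence, the lifespan
#' hazard, the stimulus response, and rendering noise. The defaults
#' describe a realistic desk-scale recording: a 25 fps camera watching an
#' arena of 50 x 37.5 mm at 8 px/mm, animals of ~2.5 mm swimming at ~5 mm/s
#' when young, slowing by 0.05 mm/s per day of age while growing by
#' 0.02 mm/day, and dying under a Gompertz hazard with a median lifespan of
#' ~54 days, typical of *Daphnia magna* cohorts.
#'
#' @param n_animals number of animals in the arena.
#' @param duration_s recording length in seconds.
#' @param fps frames per second of the camera.
#' @param arena_w_px,arena_h_px arena size in pixels.
#' @param px_per_mm spatial calibration, pixels per millimetre.
#' @param baseline_speed mean swimming speed at age 0, mm/s.
#' @param speed_age_slope change in mean speed per day of age, mm/s/day
#'   (non-positive: animals slow down with age).
#' @param baseline_body_len body length at age 0, mm.
#' @param growth_rate body growth, mm/day (non-negative: crustaceans grow
#'   throughout life).
#' @param hazard_family lifespan distribution family, one of
#'   `"exponential"`, `"weibull"`, `"gompertz"`.
#' @param hazard_params named numeric vector of family parameters:
#'   exponential `c(rate=)`; weibull `c(shape=, scale=)`; gompertz
#'   `c(a=, b=)` with hazard `h(t) = a * exp(b * t)`.
#' @param stimulus_response_gain multiplicative speed factor applied
#'   during stimulus windows (1 = no response).
#' @param drift_speed magnitude of the phototactic vertical drift, mm/s;
#'   applied upward while a light stimulus is on and downward for an
#'   equally long window after light-off. Exposed as a free parameter.
#' @param speed_cv coefficient of variation of the per-frame speed
#'   (log-normal multiplicative jitter with mean exactly 1; 0 = constant
#'   speed).
#' @param turn_sd standard deviation of the per-frame wrapped-Gaussian
#'   heading increment, radians (correlated random walk).
#' @param p_plane_switch per-frame probability of switching body
#'   presentation between transverse (top view, near-circular) and
#'   sagittal (side view, elongated).
#' @param transverse_aspect,sagittal_aspect major/minor axis ratio of the
#'   rendered ellipse in each presentation.
#' @param noise_sd standard deviation of additive Gaussian pixel noise
#'   (8-bit intensity units).
#' @param n_debris number of static debris blobs rendered into the scene.
#' @param territories if `TRUE`, each animal is confined to its own grid
#'   cell of the arena (reflecting cell walls), guaranteeing a
#'   non-overlapping cohort; if `FALSE` all animals share the arena with
#'   reflecting outer walls.
#' @param seed integer seed; every stochastic generator operation is
#'   reproducible given the config.
#'
#' @return an object of class `cohort_config` (a validated named list).
#' @export
cohort_config <- function(n_animals = 20,
                          duration_s = 60,
                          fps = 25,
                          arena_w_px = 400,
                          arena_h_px = 300,
                          px_per_mm = 8,
                          baseline_speed = 5,
                          speed_age_slope = -0.05,
                          baseline_body_len = 2.5,
                          growth_rate = 0.02,
                          hazard_family = c("gompertz", "weibull", "exponential"),
                          hazard_params = c(a = 6e-4, b = 0.085),
                          stimulus_response_gain = 1,
                          drift_speed = 2,
                          speed_cv = 0.3,
                          turn_sd = 0.35,
                          p_plane_switch = 0.02,
                          transverse_aspect = 1.12,
                          sagittal_aspect = 4.5,
                          noise_sd = 4,
                          n_debris = 5,
                          territories = FALSE,
                          seed = 1L) {
  hazard_family <- match.arg(hazard_family)
  cfg <- list(
    n_animals = as.integer(n_animals), duration_s = duration_s, fps = fps,
    arena_w_px = as.integer(arena_w_px), arena_h_px = as.integer(arena_h_px),
    px_per_mm = px_per_mm, baseline_speed = baseline_speed,
    speed_age_slope = speed_age_slope,
    baseline_body_len = baseline_body_len, growth_rate = growth_rate,
    hazard_family = hazard_family, hazard_params = hazard_params,
    stimulus_response_gain = stimulus_response_gain,
    drift_speed = drift_speed, speed_cv = speed_cv, turn_sd = turn_sd,
    p_plane_switch = p_plane_switch,
    transverse_aspect = transverse_aspect,
    sagittal_aspect = sagittal_aspect,
    noise_sd = noise_sd, n_debris = as.integer(n_debris),
    territories = isTRUE(territories), seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

validate_cohort_config <- function(cfg) {
  num <- cfg[!(names(cfg) %in% c("hazard_family", "territories"))]
  bad <- names(num)[!vapply(num, function(x) all(is.finite(x)), logical(1))]
  if (length(bad) > 0) {
    abort(paste0("cohort_config: non-finite value(s) in field(s): ",
                 paste(bad, collapse = ", ")))
  }
  stopifnot(
    "fps must be > 0" = cfg$fps > 0,
    "arena dimensions must be > 0" = cfg$arena_w_px > 0 && cfg$arena_h_px > 0,
    "px_per_mm must be > 0" = cfg$px_per_mm > 0,
    "n_animals must be >= 0" = cfg$n_animals >= 0,
    "duration_s must be > 0" = cfg$duration_s > 0,
    "speed_age_slope must be <= 0" = cfg$speed_age_slope <= 0,
    "growth_rate must be >= 0" = cfg$growth_rate >= 0,
    "stimulus_response_gain must be >= 0" = cfg$stimulus_response_gain >= 0,
    "speed_cv must be >= 0" = cfg$speed_cv >= 0,
    "noise_sd must be >= 0" = cfg$noise_sd >= 0,
    "aspect ratios must be >= 1" =
      cfg$transverse_aspect >= 1 && cfg$sagittal_aspect >= 1
  )
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config> ", x$n_animals, " animals, ", x$duration_s, " s @ ",
      x$fps, " fps, arena ", x$arena_w_px, "x", x$arena_h_px, " px (",
      signif(x$arena_w_px / x$px_per_mm, 3), "x",
      signif(x$arena_h_px / x$px_per_mm, 3), " mm), hazard ",
      x$hazard_family, ", seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Stimulus schedule
#'
#' The stimulus protocol as a tidy table of labelled windows. The default
#' reproduces the standard 2-minute stimulated-swimming recording: a weak
#' light pulse at 20-30 s, a strong light pulse at 40-50 s and a
#' vibrational pulse at 70-80 s, each 10 s long with 10-20 s
#' inter-stimulus intervals.
#'
#' @param stimuli tibble/data.frame with columns `stimulus`
#'   (one of `"weak_light"`, `"strong_light"`, `"vibration"`), `onset_s`,
#'   `offset_s`.
#' @param recording_s total recording length, seconds.
#' @return a `stimulus_schedule` tibble with attribute `recording_s`.
#' @export
stimulus_schedule <- function(stimuli = tibble(
                                stimulus = c("weak_light", "strong_light", "vibration"),
                                onset_s = c(20, 40, 70),
                                offset_s = c(30, 50, 80)),
                              recording_s = 120) {
  sch <- as_tibble(stimuli)
  stopifnot(all(c("stimulus", "onset_s", "offset_s") %in% names(sch)))
  ok <- sch$stimulus %in% c("weak_light", "strong_light", "vibration")
  if (!all(ok)) abort("stimulus_schedule: unknown stimulus label(s)")
  if (any(sch$offset_s <= sch$onset_s)) {
    abort("stimulus_schedule: offset_s must exceed onset_s")
  }
  if (any(sch$onset_s < 0) || any(sch$offset_s > recording_s)) {
    abort("stimulus_schedule: windows must lie within the recording")
  }
  sch <- arrange(sch, .data$onset_s)
  if (nrow(sch) > 1 && any(sch$onset_s[-1] < sch$offset_s[-nrow(sch)])) {
    abort("stimulus_schedule: windows must not overlap")
  }
  structure(sch, recording_s = recording_s,
            class = c("stimulus_schedule", class(sch)))
}

# JSON round-trip for schedules (used by the CLI and pipeline)
#' Read / write a stimulus schedule as JSON
#' @param schedule a [stimulus_schedule()].
#' @param path file path.
#' @return `read_schedule_json` returns a `stimulus_schedule`.
#' @export
write_schedule_json <- function(schedule, path) {
  jsonlite::write_json(
    list(recording_s = attr(schedule, "recording_s"),
         stimuli = as.data.frame(schedule)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_schedule_json
#' @export
read_schedule_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  stimulus_schedule(as_tibble(x$stimuli), recording_s = x$recording_s)
}
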