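#' Simulate ground-truthed swimming trajectories
#'
#' Generates a cohort of correlated-random-walk trajectories with the
#' statistical structure the downstream pipeline assumes: per-frame
#' heading increments are wrapped-Gaussian, mean swimming speed declines
#' linearly with age, body length grows linearly with age, speed is
#' multiplied by `stimulus_response_gain` inside scheduled stimulus
#' windows, and light stimuli impose a vertical drift (upward while the
#' light is on, downward for an equally long window after light-off).
#' Arena walls are reflecting. Every animal carries a per-frame body
#' presentation (transverse vs sagittal, a slow 2-state Markov chain) and
#' a per-frame locomotor state label derived from the true kinematics, so
#' segmentation, linking, the ethogram and the plane classifier all have
#' an oracle.
#'
#' Coordinates are in pixels with the image convention (x rightward,
#' y downward); "up" in the arena is decreasing y.
#'
#' @param config a [cohort_config()].
#' @param age_days chronological age of the cohort, days (>= 0).
#' @param schedule optional [stimulus_schedule()]; `NULL` means natural
#'   swimming with no stimulus windows.
#' @return an object of class `ground_truth`: list with `trajectories`
#'   (tibble: `animal_id`, `frame` (0-based), `t_s`, `x_px`, `y_px`,
#'   `heading`, `speed_mms`, `body_len_mm`, `plane`, `state`),
#'   `age_days`, `config`, `schedule`.
#' @export
simulate_trajectories <- function(config, age_days, schedule = NULL) {
  validate_cohort_config(config)
  stopifnot("age_days must be a finite value >= 0" =
              is.finite(age_days) && age_days >= 0)
  n <- config$n_animals
  n_frames <- as.integer(round(config$duration_s * config$fps)) + 1L
  mean_speed <- max(0, config$baseline_speed + config$speed_age_slope * age_days)
  body_len <- config$baseline_body_len + config$growth_rate * age_days

  if (n == 0L) {
    traj <- tibble(animal_id = integer(), frame = integer(), t_s = numeric(),
                   x_px = numeric(), y_px = numeric(), heading = numeric(),
                   speed_mms = numeric(), body_len_mm = numeric(),
                   plane = character(), state = character())
    return(new_ground_truth(traj, age_days, config, schedule))
  }

  # reflecting bounds keep the whole ellipse inside the frame
  half_major <- body_len * config$px_per_mm / 2
  bounds <- animal_bounds(config, n, half_major)

  t_s <- (seq_len(n_frames) - 1L) / config$fps
  gain_t <- rep(1, n_frames)
  drift_t <- rep(0, n_frames) # mm/s, positive = upward
  if (!is.null(schedule)) {
    for (i in seq_len(nrow(schedule))) {
      on <- schedule$onset_s[i]; off <- schedule$offset_s[i]
      w <- t_s >= on & t_s < off
      gain_t[w] <- config$stimulus_response_gain
      if (schedule$stimulus[i] %in% c("weak_light", "strong_light")) {
        drift_t[w] <- drift_t[w] + config$drift_speed
        post <- t_s >= off & t_s < off + (off - on)
        drift_t[post] <- drift_t[post] - config$drift_speed
      }
    }
  }

  sigma <- sqrt(log(1 + config$speed_cv^2))
  out <- withr::with_seed(config$seed, {
    x <- runif(n, bounds$xmin, bounds$xmax)
    y <- runif(n, bounds$ymin, bounds$ymax)
    theta <- runif(n, -pi, pi)
    plane <- ifelse(runif(n) < 0.5, "transverse", "sagittal")

    X <- Y <- TH <- SP <- matrix(NA_real_, n_frames, n)
    PL <- matrix(NA_character_, n_frames, n)
    X[1, ] <- x; Y[1, ] <- y; TH[1, ] <- theta; SP[1, ] <- NA; PL[1, ] <- plane

    for (k in 2:n_frames) {
      theta <- wrap_angle(theta + rnorm(n, 0, config$turn_sd))
      jit <- if (sigma > 0) exp(rnorm(n, -sigma^2 / 2, sigma)) else rep(1, n)
      sp <- mean_speed * jit * gain_t[k] # mm/s, realized swimming speed
      step <- sp / config$fps * config$px_per_mm
      x_new <- x + step * cos(theta)
      y_new <- y + step * sin(theta) - drift_t[k] / config$fps * config$px_per_mm
      refl <- reflect(x_new, y_new, theta, bounds)
      x <- refl$x; y <- refl$y; theta <- refl$theta
      sw <- runif(n) < config$p_plane_switch
      plane[sw] <- ifelse(plane[sw] == "transverse", "sagittal", "transverse")
      X[k, ] <- x; Y[k, ] <- y; TH[k, ] <- theta; SP[k, ] <- sp; PL[k, ] <- plane
    }
    list(X = X, Y = Y, TH = TH, SP = SP, PL = PL)
  })

  angvel <- rbind(NA_real_, abs(apply(out$TH, 2, function(th) {
    wrap_angle(diff(th))
  })) * config$fps)
  state <- true_locomotor_state(out$SP, angvel, body_len)

  traj <- tibble(
    animal_id = rep(seq_len(n), each = n_frames),
    frame = rep(seq_len(n_frames) - 1L, times = n),
    t_s = rep(t_s, times = n),
    x_px = as.vector(out$X), y_px = as.vector(out$Y),
    heading = as.vector(out$TH),
    speed_mms = as.vector(out$SP),
    body_len_mm = body_len,
    plane = as.vector(out$PL),
    state = as.vector(state)
  )
  new_ground_truth(traj, age_days, config, schedule)
}

new_ground_truth <- function(traj, age_days, config, schedule) {
  structure(list(trajectories = traj, age_days = age_days,
                 config = config, schedule = schedule),
            class = "ground_truth")
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("<ground_truth> ", length(unique(x$trajectories$animal_id)),
      " animals x ", length(unique(x$trajectories$frame)), " frames, age ",
      x$age_days, " d\n", sep = "")
  invisible(x)
}

animal_bounds <- function(config, n, margin) {
  W <- config$arena_w_px; H <- config$arena_h_px
  if (!config$territories) {
    return(list(xmin = rep(1 + margin, n), xmax = rep(W - margin, n),
                ymin = rep(1 + margin, n), ymax = rep(H - margin, n)))
  }
  nc <- ceiling(sqrt(n * W / H)); nr <- ceiling(n / nc)
  cw <- W / nc; ch <- H / nr
  idx <- seq_len(n) - 1L
  col <- idx %% nc; row <- idx %/% nc
  list(xmin = col * cw + 1 + margin, xmax = (col + 1) * cw - margin,
       ymin = row * ch + 1 + margin, ymax = (row + 1) * ch - margin)
}

# mirror positions back inside the box, flipping heading at each bounce
reflect <- function(x, y, theta, b) {
  for (i in 1:8) {
    lo <- x < b$xmin; hi <- x > b$xmax
    if (any(lo)) { x[lo] <- 2 * b$xmin[lo] - x[lo]; theta[lo] <- wrap_angle(pi - theta[lo]) }
    if (any(hi)) { x[hi] <- 2 * b$xmax[hi] - x[hi]; theta[hi] <- wrap_angle(pi - theta[hi]) }
    lo <- y < b$ymin; hi <- y > b$ymax
    if (any(lo)) { y[lo] <- 2 * b$ymin[lo] - y[lo]; theta[lo] <- wrap_angle(-theta[lo]) }
    if (any(hi)) { y[hi] <- 2 * b$ymax[hi] - y[hi]; theta[hi] <- wrap_angle(-theta[hi]) }
    if (all(x >= b$xmin & x <= b$xmax & y >= b$ymin & y <= b$ymax)) break
  }
  list(x = x, y = y, theta = theta)
}

wrap_angle <- function(a) ((a + pi) %% (2 * pi)) - pi

# ground-truth locomotor labels via the same cascade the ethogram uses,
# applied to the true (not estimated) kinematics
true_locomotor_state <- function(speed_mms, angvel, body_len_mm,
                                 pause = 0.2, slow = 1, run = 2,
                                 turn = pi / 2, spin = 2 * pi) {
  bl <- speed_mms / body_len_mm # body lengths per second
  st <- ifelse(is.na(bl) | is.na(angvel), NA_character_,
        ifelse(bl <= pause, "Pause",
        ifelse(angvel >= spin, "Spin",
        ifelse(angvel >= turn, "Turn",
        ifelse(bl >= run, "FwdRun",
        ifelse(bl <= slow, "FwdSlow", "Fwd"))))))
  st
}

#' Simulate cohort lifespans
#'
#' Draws i.i.d. event times from the configured parametric hazard family,
#' with optional independent right-censoring: each record is censored
#' with probability `censor_prob`, at a uniformly distributed fraction of
#' its event time.
#'
#' Families and parameterizations: exponential, `rate` (hazard);
#' Weibull, `shape`/`scale` as in [stats::rweibull()]; Gompertz,
#' `a`/`b` with hazard `h(t) = a * exp(b * t)` (so the survival function
#' is `exp(-(a/b) * (exp(b*t) - 1))` and the median is
#' `(1/b) * log(1 - (b/a) * log(0.5))`).
#'
#' @param config a [cohort_config()]; supplies `hazard_family`,
#'   `hazard_params` and `seed`.
#' @param n number of animals to draw.
#' @param censor_prob probability in `[0, 1]` that a record is
#'   right-censored.
#' @return tibble with columns `id`, `time_days` (> 0) and `event`
#'   (1 = death observed, 0 = censored).
#' @export
simulate_survival <- function(config, n, censor_prob = 0) {
  validate_cohort_config(config)
  stopifnot(n >= 1, censor_prob >= 0, censor_prob <= 1)
  p <- config$hazard_params
  withr::with_seed(config$seed, {
    t <- switch(config$hazard_family,
      exponential = {
        if (!("rate" %in% names(p))) abort("exponential hazard needs 'rate'")
        rexp(n, rate = p[["rate"]])
      },
      weibull = {
        if (!all(c("shape", "scale") %in% names(p)))
          abort("weibull hazard needs 'shape' and 'scale'")
        rweibull(n, shape = p[["shape"]], scale = p[["scale"]])
      },
      gompertz = {
        if (!all(c("a", "b") %in% names(p)))
          abort("gompertz hazard needs 'a' and 'b'")
        # inverse CDF of S(t) = exp(-(a/b)(e^{bt}-1))
        u <- runif(n)
        (1 / p[["b"]]) * log(1 - (p[["b"]] / p[["a"]]) * log(u))
      },
      abort(paste0("unknown hazard family: ", config$hazard_family))
    )
    cens <- runif(n) < censor_prob
    time <- ifelse(cens, t * runif(n), t)
    tibble(id = seq_len(n), time_days = time, event = as.integer(!cens))
  })
}

#' Closed-form median lifespan of a configured hazard
#'
#' @param config a [cohort_config()].
#' @return median event time in days.
#' @export
hazard_median <- function(config) {
  p <- config$hazard_params
  switch(config$hazard_family,
    exponential = log(2) / p[["rate"]],
    weibull = p[["scale"]] * log(2)^(1 / p[["shape"]]),
    gompertz = (1 / p[["b"]]) * log(1 - (p[["b"]] / p[["a"]]) * log(0.5)))
}

#' Simulate a per-trajectory feature cohort for clock training
#'
#' Emulates the feature tables the video pipeline produces, directly at
#' the table level: behavioural features decline monotonically with age
#' (speed, fast-swimming occupancy, stimulus response), morphological
#' features grow (body length, transverse area), pause occupancy rises,
#' and pure-noise features carry no signal. A `shift_days` offset
#' generates intervention cohorts: features are evaluated at
#' `age + shift_days`, so a negative shift mimics a "healthier" cohort
#' (young-looking features at old chronological age) and a positive one
#' a "toxic" cohort.
#'
#' With `attrition = TRUE` the number of rows per age is thinned by the
#' Gompertz survival of the default cohort, reproducing the old-age data
#' scarcity of longitudinal lifespan designs (the reason oversampling is
#' needed when training the clock).
#'
#' @param ages vector of chronological ages (days) at which trajectories
#'   are recorded.
#' @param n_per_age trajectories per age before attrition.
#' @param shift_days phenotypic-age offset applied to the feature
#'   generator (days).
#' @param missing_rate fraction of feature cells set missing at random.
#' @param n_noise_features number of uninformative N(0,1) features.
#' @param attrition thin old ages by cohort survival?
#' @param condition label stored in the `condition` column.
#' @param seed integer seed.
#' @return tibble with `age_days`, `condition` and numeric feature
#'   columns.
#' @export
simulate_feature_cohort <- function(ages = seq(5, 60, by = 5),
                                    n_per_age = 30,
                                    shift_days = 0,
                                    missing_rate = 0,
                                    n_noise_features = 3,
                                    attrition = FALSE,
                                    condition = "control",
                                    seed = 1L) {
  stopifnot(all(ages >= 0), n_per_age >= 1,
            missing_rate >= 0, missing_rate < 1)
  withr::with_seed(as.integer(seed), {
    n_at_age <- rep(as.integer(n_per_age), length(ages))
    if (attrition) {
      surv <- exp(-(0.002 / 0.085) * (exp(0.085 * ages) - 1))
      n_at_age <- pmax(3L, as.integer(round(n_per_age * surv)))
    }
    age <- rep(ages, times = n_at_age)
    m <- length(age)
    a <- age + shift_days # effective (phenotypic) age driving the features
    lg <- function(s) exp(rnorm(m, 0, s)) # multiplicative log-normal noise
    feat <- tibble(
      mean_speed_mms = pmax(0.05, 5 - 0.05 * a) * lg(0.10),
      sd_speed_mms = pmax(0.02, 1.5 - 0.012 * a) * lg(0.15),
      body_len_mm = (2 + 0.02 * a) * lg(0.04),
      area_transverse_mm2 = (0.6 * (2 + 0.02 * a)^2) * lg(0.08),
      p_fwdrun = clamp01(plogis(1.2 - 0.045 * a) + rnorm(m, 0, 0.05)),
      p_pause = clamp01(plogis(-2.5 + 0.035 * a) + rnorm(m, 0, 0.04)),
      response_ratio = (1 + 1.2 * exp(-a / 30)) * lg(0.08),
      mean_vert_pos = clamp01(0.5 - 0.002 * a + rnorm(m, 0, 0.08))
    )
    if (n_noise_features > 0) {
      for (j in seq_len(n_noise_features)) {
        feat[[paste0("noise_", j)]] <- rnorm(m)
      }
    }
    if (missing_rate > 0) {
      fm <- as.matrix(feat)
      hole <- matrix(runif(length(fm)) < missing_rate, nrow = m)
      fm[hole] <- NA_real_
      feat <- as_tibble(fm)
    }
    bind_cols(tibble(age_days = age, condition = condition), feat)
  })
}

clamp01 <- function(x, eps = 1e-3) pmin(1 - eps, pmax(eps, x))
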