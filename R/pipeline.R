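#' Run the full synthetic-cohort pipeline
#'
#' Orchestrates simulate -> render -> track -> features -> survival on
#' one configuration, writing each stage's artifact into `out_dir` and a
#' run manifest (`manifest.json`) with the configuration hash, package
#' version and per-artifact checksums. Deterministic stages reproduce
#' identical checksums when re-run with the same config and seed.
#' Stages are resumable: an existing artifact is reused unless
#' `overwrite = TRUE`, and a stage whose upstream artifact is missing
#' fails with an error naming the file.
#'
#' @param config a [cohort_config()].
#' @param out_dir output directory (created if needed).
#' @param stages subset of `c("simulate", "render", "track", "features",
#'   "survival")`, in pipeline order.
#' @param schedule optional [stimulus_schedule()] used by simulate and
#'   features.
#' @param age_days cohort age for the simulated recording.
#' @param n_survival cohort size for the survival stage.
#' @param seg_params,track_params,feat_params stage parameter objects;
#'   defaults derived from `config`.
#' @param write_video write the rendered stack as `video.tif` (large;
#'   off by default, the in-memory stack is passed downstream either
#'   way).
#' @param overwrite recompute stages whose artifacts already exist?
#' @return the run manifest (list), invisibly; artifacts on disk.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "render", "track",
                                    "features", "survival"),
                         schedule = NULL, age_days = 10,
                         n_survival = 200,
                         seg_params = segmentation_params(),
                         track_params = tracking_params(),
                         feat_params = NULL,
                         write_video = FALSE,
                         overwrite = FALSE) {
  validate_cohort_config(config)
  stages <- match.arg(stages, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  feat_params <- feat_params %||% feature_params(
    px_per_mm = config$px_per_mm, fps = config$fps,
    arena_h_px = config$arena_h_px)
  path <- function(f) file.path(out_dir, f)
  artifacts <- character()
  log_stage <- function(stage, msg) {
    message(sprintf("[phenotrack] %s: %s", stage, msg))
  }

  truth <- NULL; video <- NULL
  if ("simulate" %in% stages) {
    truth <- simulate_trajectories(config, age_days, schedule)
    write_atomic(truth$trajectories, path("truth.csv"))
    artifacts <- c(artifacts, "truth.csv")
    log_stage("simulate", sprintf("%d animals x %d frames -> truth.csv",
                                  config$n_animals,
                                  length(unique(truth$trajectories$frame))))
  }
  if ("render" %in% stages) {
    if (is.null(truth)) abort("run_pipeline: render needs the simulate stage")
    video <- render_video(truth, config)
    if (write_video) {
      write_video_tiff(video, path("video.tif"))
      artifacts <- c(artifacts, "video.tif")
    }
    log_stage("render", sprintf("%d frames rendered", dim(video)[3]))
  }
  if ("track" %in% stages) {
    if (is.null(video)) abort("run_pipeline: track needs the render stage")
    det <- segment_video(video, params = seg_params)
    tracks <- link_tracks(det, track_params)
    tracks <- filter_tracks(tracks, track_params, config$fps)
    write_atomic(tracks, path("tracks.csv"))
    artifacts <- c(artifacts, "tracks.csv")
    log_stage("track", sprintf("%d detections -> %d tracks", nrow(det),
                               length(unique(tracks$track_id))))
  }
  if ("features" %in% stages) {
    tp <- path("tracks.csv")
    if (!file.exists(tp)) {
      abort(paste0("run_pipeline: features stage needs ", tp,
                   "; run the track stage first"))
    }
    tracks <- read_tracks_csv(tp)
    feats <- extract_features(tracks, feat_params, schedule, seg_params,
                              age_days = age_days)
    write_atomic(feats, path("features.csv"))
    artifacts <- c(artifacts, "features.csv")
    log_stage("features", sprintf("%d trajectories x %d columns",
                                  nrow(feats), ncol(feats)))
  }
  if ("survival" %in% stages) {
    rec <- simulate_survival(config, n_survival)
    write_atomic(rec, path("survival.csv"))
    km <- km_estimate(rec)
    write_atomic(km$curve, path("km_curve.csv"))
    artifacts <- c(artifacts, "survival.csv", "km_curve.csv")
    log_stage("survival", sprintf("n = %d, KM median = %s d", nrow(rec),
                                  format(km$median_days)))
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("phenotrack")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = unclass(config),
    config_hash = config_hash(config),
    stages = stages,
    checksums = as.list(tools::md5sum(file.path(out_dir, artifacts))) |>
      setNames(artifacts)
  )
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

# serialize the config canonically and hash it (timestamps excluded)
config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(unclass(config)[order(names(config))], tmp,
                       auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(tmp))
}

# write via a temp file + rename so partial output never clobbers a
# completed artifact
write_atomic <- function(df, path) {
  tmp <- paste0(path, ".tmp")
  utils::write.csv(as.data.frame(df), tmp, row.names = FALSE, na = "")
  file.rename(tmp, path)
  invisible(path)
}

table_schemas <- list(
  tracks = list(
    columns = c("track_id", "frame", "x_px", "y_px", "area_px",
                "perimeter_px", "major_px", "minor_px", "circularity"),
    check = function(d) {
      v <- character()
      if (any(d$area_px <= 0, na.rm = TRUE)) v <- c(v, "area_px must be > 0")
      if (any(d$frame < 0, na.rm = TRUE)) v <- c(v, "frame must be >= 0")
      dup <- d |> dplyr::count(.data$track_id, .data$frame) |>
        filter(.data$n > 1)
      if (nrow(dup) > 0) {
        v <- c(v, paste0("duplicate (track, frame) rows: ",
                         paste(utils::head(dup$track_id, 5), collapse = ", ")))
      }
      v
    }),
  census = list(
    columns = c("day", "auto_count"),
    check = function(d) {
      v <- character()
      if (any(d$auto_count < 0, na.rm = TRUE)) v <- c(v, "counts must be >= 0")
      cnt <- if ("count" %in% names(d)) d$count else d$auto_count
      d2 <- d[order(d$day), ]
      cnt <- cnt[order(d$day)]
      up <- which(diff(cnt) > 0)
      if (length(up) > 0) {
        v <- c(v, paste0("census counts increase at day(s): ",
                         paste(d2$day[up + 1], collapse = ", ")))
      }
      v
    }),
  ledger = list(
    columns = c("day", "curated_count"),
    check = function(d) {
      if (any(d$curated_count < 0, na.rm = TRUE)) "curated counts must be >= 0"
      else character()
    }),
  survival = list(
    columns = c("id", "time_days", "event"),
    check = function(d) {
      v <- character()
      if (any(d$time_days <= 0, na.rm = TRUE)) v <- c(v, "time_days must be > 0")
      if (!all(d$event %in% c(0, 1))) v <- c(v, "event must be 0 or 1")
      v
    }),
  features = list(
    columns = c("track_id", "mean_speed_mms"),
    kind = "schema_mismatch",
    check = function(d) {
      known <- c("track_id", "mean_speed_mms", "median_speed_mms",
                 "sd_speed_mms", "mean_angvel_rads", "sd_angvel_rads",
                 "mean_abs_vert_vel_mms", "mean_vert_pos", "frac_upper_half",
                 "net_gross_ratio", "area_transverse_mm2", "area_sagittal_mm2",
                 "major_axis_mm", "minor_axis_mm",
                 "p_fwdrun", "p_fwd", "p_fwdslow", "p_turn", "p_spin",
                 "p_pause", "duration_s", "path_length_mm",
                 "age_days", "cohort", "condition",
                 outer(c("weak_light", "strong_light", "vibration"),
                       c("_pre_speed_mms", "_post_speed_mms",
                         "_response_ratio", "_vert_vel_mms"), paste0))
      extra <- setdiff(names(d), known)
      if (length(extra) > 0) {
        paste0("unknown column(s): ", paste(extra, collapse = ", "))
      } else character()
    })
)

#' Validate a table file against a named schema
#'
#' Checks column presence and schema-specific invariants (positive
#' areas, non-increasing census counts, 0/1 event flags, known feature
#' columns, ...). I/O failures (missing/unreadable file) raise an
#' error; schema violations are returned as data, so callers can report
#' them all at once.
#'
#' @param path CSV file to validate.
#' @param schema one of `"tracks"`, `"census"`, `"ledger"`,
#'   `"survival"`, `"features"`.
#' @return tibble of violations (`kind`, `message`); zero rows when the
#'   file is valid.
#' @export
validate_tables <- function(path, schema = names(table_schemas)) {
  schema <- match.arg(schema)
  if (!file.exists(path)) {
    abort(paste0("validate_tables: cannot read file: ", path),
          class = "phenotrack_io_error")
  }
  d <- tryCatch(utils::read.csv(path), error = function(e) {
    abort(paste0("validate_tables: cannot parse ", path, ": ",
                 conditionMessage(e)), class = "phenotrack_io_error")
  })
  sc <- table_schemas[[schema]]
  v <- tibble(kind = character(), message = character())
  missing_cols <- setdiff(sc$columns, names(d))
  if (length(missing_cols) > 0) {
    v <- bind_rows(v, tibble(kind = "schema_mismatch",
                             message = paste0("missing column(s): ",
                                              paste(missing_cols, collapse = ", "))))
    return(v)
  }
  msgs <- sc$check(as_tibble(d))
  if (length(msgs) > 0) {
    v <- bind_rows(v, tibble(kind = sc$kind %||% "invariant", message = msgs))
  }
  v
}

#' Read / write census tables as CSV
#' @param census census tibble (`day`, `auto_count`, `flag`).
#' @param path file path.
#' @return `read_census_csv` returns the tibble.
#' @export
write_census_csv <- function(census, path) {
  utils::write.csv(as.data.frame(census), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_census_csv
#' @export
read_census_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("census file not found: ", path))
  as_tibble(utils::read.csv(path))
}
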