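# shared fixture builders -- everything is generated in code at test time

# small, fast cohort for pipeline tests
tiny_config <- function(...) {
  defaults <- list(n_animals = 3, duration_s = 5, arena_w_px = 240,
                   arena_h_px = 180, n_debris = 2, seed = 42)
  do.call(cohort_config, utils::modifyList(defaults, list(...)))
}

# hand-built ground truth from a trajectory data frame
make_truth <- function(traj, config, age_days = 10) {
  phenotrack:::new_ground_truth(tibble::as_tibble(traj), age_days, config,
                                NULL)
}

# a single straight-line track advancing (dx, dy) px per frame
straight_track <- function(n = 100, x0 = 50, y0 = 50, dx = 3, dy = 4,
                           major = 20, minor = 18, area = 300,
                           perimeter = 60, circ = 0.95, id = 1L) {
  tibble::tibble(
    track_id = id, frame = 0:(n - 1),
    x_px = x0 + dx * (0:(n - 1)), y_px = y0 + dy * (0:(n - 1)),
    area_px = area, perimeter_px = perimeter,
    major_px = major, minor_px = minor, circularity = circ)
}

# brute-force centroid of the brightest connected region of a frame
pixel_centroid_oracle <- function(frame, thresh) {
  on <- which(frame > thresh, arr.ind = TRUE)
  c(x = mean(on[, 2]), y = mean(on[, 1]))
}

# independent exhaustive linking oracle: per frame transition, enumerate
# every injective matching of detections to open tracks (expand.grid over
# candidate-or-none), keep those passing the gates, and pick by
# (max matches, min total distance, min total area difference); identity
# propagates forward. Deliberately brute-force and separate from the
# package's assignment solver.
oracle_link <- function(detections, params) {
  det <- detections[order(detections$frame), ]
  det$.row <- seq_len(nrow(det))
  frames <- sort(unique(det$frame))
  ids <- integer(nrow(det))
  open <- list() # list of c(id, frame, x, y, area)
  next_id <- 1L
  for (f in frames) {
    open <- Filter(function(o) f - o["frame"] <= params$max_gap_frames + 1,
                   open)
    d <- det[det$frame == f, ]
    nt <- length(open); nd <- nrow(d)
    choice <- lapply(seq_len(nd), function(j) {
      ok <- which(vapply(open, function(o) {
        dist <- sqrt((o["x"] - d$x_px[j])^2 + (o["y"] - d$y_px[j])^2)
        ratio <- max(o["area"] / d$area_px[j], d$area_px[j] / o["area"])
        dist <= params$max_link_dist_px && ratio <= params$max_size_ratio
      }, logical(1)))
      c(ok, NA_integer_)
    })
    grids <- do.call(expand.grid, c(choice, KEEP.OUT.ATTRS = FALSE))
    best <- NULL
    for (g in seq_len(nrow(grids))) {
      asg <- as.integer(unlist(grids[g, ]))
      m <- asg[!is.na(asg)]
      if (anyDuplicated(m)) next
      cost <- 0; acost <- 0
      for (j in seq_len(nd)) {
        if (!is.na(asg[j])) {
          o <- open[[asg[j]]]
          cost <- cost + sqrt((o["x"] - d$x_px[j])^2 + (o["y"] - d$y_px[j])^2)
          acost <- acost + abs(o["area"] - d$area_px[j])
        }
      }
      key <- c(-length(m), cost, acost)
      if (is.null(best) || phenotrack:::lex_less(key, best$key)) {
        best <- list(key = key, asg = asg)
      }
    }
    asg <- if (nd > 0) best$asg else integer(0)
    new_open <- list()
    for (j in seq_len(nd)) {
      id <- if (!is.na(asg[j])) open[[asg[j]]]["id"] else {
        v <- next_id; next_id <- next_id + 1L; v
      }
      ids[d$.row[j]] <- id
      new_open[[length(new_open) + 1]] <-
        c(id = unname(id), frame = f, x = d$x_px[j], y = d$y_px[j],
          area = d$area_px[j])
    }
    kept <- Filter(function(o) !(o["id"] %in% vapply(new_open, `[[`, 0, "id")),
                   open)
    open <- c(new_open, kept)
  }
  ids
}

# canonical partition signature of a linking result: set of frame-row
# groups, invariant to track id relabelling
track_partition <- function(frames, rows, ids) {
  unname(sort(vapply(split(paste(frames, rows, sep = ":"), ids),
                     function(g) paste(sort(g), collapse = "|"),
                     character(1))))
}
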