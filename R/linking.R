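#' Tracking (identity linking) parameters
#'
#' @param max_link_dist_px maximum centroid displacement for a link,
#'   pixels per frame transition.
#' @param max_size_ratio morphological gate: a link is accepted only if
#'   the area ratio between the two detections lies in
#'   `[1/max_size_ratio, max_size_ratio]`.
#' @param max_gap_frames a track missing detections for more than this
#'   many frames is terminated.
#' @param min_duration_s minimum track duration; shorter tracks are not
#'   considered trajectories (published rule: less than 10 s).
#' @param min_net_disp_px per-track net-displacement floor; non-moving
#'   residual blobs (dust, gunk surviving background subtraction) below
#'   it are discarded by [filter_tracks()]. 0 disables the floor.
#' @return a `tracking_params` list.
#' @export
tracking_params <- function(max_link_dist_px = 20,
                            max_size_ratio = 5,
                            max_gap_frames = 5L,
                            min_duration_s = 10,
                            min_net_disp_px = 0) {
  stopifnot(max_link_dist_px > 0, max_size_ratio > 0, max_gap_frames >= 0,
            min_duration_s > 0, min_net_disp_px >= 0)
  structure(list(max_link_dist_px = max_link_dist_px,
                 max_size_ratio = max(max_size_ratio, 1 / max_size_ratio),
                 max_gap_frames = as.integer(max_gap_frames),
                 min_duration_s = min_duration_s,
                 min_net_disp_px = min_net_disp_px),
            class = "tracking_params")
}

#' Link per-frame detections into trajectories
#'
#' Frame-to-frame identity assignment: for each frame, open tracks are
#' matched to new detections by a minimum-total-distance assignment over
#' all candidate pairs that pass the positional gate
#' (distance <= `max_link_dist_px`) and the morphological gate (area
#' ratio within `[1/max_size_ratio, max_size_ratio]`). For frames with
#' at most 7 open tracks and 7 detections the assignment is solved
#' exactly by enumeration (maximize the number of links, then minimize
#' total distance, then total area difference, then prefer lower
#' detection indices); larger frames fall back to a greedy
#' nearest-neighbour sweep with the same tie-break order. Unmatched
#' detections start new tracks; a track unmatched for more than
#' `max_gap_frames` frames is closed. A single animal can therefore
#' produce multiple trajectories (e.g. across a missed detection or an
#' occlusion).
#'
#' @param detections tibble of detections with columns `frame` (0-based),
#'   `x_px`, `y_px`, `area_px` (plus any others, carried through).
#' @param params a [tracking_params()].
#' @return tibble: one row per (track, frame), columns `track_id`,
#'   then the detection columns, ordered by track then frame.
#' @export
link_tracks <- function(detections, params = tracking_params()) {
  det <- as_tibble(detections)
  if (nrow(det) == 0) {
    return(bind_cols(tibble(track_id = integer()), det))
  }
  stopifnot(all(c("frame", "x_px", "y_px", "area_px") %in% names(det)))
  det <- arrange(det, .data$frame)
  det$.row <- seq_len(nrow(det))
  by_frame <- split(det, det$frame)
  frames <- as.integer(names(by_frame))

  track_of_row <- integer(nrow(det))
  next_id <- 1L
  # open tracks: id, last frame, last x/y/area, last row
  open <- data.frame(id = integer(), frame = integer(), x = numeric(),
                     y = numeric(), area = numeric())

  for (fi in seq_along(frames)) {
    f <- frames[fi]
    open <- open[f - open$frame <= params$max_gap_frames + 1L, , drop = FALSE]
    d <- by_frame[[fi]]
    nd <- nrow(d); nt <- nrow(open)
    assigned <- rep(NA_integer_, nd) # index into open
    if (nt > 0 && nd > 0) {
      dist <- sqrt(outer(open$x, d$x_px, "-")^2 + outer(open$y, d$y_px, "-")^2)
      ratio <- outer(open$area, d$area_px, function(a, b) pmax(a / b, b / a))
      feasible <- dist <= params$max_link_dist_px & ratio <= params$max_size_ratio
      adiff <- abs(outer(open$area, d$area_px, "-"))
      assigned <- solve_assignment(dist, adiff, feasible)
    }
    new_open <- open[0, ]
    for (j in seq_len(nd)) {
      if (!is.na(assigned[j])) {
        id <- open$id[assigned[j]]
      } else {
        id <- next_id; next_id <- next_id + 1L
      }
      track_of_row[d$.row[j]] <- id
      new_open <- rbind(new_open, data.frame(
        id = id, frame = f, x = d$x_px[j], y = d$y_px[j], area = d$area_px[j]))
    }
    # tracks not matched this frame stay open until the gap runs out
    open <- rbind(new_open, open[!(open$id %in% new_open$id), , drop = FALSE])
  }

  det$track_id <- track_of_row
  det$.row <- NULL
  out <- arrange(det, .data$track_id, .data$frame)
  select(out, "track_id", dplyr::everything())
}

# min-cost bipartite assignment of detections (cols) to tracks (rows).
# Objective (lexicographic): max matches, min total distance, min total
# area difference, lowest detection indices. Exact for small problems,
# greedy otherwise. Returns, per detection, the matched row index or NA.
solve_assignment <- function(dist, adiff, feasible) {
  nt <- nrow(dist); nd <- ncol(dist)
  if (!any(feasible)) return(rep(NA_integer_, nd))
  if (nt <= 7 && nd <= 7) {
    best <- NULL
    # depth-first over detections; each takes a free feasible track or none
    rec <- function(j, used, asg, nmatch, cost, acost) {
      if (j > nd) {
        key <- c(-nmatch, cost, acost)
        if (is.null(best) ||
            isTRUE(lex_less(key, best$key)) ||
            (identical(all.equal(key, best$key), TRUE) &&
             lex_pref(asg, best$asg))) {
          best <<- list(key = key, asg = asg)
        }
        return(invisible())
      }
      # prune: even matching everything remaining cannot beat best count
      for (i in c(which(feasible[, j] & !used), NA_integer_)) {
        if (is.na(i)) {
          rec(j + 1L, used, asg, nmatch, cost, acost)
        } else {
          used2 <- used; used2[i] <- TRUE
          asg2 <- asg; asg2[j] <- i
          rec(j + 1L, used2, asg2, nmatch + 1L,
              cost + dist[i, j], acost + adiff[i, j])
        }
      }
    }
    rec(1L, rep(FALSE, nt), rep(NA_integer_, nd), 0L, 0, 0)
    return(best$asg)
  }
  # greedy sweep: shortest feasible pair first, ties by area diff then index
  pairs <- which(feasible, arr.ind = TRUE)
  ord <- order(dist[pairs], adiff[pairs], pairs[, 2], pairs[, 1])
  pairs <- pairs[ord, , drop = FALSE]
  asg <- rep(NA_integer_, nd); used <- rep(FALSE, nt)
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    if (!used[i] && is.na(asg[j])) { asg[j] <- i; used[i] <- TRUE }
  }
  asg
}

lex_less <- function(a, b, tol = 1e-9) {
  for (k in seq_along(a)) {
    if (a[k] < b[k] - tol) return(TRUE)
    if (a[k] > b[k] + tol) return(FALSE)
  }
  FALSE
}

# prefer assignments whose matched detection set is lexicographically
# earlier (lower detection indices matched / to lower track rows)
lex_pref <- function(a, b) {
  av <- ifelse(is.na(a), Inf, a); bv <- ifelse(is.na(b), Inf, b)
  for (k in seq_along(av)) {
    if (av[k] < bv[k]) return(TRUE)
    if (av[k] > bv[k]) return(FALSE)
  }
  FALSE
}

#' Filter tracks by duration and net displacement
#'
#' Keeps tracks whose duration `(n_detections - 1) / fps` is at least
#' `min_duration_s` (the published rule discards anything tracked for
#' less than 10 s) and, when `min_net_disp_px > 0`, whose net start-to-
#' end displacement is at least that floor (rejecting residual
#' stationary blobs).
#'
#' @param tracks track tibble from [link_tracks()].
#' @param params a [tracking_params()].
#' @param fps frames per second.
#' @return filtered track tibble.
#' @export
filter_tracks <- function(tracks, params = tracking_params(), fps = 25) {
  stopifnot(fps > 0)
  tr <- as_tibble(tracks)
  if (nrow(tr) == 0) return(tr)
  keep <- tr |>
    group_by(.data$track_id) |>
    summarise(
      duration_s = (n() - 1) / fps,
      net_px = sqrt((dplyr::last(.data$x_px) - dplyr::first(.data$x_px))^2 +
                    (dplyr::last(.data$y_px) - dplyr::first(.data$y_px))^2),
      .groups = "drop") |>
    filter(.data$duration_s >= params$min_duration_s,
           .data$net_px >= params$min_net_disp_px)
  filter(tr, .data$track_id %in% keep$track_id)
}

#' Read / write trajectory tables as CSV
#'
#' One row per (track, frame); columns `track_id, frame, x_px, y_px,
#' area_px, perimeter_px, major_px, minor_px, circularity`.
#'
#' @param tracks track tibble.
#' @param path file path.
#' @return `read_tracks_csv` returns the track tibble.
#' @export
write_tracks_csv <- function(tracks, path) {
  utils::write.csv(as.data.frame(tracks), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracks_csv
#' @export
read_tracks_csv <- function(path) {
  if (!file.exists(path)) abort(paste0("track file not found: ", path))
  as_tibble(utils::read.csv(path))
}
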