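#' Render a ground-truth cohort into a grayscale video stack
#'
#' Draws each animal as a filled oriented ellipse (bright on a dark
#' background) whose major axis is the body length and whose aspect
#' ratio encodes the body presentation (transverse: near-circular;
#' sagittal: elongated), composites static debris blobs that are
#' constant across frames, and adds i.i.d. Gaussian pixel noise.
#' Overlapping animals composite by maximum intensity.
#'
#' Pixel `(row i, col j)` has centre `(x = j, y = i)` (1-based, image
#' convention). Intensities are 8-bit (0-255).
#'
#' @param truth a `ground_truth` from [simulate_trajectories()].
#' @param config a [cohort_config()]; supplies arena size, aspect
#'   ratios, debris, noise and the rendering seed.
#' @param fg,bg foreground (animal) and background intensity levels.
#' @return a `video_stack`: integer array `[height, width, n_frames]`
#'   with attributes `fps` and `px_per_mm`.
#' @export
render_video <- function(truth, config = truth$config, fg = 220, bg = 30) {
  traj <- truth$trajectories
  H <- config$arena_h_px; W <- config$arena_w_px
  frames <- sort(unique(traj$frame))
  n_frames <- length(frames)
  if (nrow(traj) > 0) {
    inside <- traj$x_px >= 0.5 & traj$x_px <= W + 0.5 &
      traj$y_px >= 0.5 & traj$y_px <= H + 0.5
    if (!all(inside)) abort("render_video: trajectory coordinates outside arena")
  }
  if (n_frames == 0) n_frames <- as.integer(round(config$duration_s * config$fps)) + 1L

  # static scene: flat background + debris, identical in every frame
  scene <- matrix(bg, H, W)
  scene <- withr::with_seed(config$seed + 1031L, {
    if (config$n_debris > 0) {
      for (d in seq_len(config$n_debris)) {
        scene <- draw_ellipse(scene, runif(1, 5, W - 5), runif(1, 5, H - 5),
                              a = runif(1, 2, 5), b = runif(1, 2, 4),
                              theta = runif(1, -pi, pi), value = runif(1, 120, 200))
      }
    }
    scene
  })

  video <- array(0L, dim = c(H, W, n_frames))
  by_frame <- split(traj, traj$frame)
  aspect <- c(transverse = config$transverse_aspect,
              sagittal = config$sagittal_aspect)
  noise <- config$noise_sd
  withr::with_seed(config$seed + 2063L, {
    for (k in seq_len(n_frames)) {
      fr <- scene
      rows <- by_frame[[as.character(frames[k])]]
      if (!is.null(rows) && nrow(rows) > 0) {
        major_px <- rows$body_len_mm * config$px_per_mm
        minor_px <- major_px / aspect[rows$plane]
        for (i in seq_len(nrow(rows))) {
          fr <- draw_ellipse(fr, rows$x_px[i], rows$y_px[i],
                             major_px[i] / 2, minor_px[i] / 2,
                             rows$heading[i], fg)
        }
      }
      if (noise > 0) fr <- fr + rnorm(length(fr), 0, noise)
      video[, , k] <- as.integer(pmax(0, pmin(255, round(fr))))
    }
  })
  new_video_stack(video, fps = config$fps, px_per_mm = config$px_per_mm)
}

# fill pixels whose centres fall inside the oriented ellipse; composite by max
draw_ellipse <- function(img, cx, cy, a, b, theta, value) {
  a <- max(a, 0.6); b <- max(b, 0.6) # at least one pixel wide
  H <- nrow(img); W <- ncol(img)
  j0 <- max(1L, floor(cx - a - 1)); j1 <- min(W, ceiling(cx + a + 1))
  i0 <- max(1L, floor(cy - a - 1)); i1 <- min(H, ceiling(cy + a + 1))
  if (j0 > j1 || i0 > i1) return(img)
  jj <- j0:j1; ii <- i0:i1
  dx <- outer(rep(1, length(ii)), jj - cx)
  dy <- outer(ii - cy, rep(1, length(jj)))
  u <- dx * cos(theta) + dy * sin(theta)
  v <- -dx * sin(theta) + dy * cos(theta)
  inside <- (u / a)^2 + (v / b)^2 <= 1
  sub <- img[ii, jj, drop = FALSE]
  sub[inside] <- pmax(sub[inside], value)
  img[ii, jj] <- sub
  img
}

new_video_stack <- function(arr, fps, px_per_mm) {
  structure(arr, fps = fps, px_per_mm = px_per_mm, class = "video_stack")
}

#' @export
print.video_stack <- function(x, ...) {
  d <- dim(x)
  cat("<video_stack> ", d[2], "x", d[1], " px, ", d[3], " frames @ ",
      attr(x, "fps"), " fps\n", sep = "")
  invisible(x)
}

#' Number of frames in a video stack
#' @param video a `video_stack`.
#' @return integer frame count.
#' @export
n_frames <- function(video) dim(video)[3]

#' Extract one frame as a matrix
#' @param video a `video_stack`.
#' @param frame 0-based frame index (the convention used throughout).
#' @return numeric matrix `[height, width]`.
#' @export
get_frame <- function(video, frame) {
  stopifnot(frame >= 0, frame < dim(video)[3])
  v <- unclass(video)[, , frame + 1L]
  v
}

#' Write / read a video stack as multi-page 8-bit grayscale TIFF
#'
#' @param video a `video_stack` (intensities 0-255).
#' @param path file path.
#' @param fps,px_per_mm metadata restored on read (TIFF pages carry no
#'   calibration; supply the recording's values).
#' @param invert set `TRUE` if the recording has dark animals on a
#'   bright background; frames are inverted to the package's
#'   bright-on-dark convention on read.
#' @return `read_video_tiff` returns a `video_stack`.
#' @export
write_video_tiff <- function(video, path) {
  pages <- lapply(seq_len(dim(video)[3]), function(k) {
    unclass(video)[, , k] / 255
  })
  tiff::writeTIFF(pages, path, bits.per.sample = 8L)
  invisible(path)
}

#' @rdname write_video_tiff
#' @export
read_video_tiff <- function(path, fps = 25, px_per_mm = 1, invert = FALSE) {
  if (!file.exists(path)) abort(paste0("video file not found: ", path))
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  arr <- array(0L, dim = c(H, W, length(pages)))
  for (k in seq_along(pages)) {
    m <- round(pages[[k]] * 255)
    if (invert) m <- 255 - m
    arr[, , k] <- as.integer(m)
  }
  new_video_stack(arr, fps = fps, px_per_mm = px_per_mm)
}
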