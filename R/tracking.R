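#' Estimate a static background from a video
#'
#' The background is the pixel-wise mean of every `stride`-th frame,
#' starting at frame 0 (0-based indexing). At the default stride of 25
#' on a 25 fps recording this samples one frame per second, averaging
#' away the moving animals while retaining every stationary object
#' (debris, corpses), which background subtraction then removes.
#'
#' @param video a `video_stack`.
#' @param stride sampling stride in frames (>= 1).
#' @return a `background_model`: list with `background` (matrix),
#'   `stride` and `frames_used` (0-based indices).
#' @export
estimate_background <- function(video, stride = 25L) {
  nf <- dim(video)[3]
  if (is.null(nf) || nf < 1) abort("estimate_background: empty video")
  stride <- as.integer(stride)
  stopifnot("stride must be >= 1" = stride >= 1)
  idx0 <- seq(0L, nf - 1L, by = stride) # 0-based sampled frames
  sub <- unclass(video)[, , idx0 + 1L, drop = FALSE]
  d <- dim(sub)
  bgm <- matrix(rowMeans(matrix(sub, d[1] * d[2], d[3])), d[1], d[2])
  if (!all(is.finite(bgm))) abort("estimate_background: non-finite pixels")
  structure(list(background = bgm, stride = stride, frames_used = idx0),
            class = "background_model")
}

#' @export
print.background_model <- function(x, ...) {
  cat("<background_model> ", ncol(x$background), "x", nrow(x$background),
      " px, mean of ", length(x$frames_used), " frames (stride ",
      x$stride, ")\n", sep = "")
  invisible(x)
}

#' Shape circularity
#'
#' `circularity(A, P) = 4 * pi * A / P^2`: 1 for an ideal circle,
#' `pi/4` for a square, smaller for elongated shapes. On rasterized
#' blobs the discrete area/perimeter estimators bias the raw value, so
#' [normalized_circularity()] divides by the raw circularity of an ideal
#' rasterized disc of equal area (measured with the same estimators),
#' mapping a disc back to ~1. The published transverse/sagittal
#' thresholds (0.92 / 0.58) apply to the normalized value.
#'
#' @param area_px blob area, pixels^2.
#' @param perimeter_px blob perimeter, pixels.
#' @return dimensionless circularity (vectorized).
#' @export
circularity <- function(area_px, perimeter_px) {
  if (any(!is.finite(area_px)) || any(!is.finite(perimeter_px)) ||
      any(area_px <= 0) || any(perimeter_px <= 0)) {
    abort("circularity: area and perimeter must be positive and finite")
  }
  4 * pi * area_px / perimeter_px^2
}

#' @rdname circularity
#' @export
normalized_circularity <- function(area_px, perimeter_px) {
  circularity(area_px, perimeter_px) / disc_circularity_factor(area_px)
}

# raw circularity of an ideal rasterized disc of the given area, using
# the same label/measure estimators as segment_frame; tabulated over
# radius once per session and interpolated in between
the_disc_cache <- new.env(parent = emptyenv())

disc_circularity_factor <- function(area_px) {
  if (is.null(the_disc_cache$tab)) {
    radii <- c(seq(1, 12, by = 0.5), seq(13, 30, by = 1), seq(35, 80, by = 5))
    tab <- vapply(radii, function(r) {
      s <- as.integer(2 * ceiling(r) + 5)
      c0 <- (s + 1) / 2
      m <- matrix(0L, s, s)
      ij <- expand.grid(i = seq_len(s), j = seq_len(s))
      m[as.matrix(ij[((ij$j - c0)^2 + (ij$i - c0)^2) <= r^2, ])] <- 1L
      f <- measure_blobs(m)
      c(area = f$area_px, circ = circularity(f$area_px, f$perimeter_px))
    }, c(area = 0, circ = 0))
    the_disc_cache$tab <- tab[, order(tab["area", ])]
  }
  tab <- the_disc_cache$tab
  approx(tab["area", ], tab["circ", ], xout = pmin(pmax(area_px,
         min(tab["area", ])), max(tab["area", ])), rule = 2)$y
}

# label a binary matrix and measure each blob; wraps EBImage.
# EBImage indexes the first matrix dimension as "x"; for our [y, x]
# frames m.cx is therefore the row (y) and m.cy the column (x).
measure_blobs <- function(binary) {
  lab <- EBImage::bwlabel(binary)
  if (max(lab) == 0) {
    return(tibble(x_px = numeric(), y_px = numeric(), area_px = numeric(),
                  perimeter_px = numeric(), major_px = numeric(),
                  minor_px = numeric()))
  }
  sh <- EBImage::computeFeatures.shape(lab)
  mo <- EBImage::computeFeatures.moment(lab)
  sh <- matrix(sh, ncol = 6, dimnames = list(NULL, colnames(sh)))
  mo <- matrix(mo, ncol = 5, dimnames = list(NULL, colnames(mo)))
  major <- mo[, "m.majoraxis"]
  minor <- major * sqrt(pmax(0, 1 - mo[, "m.eccentricity"]^2))
  tibble(x_px = unname(mo[, "m.cy"]), y_px = unname(mo[, "m.cx"]),
         area_px = unname(sh[, "s.area"]),
         perimeter_px = unname(pmax(sh[, "s.perimeter"], 1)),
         major_px = unname(major), minor_px = unname(pmax(minor, 1)))
}

#' Segmentation parameters
#'
#' @param threshold `"otsu"` for an automatic Otsu threshold on each
#'   difference image, or a fixed numeric intensity (0-255).
#' @param min_area_px,max_area_px area filter for accepted blobs,
#'   pixels^2.
#' @param transverse_circ_threshold normalized circularity above which a
#'   blob is a transverse (top-view) presentation; published value 0.92.
#' @param sagittal_circ_threshold normalized circularity below which a
#'   blob is a sagittal (side-view) presentation; published value 0.58.
#' @param circularity_scale `"normalized"` (divide by the equal-area
#'   ideal rasterized disc; default) or `"raw"` (plain `4*pi*A/P^2`).
#' @param min_threshold floor for the automatic threshold; keeps a
#'   blank (all-noise) difference image from segmenting noise.
#' @return a `segmentation_params` list.
#' @export
segmentation_params <- function(threshold = "otsu",
                                min_area_px = 5,
                                max_area_px = Inf,
                                transverse_circ_threshold = 0.92,
                                sagittal_circ_threshold = 0.58,
                                circularity_scale = c("normalized", "raw"),
                                min_threshold = 8) {
  circularity_scale <- match.arg(circularity_scale)
  stopifnot(
    "circularity thresholds must satisfy 0 < sagittal < transverse <= 1" =
      sagittal_circ_threshold > 0 &&
      sagittal_circ_threshold < transverse_circ_threshold &&
      transverse_circ_threshold <= 1,
    "min_area_px must be >= 0" = min_area_px >= 0,
    "max_area_px must exceed min_area_px" = max_area_px > min_area_px
  )
  structure(list(threshold = threshold, min_area_px = min_area_px,
                 max_area_px = max_area_px,
                 transverse_circ_threshold = transverse_circ_threshold,
                 sagittal_circ_threshold = sagittal_circ_threshold,
                 circularity_scale = circularity_scale,
                 min_threshold = min_threshold),
            class = "segmentation_params")
}

#' Segment one frame against a background model
#'
#' Thresholds the absolute difference image, labels connected
#' components, filters them by area and parameterizes each surviving
#' blob by centroid, area, perimeter, ellipse-equivalent axes and
#' circularity.
#'
#' @param frame numeric matrix `[height, width]` (or 0-based frame index
#'   via [get_frame()]).
#' @param bg a `background_model` from [estimate_background()].
#' @param params a [segmentation_params()].
#' @return tibble of detections: `x_px`, `y_px`, `area_px`,
#'   `perimeter_px`, `major_px`, `minor_px`, `circularity`.
#' @export
segment_frame <- function(frame, bg, params = segmentation_params()) {
  bgm <- bg$background
  if (!all(dim(frame) == dim(bgm))) {
    abort("segment_frame: frame and background differ in shape")
  }
  d <- abs(frame - bgm)
  th <- if (identical(params$threshold, "otsu")) {
    max(EBImage::otsu(EBImage::Image(d / 255), range = c(0, 1)) * 255,
        params$min_threshold)
  } else {
    as.numeric(params$threshold)
  }
  det <- measure_blobs((d > th) * 1L)
  det <- det[det$area_px >= params$min_area_px &
             det$area_px <= params$max_area_px, , drop = FALSE]
  if (nrow(det) == 0) {
    det$circularity <- numeric()
    return(as_tibble(det))
  }
  det$circularity <- switch(params$circularity_scale,
    normalized = normalized_circularity(det$area_px, det$perimeter_px),
    raw = circularity(det$area_px, det$perimeter_px))
  as_tibble(det)
}

#' Segment every frame of a video
#'
#' @param video a `video_stack`.
#' @param bg a `background_model`; estimated from `video` when `NULL`.
#' @param params a [segmentation_params()].
#' @param stride background stride when `bg` is `NULL`.
#' @return tibble of detections with a 0-based `frame` column.
#' @export
segment_video <- function(video, bg = NULL, params = segmentation_params(),
                          stride = 25L) {
  if (is.null(bg)) bg <- estimate_background(video, stride)
  nf <- dim(video)[3]
  out <- vector("list", nf)
  for (k in seq_len(nf)) {
    det <- segment_frame(unclass(video)[, , k], bg, params)
    if (nrow(det) > 0) det$frame <- k - 1L
    out[[k]] <- det
  }
  res <- bind_rows(out)
  if (nrow(res) == 0) {
    return(tibble(frame = integer(), x_px = numeric(), y_px = numeric(),
                  area_px = numeric(), perimeter_px = numeric(),
                  major_px = numeric(), minor_px = numeric(),
                  circularity = numeric()))
  }
  select(res, "frame", "x_px", "y_px", "area_px", "perimeter_px",
         "major_px", "minor_px", "circularity")
}
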