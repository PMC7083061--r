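# Rectangular regions of interest enclosed by landmarks on structures
# treated as stable during growth and treatment. Confining keypoint
# detection to these rectangles is what makes the superimposition
# "structural": the dentition and remodelling surfaces outside them never
# contribute matches.

# The three regions and their four defining landmarks.
REGION_LANDMARKS <- list(
  cranial_base = c("URP", "S", "Pt", "N"),
  maxilla      = c("Pt", "PNS", "ANS", "A"),
  mandible     = c("LM", "Pg", "Me", "Go")
)

#' Region names and their defining landmarks
#'
#' @param region one of `"cranial_base"`, `"maxilla"`, `"mandible"`.
#' @return Character vector of the four landmark abbreviations that enclose
#'   the region's rectangle.
#' @export
region_landmarks <- function(region) {
  region <- match.arg(region, names(REGION_LANDMARKS))
  REGION_LANDMARKS[[region]]
}

#' Build a rectangular ROI from a region's defining landmarks
#'
#' The ROI is the axis-aligned bounding box of the four defining landmarks,
#' expanded by `margin_px` on every side and clipped to the image. Bounds are
#' half-open `[x_min, x_max) x [y_min, y_max)` with the max side extended by
#' one pixel so the extreme landmark itself is inside.
#'
#' @param landmarks a [landmark_set].
#' @param region region name (see [region_landmarks]).
#' @param image a [radiograph] providing the clipping bounds.
#' @param margin_px non-negative integer margin (default 10).
#' @return An object of class `roi` with fields `x_min`, `y_min`, `x_max`,
#'   `y_max` and `region`.
#' @export
roi_from_landmarks <- function(landmarks, region, image, margin_px = 10) {
  region <- match.arg(region, names(REGION_LANDMARKS))
  stopifnot(inherits(image, "radiograph"))
  if (margin_px < 0) stop("`margin_px` must be non-negative", call. = FALSE)
  need <- REGION_LANDMARKS[[region]]
  missing <- setdiff(need, rownames(landmarks))
  if (length(missing) > 0) {
    stop(errorCondition(
      sprintf("region '%s' is missing landmark(s): %s",
              region, paste(missing, collapse = ", ")),
      class = "ceph_landmark_error"))
  }
  pts <- landmarks[need, , drop = FALSE]
  x_min <- floor(min(pts[, 1])) - margin_px
  y_min <- floor(min(pts[, 2])) - margin_px
  x_max <- ceiling(max(pts[, 1])) + 1 + margin_px  # half-open, +1 includes extreme
  y_max <- ceiling(max(pts[, 2])) + 1 + margin_px
  x_min <- max(x_min, 0)
  y_min <- max(y_min, 0)
  x_max <- min(x_max, image$width)
  y_max <- min(y_max, image$height)
  if ((x_max - x_min) < 32 || (y_max - y_min) < 32) {
    stop(errorCondition(sprintf(
      "degenerate ROI for region '%s': clipped area %d x %d px is below 32 x 32",
      region, max(x_max - x_min, 0), max(y_max - y_min, 0)),
      class = "ceph_landmark_error"))
  }
  structure(
    list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
         region = region),
    class = "roi"
  )
}

#' @export
print.roi <- function(x, ...) {
  cat(sprintf("<roi> %s: [%d, %d) x [%d, %d)  (%d x %d px)\n",
              x$region, x$x_min, x$x_max, x$y_min, x$y_max,
              x$x_max - x$x_min, x$y_max - x$y_min))
  invisible(x)
}

#' Crop an image to an ROI
#'
#' @param image a [radiograph].
#' @param roi an `roi` from [roi_from_landmarks].
#' @return List with `pixels` (the sub-image matrix) and `offset = c(x_min,
#'   y_min)`; adding the offset to ROI-local coordinates recovers full-image
#'   coordinates.
#' @export
crop <- function(image, roi) {
  stopifnot(inherits(image, "radiograph"), inherits(roi, "roi"))
  if (roi$x_min < 0 || roi$y_min < 0 ||
      roi$x_max > image$width || roi$y_max > image$height) {
    stop("ROI exceeds image bounds", call. = FALSE)
  }
  sub <- image$pixels[(roi$y_min + 1):roi$y_max, (roi$x_min + 1):roi$x_max,
                      drop = FALSE]
  list(pixels = sub, offset = c(roi$x_min, roi$y_min))
}
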