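#' Construct a radiograph image object
#'
#' A `radiograph` wraps a grayscale intensity matrix together with its
#' physical pixel calibration. Pixel coordinates are 0-based with the origin
#' at the top-left corner, x rightward and y downward; pixel `(x, y)` lives
#' at matrix entry `[y + 1, x + 1]`.
#'
#' @param pixels numeric matrix, rows = image height, columns = width,
#'   intensities in `[0, 1]`.
#' @param mm_per_px physical size of one pixel in millimetres. The default
#'   corresponds to films scanned at original size and 600 dpi.
#' @return An object of class `radiograph` with elements `pixels`, `width`,
#'   `height` and `mm_per_px`.
#' @export
radiograph <- function(pixels, mm_per_px = DEFAULT_MM_PER_PX) {
  if (!is.matrix(pixels) || !is.numeric(pixels)) {
    stop("`pixels` must be a numeric matrix", call. = FALSE)
  }
  if (!all(is.finite(pixels))) {
    stop("image intensities must be finite", call. = FALSE)
  }
  if (min(pixels) < 0 || max(pixels) > 1) {
    stop("image intensities must lie in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(mm_per_px) || length(mm_per_px) != 1 || !is.finite(mm_per_px) ||
      mm_per_px <= 0) {
    stop("`mm_per_px` must be a positive number", call. = FALSE)
  }
  structure(
    list(
      pixels = pixels,
      width = ncol(pixels),
      height = nrow(pixels),
      mm_per_px = mm_per_px
    ),
    class = "radiograph"
  )
}

#' @export
print.radiograph <- function(x, ...) {
  cat(sprintf(
    "<radiograph> %d x %d px, %.5f mm/px (%.1f x %.1f mm)\n",
    x$width, x$height, x$mm_per_px,
    x$width * x$mm_per_px, x$height * x$mm_per_px
  ))
  invisible(x)
}

#' Load a cephalogram from a PNG or TIFF file
#'
#' Reads an 8- or 16-bit raster, converts colour inputs to luminance
#' (Rec. 601 weights), and min-max normalizes intensities to `[0, 1]`.
#'
#' @param path path to a PNG or TIFF file.
#' @param mm_per_px pixel calibration in mm; defaults to the 600-dpi scan
#'   value `25.4/600`.
#' @return A [radiograph].
#' @export
load_image <- function(path, mm_per_px = DEFAULT_MM_PER_PX) {
  if (!file.exists(path)) {
    stop(sprintf("image file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image format '%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  )
  px <- to_gray(raw)
  rng <- range(px)
  if (rng[2] - rng[1] <= 0) {
    stop("degenerate image: zero intensity variance", call. = FALSE)
  }
  px <- (px - rng[1]) / (rng[2] - rng[1])
  radiograph(px, mm_per_px = mm_per_px)
}

# Collapse an array read by png/tiff to a single luminance channel.
to_gray <- function(raw) {
  if (length(dim(raw)) == 2) return(raw)
  if (length(dim(raw)) == 3) {
    nchan <- dim(raw)[3]
    if (nchan == 1) return(raw[, , 1])
    # RGB(A): Rec. 601 luma; alpha ignored
    return(0.299 * raw[, , 1] + 0.587 * raw[, , 2] + 0.114 * raw[, , 3])
  }
  stop("unsupported image array layout", call. = FALSE)
}

#' Save a radiograph to disk
#'
#' `.png` writes an 8-bit grayscale PNG (sufficient for overlays); `.tif` /
#' `.tiff` writes a 16-bit grayscale TIFF, which preserves normalized
#' intensities to within 1/65535 on reload.
#'
#' @param image a [radiograph].
#' @param path output path (`.png`, `.tif` or `.tiff`).
#' @return The path, invisibly.
#' @export
save_image <- function(image, path) {
  stopifnot(inherits(image, "radiograph"))
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(image$pixels, target = path, dpi = 25.4 / image$mm_per_px)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(image$pixels, where = path, bits.per.sample = 16L)
  } else {
    stop(sprintf("unsupported output format '%s' (use PNG or TIFF)", ext),
         call. = FALSE)
  }
  invisible(path)
}

#' Construct a landmark set
#'
#' Named 2-D points in pixel coordinates for one film. Only the 21
#' cephalometric landmark abbreviations in `CEPH_LANDMARKS` are accepted.
#'
#' @param points a two-column numeric matrix (columns `x`, `y`) with landmark
#'   names as row names.
#' @param image optional [radiograph]; when given, points are checked to lie
#'   within its bounds.
#' @return An object of class `landmark_set` (the validated matrix).
#' @export
landmark_set <- function(points, image = NULL) {
  if (is.data.frame(points)) points <- as.matrix(points[, c("x", "y")])
  if (!is.matrix(points) || ncol(points) != 2) {
    stop("`points` must be a two-column matrix", call. = FALSE)
  }
  nm <- rownames(points)
  if (is.null(nm) || any(nm == "")) {
    stop("landmark points must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop(sprintf("duplicate landmark name(s): %s",
                 paste(unique(nm[duplicated(nm)]), collapse = ", ")),
         call. = FALSE)
  }
  unknown <- setdiff(nm, CEPH_LANDMARKS)
  if (length(unknown) > 0) {
    stop(sprintf("unknown landmark name(s): %s",
                 paste(unknown, collapse = ", ")), call. = FALSE)
  }
  storage.mode(points) <- "double"
  if (!all(is.finite(points))) {
    stop("landmark coordinates must be finite numbers", call. = FALSE)
  }
  colnames(points) <- c("x", "y")
  if (!is.null(image)) {
    bad <- points[, 1] < 0 | points[, 1] > image$width - 1 |
      points[, 2] < 0 | points[, 2] > image$height - 1
    if (any(bad)) {
      stop(sprintf("landmark(s) outside image bounds: %s",
                   paste(nm[bad], collapse = ", ")), call. = FALSE)
    }
  }
  structure(points, class = c("landmark_set", "matrix"))
}

#' @export
print.landmark_set <- function(x, ...) {
  cat(sprintf("<landmark_set> %d landmarks: %s\n",
              nrow(x), paste(rownames(x), collapse = " ")))
  invisible(x)
}

#' Load landmarks from CSV or JSON
#'
#' CSV files need a `name,x,y` header; JSON files map landmark names to
#' `[x, y]` pairs. Coordinates are 0-based pixels in the image frame.
#'
#' @param path path to the landmark file.
#' @param image optional [radiograph] used for bounds validation.
#' @return A [landmark_set].
#' @export
load_landmarks <- function(path, image = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("landmark file not found: %s", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.list(obj) && !is.matrix(obj)) {
      stop("JSON landmark file must map names to [x, y] pairs", call. = FALSE)
    }
    nm <- names(obj)
    pts <- do.call(rbind, lapply(obj, function(v) as.numeric(v[1:2])))
    rownames(pts) <- nm
  } else if (ext == "csv") {
    df <- read.csv(path, stringsAsFactors = FALSE)
    need <- c("name", "x", "y")
    if (!all(need %in% names(df))) {
      stop("CSV landmark file must have columns name,x,y", call. = FALSE)
    }
    if (!is.numeric(df$x) || !is.numeric(df$y)) {
      stop("landmark coordinates must be numeric", call. = FALSE)
    }
    pts <- cbind(x = df$x, y = df$y)
    rownames(pts) <- df$name
  } else {
    stop(sprintf("unsupported landmark format '%s' (use CSV or JSON)", ext),
         call. = FALSE)
  }
  landmark_set(pts, image = image)
}

#' Write a landmark set to CSV
#'
#' @param landmarks a [landmark_set].
#' @param path output path (`.csv`).
#' @return The path, invisibly.
#' @export
save_landmarks <- function(landmarks, path) {
  df <- data.frame(name = rownames(landmarks),
                   x = landmarks[, 1], y = landmarks[, 2],
                   row.names = NULL)
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a pixel distance to millimetres
#'
#' @param distance_px non-negative distance in pixels.
#' @param mm_per_px positive calibration (mm per pixel).
#' @return `distance_px * mm_per_px`, in mm.
#' @export
px_to_mm <- function(distance_px, mm_per_px) {
  if (any(!is.finite(distance_px)) || any(!is.finite(mm_per_px))) {
    stop("inputs must be finite", call. = FALSE)
  }
  if (any(distance_px < 0)) stop("distance must be non-negative", call. = FALSE)
  if (any(mm_per_px <= 0)) stop("calibration must be positive", call. = FALSE)
  distance_px * mm_per_px
}
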