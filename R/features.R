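# Oriented-FAST keypoint detection, rotation-steered 256-bit binary
# description, and brute-force Hamming matching. The whole module is
# deterministic: the descriptor pair table is frozen (fixed generator seed)
# and every tie-break is lexicographic, so two runs produce bit-identical
# descriptors and matches.

# ---- descriptor sampling pattern ------------------------------------------

# 256 point pairs in the 31x31 patch frame, i.i.d. Gaussian with
# sigma = patch_width/5, rounded and clamped to the patch. Generated once
# from a fixed seed and cached; R's Mersenne-Twister stream makes the table
# identical across platforms.
pattern_cache <- new.env(parent = emptyenv())

#' Descriptor sampling pattern
#'
#' Returns the frozen 256-pair sampling pattern used by the steered binary
#' descriptor: a 256 x 4 integer matrix of `(px, py, qx, qy)` offsets in a
#' 31 x 31 patch frame centred on the keypoint.
#'
#' @param n_bits number of comparison pairs (descriptor length in bits).
#' @param patch_size side of the square patch (odd).
#' @param seed generator seed; the default defines the pattern shipped with
#'   the package.
#' @return Integer matrix `n_bits x 4`.
#' @export
sampling_pattern <- function(n_bits = 256, patch_size = 31, seed = 20240901) {
  key <- sprintf("p%d_%d_%d", n_bits, patch_size, seed)
  if (!is.null(pattern_cache[[key]])) return(pattern_cache[[key]])
  half <- (patch_size - 1) %/% 2
  sigma <- patch_size / 5
  old <- .save_seed()
  set.seed(seed)
  vals <- round(rnorm(n_bits * 4, mean = 0, sd = sigma))
  .restore_seed(old)
  vals <- pmin(pmax(vals, -half), half)
  pat <- matrix(as.integer(vals), ncol = 4,
                dimnames = list(NULL, c("px", "py", "qx", "qy")))
  pattern_cache[[key]] <- pat
  pat
}

# Save/restore the global RNG state so frozen-pattern generation never
# perturbs user-visible randomness.
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

# ---- pyramid ---------------------------------------------------------------

#' Build a smoothed image pyramid
#'
#' Level 0 is the input; level k is level k-1 Gaussian-smoothed and
#' downscaled by `scale_factor`. Used so corners at coarser structural
#' scales are detected too.
#'
#' @param pixels numeric intensity matrix (rows = y, cols = x).
#' @param n_levels number of levels (>= 1).
#' @param scale_factor per-level downscaling factor (> 1).
#' @return List of levels, each with `pixels` and cumulative `scale`
#'   (`scale_factor^k`).
#' @export
build_pyramid <- function(pixels, n_levels = 8, scale_factor = 1.2) {
  stopifnot(is.matrix(pixels), n_levels >= 1)
  if (n_levels > 1 && scale_factor <= 1) {
    stop("`scale_factor` must exceed 1", call. = FALSE)
  }
  top_h <- floor(nrow(pixels) / scale_factor^(n_levels - 1))
  top_w <- floor(ncol(pixels) / scale_factor^(n_levels - 1))
  if (top_h < 32 || top_w < 32) {
    stop(sprintf("pyramid top level %d x %d px is below the 32 x 32 minimum",
                 top_w, top_h), call. = FALSE)
  }
  levels <- vector("list", n_levels)
  levels[[1]] <- list(pixels = pixels, scale = 1)
  for (k in seq_len(n_levels - 1)) {
    prev <- levels[[k]]$pixels
    out_h <- floor(nrow(pixels) / scale_factor^k)
    out_w <- floor(ncol(pixels) / scale_factor^k)
    smoothed <- cpp_gaussian_blur(prev, sigma = 0.5 * scale_factor)
    levels[[k + 1]] <- list(
      pixels = cpp_resize_bilinear(smoothed, out_h, out_w),
      scale = scale_factor^k
    )
  }
  levels
}

# Largest level count that keeps the top level >= 32 px per side.
max_pyramid_levels <- function(pixels, scale_factor, n_levels) {
  feasible <- 1 + floor(log(min(dim(pixels)) / 32) / log(scale_factor))
  max(1, min(n_levels, feasible))
}

# ---- detection -------------------------------------------------------------

#' FAST segment-test corner detection
#'
#' A pixel is a corner when at least `min_arc` contiguous pixels on the
#' 16-pixel Bresenham circle of radius 3 are all brighter than
#' `center + threshold` or all darker than `center - threshold`. Non-maximum
#' suppression on the segment-test score is applied within each 3 x 3
#' neighbourhood (score ties broken towards the lexicographically smallest
#' `(y, x)`).
#'
#' @param pixels intensity matrix in `[0, 1]`.
#' @param threshold intensity delta in `(0, 1)` (fraction of the dynamic
#'   range).
#' @param min_arc minimum contiguous arc length (default 9).
#' @return Data frame with columns `x`, `y` (0-based integer positions) and
#'   `score`; zero rows when no corner passes.
#' @export
detect_fast <- function(pixels, threshold = 0.08, min_arc = 9) {
  stopifnot(is.matrix(pixels))
  if (threshold <= 0 || threshold >= 1) {
    stop("`threshold` must lie in (0, 1)", call. = FALSE)
  }
  m <- cpp_fast_detect(pixels, threshold, as.integer(min_arc))
  as.data.frame(m)
}

#' Rank keypoints by Harris corner measure and keep the strongest
#'
#' The Harris measure `det(M) - k tr(M)^2` is computed over a square window
#' at each FAST corner; the `max_keep` strongest are retained, sorted by
#' descending response with `(y, x)` lexicographic tie-breaking.
#'
#' @param keypoints data frame with `x`, `y` columns (0-based).
#' @param pixels intensity matrix the keypoints were detected on.
#' @param max_keep keypoint budget.
#' @param half_win half-width of the Harris window (default 3, i.e. 7 x 7).
#' @param k Harris trace coefficient (default 0.04).
#' @return The retained keypoints with a `response` column added.
#' @export
harris_rank <- function(keypoints, pixels, max_keep = 500, half_win = 3, k = 0.04) {
  if (nrow(keypoints) == 0) {
    return(cbind(keypoints, data.frame(response = numeric(0))))
  }
  resp <- cpp_harris(pixels, as.matrix(keypoints[, c("x", "y")]),
                     as.integer(half_win), k)
  keypoints$response <- resp
  ord <- order(-keypoints$response, keypoints$y, keypoints$x)
  keypoints <- keypoints[ord, , drop = FALSE]
  head_n <- min(max_keep, nrow(keypoints))
  out <- keypoints[seq_len(head_n), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Intensity-centroid keypoint orientation
#'
#' Orientation is `atan2(m01, m10)` where `m_pq = sum x^p y^q I(x, y)` over
#' a circular patch centred at the keypoint (coordinates patch-centred,
#' replicate padding at image borders). A patch with both moments zero gets
#' orientation 0.
#'
#' @param keypoints data frame with `x`, `y` columns.
#' @param pixels intensity matrix.
#' @param radius patch radius in pixels (default 15).
#' @return Numeric vector of orientations in `(-pi, pi]`, radians, positive
#'   from +x towards +y (clockwise on screen with y down).
#' @export
compute_orientation <- function(keypoints, pixels, radius = 15) {
  if (nrow(keypoints) == 0) return(numeric(0))
  cpp_orientation(pixels, as.matrix(keypoints[, c("x", "y")]),
                  as.integer(radius))
}

# ---- description -----------------------------------------------------------

#' Rotation-steered binary descriptors
#'
#' For each keypoint the frozen sampling pattern is rotated by the keypoint
#' orientation; bit i is 1 iff the (smoothed) intensity at the first point
#' of pair i is strictly less than at the second. Steering the pattern is
#' what makes the plain pairwise-comparison descriptor rotation invariant.
#'
#' @param keypoints data frame with `x`, `y`, `orientation` columns.
#' @param pixels intensity matrix; it is blurred with a small Gaussian
#'   (`sigma = 2`) before sampling to stabilise the comparisons.
#' @param pattern sampling pattern from [sampling_pattern].
#' @return Integer matrix `n x 32`: 256 bits packed as bytes, bit i in byte
#'   `i %/% 8` at position `i %% 8`.
#' @export
describe_keypoints <- function(keypoints, pixels, pattern = sampling_pattern()) {
  if (nrow(keypoints) == 0) {
    return(matrix(integer(0), nrow = 0, ncol = nrow(pattern) %/% 8))
  }
  smoothed <- cpp_gaussian_blur(pixels, sigma = 2)
  kp <- cbind(keypoints$x, keypoints$y, keypoints$orientation)
  cpp_describe(smoothed, kp, pattern)
}

#' Hamming distance between two binary descriptors
#'
#' @param d1,d2 byte vectors of equal length (rows of a descriptor matrix).
#' @return Integer count of differing bits.
#' @export
hamming <- function(d1, d2) {
  if (length(d1) != length(d2)) {
    stop("descriptors must have equal length", call. = FALSE)
  }
  cpp_hamming(as.integer(d1), as.integer(d2))
}

#' Brute-force nearest-neighbour descriptor matching
#'
#' Every descriptor in `descs_a` is paired with its Hamming-nearest
#' neighbour in `descs_b` (ties resolved towards the lowest B index). No
#' ratio test and no distance cutoff are applied: the grid-based motion
#' statistics stage downstream is designed to consume abundant raw
#' nearest-neighbour matches and do the filtering.
#'
#' @param descs_a,descs_b descriptor byte matrices from
#'   [describe_keypoints].
#' @return Data frame with columns `ia`, `ib` (1-based indices into A and B)
#'   and `distance`, sorted by `ia`.
#' @export
match_bruteforce <- function(descs_a, descs_b) {
  if (nrow(descs_a) == 0 || nrow(descs_b) == 0) {
    warning("empty descriptor list; no matches")
    return(data.frame(ia = integer(0), ib = integer(0), distance = integer(0)))
  }
  as.data.frame(cpp_match_hamming(descs_a, descs_b))
}

# ---- full per-film feature extraction --------------------------------------

#' Detect and describe keypoints inside one ROI of one film
#'
#' Runs the full per-film feature pipeline: pyramid construction over the
#' cropped ROI, FAST detection per level, Harris ranking to the keypoint
#' budget, orientation assignment and steered binary description. Keypoint
#' positions are integer pixel centres at their detection level, mapped to
#' full-resolution coordinates by the level scale plus the ROI offset.
#'
#' @param image a [radiograph].
#' @param roi an `roi`.
#' @param config a [pipeline_config] list.
#' @return List with `keypoints` (data frame `x`, `y` in full-image
#'   coordinates, `response`, `orientation`, `level`, `scale`) and
#'   `descriptors` (byte matrix, one row per keypoint).
#' @export
detect_and_describe <- function(image, roi, config = pipeline_config()) {
  cropped <- crop(image, roi)
  px <- cropped$pixels
  n_levels <- max_pyramid_levels(px, config$scale_factor, config$n_levels)
  pyr <- build_pyramid(px, n_levels = n_levels, scale_factor = config$scale_factor)
  per_level_budget <- keypoint_budget(config$n_keypoints, length(pyr),
                                      config$scale_factor)
  pattern <- sampling_pattern(config$descriptor_bits, config$patch_size,
                              config$pattern_seed)
  kps <- list()
  descs <- list()
  for (k in seq_along(pyr)) {
    lev <- pyr[[k]]
    det <- detect_fast(lev$pixels, threshold = config$fast_threshold)
    det <- harris_rank(det, lev$pixels, max_keep = per_level_budget[k],
                       half_win = config$harris_half_win, k = config$harris_k)
    if (nrow(det) == 0) next
    det$orientation <- compute_orientation(det, lev$pixels,
                                           radius = config$orientation_radius)
    d <- describe_keypoints(det, lev$pixels, pattern)
    det$level <- k - 1L
    det$scale <- lev$scale
    kps[[length(kps) + 1]] <- det
    descs[[length(descs) + 1]] <- d
  }
  if (length(kps) == 0) {
    return(list(
      keypoints = data.frame(x = numeric(0), y = numeric(0),
                             response = numeric(0), orientation = numeric(0),
                             level = integer(0), scale = numeric(0)),
      descriptors = matrix(integer(0), 0, config$descriptor_bits %/% 8)
    ))
  }
  kp <- do.call(rbind, kps)
  # level coordinates -> full-image coordinates
  kp$x <- kp$x * kp$scale + cropped$offset[1]
  kp$y <- kp$y * kp$scale + cropped$offset[2]
  rownames(kp) <- NULL
  list(keypoints = kp, descriptors = do.call(rbind, descs))
}

# Split the keypoint budget across levels proportionally to level area
# (finer levels hold more keypoints), at least 20 per level.
keypoint_budget <- function(n_total, n_levels, scale_factor) {
  areas <- scale_factor^(-2 * (seq_len(n_levels) - 1))
  per <- pmax(20L, as.integer(round(n_total * areas / sum(areas))))
  per
}

#' Pipeline configuration
#'
#' All tunables of the feature, match-filtering and registration stages in
#' one validated list. Unknown keys are rejected.
#'
#' @param n_keypoints keypoint budget per ROI (default 500).
#' @param fast_threshold FAST intensity delta as a fraction of the dynamic
#'   range (default 0.08).
#' @param n_levels pyramid levels (default 8).
#' @param scale_factor pyramid per-level scale (default 1.2).
#' @param patch_size descriptor patch side (default 31).
#' @param descriptor_bits descriptor length (fixed 256).
#' @param pattern_seed seed that froze the sampling pattern.
#' @param orientation_radius intensity-centroid patch radius (default 15).
#' @param harris_half_win half-width of the Harris window (default 3).
#' @param harris_k Harris trace coefficient (default 0.04).
#' @param roi_margin_px ROI margin around the landmark bounding box
#'   (default 10).
#' @param gms_grid_divisions GMS cells per side (default 20).
#' @param gms_alpha GMS threshold multiplier (default 6).
#' @param gms_with_offsets evaluate the four half-cell-shifted grids
#'   (default TRUE).
#' @param gms_with_rotation reserved; rotated-grid variants are not applied
#'   (serial cephalograms are near-upright).
#' @param ransac_trials consensus-sampling iterations (default 500).
#' @param ransac_tol_px inlier distance tolerance in px (default 2).
#' @param ransac_seed deterministic seed for consensus sampling (default 42).
#' @param min_inliers minimum GMS inliers for a valid registration
#'   (default 10).
#' @return A named list of class `pipeline_config`.
#' @export
pipeline_config <- function(n_keypoints = 500,
                            fast_threshold = 0.08,
                            n_levels = 8,
                            scale_factor = 1.2,
                            patch_size = 31,
                            descriptor_bits = 256,
                            pattern_seed = 20240901,
                            orientation_radius = 15,
                            harris_half_win = 3,
                            harris_k = 0.04,
                            roi_margin_px = 10,
                            gms_grid_divisions = 20,
                            gms_alpha = 6,
                            gms_with_offsets = TRUE,
                            gms_with_rotation = FALSE,
                            ransac_trials = 500,
                            ransac_tol_px = 2,
                            ransac_seed = 42,
                            min_inliers = 10) {
  cfg <- as.list(environment())
  if (cfg$descriptor_bits != 256) {
    stop("descriptor length is fixed at 256 bits", call. = FALSE)
  }
  structure(cfg, class = c("pipeline_config", "list"))
}
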