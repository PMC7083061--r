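# Rigid (rotation + translation, no scaling) transfer of the T2 film onto
# the T1 template. Serial cephalograms from the same machine share
# magnification, so the transform relating them is rigid; the angle comes
# from the closed-form 2-D orthogonal Procrustes solution on the filtered
# keypoint correspondences, wrapped in a consensus-sampling loop to shed any
# residual false matches.

#' Construct a rigid transform
#'
#' Maps a point p by `R(theta) p + (tx, ty)`. The rotation sign convention
#' is +x towards +y, i.e. clockwise on screen with y pointing down.
#'
#' @param theta rotation angle in radians, normalized to `(-pi, pi]`.
#' @param tx,ty translation in pixels.
#' @return An object of class `rigid_transform`.
#' @export
rigid_transform <- function(theta = 0, tx = 0, ty = 0) {
  stopifnot(is.finite(theta), is.finite(tx), is.finite(ty))
  theta <- wrap_angle(theta)
  structure(list(theta = theta, tx = tx, ty = ty), class = "rigid_transform")
}

wrap_angle <- function(theta) {
  th <- (theta + pi) %% (2 * pi) - pi
  if (th <= -pi) th <- th + 2 * pi
  th
}

#' @export
print.rigid_transform <- function(x, ...) {
  cat(sprintf("<rigid_transform> theta = %.4f rad (%.3f deg), t = (%.3f, %.3f) px\n",
              x$theta, x$theta * 180 / pi, x$tx, x$ty))
  invisible(x)
}

#' Apply a rigid transform to points
#'
#' @param transform a [rigid_transform].
#' @param points two-column matrix (or data frame) of `(x, y)` coordinates.
#' @return Transformed coordinates, same shape.
#' @export
apply_to_points <- function(transform, points) {
  p <- as.matrix(points)
  c0 <- cos(transform$theta); s0 <- sin(transform$theta)
  out <- cbind(c0 * p[, 1] - s0 * p[, 2] + transform$tx,
               s0 * p[, 1] + c0 * p[, 2] + transform$ty)
  dimnames(out) <- dimnames(p)
  out
}

#' Invert a rigid transform
#'
#' @param transform a [rigid_transform].
#' @return The inverse transform.
#' @export
invert_transform <- function(transform) {
  c0 <- cos(transform$theta); s0 <- sin(transform$theta)
  # inverse: R(-theta) p - R(-theta) t
  rigid_transform(-transform$theta,
                  -(c0 * transform$tx + s0 * transform$ty),
                  -(-s0 * transform$tx + c0 * transform$ty))
}

#' Compose two rigid transforms
#'
#' `compose_transforms(a, b)` applies `b` first, then `a`.
#'
#' @param a,b [rigid_transform] objects.
#' @return The composition `a o b`.
#' @export
compose_transforms <- function(a, b) {
  ca <- cos(a$theta); sa <- sin(a$theta)
  rigid_transform(a$theta + b$theta,
                  ca * b$tx - sa * b$ty + a$tx,
                  sa * b$tx + ca * b$ty + a$ty)
}

#' Least-squares rigid fit between two point sets
#'
#' Finds the rotation and translation minimizing
#' `sum || R p_i + t - q_i ||^2` by centroid-centering and the closed-form
#' 2-D orthogonal Procrustes angle
#' `theta = atan2(sum(x y' - y x'), sum(x x' + y y'))` on the centred
#' coordinates. The rotation is constrained to be proper (no reflection, no
#' scaling).
#'
#' @param points_t2 source points (e.g. T2 keypoints), two-column matrix.
#' @param points_t1 target points (e.g. their T1 partners), same size.
#' @return A [rigid_transform] mapping `points_t2` onto `points_t1`.
#' @export
estimate_rigid <- function(points_t2, points_t1) {
  p <- as.matrix(points_t2); q <- as.matrix(points_t1)
  if (nrow(p) != nrow(q)) stop("point sets must have equal size", call. = FALSE)
  if (nrow(p) < 2) stop("at least 2 point pairs are required", call. = FALSE)
  cp <- colMeans(p); cq <- colMeans(q)
  pc <- sweep(p, 2, cp); qc <- sweep(q, 2, cq)
  if (max(abs(pc)) < 1e-12 && max(abs(qc)) < 1e-12) {
    stop("degenerate geometry: all points coincident", call. = FALSE)
  }
  num <- sum(pc[, 1] * qc[, 2] - pc[, 2] * qc[, 1])
  den <- sum(pc[, 1] * qc[, 1] + pc[, 2] * qc[, 2])
  theta <- atan2(num, den)
  c0 <- cos(theta); s0 <- sin(theta)
  tx <- cq[1] - (c0 * cp[1] - s0 * cp[2])
  ty <- cq[2] - (s0 * cp[1] + c0 * cp[2])
  rigid_transform(theta, tx, ty)
}

#' Robust rigid fit by consensus sampling
#'
#' RANSAC-style wrapper around [estimate_rigid]: repeatedly fits minimal
#' 2-point rigid hypotheses, counts points within `inlier_tol_px` of their
#' partners, and refits on the best consensus set. Deterministic under a
#' fixed seed. With 4 or fewer pairs the plain least-squares fit is
#' returned unchanged.
#'
#' @param points_t2,points_t1 matched point sets (two-column matrices).
#' @param trials number of sampling iterations (default 500).
#' @param inlier_tol_px consensus distance tolerance in pixels (default 2).
#' @param seed RNG seed for the sampling loop (default 42).
#' @return A [rigid_transform] with attributes `n_consensus` (size of the
#'   final inlier set) and `low_consensus` (TRUE when no hypothesis reached
#'   50% support).
#' @export
estimate_rigid_robust <- function(points_t2, points_t1, trials = 500,
                                  inlier_tol_px = 2, seed = 42) {
  p <- as.matrix(points_t2); q <- as.matrix(points_t1)
  n <- nrow(p)
  if (n != nrow(q)) stop("point sets must have equal size", call. = FALSE)
  if (n < 2) stop("at least 2 point pairs are required", call. = FALSE)
  if (n <= 4) {
    fit <- estimate_rigid(p, q)
    attr(fit, "n_consensus") <- n
    attr(fit, "low_consensus") <- FALSE
    return(fit)
  }
  old <- .save_seed()
  set.seed(seed)
  best_inliers <- logical(n)
  best_count <- -1L
  tol2 <- inlier_tol_px^2
  for (trial in seq_len(trials)) {
    id <- sample.int(n, 2)
    if (sum((p[id[1], ] - p[id[2], ])^2) < 1e-12) next  # coincident sample
    hyp <- tryCatch(estimate_rigid(p[id, , drop = FALSE], q[id, , drop = FALSE]),
                    error = function(e) NULL)
    if (is.null(hyp)) next
    res <- apply_to_points(hyp, p) - q
    ok <- res[, 1]^2 + res[, 2]^2 <= tol2
    cnt <- sum(ok)
    if (cnt > best_count) { best_count <- cnt; best_inliers <- ok }
  }
  .restore_seed(old)
  low <- best_count < n / 2
  if (low) {
    warning("low consensus: no hypothesis reached 50% support")
  }
  if (best_count >= 2) {
    fit <- estimate_rigid(p[best_inliers, , drop = FALSE],
                          q[best_inliers, , drop = FALSE])
  } else {
    fit <- estimate_rigid(p, q)
    best_count <- n
  }
  attr(fit, "n_consensus") <- as.integer(best_count)
  attr(fit, "low_consensus") <- low
  fit
}

#' Warp a radiograph by a rigid transform
#'
#' Inverse-mapped bilinear resampling onto a canvas of `output_size`: output
#' pixel q takes the source intensity at `R(-theta) (q - t)`. Pixels mapping
#' outside the source are filled with 0. The calibration of the output is
#' taken from `calibration_from` (the T1 frame) when given.
#'
#' @param image a [radiograph] (the T2 film).
#' @param transform a [rigid_transform] mapping source into output frame.
#' @param output_size `(width, height)` of the canvas; defaults to the input
#'   size.
#' @param calibration_from optional [radiograph] supplying `mm_per_px`.
#' @return A [radiograph] on the output canvas.
#' @export
warp_image <- function(image, transform, output_size = NULL,
                       calibration_from = NULL) {
  stopifnot(inherits(image, "radiograph"), inherits(transform, "rigid_transform"))
  if (is.null(output_size)) output_size <- c(image$width, image$height)
  px <- cpp_warp_rigid(image$pixels, transform$theta, transform$tx,
                       transform$ty, output_size[2], output_size[1], 0)
  mmpp <- if (is.null(calibration_from)) image$mm_per_px else calibration_from$mm_per_px
  radiograph(pmin(pmax(px, 0), 1), mm_per_px = mmpp)
}

#' Automated structural superimposition of a film pair
#'
#' Runs the full pipeline for one region: ROI construction on both films,
#' keypoint detection and steered binary description per film, brute-force
#' Hamming matching (T2 queries against T1), grid-based motion statistics
#' filtering, and a robust least-squares rigid fit on the surviving
#' correspondences. The returned transform maps T2 coordinates into the T1
#' frame.
#'
#' @param t1,t2 [radiograph] objects (pre- and post-treatment films).
#' @param lm1,lm2 [landmark_set] objects for the two films.
#' @param region `"cranial_base"`, `"maxilla"` or `"mandible"`.
#' @param config a [pipeline_config].
#' @return An object of class `superimposition` with elements `transform`
#'   (T2 -> T1 [rigid_transform]), `n_raw_matches`, `n_inlier_matches`,
#'   `rms_residual_px`, `region`, plus the per-film keypoints and the match
#'   table with its inlier mask.
#' @export
superimpose <- function(t1, t2, lm1, lm2, region, config = pipeline_config()) {
  region <- match.arg(region, names(REGION_LANDMARKS))
  roi1 <- roi_from_landmarks(lm1, region, t1, margin_px = config$roi_margin_px)
  roi2 <- roi_from_landmarks(lm2, region, t2, margin_px = config$roi_margin_px)
  feat1 <- detect_and_describe(t1, roi1, config)
  feat2 <- detect_and_describe(t2, roi2, config)
  if (nrow(feat1$keypoints) == 0 || nrow(feat2$keypoints) == 0) {
    stop(errorCondition(
      sprintf("registration failure in region '%s': no keypoints detected",
              region), class = "ceph_registration_error"))
  }
  matches <- match_bruteforce(feat2$descriptors, feat1$descriptors)
  gcfg <- gms_config(config$gms_grid_divisions, config$gms_alpha,
                     config$gms_with_offsets, config$gms_with_rotation)
  # GMS statistics evaluated on the ROI windows the keypoints came from
  kp2_local <- data.frame(x = feat2$keypoints$x - roi2$x_min,
                          y = feat2$keypoints$y - roi2$y_min)
  kp1_local <- data.frame(x = feat1$keypoints$x - roi1$x_min,
                          y = feat1$keypoints$y - roi1$y_min)
  mask <- gms_filter(matches, kp2_local, kp1_local,
                     c(roi2$x_max - roi2$x_min, roi2$y_max - roi2$y_min),
                     c(roi1$x_max - roi1$x_min, roi1$y_max - roi1$y_min),
                     gcfg)
  n_inlier <- sum(mask)
  if (n_inlier < config$min_inliers) {
    stop(errorCondition(sprintf(
      "registration failure in region '%s': only %d inlier matches (need %d)",
      region, n_inlier, config$min_inliers),
      class = "ceph_registration_error"))
  }
  p2 <- as.matrix(feat2$keypoints[matches$ia[mask], c("x", "y")])
  p1 <- as.matrix(feat1$keypoints[matches$ib[mask], c("x", "y")])
  fit <- estimate_rigid_robust(p2, p1, trials = config$ransac_trials,
                               inlier_tol_px = config$ransac_tol_px,
                               seed = config$ransac_seed)
  res <- apply_to_points(fit, p2) - p1
  rms <- sqrt(mean(res[, 1]^2 + res[, 2]^2))
  matches$inlier <- mask
  structure(
    list(transform = fit,
         n_raw_matches = nrow(matches),
         n_inlier_matches = n_inlier,
         rms_residual_px = rms,
         region = region,
         keypoints_t1 = feat1$keypoints,
         keypoints_t2 = feat2$keypoints,
         matches = matches),
    class = "superimposition"
  )
}

#' @export
print.superimposition <- function(x, ...) {
  cat(sprintf(
    "<superimposition> region %s: theta = %.3f deg, t = (%.2f, %.2f) px\n  %d raw matches -> %d inliers, rms residual %.2f px\n",
    x$region, x$transform$theta * 180 / pi, x$transform$tx, x$transform$ty,
    x$n_raw_matches, x$n_inlier_matches, x$rms_residual_px))
  invisible(x)
}

#' Per-pair median rigid estimator
#'
#' Alternative estimator that derives an angle from every pair of match
#' pairs (the rotation aligning the segment p_i p_j with q_i q_j) and takes
#' the circular median, then the median translation at that angle. Provided
#' for comparison with the default joint least-squares fit; on small clean
#' sets both agree closely.
#'
#' @param points_t2,points_t1 matched point sets.
#' @param max_pairs cap on the number of pair-of-pairs samples (default
#'   2000, taken deterministically from the lowest indices).
#' @return A [rigid_transform].
#' @export
estimate_rigid_perpair <- function(points_t2, points_t1, max_pairs = 2000) {
  p <- as.matrix(points_t2); q <- as.matrix(points_t1)
  n <- nrow(p)
  if (n < 2) stop("at least 2 point pairs are required", call. = FALSE)
  combs <- utils::combn(n, 2)
  if (ncol(combs) > max_pairs) combs <- combs[, seq_len(max_pairs), drop = FALSE]
  vp <- p[combs[2, ], ] - p[combs[1, ], ]
  vq <- q[combs[2, ], ] - q[combs[1, ], ]
  keep <- rowSums(vp^2) > 1e-12 & rowSums(vq^2) > 1e-12
  ang <- atan2(vq[keep, 2], vq[keep, 1]) - atan2(vp[keep, 2], vp[keep, 1])
  # circular median via the angle minimizing summed absolute circular deviation
  ang <- vapply(ang, wrap_angle, numeric(1))
  dev <- vapply(ang, function(a) {
    sum(abs(vapply(ang - a, wrap_angle, numeric(1))))
  }, numeric(1))
  theta <- ang[which.min(dev)]
  c0 <- cos(theta); s0 <- sin(theta)
  tx <- stats::median(q[, 1] - (c0 * p[, 1] - s0 * p[, 2]))
  ty <- stats::median(q[, 2] - (s0 * p[, 1] + c0 * p[, 2]))
  rigid_transform(theta, tx, ty)
}
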