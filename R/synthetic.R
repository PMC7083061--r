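# Seed-deterministic synthetic cephalogram pairs. The phantom emulates the
# features the matching pipeline relies on in real films — a smooth
# low-frequency background, high-contrast curvilinear "bony edge" strokes,
# and fine two-scale speckle standing in for trabecular texture — with 21
# named landmarks placed in anatomically ordered positions so all three
# stable-structure ROIs are valid. It does not model radiographic physics;
# its purpose is transform-recovery validation with known ground truth.

# Nominal landmark positions on the default 800 x 640 canvas (x right,
# y down, patient facing right), perturbed per seed. Chosen so that the
# three ROI rectangles are non-degenerate and everything stays in frame
# under the perturbations used in validation (|theta| <= 5 deg, |t| <= 20 px).
PHANTOM_NOMINAL <- matrix(c(
  430, 120,   # URP
  430, 430,   # LRP
  330, 200,   # S
  560, 185,   # N
  420, 280,   # Pt
  400, 330,   # PNS
  600, 330,   # ANS
  600, 360,   # A
  585, 495,   # B
  585, 540,   # Pg
  545, 570,   # Me
  350, 495,   # Go
  330, 290,   # Co
  640, 430,   # UIE
  610, 370,   # UIA
  500, 390,   # UM
  500, 350,   # UMA
  625, 445,   # LIE
  600, 505,   # LIA
  490, 440,   # LM
  490, 490    # LMA
), ncol = 2, byrow = TRUE,
  dimnames = list(c("URP", "LRP", "S", "N", "Pt", "PNS", "ANS", "A", "B",
                    "Pg", "Me", "Go", "Co", "UIE", "UIA", "UM", "UMA",
                    "LIE", "LIA", "LM", "LMA"), c("x", "y")))

# Independent substreams from one spec seed (kept below 2^31).
substream_seed <- function(seed, id) {
  as.integer((as.numeric(seed) * 1009 + id) %% 2147483647)
}

#' Specification of a synthetic cephalogram pair
#'
#' @param seed integer master seed; every random choice flows from it
#'   through named substreams (texture, landmarks, jitter, corruption).
#' @param size `(width, height)` in pixels.
#' @param theta_true applied rotation in radians (about the image centre).
#' @param t_true applied translation `(tx, ty)` in pixels.
#' @param noise_sigma additive Gaussian intensity noise SD on the T2 film.
#' @param gamma illumination exponent applied to the T2 film.
#' @param outside_roi_corruption replace all T2 pixels outside the three
#'   ROIs with unrelated texture.
#' @param n_operators number of simulated tracing operators.
#' @param operator_jitter_mm per-coordinate isotropic Gaussian jitter SD in
#'   mm for simulated operators (0.5 mm default, the order of reported
#'   inter-operator tracing variability).
#' @param mm_per_px pixel calibration (default: 600-dpi scan).
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(seed = 1, size = c(800, 640), theta_true = 0,
                           t_true = c(0, 0), noise_sigma = 0.01, gamma = 1.1,
                           outside_roi_corruption = FALSE, n_operators = 3,
                           operator_jitter_mm = 0.5,
                           mm_per_px = DEFAULT_MM_PER_PX) {
  stopifnot(length(size) == 2, size[1] >= 64, size[2] >= 64,
            is.finite(theta_true), all(is.finite(t_true)),
            noise_sigma >= 0, gamma > 0, n_operators >= 1,
            operator_jitter_mm >= 0, mm_per_px > 0)
  structure(as.list(environment()), class = c("synthetic_spec", "list"))
}

#' Landmark geometry of a phantom
#'
#' Nominal anatomically ordered positions (scaled to the canvas) with a
#' seeded uniform perturbation of up to 8 px per coordinate.
#'
#' @param seed integer seed.
#' @param size `(width, height)` canvas in pixels.
#' @return A [landmark_set].
#' @export
phantom_landmarks <- function(seed = 1, size = c(800, 640)) {
  old <- .save_seed()
  set.seed(substream_seed(seed, 1))
  jitter <- matrix(runif(nrow(PHANTOM_NOMINAL) * 2, -8, 8), ncol = 2)
  .restore_seed(old)
  pts <- PHANTOM_NOMINAL
  pts[, 1] <- pts[, 1] * size[1] / 800 + jitter[, 1]
  pts[, 2] <- pts[, 2] * size[2] / 640 + jitter[, 2]
  landmark_set(pts)
}

#' Generate a synthetic cephalogram phantom
#'
#' @param spec a [synthetic_spec].
#' @return List with `image` (a [radiograph]) and `landmarks` (a
#'   [landmark_set]).
#' @export
make_phantom <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  w <- spec$size[1]; h <- spec$size[2]
  lm <- phantom_landmarks(spec$seed, spec$size)

  old <- .save_seed()
  set.seed(substream_seed(spec$seed, 2))

  # (i) smooth low-frequency background: coarse noise upsampled
  coarse <- matrix(runif(8 * 10, 0.25, 0.55), nrow = 8, ncol = 10)
  bg <- cpp_resize_bilinear(coarse, h, w)

  # (ii) curvilinear high-contrast "bony edge" strokes through seeded
  # control points, Gaussian cross-section, stamped by maximum
  n_strokes <- sample(6:10, 1)
  pos_layer <- matrix(0, h, w)
  neg_layer <- matrix(0, h, w)
  for (s in seq_len(n_strokes)) {
    n_ctrl <- sample(3:5, 1)
    cx <- runif(1, 0.15 * w, 0.85 * w) + cumsum(runif(n_ctrl, -0.22 * w, 0.22 * w))
    cy <- runif(1, 0.15 * h, 0.85 * h) + cumsum(runif(n_ctrl, -0.22 * h, 0.22 * h))
    cx <- pmin(pmax(cx, 3), w - 4); cy <- pmin(pmax(cy, 3), h - 4)
    tt <- seq_len(n_ctrl)
    dense <- seq(1, n_ctrl, length.out = 250)
    sx <- pmin(pmax(spline(tt, cx, xout = dense)$y, 1), w)
    sy <- pmin(pmax(spline(tt, cy, xout = dense)$y, 1), h)
    amp <- runif(1, 0.25, 0.4)
    sgn <- sample(c(1, -1), 1)
    layer <- stamp_stroke(if (sgn > 0) pos_layer else neg_layer, sx, sy,
                          amp = amp, sigma = 1.5)
    if (sgn > 0) pos_layer <- layer else neg_layer <- layer
  }

  # (iii) band-limited speckle at two spatial frequencies
  sp1 <- cpp_gaussian_blur(matrix(runif(h * w, -1, 1), h, w), 0.8)
  sp1 <- sp1 / stats::sd(sp1) * 0.085
  sp2 <- cpp_gaussian_blur(matrix(runif(h * w, -1, 1), h, w), 2.5)
  sp2 <- sp2 / stats::sd(sp2) * 0.05
  .restore_seed(old)

  img <- bg + sp1 + sp2 + pos_layer - neg_layer
  img <- (img - min(img)) / (max(img) - min(img))
  image <- radiograph(img, mm_per_px = spec$mm_per_px)
  # constructive validity: all three ROIs must pass their invariants
  for (reg in names(REGION_LANDMARKS)) {
    roi_from_landmarks(lm, reg, image, margin_px = 10)
  }
  list(image = image, landmarks = landmark_set(lm, image))
}

# Stamp a Gaussian-profile stroke along a dense polyline; overlapping
# samples combine by maximum so the ridge height stays at `amp`.
stamp_stroke <- function(layer, sx, sy, amp, sigma) {
  h <- nrow(layer); w <- ncol(layer)
  r <- ceiling(3 * sigma)
  prof <- outer((-r):r, (-r):r, function(dy, dx) exp(-(dx^2 + dy^2) / (2 * sigma^2)))
  for (i in seq_along(sx)) {
    x0 <- round(sx[i]); y0 <- round(sy[i])
    xs <- max(1, x0 - r):min(w, x0 + r)
    ys <- max(1, y0 - r):min(h, y0 + r)
    sub_x <- xs - (x0 - r) + 1
    sub_y <- ys - (y0 - r) + 1
    layer[ys, xs] <- pmax(layer[ys, xs], amp * prof[sub_y, sub_x, drop = FALSE])
  }
  layer
}

#' Rigid transform about a centre point
#'
#' Express "rotate by theta about `center`, then translate by t" in the
#' origin-referenced `R p + t` form used by [rigid_transform].
#'
#' @param theta rotation angle (radians).
#' @param t translation `(tx, ty)` in pixels.
#' @param center centre of rotation `(cx, cy)`.
#' @return A [rigid_transform].
#' @export
rigid_about_center <- function(theta, t, center) {
  c0 <- cos(theta); s0 <- sin(theta)
  rigid_transform(theta,
                  center[1] + t[1] - (c0 * center[1] - s0 * center[2]),
                  center[2] + t[2] - (s0 * center[1] + c0 * center[2]))
}

#' Generate a synthetic T1/T2 film pair with known ground truth
#'
#' The T1 film is a phantom; the T2 film is the same phantom resampled under
#' the inverse of the ground-truth transform (so that superimposing T2 onto
#' T1 should recover `truth` exactly), then gamma-adjusted and degraded with
#' additive Gaussian noise. Rotation is applied about the image centre.
#' With `outside_roi_corruption` every T2 pixel outside all three
#' stable-structure ROIs is replaced by unrelated texture, which must not
#' change the recovered transform (detection is confined to the ROIs).
#'
#' @param spec a [synthetic_spec].
#' @return List with `t1`, `t2` ([radiograph]), `lm1`, `lm2`
#'   ([landmark_set]) and `truth` (the T2 -> T1 [rigid_transform]).
#' @export
make_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  ph <- make_phantom(spec)
  t1 <- ph$image; lm1 <- ph$landmarks
  center <- c((t1$width - 1) / 2, (t1$height - 1) / 2)
  truth <- rigid_about_center(spec$theta_true, spec$t_true, center)

  inv <- invert_transform(truth)
  t2px <- cpp_warp_rigid(t1$pixels, inv$theta, inv$tx, inv$ty,
                         t1$height, t1$width, 0)
  t2px <- pmin(pmax(t2px, 0), 1)^spec$gamma
  if (spec$noise_sigma > 0) {
    old <- .save_seed()
    set.seed(substream_seed(spec$seed, 3))
    t2px <- t2px + matrix(rnorm(length(t2px), 0, spec$noise_sigma),
                          nrow = nrow(t2px))
    .restore_seed(old)
    t2px <- pmin(pmax(t2px, 0), 1)
  }
  lm2pts <- apply_to_points(inv, lm1)
  t2 <- radiograph(t2px, mm_per_px = spec$mm_per_px)
  lm2 <- landmark_set(lm2pts, t2)

  if (isTRUE(spec$outside_roi_corruption)) {
    t2$pixels <- corrupt_outside_rois(t2, lm2, seed = substream_seed(spec$seed, 4))
  }
  list(t1 = t1, t2 = t2, lm1 = lm1, lm2 = lm2, truth = truth)
}

# Replace everything outside the union of the three ROI rectangles with
# unrelated texture (checkerboard-modulated noise). ROI pixels are
# untouched, exactly.
corrupt_outside_rois <- function(image, landmarks, seed) {
  px <- image$pixels
  h <- nrow(px); w <- ncol(px)
  keep <- matrix(FALSE, h, w)
  for (reg in names(REGION_LANDMARKS)) {
    roi <- roi_from_landmarks(landmarks, reg, image, margin_px = 10)
    keep[(roi$y_min + 1):roi$y_max, (roi$x_min + 1):roi$x_max] <- TRUE
  }
  old <- .save_seed()
  set.seed(seed)
  noise <- matrix(runif(h * w), h, w)
  .restore_seed(old)
  checker <- outer(seq_len(h), seq_len(w),
                   function(i, j) ((i %/% 16) + (j %/% 16)) %% 2)
  corrupted <- 0.5 * checker + 0.5 * noise
  px[!keep] <- corrupted[!keep]
  px
}

#' Simulate operator tracings around a truth landmark set
#'
#' Each simulated operator displaces every landmark by independent
#' per-coordinate Gaussian jitter of SD `jitter_mm` (converted to pixels by
#' the calibration), emulating inter-operator tracing variability.
#'
#' @param truth_landmarks a [landmark_set] or coordinate matrix (the
#'   transferred T2 landmarks in the T1 frame).
#' @param n_operators number of operators (default 3).
#' @param jitter_mm per-coordinate jitter SD in mm.
#' @param seed integer seed.
#' @param region region label for the resulting sets.
#' @param mm_per_px calibration.
#' @return List of [superimposed_landmarks], sources `"op1"`, `"op2"`, ...
#' @export
make_operator_set <- function(truth_landmarks, n_operators = 3, jitter_mm = 0.5,
                              seed = 1, region = "maxilla",
                              mm_per_px = DEFAULT_MM_PER_PX) {
  stopifnot(jitter_mm >= 0, n_operators >= 1)
  pts <- as.matrix(truth_landmarks)
  jitter_px <- jitter_mm / mm_per_px
  old <- .save_seed()
  set.seed(substream_seed(seed, 5))
  ops <- lapply(seq_len(n_operators), function(k) {
    noisy <- pts + matrix(rnorm(length(pts), 0, jitter_px), ncol = 2)
    dimnames(noisy) <- dimnames(pts)
    superimposed_landmarks(noisy, source = sprintf("op%d", k),
                           region = region, mm_per_px = mm_per_px)
  })
  .restore_seed(old)
  ops
}
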