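test_that("pyramid levels follow the geometric schedule", {
  img <- matrix(runif(256 * 256), 256)
  p1 <- build_pyramid(img, n_levels = 1)
  expect_length(p1, 1)
  expect_identical(p1[[1]]$pixels, img)

  p3 <- build_pyramid(img, n_levels = 3, scale_factor = 2)
  expect_equal(vapply(p3, function(l) nrow(l$pixels), numeric(1)),
               c(256, 128, 64))

  big <- matrix(runif(512 * 512), 512)
  p8 <- build_pyramid(big, n_levels = 8, scale_factor = 1.2)
  expect_equal(nrow(p8[[8]]$pixels), floor(512 / 1.2^7))  # = 142
  expect_equal(p8[[8]]$scale, 1.2^7)

  expect_error(build_pyramid(matrix(runif(64 * 64), 64), n_levels = 8,
                             scale_factor = 1.5), "32 x 32")
})

test_that("FAST fires on isolated dots but not along straight edges", {
  expect_equal(nrow(detect_fast(matrix(0.5, 50, 50), 0.1)), 0)

  dot <- matrix(0, 40, 40); dot[20, 20] <- 1
  d <- detect_fast(dot, 0.1)
  expect_equal(nrow(d), 1)
  expect_true(abs(d$x - 19) <= 1 && abs(d$y - 19) <= 1)

  # dark dot detected symmetrically
  ddark <- detect_fast(1 - dot, 0.1)
  expect_equal(nrow(ddark), 1)

  # vertical step edge: the brighter arc spans at most 8 contiguous circle
  # positions in the interior, so the 9-of-16 segment test cannot fire
  step <- cbind(matrix(0, 40, 20), matrix(1, 40, 20))
  ds <- detect_fast(step, 0.1)
  interior <- ds[ds$y >= 5 & ds$y <= 34, ]
  expect_equal(nrow(interior), 0)
})

test_that("Harris ranking keeps the strongest corners deterministically", {
  img <- matrix(0.5, 60, 60)
  # strong corner: bright block; weak corner: faint block
  img[10:15, 10:15] <- 1
  img[40:45, 40:45] <- 0.62
  kp <- detect_fast(img, 0.05)
  expect_gte(nrow(kp), 2)
  ranked <- harris_rank(kp, img, max_keep = nrow(kp))
  expect_equal(nrow(ranked), nrow(kp))
  # the highest-contrast structure ranks first
  expect_true(ranked$x[1] < 20 && ranked$y[1] < 20)
  expect_true(all(diff(ranked$response) <= 0))
  top1 <- harris_rank(kp, img, max_keep = 1)
  expect_equal(nrow(top1), 1)
  empty <- harris_rank(kp[0, ], img, max_keep = 10)
  expect_equal(nrow(empty), 0)
})

test_that("intensity-centroid orientation follows the gradient direction", {
  n <- 61
  rampx <- matrix(seq(0, 1, length.out = n)[col(matrix(0, n, n))], n)
  kp <- data.frame(x = 30, y = 30)
  expect_equal(compute_orientation(kp, rampx), 0, tolerance = 1e-10)
  # rotating the ramp by 90 deg shifts the orientation by pi/2
  expect_equal(compute_orientation(kp, t(rampx)), pi / 2, tolerance = 0.05)
  # reversed ramp points along -x
  expect_equal(abs(compute_orientation(kp, rampx[, n:1])), pi, tolerance = 0.05)
  # uniform patch: both moments zero -> orientation 0 by convention
  expect_equal(compute_orientation(kp, matrix(0.7, n, n)), 0)
})

test_that("descriptors are deterministic, 256-bit, and rotation tolerant", {
  pat <- sampling_pattern()
  expect_equal(dim(pat), c(256, 4))
  expect_true(all(abs(pat) <= 15))
  expect_identical(pat, sampling_pattern())  # frozen

  ph <- fixture_phantom()
  roi <- fixture_roi()
  cr <- crop(ph$image, roi)
  kp <- detect_fast(cr$pixels, 0.08)
  kp <- harris_rank(kp, cr$pixels, max_keep = 20)
  kp$orientation <- compute_orientation(kp, cr$pixels)
  d1 <- describe_keypoints(kp, cr$pixels)
  d2 <- describe_keypoints(kp, cr$pixels)
  expect_identical(d1, d2)
  expect_equal(ncol(d1), 32)

  # constant patch: every strict "<" comparison is false -> all-zero bits
  flat_kp <- data.frame(x = 30, y = 30, orientation = 0.3)
  expect_true(all(describe_keypoints(flat_kp, matrix(0.4, 61, 61)) == 0))

  # a corresponding keypoint on a 30-deg rotated copy differs by <= 64 bits
  ctr <- c((ph$image$width - 1) / 2, (ph$image$height - 1) / 2)
  rot <- rigid_about_center(30 * pi / 180, c(0, 0), ctr)
  J <- warp_image(ph$image, rot)
  kp_full <- kp
  kp_full$x <- kp$x + cr$offset[1]; kp_full$y <- kp$y + cr$offset[2]
  moved <- apply_to_points(rot, as.matrix(kp_full[, c("x", "y")]))
  kpJ <- data.frame(x = moved[, 1], y = moved[, 2])
  kpJ$orientation <- compute_orientation(kpJ, J$pixels)
  dJ <- describe_keypoints(kpJ, J$pixels)
  dI <- describe_keypoints(kp_full, ph$image$pixels)
  dists <- vapply(seq_len(nrow(dI)), function(i) hamming(dI[i, ], dJ[i, ]),
                  numeric(1))
  expect_lte(median(dists), 64)
})

test_that("hamming distance is a metric and matches hand arithmetic", {
  d <- random_descriptors(30, seed = 5)
  expect_equal(hamming(d[1, ], d[1, ]), 0)
  expect_equal(hamming(d[1, ], as.integer(bitwXor(d[1, ], 255L))), 256)
  # toy 8-bit case: 10110010 vs 00110110 differ in 2 bits
  expect_equal(hamming(strtoi("10110010", 2), strtoi("00110110", 2)), 2)
  expect_error(hamming(d[1, ], d[1, 1:16]), "equal length")
  # metric properties on random descriptors
  for (i in 1:25) {
    a <- d[sample(30, 1), ]; b <- d[sample(30, 1), ]; c <- d[sample(30, 1), ]
    expect_equal(hamming(a, b), hamming(b, a))
    expect_true(hamming(a, c) <= hamming(a, b) + hamming(b, c))
    if (hamming(a, b) == 0) expect_identical(a, b)
  }
})

test_that("brute-force matching equals the all-pairs argmin oracle", {
  da <- random_descriptors(50, seed = 21)
  db <- random_descriptors(50, seed = 22)
  m <- match_bruteforce(da, db)
  expect_equal(m$ia, 1:50)
  dm <- oracle_distance_matrix(da, db)
  expect_equal(m$ib, apply(dm, 1, which.min))
  expect_equal(m$distance, apply(dm, 1, min))

  # self-match on distinct descriptors
  ms <- match_bruteforce(da, da)
  expect_equal(ms$ib, 1:50)
  expect_true(all(ms$distance == 0))

  # tie rule: duplicate best candidates resolve to the lowest B index
  db_tie <- rbind(db[1, , drop = FALSE], da[1, , drop = FALSE],
                  db[2, , drop = FALSE], da[1, , drop = FALSE])
  mt <- match_bruteforce(da[1, , drop = FALSE], db_tie)
  expect_equal(mt$ib, 2)

  expect_warning(m0 <- match_bruteforce(da[0, , drop = FALSE], db), "empty")
  expect_equal(nrow(m0), 0)
})

test_that("detected keypoint sets are rotation covariant through the pipeline", {
  ph <- fixture_phantom()
  roi <- fixture_roi()
  cfg <- pipeline_config()
  ctr <- c((ph$image$width - 1) / 2, (ph$image$height - 1) / 2)
  fA <- detect_and_describe(ph$image, roi, cfg)
  expect_gte(nrow(fA$keypoints), 200)
  size <- c(roi$x_max - roi$x_min, roi$y_max - roi$y_min)
  for (r in c(5, 10, 15)) {
    rot <- rigid_about_center(r * pi / 180, c(0, 0), ctr)
    J <- warp_image(ph$image, rot)
    fB <- detect_and_describe(J, roi, cfg)
    m <- match_bruteforce(fA$descriptors, fB$descriptors)
    mask <- gms_filter(m, fA$keypoints, fB$keypoints, size, size)
    expect_gte(sum(mask), 50)
    pA <- as.matrix(fA$keypoints[m$ia[mask], c("x", "y")])
    pB <- as.matrix(fB$keypoints[m$ib[mask], c("x", "y")])
    res <- apply_to_points(rot, pA) - pB
    d <- sqrt(res[, 1]^2 + res[, 2]^2)
    # typical correspondence error under the known rotation; individual
    # matches at coarse pyramid levels carry integer-centre quantization
    expect_lt(median(d), 1.5)
  }
})
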