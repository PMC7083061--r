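test_that("transform algebra: apply, invert, compose, quarter turn", {
  id <- rigid_transform()
  p <- matrix(c(3, 4, -1, 2), ncol = 2, byrow = TRUE)
  expect_equal(apply_to_points(id, p), p)
  # quarter turn under the +x -> +y sign convention
  q <- apply_to_points(rigid_transform(pi / 2), rbind(c(1, 0)))
  expect_equal(unname(q), rbind(c(0, 1)), tolerance = 1e-12)
  set.seed(3)
  for (i in 1:20) {
    tr <- rigid_transform(runif(1, -pi, pi), runif(1, -50, 50), runif(1, -50, 50))
    pts <- matrix(runif(20, -100, 100), ncol = 2)
    back <- apply_to_points(invert_transform(tr), apply_to_points(tr, pts))
    expect_equal(back, pts, tolerance = 1e-12)
    expect_equal(compose_transforms(invert_transform(tr), tr)$theta, 0,
                 tolerance = 1e-12)
    # rigid maps preserve pairwise distances
    d0 <- dist(pts); d1 <- dist(apply_to_points(tr, pts))
    expect_lt(max(abs(d0 - d1)), 1e-9)
  }
})

test_that("estimate_rigid recovers generating transforms exactly", {
  p0 <- matrix(c(0, 0, 10, 0, 0, 10, 7, 3), ncol = 2, byrow = TRUE)
  fit_id <- estimate_rigid(p0, p0)
  expect_equal(fit_id$theta, 0)
  expect_equal(c(fit_id$tx, fit_id$ty), c(0, 0))

  # translation by (5, -3) means q = p + (5, -3)
  fit_t <- estimate_rigid(p0, sweep(p0, 2, c(5, -3), `+`))
  expect_equal(fit_t$theta, 0)
  expect_equal(c(fit_t$tx, fit_t$ty), c(5, -3))

  set.seed(8)
  for (i in 1:10) {
    p <- matrix(runif(10, 0, 200), ncol = 2)
    tr <- rigid_about_center(runif(1, -0.6, 0.6), runif(2, -20, 20),
                             c(100, 100))
    q <- apply_to_points(tr, p)
    fit <- estimate_rigid(p, q)
    expect_equal(fit$theta, tr$theta, tolerance = 1e-9)
    expect_equal(c(fit$tx, fit$ty), c(tr$tx, tr$ty), tolerance = 1e-9)
  }
  expect_error(estimate_rigid(p0[1, , drop = FALSE], p0[1, , drop = FALSE]),
               "at least 2")
  same <- matrix(5, 4, 2)
  expect_error(estimate_rigid(same, same + 1), "coincident")
})

test_that("estimate_rigid is equivariant under pre-composition", {
  set.seed(12)
  p <- matrix(runif(16, 0, 300), ncol = 2)
  tr <- rigid_transform(0.3, 12, -7)
  q <- apply_to_points(tr, p)
  pre <- rigid_transform(-0.2, 5, 9)
  # fitting from pre^-1(p) must give tr o pre
  fit <- estimate_rigid(apply_to_points(invert_transform(pre), p), q)
  want <- compose_transforms(tr, pre)
  expect_equal(fit$theta, want$theta, tolerance = 1e-9)
  expect_equal(c(fit$tx, fit$ty), c(want$tx, want$ty), tolerance = 1e-9)
})

test_that("consensus sampling shrugs off injected outliers", {
  set.seed(31)
  tr <- rigid_about_center(0.2, c(9, -6), c(150, 150))
  p <- matrix(runif(160, 0, 300), ncol = 2)
  q <- apply_to_points(tr, p)
  # clean data: robust equals plain least squares
  fit_clean <- estimate_rigid_robust(p, q, seed = 4)
  fit_plain <- estimate_rigid(p, q)
  expect_equal(fit_clean$theta, fit_plain$theta, tolerance = 1e-9)

  # 80 clean + 20 arbitrary pairs
  p_out <- rbind(p, matrix(runif(40, 0, 300), ncol = 2))
  q_out <- rbind(q, matrix(runif(40, 0, 300), ncol = 2))
  fit <- estimate_rigid_robust(p_out, q_out, inlier_tol_px = 2, seed = 4)
  expect_lt(abs(fit$theta - tr$theta) * 180 / pi, 0.1)
  expect_lt(max(abs(c(fit$tx - tr$tx, fit$ty - tr$ty))), 0.5)
  expect_false(attr(fit, "low_consensus"))

  # <= 4 pairs falls back to the plain fit
  fit3 <- estimate_rigid_robust(p[1:3, ], q[1:3, ], seed = 4)
  plain3 <- estimate_rigid(p[1:3, ], q[1:3, ])
  expect_equal(fit3$theta, plain3$theta)
  expect_equal(attr(fit3, "n_consensus"), 3L)

  # determinism under a fixed seed
  f1 <- estimate_rigid_robust(p_out, q_out, seed = 99)
  f2 <- estimate_rigid_robust(p_out, q_out, seed = 99)
  expect_identical(unclass(f1), unclass(f2))
})

test_that("per-pair median estimator agrees on clean data", {
  set.seed(41)
  tr <- rigid_about_center(0.05, c(4, 2), c(100, 100))
  p <- matrix(runif(30, 0, 200), ncol = 2)
  q <- apply_to_points(tr, p)
  fit <- estimate_rigid_perpair(p, q)
  expect_equal(fit$theta, tr$theta, tolerance = 1e-6)
  expect_equal(c(fit$tx, fit$ty), c(tr$tx, tr$ty), tolerance = 1e-6)
})

test_that("warp_image: identity, integer shift, and 90-degree rotation", {
  set.seed(15)
  px <- matrix(runif(41 * 41), 41)
  img <- radiograph(px)
  # identity
  out <- warp_image(img, rigid_transform())
  expect_lt(max(abs(out$pixels - px)), 1e-12)
  # integer shift is exact where defined
  sh <- warp_image(img, rigid_transform(0, 10, 0))
  expect_equal(sh$pixels[, 11:41], px[, 1:31], tolerance = 1e-12)
  expect_true(all(sh$pixels[, 1:10] == 0))
  # 90-degree rotation about the canvas centre equals the directly
  # constructed rotated card
  ctr <- c(20, 20)
  rot <- warp_image(img, rigid_about_center(pi / 2, c(0, 0), ctr))
  want <- matrix(0, 41, 41)
  for (y in 0:40) for (x in 0:40) {
    nx <- ctr[1] - (y - ctr[2]); ny <- ctr[2] + (x - ctr[1])
    want[ny + 1, nx + 1] <- px[y + 1, x + 1]
  }
  expect_lt(max(abs(rot$pixels - want)), 0.01)
})

test_that("self-registration of an identical film recovers the identity", {
  ph <- fixture_phantom()
  res <- superimpose(ph$image, ph$image, ph$landmarks, ph$landmarks, "maxilla")
  expect_lt(abs(res$transform$theta) * 180 / pi, 0.05)
  expect_lt(max(abs(c(res$transform$tx, res$transform$ty))), 0.5)
  expect_lt(res$rms_residual_px, 1)
  expect_lte(res$n_inlier_matches, res$n_raw_matches)
})

test_that("round trip: A onto B and B onto A are mutually inverse", {
  spec <- synthetic_spec(seed = 5, theta_true = 2 * pi / 180, t_true = c(6, -9))
  pair <- make_pair(spec)
  ab <- superimpose(pair$t1, pair$t2, pair$lm1, pair$lm2, "cranial_base")
  ba <- superimpose(pair$t2, pair$t1, pair$lm2, pair$lm1, "cranial_base")
  comp <- compose_transforms(ab$transform, ba$transform)
  expect_lt(abs(comp$theta) * 180 / pi, 0.1)
  ctr <- rbind(c(400, 320))
  expect_lt(sqrt(sum((apply_to_points(comp, ctr) - ctr)^2)), 0.5)
})
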