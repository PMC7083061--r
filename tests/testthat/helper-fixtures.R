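# Shared fixtures, computed once per test run. All synthetic, all seeded.

# A default-size phantom used by feature-level tests.
fixture_phantom <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_phantom(synthetic_spec(seed = 7))
    cache
  }
})

# A rectangular ROI covering a texture-rich window of the phantom,
# constructed directly (no landmarks needed).
fixture_roi <- function(x_min = 150L, y_min = 100L, x_max = 650L, y_max = 540L) {
  structure(list(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
                 region = "maxilla"),
            class = "roi")
}

# Random packed descriptors (n x 32 bytes) for matcher/metric tests.
random_descriptors <- function(n, seed) {
  set.seed(seed)
  matrix(sample(0:255, n * 32, replace = TRUE), nrow = n, ncol = 32)
}

# Expand packed descriptor bytes to a 0/1 bit matrix (independent of the
# package's popcount path).
unpack_bits <- function(descs) {
  t(apply(descs, 1, function(row) {
    as.integer(unlist(lapply(row, function(b) bitwAnd(bitwShiftR(b, 0:7), 1L))))
  }))
}

# Independent all-pairs Hamming distance matrix via bit expansion.
oracle_distance_matrix <- function(da, db) {
  ba <- unpack_bits(da); bb <- unpack_bits(db)
  n <- nrow(ba); m <- nrow(bb)
  out <- matrix(0L, n, m)
  for (j in seq_len(m)) {
    out[, j] <- as.integer(rowSums(ba != matrix(bb[j, ], n, ncol(bb), byrow = TRUE)))
  }
  out
}

# Independent GMS oracle: explicit 9-cell loops per match, no shared
# bookkeeping with the implementation.
oracle_gms <- function(matches, kps_a, kps_b, size_a, size_b, g, alpha,
                       offsets = 0:3) {
  n <- nrow(matches)
  xa <- kps_a$x[matches$ia]; ya <- kps_a$y[matches$ia]
  xb <- kps_b$x[matches$ib]; yb <- kps_b$y[matches$ib]
  accept_any <- rep(FALSE, n)
  for (off in offsets) {
    ca <- assign_cells(xa, ya, size_a[1], size_a[2], g, off)
    cb <- assign_cells(xb, yb, size_b[1], size_b[2], g, off)
    for (m in seq_len(n)) {
      ix <- ca[m] %% g; iy <- ca[m] %/% g
      jx <- cb[m] %% g; jy <- cb[m] %/% g
      support <- 0L
      tot_a <- 0L
      valid_a <- 0L
      for (dy in -1:1) for (dx in -1:1) {
        aix <- ix + dx; aiy <- iy + dy
        bjx <- jx + dx; bjy <- jy + dy
        if (aix >= 0 && aix < g && aiy >= 0 && aiy < g) {
          acell <- aix + g * aiy
          valid_a <- valid_a + 1L
          tot_a <- tot_a + sum(ca == acell)
          if (bjx >= 0 && bjx < g && bjy >= 0 && bjy < g) {
            bcell <- bjx + g * bjy
            support <- support + sum(ca == acell & cb == bcell)
          }
        }
      }
      support <- support - 1L
      if (support > alpha * sqrt(tot_a / valid_a)) accept_any[m] <- TRUE
    }
  }
  accept_any
}

# Angular difference of two transforms in degrees, and the displacement of
# the canvas-centre point under recovered o truth^-1 (the registration
# error that matters for landmark transfer).
transform_errors <- function(recovered, truth, center) {
  err <- compose_transforms(recovered, invert_transform(truth))
  d <- apply_to_points(err, rbind(center)) - rbind(center)
  list(theta_deg = abs(err$theta) * 180 / pi, center_px = sqrt(sum(d^2)))
}
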