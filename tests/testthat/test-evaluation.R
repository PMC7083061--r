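sl <- function(pts, source = "op1", region = "maxilla",
               mm_per_px = 0.1) {
  superimposed_landmarks(pts, source = source, region = region,
                         mm_per_px = mm_per_px)
}

test_that("t2ld is the calibrated Euclidean distance, symmetric on shared names", {
  a <- sl(rbind(PNS = c(0, 0), ANS = c(10, 10)))
  b <- sl(rbind(PNS = c(3, 4), ANS = c(10, 10)), source = "op2")
  d <- t2ld(a, b)
  expect_equal(unname(d["PNS"]), 0.5)  # 3-4-5 triangle times 0.1 mm/px
  expect_equal(unname(d["ANS"]), 0)
  expect_equal(t2ld(a, b), t2ld(b, a)[names(d)])
  expect_equal(unname(t2ld(a, a)), c(0, 0))

  # landmark present on one side only is excluded (with a log message)
  c3 <- sl(rbind(PNS = c(1, 1), ANS = c(2, 2), A = c(3, 3)), source = "op3")
  expect_message(d3 <- t2ld(a, c3), "excluded: A")
  expect_setequal(names(d3), c("PNS", "ANS"))

  bad_cal <- sl(rbind(PNS = c(0, 0)), mm_per_px = 0.2)
  expect_error(t2ld(a, bad_cal), "calibration mismatch")
  other_region <- sl(rbind(PNS = c(0, 0)), region = "mandible")
  expect_error(t2ld(a, other_region), "different regions")
})

test_that("pairwise operator bookkeeping yields cases x k(k-1)/2 values", {
  pts <- rbind(PNS = c(10, 10), ANS = c(50, 12), A = c(52, 30))
  make_case <- function(seed) {
    set.seed(seed)
    lapply(1:3, function(k) sl(pts + matrix(rnorm(6, 0, 2), 3),
                               source = sprintf("op%d", k)))
  }
  cases28 <- lapply(1:28, make_case)
  rep28 <- pairwise_operator_differences(cases28)
  expect_true(all(rep28$n == 84))  # 28 cases x 3 pairs
  expect_true(all(rep28$mean_mm >= 0) && all(rep28$sd_mm >= 0))

  one_case_two_ops <- list(lapply(1:2, function(k)
    sl(pts, source = sprintf("op%d", k))))
  rep1 <- pairwise_operator_differences(one_case_two_ops)
  expect_true(all(rep1$n == 1))
  expect_true(all(rep1$mean_mm == 0))
})

test_that("consensus truth is the coordinate-wise mean and operator-order invariant", {
  ops <- list(sl(rbind(PNS = c(0, 0))), sl(rbind(PNS = c(2, 0)), "op2"),
              sl(rbind(PNS = c(4, 0)), "op3"))
  truth <- consensus_truth(ops)
  expect_equal(unname(truth$points["PNS", ]), c(2, 0))
  expect_equal(truth$source, "truth")
  perm <- consensus_truth(ops[c(3, 1, 2)])
  expect_equal(perm$points, truth$points)

  # the mean minimizes the summed squared deviation (grid-search oracle)
  grid <- expand.grid(x = seq(-1, 5, by = 0.05), y = seq(-1, 1, by = 0.05))
  ss <- (grid$x - 0)^2 + (grid$x - 2)^2 + (grid$x - 4)^2 +
        3 * grid$y^2
  best <- grid[which.min(ss), ]
  expect_equal(unname(unlist(best)), unname(truth$points["PNS", ]),
               tolerance = 0.05)
})

test_that("accuracy against a 3-operator mean follows the 2/3 geometry", {
  # two operators coincide; truth = mean; the odd operator sits at
  # (2/3) |op1 - op2| from it
  op1 <- sl(rbind(PNS = c(0, 0)))
  op2 <- sl(rbind(PNS = c(6, 0)), "op2")
  op3 <- sl(rbind(PNS = c(6, 0)), "op3")
  truth <- consensus_truth(list(op1, op2, op3))
  d <- accuracy_vs_truth(op1, truth)
  expect_equal(unname(d["PNS"]), (2 / 3) * 6 * 0.1)

  # isotropic jitter: mean distance approaches the Rayleigh mean
  # sigma * sqrt(pi / 2)
  set.seed(21)
  n <- 10000
  sigma_mm <- 0.5
  mmpp <- 0.1
  truth_pts <- cbind(runif(n, 0, 1000), runif(n, 0, 1000))
  rownames(truth_pts) <- sprintf("UM%04d", seq_len(n))  # free-form names
  jit <- truth_pts + matrix(rnorm(2 * n, 0, sigma_mm / mmpp), ncol = 2)
  d <- sqrt(rowSums((jit - truth_pts)^2)) * mmpp
  expect_equal(mean(d), sigma_mm * sqrt(pi / 2), tolerance = 0.02)
})

test_that("paired t-test matches the closed form and the reference implementation", {
  # 3-element textbook case: diffs (-1, -1, -2)
  res <- paired_t_test(c(1, 2, 3), c(2, 3, 5))
  expect_equal(res$mean_diff, -4 / 3)
  expect_equal(res$t, (-4 / 3) / (sd(c(-1, -1, -2)) / sqrt(3)))
  ref <- t.test(c(1, 2, 3), c(2, 3, 5), paired = TRUE)
  expect_equal(res$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p, ref$p.value, tolerance = 1e-12)

  expect_equal(paired_t_test(1:5, 1:5), list(t = 0, p = 1, n = 5, mean_diff = 0))
  degen <- paired_t_test(c(2, 3), c(1, 2))  # zero-variance, nonzero mean
  expect_equal(degen$p, 0)
  expect_true(is.infinite(degen$t))

  # agreement with stats::t.test on random paired samples
  set.seed(77)
  for (i in 1:100) {
    n <- sample(3:40, 1)
    x <- rnorm(n); y <- rnorm(n)
    mine <- paired_t_test(x, y)
    ref <- t.test(x, y, paired = TRUE)
    expect_equal(mine$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(mine$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("evaluation_report mirrors the protocol's n bookkeeping", {
  pts <- rbind(PNS = c(100, 100), ANS = c(300, 110), A = c(310, 200))
  n_cases <- 28
  set.seed(5)
  operators <- lapply(seq_len(n_cases), function(ci) {
    lapply(1:3, function(k) sl(pts + matrix(rnorm(6, 0, 3), 3),
                               source = sprintf("op%d", k)))
  })
  automated <- lapply(seq_len(n_cases), function(ci) {
    sl(pts + matrix(rnorm(6, 0, 3), 3), source = "automated")
  })
  rep <- evaluation_report(automated, operators)
  expect_true(all(rep$pairwise$n == 84))
  expect_true(all(rep$accuracy$n_hand == 28))
  expect_true(all(rep$accuracy$n_automated == 28))
  expect_true(all(rep$ttest$n == 28))
  expect_true(all(is.finite(rep$ttest$p)))

  # automated identical to consensus: automated accuracy all zero
  automated0 <- lapply(seq_len(n_cases), function(ci) {
    tr <- consensus_truth(operators[[ci]])
    sl(tr$points, source = "automated")
  })
  rep0 <- evaluation_report(automated0, operators)
  expect_true(all(rep0$accuracy$automated_mean_mm == 0))
  # with hand accuracy nonzero the t-test flags the difference
  expect_true(all(rep0$ttest$p < 0.05))

  # operator-replicated pooling multiplies n by the operator count
  rep_r <- evaluation_report(automated, operators, pooling = "operator-replicated")
  expect_true(all(rep_r$ttest$n == 84))
})
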