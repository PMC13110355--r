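test_that("distance to a region is plain Euclidean geometry", {
  tr <- eye_trace(0:3, c(0, 3, 1, -3), c(0, 4, 0, -4))
  expect_equal(distance_to_region(tr, c(0, 0)), c(0, 5, 1, 5))
  # translation invariance
  tr2 <- eye_trace(0:3, c(0, 3, 1, -3) + 2, c(0, 4, 0, -4) - 1)
  expect_equal(distance_to_region(tr2, c(2, -1)),
               distance_to_region(tr, c(0, 0)))
})

test_that("alignment slices windows and drops edge reversals", {
  t <- seq(0, 10000, by = 10)
  d <- sin(t / 500)
  al <- align_to_reversals(t, d, 5000, window = c(-1000, 1000))
  expect_identical(nrow(al$rows), 1L)
  expect_identical(al$n_dropped, 0L)
  expect_equal(al$rows[1, ], d[t >= 4000 & t <= 6000])
  expect_equal(range(al$time), c(-1000, 1000))
  # a reversal 200 ms from the start is dropped and counted
  al2 <- align_to_reversals(t, d, c(200, 5000), window = c(-1000, 1000))
  expect_identical(nrow(al2$rows), 1L)
  expect_identical(al2$n_dropped, 1L)
  # no reversals: empty but well-formed
  al3 <- align_to_reversals(t, d, numeric(0))
  expect_identical(nrow(al3$rows), 0L)
})

test_that("identical conditions give no cluster and p = 1", {
  withr::with_seed(1, {
    A <- matrix(rnorm(8 * 50), 8, 50)
  })
  r <- cluster_permutation(A, A, n_perm = 200, seed = 2)
  expect_identical(r$t_sum, 0)
  expect_identical(r$p, 1)
  expect_true(all(is.na(r$window)))
})

test_that("an injected separation is localised and significant", {
  withr::with_seed(3, {
    n <- 12; tpts <- 100
    time <- seq(-500, 490, by = 10)
    A <- matrix(rnorm(n * tpts), n, tpts)
    B <- matrix(rnorm(n * tpts), n, tpts)
    # 5-SD mean separation over samples where time is in [100, 300] ms
    eff <- time >= 100 & time <= 300
    B[, eff] <- B[, eff] + 5 * sqrt(2)  # 5 SD of the paired difference
  })
  r <- cluster_permutation(A, B, time = time, n_perm = 1000, seed = 4)
  expect_lte(r$p, 0.002)
  # window covers at least 90% of the injected span
  covered <- time[eff][time[eff] >= r$window[1] & time[eff] <= r$window[2]]
  expect_gte(length(covered) / sum(eff), 0.9)
  expect_gt(abs(r$t_sum), r$t_crit)
})

test_that("Monte-Carlo p matches exhaustive sign-flip enumeration at n = 6", {
  withr::with_seed(5, {
    D <- matrix(rnorm(6 * 30), 6, 30)
    D[, 10:15] <- D[, 10:15] + 1.2
  })
  r <- cluster_permutation(D, n_perm = 4000, seed = 6)
  p_exact <- exhaustive_cluster_p(D)
  expect_lt(abs(r$p - p_exact), 0.02)
})

test_that("cluster p is invariant to swapping the condition labels", {
  withr::with_seed(7, {
    A <- matrix(rnorm(10 * 40), 10, 40)
    B <- matrix(rnorm(10 * 40, 0.4), 10, 40)
  })
  r_ab <- cluster_permutation(A, B, n_perm = 500, seed = 8)
  r_ba <- cluster_permutation(B, A, n_perm = 500, seed = 8)
  expect_identical(r_ab$p, r_ba$p)
  expect_equal(r_ab$t_sum, -r_ba$t_sum)
})

test_that("seeded permutation runs replay exactly", {
  withr::with_seed(9, {
    A <- matrix(rnorm(8 * 30), 8, 30)
    B <- matrix(rnorm(8 * 30, 0.3), 8, 30)
  })
  r1 <- cluster_permutation(A, B, n_perm = 300, seed = 11)
  r2 <- cluster_permutation(A, B, n_perm = 300, seed = 11)
  expect_identical(r1[c("t_sum", "t_crit", "p", "window")],
                   r2[c("t_sum", "t_crit", "p", "window")])
  g1 <- gaze_label_permutation(A[, 1:2], B[, 1:2], n_perm = 300, seed = 12)
  g2 <- gaze_label_permutation(A[, 1:2], B[, 1:2], n_perm = 300, seed = 12)
  expect_identical(g1$p, g2$p)
})

test_that("identical point clouds give a zero statistic and p = 1", {
  withr::with_seed(13, {
    P <- matrix(rnorm(16), 8, 2)
  })
  r <- gaze_label_permutation(P, P, n_perm = 200, seed = 14)
  expect_identical(r$delta_gaze, 0)
  expect_identical(r$p, 1)
})

test_that("well-separated point clouds are detected decisively", {
  withr::with_seed(15, {
    A <- matrix(rnorm(24, sd = 0.5), 12, 2)
    B <- matrix(rnorm(24, sd = 0.5), 12, 2) + 10
  })
  r <- gaze_label_permutation(A, B, n_perm = 1000, seed = 16)
  expect_gte(r$delta_gaze, 9)
  expect_lte(r$p, 0.002)
  expect_gt(r$delta_gaze, r$delta_gaze_crit)
})

test_that("small-n label permutation agrees with exhaustive enumeration", {
  withr::with_seed(17, {
    A <- matrix(rnorm(12, sd = 1), 6, 2)
    B <- matrix(rnorm(12, sd = 1), 6, 2) + 0.9
  })
  r <- gaze_label_permutation(A, B, n_perm = 4000, seed = 18)
  p_exact <- exhaustive_centroid_p(A, B)
  expect_lt(abs(r$p - p_exact), 0.02)
})

test_that("the region-distance statistic variant needs its region", {
  A <- matrix(rnorm(12), 6, 2); B <- matrix(rnorm(12), 6, 2)
  expect_error(gaze_label_permutation(A, B,
                                      statistic = "mean_region_distance_diff",
                                      n_perm = 100),
               "region_point")
  r <- gaze_label_permutation(A, B + 4,
                              statistic = "mean_region_distance_diff",
                              region_point = c(0, 0), n_perm = 200, seed = 19)
  expect_gte(r$delta_gaze, 0)
})

test_that("the critical mass grows as the forming threshold loosens", {
  withr::with_seed(20, {
    A <- matrix(rnorm(10 * 50), 10, 50)
    B <- matrix(rnorm(10 * 50), 10, 50)
  })
  crits <- vapply(c(0.01, 0.05, 0.2), function(a) {
    cluster_permutation(A, B, n_perm = 300, alpha_cf = a, seed = 21)$t_crit
  }, numeric(1))
  expect_true(all(diff(crits) >= 0))
})
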