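test_that("t statistics match hand computation", {
  r <- t_test(c(-1, 0, 1))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  expect_equal(r$cohens_d, 0)
  expect_true(r$d_ci[1] < 0 && r$d_ci[2] > 0)

  r2 <- t_test(c(1, 2, 3, 4, 5))
  expect_equal(r2$t, 3 / (sqrt(2.5) / sqrt(5)), tolerance = 1e-12)
  expect_equal(r2$df, 4)
})

test_that("paired identical samples yield zero-variance error", {
  a <- c(0.3, 1.2, -0.5, 2)
  expect_error(t_test(a, a, paired = TRUE), "variance")
})

test_that("one-sided p is half the two-sided p in the favoured direction", {
  withr::with_seed(9, {
    for (i in 1:20) {
      x <- rnorm(12, mean = 0.5)
      if (mean(x) <= 0) next
      p2 <- t_test(x)$p
      p1 <- t_test(x, sides = "greater")$p
      expect_equal(p1, p2 / 2, tolerance = 1e-12)
    }
  })
})

test_that("JZS Bayes factor matches an independent quadrature oracle", {
  cases <- list(c(t = 0, n = 20), c(t = 2.39, n = 60), c(t = 4.165, n = 20),
                c(t = -1.68, n = 60), c(t = 10, n = 20))
  for (cs in cases) {
    bf <- jzs_bf10(cs["t"], cs["n"])
    oracle <- bf_quadrature_oracle(cs["t"], cs["n"])
    expect_equal(bf, oracle, tolerance = 1e-3)
  }
  # two-sample path
  expect_equal(jzs_bf10(2.897, 20, 20), bf_quadrature_oracle(2.897, 20, 20),
               tolerance = 1e-3)
  expect_lt(jzs_bf10(0, 20), 1)
  expect_gt(jzs_bf10(10, 20), 100)
})

test_that("the Bayes factor increases with |t| at fixed n", {
  ts <- seq(0, 6, by = 0.5)
  bfs <- vapply(ts, jzs_bf10, numeric(1), n1 = 20)
  expect_true(all(diff(bfs) > 0))
})

test_that("regression output matches the normal equations", {
  x <- c(1, 2, 3, 5, 8, 13)
  y <- 2 * x
  # a perfect fit makes the F-test degenerate; only the coefficients matter
  r <- suppressWarnings(linregress(y, x))
  expect_equal(r$beta_std, 1, tolerance = 1e-12)
  expect_equal(r$r, 1, tolerance = 1e-12)

  withr::with_seed(3, {
    x <- rnorm(15); y <- 0.4 * x + rnorm(15)
    r <- linregress(y, x)
    # algebraic oracle: closed-form slope/intercept
    sl <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    expect_equal(r$slope, sl, tolerance = 1e-10)
    expect_equal(r$intercept, mean(y) - sl * mean(x), tolerance = 1e-10)
    expect_equal(r$beta_std, cor(x, y), tolerance = 1e-10)
    # F test of the slope equals squared t of the correlation
    expect_equal(r$p, cor.test(x, y)$p.value, tolerance = 1e-10)
  })

  withr::with_seed(4, {
    x <- rnorm(1e4); y <- rnorm(1e4)
    expect_lt(abs(linregress(y, x)$beta_std), 0.03)
  })
  expect_error(linregress(c(1, 2, 3), c(2, 2, 2)), "constant")
})

test_that("Wilcoxon signed-rank uses the exact distribution where printed", {
  # all positive differences, n = 10: one-sided exact p = 2^-10
  r <- wilcoxon_signed_rank(1:10, mu0 = 0, sides = "greater")
  expect_true(r$exact)
  expect_equal(r$p, 1 / 2^10, tolerance = 1e-12)
  # symmetric sample: two-sided p near 1
  r2 <- wilcoxon_signed_rank(c(-3, -2, -1, 1, 2, 3))
  expect_gt(r2$p, 0.9)
  # exact and approximate paths agree at the crossover
  withr::with_seed(8, {
    x <- rnorm(25, 0.2)
    pe <- wilcoxon_signed_rank(x)$p
    pa <- suppressWarnings(
      stats::wilcox.test(x, exact = FALSE, correct = TRUE))$p.value
    expect_lt(abs(pe - pa), 0.01)
  })
  expect_error(wilcoxon_signed_rank(rep(0, 5)), "zero")
})

test_that("questionnaire scoring composes subscales as documented", {
  # all autonomous items at scale max (7), all controlled at min (1)
  items <- matrix(rep(c(7, 1), each = 12), nrow = 1)
  items <- rbind(items, matrix(rep(c(1, 7), each = 12), nrow = 1),
                 matrix(4, 1, 24))
  sc <- crai_score(items)
  expect_equal(unname(sc$self_concordance_raw), c(6, -6, 0))
  expect_equal(max(sc$self_concordance_raw), sc$self_concordance_raw[1])
  expect_lt(abs(sum(sc$self_concordance_z)), 1e-12)
  # sum variant scales by 3
  sc_sum <- crai_score(items, composite = "sum")
  expect_equal(unname(sc_sum$self_concordance_raw), c(18, -18, 0))

  expect_error(crai_score(matrix(4, 3, 24)), "zero variance")
  expect_error(crai_score(matrix(1, 2, 23)), "24 item")
  bad <- matrix(4, 2, 24); bad[1, 3] <- NA
  expect_error(crai_score(bad), "missing")
})

test_that("Cronbach's alpha matches its defining formula", {
  m <- matrix(c(1, 2, 3,
                2, 3, 4,
                1, 3, 3,
                4, 5, 6), nrow = 4, byrow = TRUE)
  k <- ncol(m)
  oracle <- k / (k - 1) * (1 - sum(apply(m, 2, var)) / var(rowSums(m)))
  expect_equal(cronbach_alpha(m), oracle, tolerance = 1e-10)
  # perfectly correlated items
  base <- c(1, 5, 3, 2, 4)
  expect_equal(cronbach_alpha(cbind(base, base, base)), 1, tolerance = 1e-10)
  # independent items at large n drift to ~0
  withr::with_seed(6, {
    big <- matrix(rnorm(4000), ncol = 4)
    expect_lt(abs(cronbach_alpha(big)), 0.1)
  })
})

test_that("Cohen's d interval has near-nominal coverage", {
  true_d <- 0.5
  hits <- withr::with_seed(31, {
    vapply(1:600, function(i) {
      x <- rnorm(60, mean = true_d)
      ci <- t_test(x)$d_ci
      ci[1] <= true_d && true_d <= ci[2]
    }, logical(1))
  })
  expect_gt(mean(hits), 0.92)
  expect_lt(mean(hits), 0.98)
})
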