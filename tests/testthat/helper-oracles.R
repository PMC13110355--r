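# Independent oracles used across tests. These deliberately avoid the code
# paths they validate.

# Exhaustive grid-search maximum likelihood for the cumulative-Gaussian
# psychometric model with gamma = lambda = 0 (used where the fit under test
# also fixes the asymptotes).
grid_oracle_loglik <- function(level, n, k, mu_grid, sigma_grid) {
  best <- -Inf
  for (mu in mu_grid) {
    for (sg in sigma_grid) {
      p <- pnorm((level - mu) / sg)
      p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
      ll <- sum(k * log(p) + (n - k) * log(1 - p))
      if (ll > best) best <- ll
    }
  }
  best
}

# High-resolution trapezoid quadrature for the JZS Bayes factor on a
# substituted bounded variable u = atan(delta / r): an integration scheme
# independent of stats::integrate.
bf_quadrature_oracle <- function(t, n1, n2 = NULL, rscale = sqrt(2) / 2,
                                 n_grid = 20001L) {
  if (is.null(n2)) {
    n_eff <- n1; df <- n1 - 1
  } else {
    n_eff <- n1 * n2 / (n1 + n2); df <- n1 + n2 - 2
  }
  u <- seq(-pi / 2 + 1e-9, pi / 2 - 1e-9, length.out = n_grid)
  delta <- rscale * tan(u)
  jac <- rscale / cos(u)^2
  f <- suppressWarnings(dt(t, df, ncp = delta * sqrt(n_eff))) *
    dcauchy(delta, 0, rscale) * jac
  du <- u[2] - u[1]
  marg <- (sum(f) - (f[1] + f[n_grid]) / 2) * du
  marg / dt(t, df)
}

# Exhaustive sign-flip cluster permutation p-value for paired time courses
# (n rows). Mirrors the max-cluster-mass statistic definition from first
# principles using its own run-length code.
exhaustive_cluster_p <- function(D, alpha_cf = 0.05) {
  n <- nrow(D)
  t_cf <- qt(1 - alpha_cf / 2, df = n - 1)
  tvec <- function(M) {
    m <- colMeans(M)
    s <- apply(M, 2, sd)
    tv <- m / (s / sqrt(n))
    tv[!is.finite(tv)] <- 0
    tv
  }
  mass <- function(tv) {
    above <- abs(tv) > t_cf
    if (!any(above)) return(0)
    best <- 0
    i <- 1
    while (i <= length(tv)) {
      if (above[i]) {
        j <- i
        while (j < length(tv) && above[j + 1] &&
               sign(tv[j + 1]) == sign(tv[i])) j <- j + 1
        best <- max(best, abs(sum(tv[i:j])))
        i <- j + 1
      } else i <- i + 1
    }
    best
  }
  obs <- mass(tvec(D))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), n)))
  perm <- apply(signs, 1, function(s) mass(tvec(D * s)))
  mean(perm >= obs - 1e-12)
}

# Exhaustive within-pair label-swap distribution of the centroid-distance
# statistic for small n.
exhaustive_centroid_p <- function(A, B) {
  n <- nrow(A)
  stat <- function(A, B) sqrt(sum((colMeans(A) - colMeans(B))^2))
  obs <- stat(A, B)
  swaps <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  perm <- apply(swaps, 1, function(sw) {
    A2 <- A; B2 <- B
    A2[sw, ] <- B[sw, , drop = FALSE]
    B2[sw, ] <- A[sw, , drop = FALSE]
    stat(A2, B2)
  })
  mean(perm >= obs - 1e-12)
}

# A synthetic saccade velocity waveform: baseline pursuit plus a raised-
# cosine velocity pulse of given peak and duration.
make_saccade_velocity <- function(t, onset, duration, peak, baseline = 0) {
  v <- rep(baseline, length(t))
  idx <- t >= onset & t < onset + duration
  phase <- (t[idx] - onset) / duration
  v[idx] <- baseline + peak * sin(pi * phase)^2
  v
}
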