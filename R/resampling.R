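# Permutation inference: cluster-based tests on reversal-aligned gaze time
# courses and label-permutation tests on fixation positions. Both use the
# max-statistic construction, the (b + 1) / (B + 1) p-value convention, and
# a 95th-percentile critical value.

#' Per-sample Euclidean distance of gaze to a diagnostic region
#'
#' @param trace An [eye_trace()].
#' @param region_point Length-2 (x, y) coordinate of the region, deg.
#' @return Numeric vector of distances, one per sample.
#' @export
distance_to_region <- function(trace, region_point) {
  stopifnot(inherits(trace, "eye_trace"))
  if (length(region_point) != 2L || any(!is.finite(region_point))) {
    stop("`region_point` must be a finite (x, y) pair", call. = FALSE)
  }
  sqrt((trace$x - region_point[1])^2 + (trace$y - region_point[2])^2)
}

#' Align a distance series to perceptual reversals
#'
#' Extracts one window per reversal from a continuous series, then averages
#' windows within participant (and, if labels are given, within condition),
#' so the participant is the exchangeable unit for the group test.
#' Reversals too close to the recording edges for a full window are dropped
#' and counted.
#'
#' @param t Time stamps of the series, ms (uniform).
#' @param d The distance (or any) series, same length as `t`.
#' @param reversal_times Times of report flips, ms.
#' @param window Length-2 window around each reversal, ms (0 = flip).
#' @param labels Optional condition label per reversal.
#' @return List of class `aligned_tc`: `time` (ms relative to reversal),
#'   `rows` (matrix, one row per reversal or per label after averaging),
#'   `labels`, `n_dropped`.
#' @export
align_to_reversals <- function(t, d, reversal_times,
                               window = c(-1000, 1000), labels = NULL) {
  if (length(t) != length(d)) stop("lengths differ", call. = FALSE)
  dt <- stats::median(diff(t))
  n_pre <- round(-window[1] / dt)
  n_post <- round(window[2] / dt)
  rel_time <- seq(-n_pre, n_post) * dt
  keep <- logical(length(reversal_times))
  rows <- matrix(NA_real_, nrow = length(reversal_times),
                 ncol = n_pre + n_post + 1L)
  for (i in seq_along(reversal_times)) {
    j <- which.min(abs(t - reversal_times[i]))
    if (j - n_pre >= 1L && j + n_post <= length(t)) {
      rows[i, ] <- d[(j - n_pre):(j + n_post)]
      keep[i] <- TRUE
    }
  }
  n_dropped <- sum(!keep)
  rows <- rows[keep, , drop = FALSE]
  labels <- if (!is.null(labels)) labels[keep]
  structure(list(time = rel_time, rows = rows, labels = labels,
                 n_dropped = n_dropped),
            class = "aligned_tc")
}

# Max cluster mass of a t-value vector at a given threshold: clusters are
# maximal runs of contiguous supra-threshold samples (same sign within a
# run is implied by contiguity of the thresholded statistic's sign).
max_cluster <- function(tvals, t_cf) {
  above <- abs(tvals) > t_cf
  if (!any(above)) return(list(mass = 0, start = NA_integer_,
                               end = NA_integer_))
  # split runs where the sign flips so a cluster is one-signed
  sgn <- sign(tvals)
  grp <- cumsum(c(TRUE, diff(above) != 0 | (above[-1] & diff(sgn) != 0)))
  best_mass <- 0; best <- c(NA_integer_, NA_integer_)
  for (g in unique(grp[above])) {
    idx <- which(grp == g & above)
    m <- sum(tvals[idx])
    if (abs(m) > abs(best_mass)) {
      best_mass <- m
      best <- c(idx[1], idx[length(idx)])
    }
  }
  list(mass = best_mass, start = best[1], end = best[2])
}

# Paired t values per column of a difference matrix, given sign flips.
col_t <- function(D, signs = NULL) {
  n <- nrow(D)
  if (!is.null(signs)) D <- D * signs
  m <- colMeans(D)
  s <- sqrt((colSums(D^2) - n * m^2) / (n - 1))
  m / (s / sqrt(n))
}

#' Cluster-based permutation test on paired time courses
#'
#' Tests, at every time point, a paired difference between two conditions;
#' clusters are maximal runs of contiguous samples whose |t| exceeds the
#' cluster-forming threshold (pointwise two-sided t at `alpha_cf`), with
#' cluster mass the sum of t-values. The observed strongest cluster is
#' compared against the permutation distribution of strongest clusters
#' obtained by randomly flipping, per participant, the condition assignment
#' (sign of the difference curve). `t_crit` is the 95th percentile of the
#' permuted strongest-cluster masses; `p = (b + 1) / (n_perm + 1)` where `b`
#' counts permuted masses at least as large as the observed one.
#'
#' @param cond_a,cond_b Matrices, participants x time, same shape. (Or pass
#'   `cond_a` as the precomputed difference matrix and omit `cond_b`.)
#' @param time Optional time axis, ms (defaults to sample index).
#' @param n_perm Number of permutations (>= 100).
#' @param alpha_cf Cluster-forming pointwise alpha (two-sided).
#' @param seed Seed for the permutation draw.
#' @return List of class `cluster_result`: `t_sum`, `t_crit`, `p`,
#'   `window` (ms), `tvals`, `n_perm`.
#' @export
cluster_permutation <- function(cond_a, cond_b = NULL, time = NULL,
                                n_perm = 1000L, alpha_cf = 0.05,
                                seed = 1L) {
  D <- if (is.null(cond_b)) as.matrix(cond_a) else
    as.matrix(cond_a) - as.matrix(cond_b)
  n <- nrow(D)
  if (n < 2L) stop("need >= 2 participants", call. = FALSE)
  n_perm <- stop_if_not_count(n_perm, "n_perm", lower = 100L)
  if (is.null(time)) time <- seq_len(ncol(D))
  t_cf <- stats::qt(1 - alpha_cf / 2, df = n - 1)

  tvals <- col_t(D)
  tvals[!is.finite(tvals)] <- 0
  obs <- max_cluster(tvals, t_cf)

  perm_mass <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      signs <- sample(c(-1, 1), n, replace = TRUE)
      tv <- col_t(D, signs)
      tv[!is.finite(tv)] <- 0
      abs(max_cluster(tv, t_cf)$mass)
    }, numeric(1))
  })

  p <- (sum(perm_mass >= abs(obs$mass)) + 1) / (n_perm + 1)
  window <- if (is.na(obs$start)) c(NA_real_, NA_real_) else
    c(time[obs$start], time[obs$end])
  structure(list(t_sum = obs$mass,
                 t_crit = unname(stats::quantile(perm_mass, 0.95)),
                 p = p, window = window, tvals = tvals, time = time,
                 n_perm = n_perm, alpha_cf = alpha_cf),
            class = "cluster_result")
}

#' Label-permutation test on gaze positions
#'
#' Compares gaze under two condition labels with one of two statistics:
#' `centroid_distance`, the Euclidean distance between the condition mean
#' gaze positions; or `mean_region_distance_diff`, the absolute difference
#' of mean distances to a diagnostic region. Rows are paired within
#' participant and permutation swaps each participant's condition labels.
#'
#' @param points_a,points_b Matrices (participants x 2) of gaze positions
#'   (deg) under the two conditions, row i = participant i.
#' @param statistic Which statistic to permute.
#' @param region_point Diagnostic region (needed for the distance variant).
#' @param n_perm Number of permutations.
#' @param seed Seed.
#' @return List of class `gaze_perm_result`: `delta_gaze`,
#'   `delta_gaze_crit` (95th percentile of permuted statistics), `p`.
#' @export
gaze_label_permutation <- function(points_a, points_b,
                                   statistic = c("centroid_distance",
                                                 "mean_region_distance_diff"),
                                   region_point = NULL, n_perm = 1000L,
                                   seed = 1L) {
  statistic <- match.arg(statistic)
  A <- as.matrix(points_a); B <- as.matrix(points_b)
  if (!all(dim(A) == dim(B)) || ncol(A) != 2L) {
    stop("point sets must be matched participants x 2 matrices",
         call. = FALSE)
  }
  n <- nrow(A)
  if (n < 2L) stop("need >= 2 points per condition", call. = FALSE)
  n_perm <- stop_if_not_count(n_perm, "n_perm", lower = 100L)

  stat_fun <- if (statistic == "centroid_distance") {
    function(A, B) sqrt(sum((colMeans(A) - colMeans(B))^2))
  } else {
    if (is.null(region_point)) {
      stop("`region_point` required for mean_region_distance_diff",
           call. = FALSE)
    }
    dist_to <- function(M) sqrt((M[, 1] - region_point[1])^2 +
                                  (M[, 2] - region_point[2])^2)
    function(A, B) abs(mean(dist_to(A)) - mean(dist_to(B)))
  }

  obs <- stat_fun(A, B)
  perm <- with_seed(seed, {
    vapply(seq_len(n_perm), function(b) {
      swap <- stats::runif(n) < 0.5
      A2 <- A; B2 <- B
      A2[swap, ] <- B[swap, , drop = FALSE]
      B2[swap, ] <- A[swap, , drop = FALSE]
      stat_fun(A2, B2)
    }, numeric(1))
  })
  p <- (sum(perm >= obs) + 1) / (n_perm + 1)
  structure(list(delta_gaze = obs,
                 delta_gaze_crit = unname(stats::quantile(perm, 0.95)),
                 p = p, n_perm = n_perm, statistic = statistic),
            class = "gaze_perm_result")
}
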