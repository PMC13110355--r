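# Smooth-pursuit signal processing: raw eye-position traces to saccade
# events, desaccaded velocity, pursuit-velocity summaries, oculometric
# decisions and saccade endpoints. Angles in degrees, times in ms,
# velocities in deg/s.

#' Construct an eye-position trace
#'
#' @param t Time stamps in ms, strictly increasing, uniformly sampled.
#' @param x,y Gaze position in degrees, screen-centred (x positive
#'   rightward, y positive upward). NA marks signal loss.
#' @param markers Named numeric vector of event times (e.g. `target_onset`).
#' @return Object of class `eye_trace`.
#' @export
eye_trace <- function(t, x, y = rep(0, length(t)), markers = c()) {
  if (length(t) < 2L || any(diff(t) <= 0)) {
    stop("`t` must be strictly increasing with at least 2 samples",
         call. = FALSE)
  }
  dt <- diff(t)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop("non-uniform sampling", call. = FALSE)
  }
  if (length(x) != length(t) || length(y) != length(t)) {
    stop("`x`, `y` must match `t` in length", call. = FALSE)
  }
  structure(list(t = as.numeric(t), x = as.numeric(x), y = as.numeric(y),
                 markers = markers, fs = 1000 / stats::median(dt)),
            class = "eye_trace")
}

#' Differentiate an eye trace and apply zero-phase Butterworth filtering
#'
#' Position is low-pass filtered (zero-phase, forward-backward), velocity is
#' obtained by central differences and filtered again. Short NA gaps
#' (<= `max_gap_ms`) are linearly interpolated and flagged; longer gaps are
#' an error that lists the offending spans.
#'
#' @param trace An [eye_trace()].
#' @param cutoff_pos,cutoff_vel Low-pass cutoffs in Hz for position and
#'   velocity (2nd-order Butterworth).
#' @param order Filter order.
#' @param max_gap_ms Longest NA gap bridged by interpolation.
#' @return Object of class `velocity_trace`: `t`, `v` (horizontal, deg/s),
#'   `vy`, `interpolated` (logical mask), `markers`, `fs`.
#' @export
differentiate_and_filter <- function(trace, cutoff_pos = 30,
                                     cutoff_vel = 40, order = 2,
                                     max_gap_ms = 50) {
  stopifnot(inherits(trace, "eye_trace"))
  fs <- trace$fs
  n <- length(trace$t)
  if (n < 3 * (order + 1) * 3) {
    stop("trace too short for filter warm-up", call. = FALSE)
  }
  interp_mask <- rep(FALSE, n)
  fill <- function(z) {
    bad <- !is.finite(z)
    if (!any(bad)) return(z)
    runs <- rle(bad)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    gap_ms <- runs$lengths[runs$values] * 1000 / fs
    if (any(gap_ms > max_gap_ms)) {
      idx <- which(runs$values)[gap_ms > max_gap_ms]
      spans <- paste(sprintf("[%g, %g] ms", trace$t[starts[idx]],
                             trace$t[ends[idx]]), collapse = ", ")
      stop("NA gaps longer than ", max_gap_ms, " ms: ", spans, call. = FALSE)
    }
    interp_mask[bad] <<- TRUE
    stats::approx(trace$t[!bad], z[!bad], xout = trace$t, rule = 2)$y
  }
  x <- fill(trace$x)
  y <- fill(trace$y)

  bf_pos <- signal::butter(order, cutoff_pos / (fs / 2), type = "low")
  bf_vel <- signal::butter(order, cutoff_vel / (fs / 2), type = "low")
  cdiff <- function(z) {
    v <- numeric(n)
    v[2:(n - 1)] <- (z[3:n] - z[1:(n - 2)]) * fs / 2
    v[1] <- (z[2] - z[1]) * fs
    v[n] <- (z[n] - z[n - 1]) * fs
    v
  }
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass on signals that do not begin at zero
  zp_filter <- function(bf, z) {
    p <- min(n - 1L, 200L)
    head_pad <- 2 * z[1] - z[(p + 1L):2L]
    tail_pad <- 2 * z[n] - z[(n - 1L):(n - p)]
    out <- signal::filtfilt(bf, c(head_pad, z, tail_pad))
    out[(p + 1L):(p + n)]
  }
  xf <- zp_filter(bf_pos, x)
  vx <- zp_filter(bf_vel, cdiff(xf))
  if (all(y == y[1])) {
    vy <- numeric(n)  # constant channel differentiates to zero exactly
  } else {
    yf <- zp_filter(bf_pos, y)
    vy <- zp_filter(bf_vel, cdiff(yf))
  }

  structure(list(t = trace$t, v = vx, vy = vy,
                 interpolated = interp_mask, markers = trace$markers,
                 fs = fs),
            class = "velocity_trace")
}

#' Construct a velocity trace directly
#'
#' @param t Time in ms (uniform, increasing).
#' @param v Horizontal velocity in deg/s.
#' @param vy Optional vertical velocity.
#' @param markers Named event times.
#' @param interpolated Optional logical mask.
#' @return A `velocity_trace`.
#' @export
velocity_trace <- function(t, v, vy = NULL, markers = c(),
                           interpolated = rep(FALSE, length(t))) {
  if (length(t) != length(v)) stop("lengths differ", call. = FALSE)
  structure(list(t = as.numeric(t), v = as.numeric(v), vy = vy,
                 interpolated = interpolated, markers = markers,
                 fs = 1000 / stats::median(diff(t))),
            class = "velocity_trace")
}

#' Detect saccades from a velocity trace
#'
#' Candidate intervals are maximal runs where eye speed exceeds
#' `v_thresh`; an interval counts as a saccade if its peak absolute
#' acceleration exceeds `a_thresh` (velocity-plus-acceleration criterion in
#' the style of video-oculography event parsers). Onset/offset are the speed
#' threshold re-crossings; events closer than `merge_ms` are merged.
#'
#' @param vel A `velocity_trace`.
#' @param v_thresh Speed threshold, deg/s.
#' @param a_thresh Acceleration threshold, deg/s^2.
#' @param merge_ms Merge events separated by less than this many ms.
#' @param trace Optional source [eye_trace()] used to fill in amplitude and
#'   landing position.
#' @return Data frame of class `saccade_events`: `onset`, `offset` (ms),
#'   `peak_velocity`, `amplitude`, `landing_x`, `landing_y`.
#' @export
detect_saccades <- function(vel, v_thresh = 30, a_thresh = 8000,
                            merge_ms = 20, trace = NULL) {
  stopifnot(inherits(vel, "velocity_trace"))
  empty <- data.frame(onset = numeric(0), offset = numeric(0),
                      peak_velocity = numeric(0), amplitude = numeric(0),
                      landing_x = numeric(0), landing_y = numeric(0))
  class(empty) <- c("saccade_events", "data.frame")
  n <- length(vel$v)
  if (n == 0L) return(empty)
  speed <- if (!is.null(vel$vy)) sqrt(vel$v^2 + vel$vy^2) else abs(vel$v)
  acc <- c(0, diff(speed)) * vel$fs
  above <- speed > v_thresh
  if (!any(above)) return(empty)
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  keep <- which(runs$values)
  iv <- cbind(starts[keep], ends[keep])
  # acceleration gate
  ok <- apply(iv, 1, function(r) max(abs(acc[r[1]:r[2]])) > a_thresh)
  iv <- iv[ok, , drop = FALSE]
  if (nrow(iv) == 0L) return(empty)
  # merge close events
  merged <- iv[1, , drop = FALSE]
  if (nrow(iv) > 1L) {
    for (i in 2:nrow(iv)) {
      gap_ms <- (iv[i, 1] - merged[nrow(merged), 2]) * 1000 / vel$fs
      if (gap_ms < merge_ms) {
        merged[nrow(merged), 2] <- iv[i, 2]
      } else {
        merged <- rbind(merged, iv[i, ])
      }
    }
  }
  out <- data.frame(
    onset = vel$t[merged[, 1]],
    offset = vel$t[merged[, 2]],
    peak_velocity = apply(merged, 1, function(r) max(speed[r[1]:r[2]])),
    amplitude = NA_real_, landing_x = NA_real_, landing_y = NA_real_)
  if (!is.null(trace)) {
    idx_on <- match(out$onset, trace$t)
    idx_off <- match(out$offset, trace$t)
    out$landing_x <- trace$x[idx_off]
    out$landing_y <- trace$y[idx_off]
    out$amplitude <- sqrt((trace$x[idx_off] - trace$x[idx_on])^2 +
                            (trace$y[idx_off] - trace$y[idx_on])^2)
  }
  class(out) <- c("saccade_events", "data.frame")
  out
}

#' Remove saccades from a velocity trace by linear interpolation
#'
#' Samples within `[onset - pad, offset + pad]` of each event are replaced
#' by a straight line between the boundary samples; overlapping padded spans
#' are merged. Spans touching the trace edge hold the boundary value (with a
#' warning). The interpolation mask is updated.
#'
#' @param vel A `velocity_trace`.
#' @param events A `saccade_events` data frame.
#' @param pad Padding around each event, ms.
#' @return The desaccaded `velocity_trace`.
#' @export
desaccade <- function(vel, events, pad = 10) {
  stopifnot(inherits(vel, "velocity_trace"))
  if (is.null(events) || nrow(events) == 0L) return(vel)
  n <- length(vel$v)
  mask <- rep(FALSE, n)
  for (i in seq_len(nrow(events))) {
    mask[vel$t >= events$onset[i] - pad & vel$t <= events$offset[i] + pad] <-
      TRUE
  }
  runs <- rle(mask)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  for (j in which(runs$values)) {
    a <- starts[j]; b <- ends[j]
    if (a == 1L && b == n) {
      warning("saccade span covers the whole trace; nothing to anchor on")
      next
    }
    if (a == 1L) {
      warning("saccade span touches trace start; holding boundary value")
      vel$v[a:b] <- vel$v[b + 1L]
    } else if (b == n) {
      warning("saccade span touches trace end; holding boundary value")
      vel$v[a:b] <- vel$v[a - 1L]
    } else {
      vel$v[a:b] <- vel$v[a - 1L] +
        (vel$v[b + 1L] - vel$v[a - 1L]) *
        (vel$t[a:b] - vel$t[a - 1L]) / (vel$t[b + 1L] - vel$t[a - 1L])
    }
  }
  vel$interpolated <- vel$interpolated | mask
  vel
}

#' Mean pursuit velocity in a post-onset window
#'
#' Arithmetic mean of the (desaccaded) horizontal velocity over the
#' half-open window `[onset + window[1], onset + window[2])` ms relative to
#' the target-onset marker. If more than half of the window was
#' interpolated the value is returned with `low_quality = TRUE`.
#'
#' @param vel A `velocity_trace` whose markers include `target_onset` (or
#'   pass `onset` explicitly).
#' @param window Length-2 window in ms after target onset.
#' @param onset Optional explicit onset time, ms.
#' @return List: `value` (deg/s), `prop_interpolated`, `low_quality`.
#' @export
mean_pursuit_velocity <- function(vel, window = c(250, 500), onset = NULL) {
  stopifnot(inherits(vel, "velocity_trace"))
  if (is.null(onset)) {
    onset <- vel$markers[["target_onset"]]
    if (is.null(onset)) stop("no `target_onset` marker", call. = FALSE)
  }
  sel <- vel$t >= onset + window[1] & vel$t < onset + window[2]
  if (!any(sel)) stop("analysis window outside trace", call. = FALSE)
  prop <- mean(vel$interpolated[sel])
  list(value = mean(vel$v[sel]), prop_interpolated = prop,
       low_quality = prop > 0.5)
}

#' Oculometric decision: was the comparison pursued faster?
#'
#' Exact ties (measure-zero with real noise, common with noiseless synthetic
#' input) are broken by a seeded fair coin.
#'
#' @param v_standard,v_comparison Pursuit velocities, deg/s.
#' @param tie_seed Seed for the tie-breaking coin.
#' @return TRUE iff the comparison was pursued faster.
#' @export
oculometric_decision <- function(v_standard, v_comparison, tie_seed = 1L) {
  stop_if_not_number(v_standard, "v_standard")
  stop_if_not_number(v_comparison, "v_comparison")
  if (v_comparison == v_standard) {
    return(with_seed(tie_seed, stats::runif(1) < 0.5))
  }
  v_comparison > v_standard
}

#' Landing point of the first midline-crossing saccade
#'
#' Returns the landing position of the first detected saccade whose landing
#' x-coordinate exceeds `midline_x`; the vertical component is reported
#' relative to the horizontal midline (y = 0). Trials without a crossing
#' saccade are flagged invalid.
#'
#' @param trace An [eye_trace()].
#' @param events `saccade_events` with landing positions (detect with
#'   `trace` supplied).
#' @param midline_x Vertical monitor midline, deg.
#' @return List: `x`, `y`, `valid`.
#' @export
saccade_endpoint <- function(trace, events, midline_x = 0) {
  stopifnot(inherits(trace, "eye_trace"))
  if (is.null(events) || nrow(events) == 0L ||
      all(is.na(events$landing_x))) {
    return(list(x = NA_real_, y = NA_real_, valid = FALSE))
  }
  cross <- which(events$landing_x > midline_x)
  if (length(cross) == 0L) {
    return(list(x = NA_real_, y = NA_real_, valid = FALSE))
  }
  i <- cross[1]
  list(x = events$landing_x[i], y = events$landing_y[i], valid = TRUE)
}

#' Sliding Gaussian-window running average
#'
#' Gaussian-kernel weighted mean with edge renormalisation (weights are
#' rescaled to sum to one wherever the kernel is truncated by the series
#' boundary).
#'
#' @param series Numeric vector.
#' @param window_sd Kernel standard deviation in samples (> 0).
#' @return Smoothed numeric vector of the same length.
#' @export
running_average <- function(series, window_sd) {
  stop_if_not_number(window_sd, "window_sd", lower = 1e-12)
  n <- length(series)
  half <- max(1L, ceiling(4 * window_sd))
  kern <- stats::dnorm(-half:half, sd = window_sd)
  if (sum(kern) == 0) return(series)  # sd -> 0 limit: identity
  out <- numeric(n)
  for (i in seq_len(n)) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    w <- kern[(lo - i + half + 1L):(hi - i + half + 1L)]
    out[i] <- sum(w * series[lo:hi]) / sum(w)
  }
  out
}
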