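test_that("differentiation recovers a ramp and kills a constant", {
  t <- 0:1200
  tr <- eye_trace(t, 8 * t / 1000)
  v <- differentiate_and_filter(tr)
  mid <- v$t > 150 & v$t < 1050
  expect_lt(max(abs(v$v[mid] - 8)), 0.01)

  v0 <- differentiate_and_filter(eye_trace(t, rep(2, length(t))))
  expect_lt(max(abs(v0$v)), 1e-9)
})

test_that("the filter attenuates above-cutoff oscillation", {
  t <- 0:2000
  f_hz <- 80  # above both cutoffs
  x <- 0.5 * sin(2 * pi * f_hz * t / 1000)
  v <- differentiate_and_filter(eye_trace(t, x))
  # analytic unfiltered velocity amplitude: 0.5 * 2 pi f deg/s
  amp_in <- 0.5 * 2 * pi * f_hz
  amp_out <- max(abs(v$v[500:1500]))
  expect_lt(amp_out / amp_in, 0.05)
})

test_that("filtering is zero-phase on a ramp-plus-wiggle signal", {
  t <- 0:2000
  x <- 8 * t / 1000 + 0.2 * sin(2 * pi * 10 * t / 1000)
  v <- differentiate_and_filter(eye_trace(t, x))
  raw_v <- c(0, diff(x)) * 1000
  cc <- ccf(v$v[200:1800], raw_v[200:1800], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
})

test_that("long signal-loss gaps abort with their spans listed", {
  t <- 0:1200
  x <- 8 * t / 1000
  x[300:400] <- NA  # 101 ms gap
  expect_error(differentiate_and_filter(eye_trace(t, x)), "gaps")
  x2 <- 8 * t / 1000
  x2[300:320] <- NA  # 21 ms gap: interpolated and flagged
  v <- differentiate_and_filter(eye_trace(t, x2))
  expect_true(any(v$interpolated[300:320]))
})

test_that("constructed saccades are detected at the right time", {
  t <- 0:1000
  v <- make_saccade_velocity(t, onset = 500, duration = 30, peak = 200,
                             baseline = 8)
  ev <- detect_saccades(velocity_trace(t, v))
  expect_identical(nrow(ev), 1L)
  expect_lt(abs(ev$onset - 500), 5 + 1e-9)
  expect_gt(ev$peak_velocity, 150)

  # two saccades 100 ms apart stay separate events
  v2 <- make_saccade_velocity(t, 300, 30, 200, 8) +
    make_saccade_velocity(t, 430, 30, 200, 0)
  ev2 <- detect_saccades(velocity_trace(t, v2))
  expect_identical(nrow(ev2), 2L)

  # sub-threshold fixation noise yields no events
  vn <- withr::with_seed(2, rnorm(1001, 0, 5))
  expect_identical(nrow(detect_saccades(velocity_trace(t, vn))), 0L)
})

test_that("desaccading interpolates only within padded spans", {
  t <- 0:1000
  v <- make_saccade_velocity(t, 500, 40, 300, 8)
  vt <- velocity_trace(t, v)
  ev <- detect_saccades(vt)
  dv <- desaccade(vt, ev, pad = 10)
  spike <- t >= 500 & t <= 540
  expect_equal(mean(dv$v[spike]), 8, tolerance = 0.01)
  outside <- t < ev$onset - 10 | t > ev$offset + 10
  expect_identical(dv$v[outside], vt$v[outside])
  # no events: identity
  none <- detect_saccades(velocity_trace(t, rep(8, 1001)))
  expect_identical(desaccade(vt, none)$v, vt$v)
})

test_that("overlapping padded events merge into one interpolation span", {
  t <- 0:400
  v <- rep(8, 401)
  ev <- data.frame(onset = c(100, 130), offset = c(115, 145),
                   peak_velocity = NA, amplitude = NA,
                   landing_x = NA, landing_y = NA)
  v[101:116] <- 300; v[131:146] <- 300
  dv <- desaccade(velocity_trace(t, v), ev, pad = 10)
  expect_lt(max(abs(dv$v - 8)), 1e-9)
  # the whole merged span [90, 155] is flagged
  expect_true(all(dv$interpolated[t >= 90 & t <= 155]))
})

test_that("mean pursuit velocity honours the half-open window", {
  t <- 0:800
  v <- ifelse(t < 450, 2, 8)  # switches exactly at window start (200 + 250)
  vt <- velocity_trace(t, v, markers = c(target_onset = 200))
  m <- mean_pursuit_velocity(vt)
  expect_equal(m$value, 8)
  expect_false(m$low_quality)
  # more than half the window interpolated => flagged, value still returned
  vt$interpolated[t >= 450 & t < 600] <- TRUE
  m2 <- mean_pursuit_velocity(vt)
  expect_true(m2$low_quality)
  expect_equal(m2$value, 8)
  expect_error(mean_pursuit_velocity(velocity_trace(t, v)), "marker")
})

test_that("oculometric decisions compare velocities with a fair tie-break", {
  expect_true(oculometric_decision(8.0, 9.1))
  expect_false(oculometric_decision(8.0, 7.2))
  ties <- vapply(1:10000, function(s) oculometric_decision(8, 8, tie_seed = s),
                 logical(1))
  expect_gt(mean(ties), 0.48)
  expect_lt(mean(ties), 0.52)
})

test_that("the endpoint comes from the first midline-crossing saccade", {
  # construct a two-saccade position trace: first lands short of the
  # midline, second crosses it
  t <- 0:600
  x <- approx(c(0, 100, 130, 300, 330, 600), c(-6, -6, -1, -1, 6.2, 6.2),
              xout = t)$y
  y <- approx(c(0, 300, 330, 600), c(0, 0, 2.9, 2.9), xout = t)$y
  tr <- eye_trace(t, x, y)
  vel <- differentiate_and_filter(tr)
  ev <- detect_saccades(vel, trace = tr)
  expect_gte(nrow(ev), 2L)
  ep <- saccade_endpoint(tr, ev, midline_x = 0)
  expect_true(ep$valid)
  expect_equal(ep$x, 6.2, tolerance = 0.2)
  expect_equal(ep$y, 2.9, tolerance = 0.2)
  # no saccade: invalid flag
  still <- eye_trace(t, rep(-6, 601), rep(0, 601))
  ev0 <- detect_saccades(differentiate_and_filter(still), trace = still)
  expect_false(saccade_endpoint(still, ev0)$valid)
})

test_that("generator catch-up saccades are recovered by detection", {
  # pursuit intervals with deliberately low gain produce catch-up saccades;
  # detection should find an event near each injected pulse
  obs <- observer_exp2(pursuit_gain = 0.7, motor_noise_sd = 3,
                       sensory_noise_sd = 0)
  found <- 0L; injected <- 0L
  for (s in 1:10) {
    tr <- withr::with_seed(s, gazebias:::gen_pursuit_interval(8, 8, 900, obs))
    vel <- differentiate_and_filter(tr)
    # acceleration gate matched to the 30/40 Hz filtered signal, as in the
    # analysis pipeline
    ev <- detect_saccades(vel, a_thresh = 1500)
    # ground truth: pulses push the raw velocity far above pursuit level
    raw_v <- c(0, diff(tr$x)) * 1000
    truth <- which(diff(raw_v > 45) == 1)
    injected <- injected + length(truth)
    for (tt in tr$t[truth]) {
      if (any(abs(ev$onset - tt) <= 10)) found <- found + 1L
    }
  }
  expect_gt(injected, 3L)
  expect_gte(found / injected, 0.95)
})

test_that("running averages keep mass and collapse to identity", {
  s <- rep(3.3, 50)
  expect_equal(running_average(s, 5), s)
  # delta impulse spreads into a discrete Gaussian profile with the same sum
  imp <- c(rep(0, 50), 1, rep(0, 50))
  sm <- running_average(imp, 3)
  expect_equal(sum(sm), 1, tolerance = 1e-6)
  expect_identical(which.max(sm), 51L)
  prof <- dnorm(-12:12, sd = 3); prof <- prof / sum(prof)
  expect_equal(sm[39:63], prof, tolerance = 1e-6)
  # sd -> 0 limit returns the series
  x <- sin(1:20)
  expect_equal(running_average(x, 1e-6), x)
})
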