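# Synthetic observers and session generators for the four experimental
# designs, with known ground-truth parameters so every analysis stage can
# be exercised and validated without human data.
#
# Conventions: the high-value / "percept A" location sits at +3 deg on the
# vertical axis (low-value at -3); endpoints are signed positive towards the
# high-value location. All times ms, positions deg, velocities deg/s.

#' Synthetic observer for the digit-detection experiment
#'
#' Generative counterpart of the signal-detection analysis: a saccade
#' endpoint distribution, a sensitivity that decays linearly with the
#' distance between gaze endpoint and target, value-conditioned criterion
#' shifts, and contrast thresholds for the attention staircases.
#'
#' @param endpoint_bias_mean Mean vertical endpoint, deg, positive towards
#'   the high-value target.
#' @param endpoint_sd Trial-to-trial endpoint SD, deg (> 0).
#' @param dprime_at_target Sensitivity when gaze lands on the target.
#' @param dprime_falloff Loss of d-prime per degree of gaze-target distance.
#' @param criterion_shift_high,criterion_shift_low Criterion offsets at the
#'   two value locations (negative = liberal, reports "present" more).
#' @param attn_threshold_low,attn_threshold_high Contrast thresholds
#'   (Michelson) at the two locations, in (0.01, 0.9).
#' @param lapse_rate Probability of a random response, in [0, 0.1].
#' @return Object of class `observer_exp1`.
#' @export
observer_exp1 <- function(endpoint_bias_mean = 0.3, endpoint_sd = 1.0,
                          dprime_at_target = 1.8, dprime_falloff = 0.4,
                          criterion_shift_high = -0.24,
                          criterion_shift_low = -0.09,
                          attn_threshold_low = 0.2,
                          attn_threshold_high = 0.2,
                          lapse_rate = 0.02) {
  stop_if_not_number(endpoint_sd, "endpoint_sd", lower = 1e-9)
  stop_if_not_number(dprime_at_target, "dprime_at_target", lower = 0)
  stop_if_not_number(attn_threshold_low, "attn_threshold_low",
                     lower = 0.01, upper = 0.9)
  stop_if_not_number(attn_threshold_high, "attn_threshold_high",
                     lower = 0.01, upper = 0.9)
  stop_if_not_number(lapse_rate, "lapse_rate", lower = 0, upper = 0.1)
  structure(list(endpoint_bias_mean = endpoint_bias_mean,
                 endpoint_sd = endpoint_sd,
                 dprime_at_target = dprime_at_target,
                 dprime_falloff = dprime_falloff,
                 criterion_shift_high = criterion_shift_high,
                 criterion_shift_low = criterion_shift_low,
                 attn_threshold_low = attn_threshold_low,
                 attn_threshold_high = attn_threshold_high,
                 lapse_rate = lapse_rate),
            class = "observer_exp1")
}

#' Synthetic observer for the pursuit speed-judgment experiment
#'
#' Embodies the dissociation logic of the design: `perceptual_bias` shifts
#' the shared internal velocity estimate and therefore shows up in both
#' pursuit and reports, whereas `response_bias` is applied at the report
#' decision only.
#'
#' @param pursuit_gain Ratio of eye to perceived target velocity, (0, 1.2].
#' @param pursuit_latency Pursuit onset latency, ms, in [80, 300].
#' @param motor_noise_sd Within-trial velocity noise, deg/s.
#' @param sensory_noise_sd Trial-level noise on the internal velocity
#'   estimate, deg/s.
#' @param response_bias Report-only bias, deg/s equivalent (favours the
#'   rewarded interval; active in the biased block only).
#' @param perceptual_bias Shift of the internal estimate of the rewarded
#'   interval, deg/s (feeds both pursuit and report; biased block only).
#' @param catchup_rate Maximum catch-up saccade rate, saccades/s.
#' @return Object of class `observer_exp2`.
#' @export
observer_exp2 <- function(pursuit_gain = 0.95, pursuit_latency = 140,
                          motor_noise_sd = 3, sensory_noise_sd = 0.8,
                          response_bias = 0, perceptual_bias = 0,
                          catchup_rate = 2) {
  stop_if_not_number(pursuit_gain, "pursuit_gain", lower = 1e-9, upper = 1.2)
  stop_if_not_number(pursuit_latency, "pursuit_latency",
                     lower = 80, upper = 300)
  stop_if_not_number(motor_noise_sd, "motor_noise_sd", lower = 0)
  stop_if_not_number(sensory_noise_sd, "sensory_noise_sd", lower = 0)
  structure(list(pursuit_gain = pursuit_gain,
                 pursuit_latency = pursuit_latency,
                 motor_noise_sd = motor_noise_sd,
                 sensory_noise_sd = sensory_noise_sd,
                 response_bias = response_bias,
                 perceptual_bias = perceptual_bias,
                 catchup_rate = catchup_rate),
            class = "observer_exp2")
}

#' Synthetic observer for the free-viewing ambiguity experiment
#'
#' @param reversal_rate Spontaneous reversal rate, reversals/s (> 0).
#' @param gaze_lead Time by which the gaze approach to a percept's
#'   diagnostic region precedes the reported reversal, ms (>= 0).
#' @param fixation_jitter_sd Gaze jitter SD, deg.
#' @param diagnostic_point_a,diagnostic_point_b (x, y) coordinates of the
#'   two percepts' diagnostic regions, deg.
#' @param gaze_tau Time constant of the gaze approach, ms.
#' @return Object of class `observer_exp3`.
#' @export
observer_exp3 <- function(reversal_rate = 0.25, gaze_lead = 300,
                          fixation_jitter_sd = 0.5,
                          diagnostic_point_a = c(-3, 0),
                          diagnostic_point_b = c(3, 0),
                          gaze_tau = 120) {
  stop_if_not_number(reversal_rate, "reversal_rate", lower = 0)
  stop_if_not_number(gaze_lead, "gaze_lead", lower = 0)
  structure(list(reversal_rate = reversal_rate, gaze_lead = gaze_lead,
                 fixation_jitter_sd = fixation_jitter_sd,
                 diagnostic_point_a = diagnostic_point_a,
                 diagnostic_point_b = diagnostic_point_b,
                 gaze_tau = gaze_tau),
            class = "observer_exp3")
}

#' Synthetic observer for the forced-fixation experiment
#'
#' @param pse_fix_a,pse_fix_b PSEs (face-proportion units, in (0, 1)) under
#'   fixation on the eye region (a) and the house feature (b).
#' @param slope_sd Psychometric spread in proportion units.
#' @param lapse_rate Lapse probability in [0, 0.1].
#' @param illusion_congruence Probability of reporting the fixation-targeted
#'   percept in the illusion block.
#' @return Object of class `observer_exp4`.
#' @export
observer_exp4 <- function(pse_fix_a = 0.43, pse_fix_b = 0.49,
                          slope_sd = 0.1, lapse_rate = 0.02,
                          illusion_congruence = 0.7) {
  stop_if_not_number(pse_fix_a, "pse_fix_a", lower = 1e-9, upper = 1 - 1e-9)
  stop_if_not_number(pse_fix_b, "pse_fix_b", lower = 1e-9, upper = 1 - 1e-9)
  stop_if_not_number(slope_sd, "slope_sd", lower = 1e-9)
  stop_if_not_number(lapse_rate, "lapse_rate", lower = 0, upper = 0.1)
  structure(list(pse_fix_a = pse_fix_a, pse_fix_b = pse_fix_b,
                 slope_sd = slope_sd, lapse_rate = lapse_rate,
                 illusion_congruence = illusion_congruence),
            class = "observer_exp4")
}

#' Session specification
#'
#' Holds the experiment id, seed and trial-count overrides. Defaults
#' reproduce the printed designs: 500 trials (400 detection + 100
#' attention) for experiment 1; 2 blocks of 216 for experiment 2; 34 trials
#' for experiment 3; a 40-trial illusion block plus 560 composite trials
#' for experiment 4.
#'
#' @param experiment_id 1, 2, 3 or 4.
#' @param seed Integer session seed.
#' @param ... Named overrides (e.g. `n_em_trials`, `n_attention_trials`,
#'   `n_blocks`, `n_trials`, `scale` for proportionally scaled designs).
#' @return Object of class `session_spec`.
#' @export
session_spec <- function(experiment_id, seed = 1L, ...) {
  if (!experiment_id %in% 1:4) stop("experiment_id must be 1..4",
                                    call. = FALSE)
  seed <- stop_if_not_count(seed, "seed", lower = 0L)
  overrides <- list(...)
  for (nm in names(overrides)) {
    if (is.numeric(overrides[[nm]]) &&
        any(overrides[[nm]] != as.integer(overrides[[nm]]))) {
      stop("trial-count override `", nm, "` must be integer", call. = FALSE)
    }
  }
  structure(list(experiment_id = as.integer(experiment_id), seed = seed,
                 overrides = overrides),
            class = "session_spec")
}

spec_get <- function(spec, name, default) {
  v <- spec$overrides[[name]]
  if (is.null(v)) default else as.integer(v)
}

# ---------------------------------------------------------------------------
# Experiment 1: value-conditioned digit distributions and detection trials

digit_sd_cache <- new.env(parent = emptyenv())

#' Probability table for value-conditioned digits
#'
#' Digits come from a normal distribution discretised over the admissible
#' set {1,2,3,4,6,7,8,9} (5 is excluded by design), centred at 7 for the
#' high-value and 3 for the low-value condition, with the SD solved
#' numerically so that the probability of a digit above 5 equals `p_high`
#' (0.75 by default, hence 0.25 below for the low-value condition by
#' symmetry).
#'
#' @param value_condition `"high"` or `"low"`.
#' @param p_high Target probability of digits > 5 in the high condition.
#' @return Named probability vector over the eight admissible digits.
#' @export
digit_probs <- function(value_condition = c("high", "low"), p_high = 0.75) {
  value_condition <- match.arg(value_condition)
  digits <- c(1, 2, 3, 4, 6, 7, 8, 9)
  if (p_high <= 0.5 || p_high >= 1) {
    stop("the digit distribution cannot satisfy P(>5) = ", p_high,
         ": attainable range is (0.5, 1) for a normal centred at 7",
         call. = FALSE)
  }
  key <- sprintf("%.10f", p_high)
  if (is.null(digit_sd_cache[[key]])) {
    frac_high <- function(s) {
      w <- stats::dnorm(digits, mean = 7, sd = s)
      sum(w[digits > 5]) / sum(w)
    }
    digit_sd_cache[[key]] <-
      stats::uniroot(function(s) frac_high(s) - p_high,
                     c(0.2, 100), tol = 1e-10)$root
  }
  s <- digit_sd_cache[[key]]
  centre <- if (value_condition == "high") 7 else 3
  w <- stats::dnorm(digits, mean = centre, sd = s)
  stats::setNames(w / sum(w), digits)
}

#' Draw value-conditioned digits
#'
#' @param value_condition `"high"` or `"low"`.
#' @param n Number of digits to draw.
#' @param p_high See [digit_probs()].
#' @return Integer vector of digits in {1,2,3,4,6,7,8,9}.
#' @export
sample_digit <- function(value_condition = c("high", "low"), n = 1L,
                         p_high = 0.75) {
  pr <- digit_probs(value_condition, p_high)
  as.integer(sample(names(pr), n, replace = TRUE, prob = pr))
}

#' Simulate one digit-detection session
#'
#' Generates the full printed design: 400 detection trials and 100
#' attention trials (50 per location), randomly interleaved. Each detection
#' trial draws a saccade endpoint from the observer's endpoint
#' distribution; the detection response comes from a signal-detection
#' observer whose sensitivity decays linearly with the endpoint-to-target
#' distance and whose criterion carries the value-conditioned shift. Scores
#' follow the published rule (+5 correct absent, +digit correct present,
#' -5 incorrect). Attention trials run two QUEST staircases (one per
#' location) against a Weibull observer at the specified thresholds.
#'
#' @param obs An [observer_exp1()].
#' @param spec A [session_spec()] with `experiment_id = 1`.
#' @return List: `trials` (all trials in presentation order), `detection`
#'   (detection-trial subset), `attention` (attention-trial subset),
#'   `endpoints` (per detection trial), `quest_high`, `quest_low` (final
#'   staircase states), `observer`, `spec`.
#' @export
gen_exp1_session <- function(obs, spec = session_spec(1)) {
  stopifnot(inherits(obs, "observer_exp1"), inherits(spec, "session_spec"))
  n_em <- spec_get(spec, "n_em_trials", 400L)
  n_attn <- spec_get(spec, "n_attention_trials", 100L)
  if (n_attn %% 2L != 0L) stop("attention trials must split evenly per location",
                               call. = FALSE)
  seeds <- derive_seeds(spec$seed, 5L)

  det <- with_seed(seeds[1], {
    present_high <- sample(rep(c(TRUE, FALSE), length.out = n_em))
    present_low <- sample(rep(c(TRUE, FALSE), length.out = n_em))
    probed <- sample(rep(c("high", "low"), length.out = n_em))
    digit_high <- ifelse(present_high, sample_digit("high", n_em), NA)
    digit_low <- ifelse(present_low, sample_digit("low", n_em), NA)
    endpoint_y <- stats::rnorm(n_em, obs$endpoint_bias_mean, obs$endpoint_sd)
    endpoint_x <- stats::rnorm(n_em, 6, 0.5)
    data.frame(type = "detection", location = probed,
               present_high = present_high, present_low = present_low,
               digit_present = ifelse(probed == "high", present_high,
                                      present_low),
               digit_value = ifelse(probed == "high", digit_high, digit_low),
               endpoint_x = endpoint_x, endpoint_y = endpoint_y)
  })
  # SDT response generation for the probed disc
  target_y <- ifelse(det$location == "high", 3, -3)
  dist <- abs(det$endpoint_y - target_y)
  dp <- pmax(0, obs$dprime_at_target - obs$dprime_falloff * dist)
  crit <- ifelse(det$location == "high", obs$criterion_shift_high,
                 obs$criterion_shift_low)
  det <- with_seed(seeds[2], {
    internal <- stats::rnorm(nrow(det), mean = ifelse(det$digit_present, dp, 0))
    resp <- internal > dp / 2 + crit
    lapse <- stats::runif(nrow(det)) < obs$lapse_rate
    resp[lapse] <- stats::runif(sum(lapse)) < 0.5
    det$response <- ifelse(resp, "present", "absent")
    det
  })
  det$score <- vapply(seq_len(nrow(det)), function(i) {
    score_trial(det$response[i], det$digit_present[i], det$digit_value[i])
  }, integer(1))

  # Attention trials: one QUEST staircase per location
  run_staircase <- function(threshold, seed) {
    with_seed(seed, {
      st <- quest_init()
      quest_run(st, function(x) {
        p <- quest_psychometric(log10(x), log10(threshold),
                                st$beta, st$guess, st$lapse)
        stats::runif(1) < p
      }, n_attn %/% 2L)
    })
  }
  q_high <- run_staircase(obs$attn_threshold_high, seeds[3])
  q_low <- run_staircase(obs$attn_threshold_low, seeds[4])
  attn <- data.frame(
    type = "attention",
    location = rep(c("high", "low"), each = n_attn %/% 2L),
    intensity = c(q_high$history$intensity, q_low$history$intensity),
    correct = c(q_high$history$correct, q_low$history$correct))

  trials <- with_seed(seeds[5], {
    order <- sample(c(rep("detection", n_em), rep("attention", n_attn)))
    det$trial_index <- which(order == "detection")
    attn$trial_index <- which(order == "attention")
    common <- union(names(det), names(attn))
    for (nm in setdiff(common, names(det))) det[[nm]] <- NA
    for (nm in setdiff(common, names(attn))) attn[[nm]] <- NA
    all <- rbind(det[common], attn[common])
    all[order(all$trial_index), ]
  })
  rownames(trials) <- NULL

  list(trials = trials, detection = det, attention = attn,
       endpoints = det[, c("endpoint_x", "endpoint_y")],
       quest_high = q_high, quest_low = q_low,
       observer = obs, spec = spec)
}

# ---------------------------------------------------------------------------
# Experiment 2: step-ramp pursuit and speed judgments

#' The balanced speed-judgment design table
#'
#' One block: 216 trials, 36 each of the three hardest comparison speeds
#' (7.5, 8, 8.5 deg/s) and 18 each of the remaining six (4, 6, 7, 9, 10,
#' 12 deg/s), fully crossed with stimulus order (standard first/second) and
#' motion duration (540, 720, 900 ms).
#'
#' @param n_blocks Number of blocks (2 by default: unbiased then biased).
#' @param seed Seed for the trial-order shuffle.
#' @return Data frame: `block`, `biased`, `order`, `duration`, `v_comp`.
#' @export
exp2_design <- function(n_blocks = 2L, seed = 1L) {
  vels <- c(4, 6, 7, 7.5, 8, 8.5, 9, 10, 12)
  reps <- c(18, 18, 18, 36, 36, 36, 18, 18, 18)
  durations <- c(540, 720, 900)
  one <- do.call(rbind, lapply(seq_along(vels), function(i) {
    expand.grid(order = c("standard_first", "standard_second"),
                duration = durations,
                rep = seq_len(reps[i] / 6L),
                KEEP.OUT.ATTRS = FALSE)[, 1:2] |>
      transform(v_comp = vels[i])
  }))
  seeds <- derive_seeds(seed, n_blocks)
  do.call(rbind, lapply(seq_len(n_blocks), function(b) {
    shuffled <- with_seed(seeds[b], one[sample(nrow(one)), ])
    data.frame(block = b, biased = b > 1L, shuffled, row.names = NULL)
  }))
}

# One pursuit interval: step-ramp target, eye with latency, gain, noise and
# error-triggered ballistic catch-up saccades. v_est is the trial's internal
# velocity estimate (drives pursuit).
gen_pursuit_interval <- function(v_target, v_est, duration, obs,
                                 pre_ms = 200) {
  n <- pre_ms + duration + 1L
  t <- seq(-pre_ms, duration)
  target_x <- ifelse(t < 0, 0, -1 + v_target * t / 1000)
  v_eye <- numeric(n)
  moving <- t >= obs$pursuit_latency
  v_eye[moving] <- obs$pursuit_gain * v_est +
    stats::rnorm(sum(moving), 0, obs$motor_noise_sd)
  x <- cumsum(v_eye) / 1000
  # catch-up saccades: brief ballistic raised-cosine velocity pulses that
  # close the position error, triggered when it exceeds 0.5 deg; duration
  # follows a main-sequence-like rule so small saccades still reach
  # realistic peak velocities (peak = 2 x amplitude / duration)
  refractory <- max(50, 1000 / max(obs$catchup_rate, 1e-6))
  last_sacc <- -Inf
  i <- which(t == obs$pursuit_latency)
  while (length(i) == 1L && i <= n - 40L) {
    err <- target_x[i] - x[i]
    if (abs(err) > 0.5 && (t[i] - last_sacc) >= refractory) {
      # extrapolate target motion over the saccade, as real catch-up
      # saccades do, then close the predicted error ballistically
      amp <- err + 0.025 * v_target
      dur <- max(15L, round(21 + 2.2 * abs(amp)))  # main-sequence-like, ms
      idx <- i:(i + dur - 1L)
      prof <- sin(pi * (seq_len(dur) - 0.5) / dur)^2
      v_eye[idx] <- v_eye[idx] + amp * 1000 / sum(prof) * prof
      x <- cumsum(v_eye) / 1000
      last_sacc <- t[i]
      i <- i + dur
    } else {
      i <- i + 5L
    }
  }
  eye_trace(t, x, y = rep(0, n), markers = c(target_onset = 0))
}

#' Simulate one pursuit speed-judgment session
#'
#' Two blocks of 216 trials by default. In every trial, both intervals get
#' an internal velocity estimate (true velocity + trial-level sensory
#' noise); in the biased block the interval in the rewarded position
#' additionally receives the observer's `perceptual_bias`. The estimate
#' drives the pursuit trace of that interval. The speed report compares the
#' two estimates; in the biased block the comparison is additionally tilted
#' by `response_bias` towards the rewarded interval -- at the decision
#' stage only, leaving pursuit untouched.
#'
#' @param obs An [observer_exp2()].
#' @param spec A [session_spec()] with `experiment_id = 2`.
#' @param reward_order `"first"` or `"second"`: the highly rewarded
#'   presentation interval in the biased block.
#' @param traces If FALSE, skip raw trace synthesis and return the
#'   noiseless generator velocities only (fast design checks).
#' @return List: `trials` (design + `report_comp_faster` + generator
#'   truths), `traces` (per trial, list with `standard` and `comparison`
#'   [eye_trace()]s), `reward_order`, `observer`, `spec`.
#' @export
gen_exp2_session <- function(obs, spec = session_spec(2),
                             reward_order = c("first", "second"),
                             traces = TRUE) {
  stopifnot(inherits(obs, "observer_exp2"), inherits(spec, "session_spec"))
  reward_order <- match.arg(reward_order)
  n_blocks <- spec_get(spec, "n_blocks", 2L)
  design <- exp2_design(n_blocks, seed = spec$seed)
  if (!all(design$duration %in% c(540, 720, 900))) {
    stop("durations outside the designed set", call. = FALSE)
  }
  n <- nrow(design)
  seeds <- derive_seeds(spec$seed + 1L, n + 1L)
  v_std <- 8
  reward_pos <- if (reward_order == "first") 1L else 2L

  rows <- vector("list", n)
  trace_list <- if (traces) vector("list", n) else NULL
  for (i in seq_len(n)) {
    tr <- design[i, ]
    res <- with_seed(seeds[i], {
      # interval 1 / interval 2 velocities by stimulus order
      v1 <- if (tr$order == "standard_first") v_std else tr$v_comp
      v2 <- if (tr$order == "standard_first") tr$v_comp else v_std
      est <- c(v1, v2) + stats::rnorm(2, 0, obs$sensory_noise_sd)
      if (tr$biased) est[reward_pos] <- est[reward_pos] + obs$perceptual_bias
      # report: comparison faster?
      comp_pos <- if (tr$order == "standard_first") 2L else 1L
      diff <- est[comp_pos] - est[3L - comp_pos]
      if (tr$biased) {
        diff <- diff + obs$response_bias * (if (comp_pos == reward_pos) 1 else -1)
      }
      report <- if (diff == 0) stats::runif(1) < 0.5 else diff > 0
      tl <- NULL
      if (traces) {
        iv1 <- gen_pursuit_interval(v1, est[1], tr$duration, obs)
        iv2 <- gen_pursuit_interval(v2, est[2], tr$duration, obs)
        tl <- if (tr$order == "standard_first") {
          list(standard = iv1, comparison = iv2)
        } else {
          list(standard = iv2, comparison = iv1)
        }
      }
      list(report = report, est1 = est[1], est2 = est[2], traces = tl)
    })
    rows[[i]] <- data.frame(tr, report_comp_faster = res$report,
                            est_interval1 = res$est1,
                            est_interval2 = res$est2)
    if (traces) trace_list[[i]] <- res$traces
  }
  trials <- do.call(rbind, rows)
  rownames(trials) <- NULL
  trials$trial <- seq_len(n)
  list(trials = trials, traces = trace_list, reward_order = reward_order,
       observer = obs, spec = spec)
}

# ---------------------------------------------------------------------------
# Experiment 3: free viewing with continuous percept report

#' Simulate one free-viewing ambiguity session
#'
#' Each of the 34 trials has three phases: spontaneous viewing with
#' continuous percept report, then two instructed-percept phases ending in
#' a 2500 ms hold. The hidden percept alternates as a two-state process
#' with exponential dwell times (mean `1 / reversal_rate`). Gaze drifts
#' towards the diagnostic point of the *upcoming* percept starting
#' `gaze_lead` ms before the report channel flips, with first-order
#' dynamics (`gaze_tau`) plus Gaussian jitter.
#'
#' @param obs An [observer_exp3()].
#' @param spec A [session_spec()] with `experiment_id = 3`.
#' @param phase1_ms,phase_instructed_ms Phase durations, ms.
#' @param fs Sampling rate, Hz.
#' @return List: `sessions` -- per trial a list with `trace`
#'   ([eye_trace()]), `percept` (per-sample reported percept, "a"/"b"),
#'   `phase` (per-sample phase 1..3), `reversals` (data frame of phase-1
#'   flip times and post-flip percept), `instructed` (percepts instructed
#'   in phases 2-3) -- plus `observer`, `spec`.
#' @export
gen_exp3_session <- function(obs, spec = session_spec(3),
                             phase1_ms = 12000, phase_instructed_ms = 4000,
                             fs = 1000) {
  stopifnot(inherits(obs, "observer_exp3"), inherits(spec, "session_spec"))
  n_trials <- spec_get(spec, "n_trials", 34L)
  seeds <- derive_seeds(spec$seed, n_trials)
  hold_ms <- 2500
  pts <- rbind(a = obs$diagnostic_point_a, b = obs$diagnostic_point_b)

  one_trial <- function(seed) {
    with_seed(seed, {
      total_ms <- phase1_ms + 2 * phase_instructed_ms
      nsamp <- round(total_ms * fs / 1000)
      t <- (seq_len(nsamp) - 1L) * 1000 / fs
      phase <- 1L + (t >= phase1_ms) + (t >= phase1_ms + phase_instructed_ms)

      # phase 1: alternating percept with exponential dwells
      flips <- numeric(0)
      cur <- sample(c("a", "b"), 1)
      start <- c(cur)
      pos <- if (obs$reversal_rate > 0) stats::rexp(1, obs$reversal_rate) * 1000 else Inf
      while (pos < phase1_ms) {
        flips <- c(flips, pos)
        cur <- if (cur == "a") "b" else "a"
        start <- c(start, cur)
        pos <- pos + stats::rexp(1, obs$reversal_rate) * 1000
      }
      # phases 2-3: instructed percepts (one each, counterbalanced order)
      instructed <- sample(c("a", "b"))
      report <- character(nsamp)
      seg_bounds <- c(0, flips, phase1_ms, phase1_ms + phase_instructed_ms,
                      total_ms)
      seg_percept <- c(start, instructed)
      report <- seg_percept[findInterval(t, seg_bounds,
                                         rightmost.closed = TRUE)]

      # gaze channel flips gaze_lead ms before the report channel
      gaze_bounds <- c(0, pmax(0, c(flips, phase1_ms,
                                    phase1_ms + phase_instructed_ms) -
                                 obs$gaze_lead), total_ms)
      gaze_percept <- seg_percept[findInterval(t, gaze_bounds,
                                               rightmost.closed = TRUE)]
      tgt <- pts[gaze_percept, , drop = FALSE]
      # first-order approach to the current target point (recursive filter)
      alpha <- (1000 / fs) / obs$gaze_tau
      smooth1 <- function(z) {
        as.numeric(stats::filter(alpha * z, 1 - alpha, method = "recursive",
                                 init = z[1]))
      }
      x <- smooth1(tgt[, 1]) + stats::rnorm(nsamp, 0, obs$fixation_jitter_sd)
      y <- smooth1(tgt[, 2]) + stats::rnorm(nsamp, 0, obs$fixation_jitter_sd)

      list(trace = eye_trace(t, x, y,
                             markers = c(hold_onset = total_ms - hold_ms)),
           percept = report, phase = phase,
           reversals = data.frame(time = flips,
                                  percept_after = if (length(flips))
                                    start[-1] else character(0)),
           instructed = instructed)
    })
  }
  sessions <- lapply(seeds, one_trial)
  list(sessions = sessions, observer = obs, spec = spec)
}

# ---------------------------------------------------------------------------
# Experiment 4: forced-fixation reports

#' Simulate one forced-fixation session
#'
#' Illusion block: 4 stimuli x 10 repetitions, five per fixation location,
#' reporting the percept (congruent with the fixated diagnostic region with
#' probability `illusion_congruence`). Composite block: 280 trials per
#' fixation location -- 40 repetitions of each difficult face proportion
#' (0.42, 0.48, 0.5, 0.52, 0.58) and 20 of each easy one (0.2, 0.33, 0.66,
#' 0.8) -- with "face" reports drawn from a cumulative Gaussian whose
#' location is the fixation-conditioned PSE.
#'
#' @param obs An [observer_exp4()].
#' @param spec A [session_spec()] with `experiment_id = 4`.
#' @return List: `illusion` and `composite` trial tables, `observer`,
#'   `spec`.
#' @export
gen_exp4_session <- function(obs, spec = session_spec(4)) {
  stopifnot(inherits(obs, "observer_exp4"), inherits(spec, "session_spec"))
  n_ill_reps <- spec_get(spec, "n_illusion_reps", 10L)
  rep_hard <- spec_get(spec, "n_rep_difficult", 40L)
  rep_easy <- spec_get(spec, "n_rep_easy", 20L)
  if (n_ill_reps %% 2L != 0L) {
    stop("illusion repetitions must split evenly across fixations",
         call. = FALSE)
  }
  seeds <- derive_seeds(spec$seed, 2L)

  illusion <- with_seed(seeds[1], {
    d <- expand.grid(stimulus = 1:4,
                     fixation = c("a", "b"),
                     rep = seq_len(n_ill_reps %/% 2L),
                     KEEP.OUT.ATTRS = FALSE)
    d <- d[sample(nrow(d)), c("stimulus", "fixation")]
    d$report_congruent <- stats::runif(nrow(d)) < obs$illusion_congruence
    d
  })
  rownames(illusion) <- NULL

  hard <- c(0.42, 0.48, 0.5, 0.52, 0.58)
  easy <- c(0.2, 0.33, 0.66, 0.8)
  composite <- with_seed(seeds[2], {
    d <- do.call(rbind, lapply(c("a", "b"), function(fx) {
      data.frame(fixation = fx,
                 proportion = c(rep(hard, each = rep_hard),
                                rep(easy, each = rep_easy)))
    }))
    d <- d[sample(nrow(d)), ]
    mu <- ifelse(d$fixation == "a", obs$pse_fix_a, obs$pse_fix_b)
    p_face <- obs$lapse_rate + (1 - 2 * obs$lapse_rate) *
      stats::pnorm((d$proportion - mu) / obs$slope_sd)
    d$report_face <- stats::runif(nrow(d)) < p_face
    d
  })
  rownames(composite) <- NULL

  list(illusion = illusion, composite = composite,
       observer = obs, spec = spec)
}
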