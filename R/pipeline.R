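# End-to-end runners: simulate a cohort, push it through the analysis
# chain of each experiment and return a bundle of per-participant measures
# and group statistics, together with the resolved configuration and seeds
# needed for exact replay.

#' Simulate a session for any experiment
#'
#' Thin dispatcher over the per-experiment generators.
#'
#' @param experiment_id 1..4.
#' @param observer Matching observer object (defaults per experiment).
#' @param seed Session seed.
#' @param ... Passed to the generator (and [session_spec()] overrides).
#' @return The generator's session bundle.
#' @export
simulate_session <- function(experiment_id, observer = NULL, seed = 1L,
                             ...) {
  dots <- list(...)
  spec_args <- dots[names(dots) %in% c("n_em_trials", "n_attention_trials",
                                       "n_blocks", "n_trials",
                                       "n_illusion_reps", "n_rep_difficult",
                                       "n_rep_easy")]
  gen_args <- dots[!names(dots) %in% names(spec_args)]
  spec <- do.call(session_spec,
                  c(list(experiment_id = experiment_id, seed = seed),
                    spec_args))
  switch(as.character(experiment_id),
         "1" = do.call(gen_exp1_session,
                       c(list(obs = observer %||% observer_exp1(),
                              spec = spec), gen_args)),
         "2" = do.call(gen_exp2_session,
                       c(list(obs = observer %||% observer_exp2(),
                              spec = spec), gen_args)),
         "3" = do.call(gen_exp3_session,
                       c(list(obs = observer %||% observer_exp3(),
                              spec = spec), gen_args)),
         "4" = do.call(gen_exp4_session,
                       c(list(obs = observer %||% observer_exp4(),
                              spec = spec), gen_args)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# ---------------------------------------------------------------------------
# Experiment 1 chain

#' Signal-detection summary of one detection-trial table
#'
#' @param detection Detection-trial data frame from [gen_exp1_session()].
#' @return Data frame with one row per location: counts, d-prime,
#'   criterion.
#' @export
sdt_by_location <- function(detection) {
  do.call(rbind, lapply(c("high", "low"), function(loc) {
    d <- detection[detection$location == loc, ]
    hits <- sum(d$digit_present & d$response == "present")
    misses <- sum(d$digit_present & d$response == "absent")
    fas <- sum(!d$digit_present & d$response == "present")
    crs <- sum(!d$digit_present & d$response == "absent")
    r <- dprime_criterion(hits, misses, fas, crs)
    data.frame(location = loc, hits = hits, misses = misses,
               false_alarms = fas, correct_rejections = crs,
               dprime = r$dprime, criterion = r$criterion,
               corrected = r$corrected)
  }))
}

#' Run the full sensitivity-experiment pipeline on a simulated cohort
#'
#' Simulates `n_participants` observers (parameters drawn around the
#' supplied cohort means), computes per-participant signal-detection
#' indices per value location, QUEST thresholds and attentional imbalance,
#' and mean saccade endpoints; then runs the group chain: one-sided tests
#' on endpoint bias, criterion and d-prime differences and imbalance,
#' per-location regressions of d-prime on endpoint, and the gaze
#' residualisation analysis.
#'
#' @param n_participants Cohort size.
#' @param seed Master seed.
#' @param cohort Named list of cohort means / between-participant SDs (see
#'   defaults in the function signature via `modifyList`).
#' @param scale Factor in (0, 1] shrinking trial counts for quick runs.
#' @return List: `participants` (per-participant measures), `group`
#'   (the group-test results), `config`.
#' @export
run_exp1 <- function(n_participants = 60L, seed = 1L, cohort = list(),
                     scale = 1) {
  defaults <- list(endpoint_bias_mean = 0.3, endpoint_between_sd = 0.98,
                   endpoint_sd = 1.0,
                   dprime_at_target = 1.8, dprime_at_target_sd = 0.3,
                   dprime_falloff = 0.4,
                   criterion_shift_high = -0.24, criterion_high_sd = 0.40,
                   criterion_shift_low = -0.09, criterion_low_sd = 0.42,
                   attn_threshold = 0.2, attn_threshold_sd = 0.05,
                   lapse_rate = 0.02)
  ch <- utils::modifyList(defaults, cohort)
  n_participants <- stop_if_not_count(n_participants, "n_participants")
  n_em <- as.integer(round(400 * scale))
  n_attn <- 2L * as.integer(round(50 * scale))
  seeds <- derive_seeds(seed, n_participants)

  per <- lapply(seq_len(n_participants), function(i) {
    obs <- with_seed(seeds[i], observer_exp1(
      endpoint_bias_mean = stats::rnorm(1, ch$endpoint_bias_mean,
                                        ch$endpoint_between_sd),
      endpoint_sd = ch$endpoint_sd,
      dprime_at_target = max(0.2, stats::rnorm(1, ch$dprime_at_target,
                                               ch$dprime_at_target_sd)),
      dprime_falloff = ch$dprime_falloff,
      criterion_shift_high = stats::rnorm(1, ch$criterion_shift_high,
                                          ch$criterion_high_sd),
      criterion_shift_low = stats::rnorm(1, ch$criterion_shift_low,
                                         ch$criterion_low_sd),
      attn_threshold_low = min(0.89, max(0.011,
        stats::rnorm(1, ch$attn_threshold, ch$attn_threshold_sd))),
      attn_threshold_high = min(0.89, max(0.011,
        stats::rnorm(1, ch$attn_threshold, ch$attn_threshold_sd))),
      lapse_rate = ch$lapse_rate))
    sess <- gen_exp1_session(obs, session_spec(1, seed = seeds[i],
                                               n_em_trials = n_em,
                                               n_attention_trials = n_attn))
    sdt <- sdt_by_location(sess$detection)
    m_high <- quest_estimate(sess$quest_high)
    m_low <- quest_estimate(sess$quest_low)
    data.frame(participant = i,
               dprime_high = sdt$dprime[sdt$location == "high"],
               dprime_low = sdt$dprime[sdt$location == "low"],
               criterion_high = sdt$criterion[sdt$location == "high"],
               criterion_low = sdt$criterion[sdt$location == "low"],
               threshold_high = m_high, threshold_low = m_low,
               imbalance = attentional_imbalance(m_low, m_high),
               mean_endpoint = mean(sess$detection$endpoint_y),
               total_score = sum(sess$detection$score))
  })
  per <- do.call(rbind, per)

  group <- list(
    endpoint_bias = t_test(per$mean_endpoint, sides = "greater"),
    criterion_diff = t_test(per$criterion_high, per$criterion_low,
                            paired = TRUE, sides = "less"),
    dprime_diff = t_test(per$dprime_high, per$dprime_low, paired = TRUE,
                         sides = "greater"),
    imbalance = t_test(per$imbalance, sides = "greater"),
    reg_high = linregress(per$dprime_high, per$mean_endpoint),
    reg_low = linregress(per$dprime_low, per$mean_endpoint),
    residualization = residualize_dprime(per$dprime_high, per$dprime_low,
                                         per$mean_endpoint))
  list(participants = per, group = group,
       config = list(n_participants = n_participants, seed = seed,
                     cohort = ch, scale = scale))
}

# ---------------------------------------------------------------------------
# Experiment 2 chain

#' Analyse the pursuit traces and reports of one speed-judgment session
#'
#' For every trial and interval: differentiate + filter, detect and excise
#' saccades, average pursuit velocity 250-500 ms after target onset, and
#' take the oculometric decision. Then fit one psychometric and one
#' oculometric function per block x stimulus-order cell and derive the two
#' bias indices.
#'
#' @param sess Output of [gen_exp2_session()] (with traces).
#' @return List: `trial_measures` (per-trial velocities and decisions),
#'   `fits` (the eight `psy_fit`s), `psychophysical_bias`,
#'   `oculomotor_bias`, `excluded` (unfittable cells).
#' @export
analyze_exp2_session <- function(sess) {
  trials <- sess$trials
  n <- nrow(trials)
  if (is.null(sess$traces)) {
    stop("session carries no traces; regenerate with traces = TRUE",
         call. = FALSE)
  }
  v_std <- numeric(n)
  v_comp <- numeric(n)
  lowq <- logical(n)
  for (i in seq_len(n)) {
    pair <- sess$traces[[i]]
    m <- lapply(pair, function(tr) {
      vel <- differentiate_and_filter(tr)
      # the 30/40 Hz zero-phase filtering caps the acceleration a small
      # catch-up saccade can show, so the acceleration gate is lowered
      # from its raw-signal default here
      ev <- detect_saccades(vel, a_thresh = 1500)
      # catch-up saccades near the trace end hold the boundary value; that
      # span lies outside the 250-500 ms analysis window, so the boundary
      # warning is routine here
      mean_pursuit_velocity(suppressWarnings(desaccade(vel, ev)))
    })
    v_std[i] <- m$standard$value
    v_comp[i] <- m$comparison$value
    lowq[i] <- m$standard$low_quality || m$comparison$low_quality
  }
  oculo <- vapply(seq_len(n), function(i) {
    oculometric_decision(v_std[i], v_comp[i], tie_seed = i)
  }, logical(1))
  tm <- data.frame(trials, v_pursuit_standard = v_std,
                   v_pursuit_comparison = v_comp,
                   oculo_comp_faster = oculo, low_quality = lowq)

  fits <- list()
  excluded <- character(0)
  for (blk in c(FALSE, TRUE)) {
    for (ord in c("standard_first", "standard_second")) {
      sel <- tm$biased == blk & tm$order == ord
      key <- paste0(if (blk) "biased" else "unbiased", "_",
                    if (ord == "standard_first") "o1" else "o2")
      fits[[paste0("psych_", key)]] <-
        fit_psychometric(level = tm$v_comp[sel],
                         response = tm$report_comp_faster[sel])
      fits[[paste0("oculo_", key)]] <-
        fit_psychometric(level = tm$v_comp[sel],
                         response = tm$oculo_comp_faster[sel])
    }
  }
  conv <- vapply(fits, function(f) f$converged, logical(1))
  if (!all(conv)) excluded <- names(fits)[!conv]

  psych_bias <- oculo_bias <- NA_real_
  if (all(conv)) {
    psych_bias <- bias_index(pse(fits$psych_unbiased_o1),
                             pse(fits$psych_unbiased_o2),
                             pse(fits$psych_biased_o1),
                             pse(fits$psych_biased_o2),
                             reward_order = sess$reward_order)
    oculo_bias <- bias_index(pse(fits$oculo_unbiased_o1),
                             pse(fits$oculo_unbiased_o2),
                             pse(fits$oculo_biased_o1),
                             pse(fits$oculo_biased_o2),
                             reward_order = sess$reward_order)
  }
  list(trial_measures = tm, fits = fits,
       psychophysical_bias = psych_bias, oculomotor_bias = oculo_bias,
       excluded = excluded)
}

#' Run the full bias-experiment pipeline on a simulated cohort
#'
#' Simulates `n_participants` pursuit observers (reward order
#' counterbalanced), runs each session through [analyze_exp2_session()],
#' and compares the resulting psychophysical and oculomotor biases against
#' zero and against each other.
#'
#' @param n_participants Cohort size.
#' @param seed Master seed.
#' @param response_bias,perceptual_bias Generative biases, deg/s, applied
#'   to every observer.
#' @param cohort Named list overriding other observer parameters.
#' @param traces Use the raw-trace pursuit chain (TRUE) throughout.
#' @return List: `participants`, `group` (`psych_vs_0`, `oculo_vs_0`,
#'   `paired`), `config`.
#' @export
run_exp2 <- function(n_participants = 20L, seed = 1L, response_bias = 0.9,
                     perceptual_bias = 0, cohort = list(), traces = TRUE) {
  defaults <- list(pursuit_gain = 0.95, gain_sd = 0.05,
                   pursuit_latency = 140, motor_noise_sd = 3,
                   sensory_noise_sd = 0.8, catchup_rate = 2)
  ch <- utils::modifyList(defaults, cohort)
  n_participants <- stop_if_not_count(n_participants, "n_participants")
  seeds <- derive_seeds(seed, n_participants)
  orders <- rep(c("first", "second"), length.out = n_participants)

  per <- lapply(seq_len(n_participants), function(i) {
    obs <- with_seed(seeds[i], observer_exp2(
      pursuit_gain = min(1.2, max(0.5, stats::rnorm(1, ch$pursuit_gain,
                                                    ch$gain_sd))),
      pursuit_latency = ch$pursuit_latency,
      motor_noise_sd = ch$motor_noise_sd,
      sensory_noise_sd = ch$sensory_noise_sd,
      response_bias = response_bias, perceptual_bias = perceptual_bias,
      catchup_rate = ch$catchup_rate))
    sess <- gen_exp2_session(obs, session_spec(2, seed = seeds[i]),
                             reward_order = orders[i], traces = traces)
    an <- analyze_exp2_session(sess)
    data.frame(participant = i, reward_order = orders[i],
               psychophysical_bias = an$psychophysical_bias,
               oculomotor_bias = an$oculomotor_bias,
               n_excluded_fits = length(an$excluded))
  })
  per <- do.call(rbind, per)
  ok <- stats::complete.cases(per[, c("psychophysical_bias",
                                      "oculomotor_bias")])
  if (!all(ok)) {
    message(sum(!ok), " participant(s) excluded (unfittable cells)")
  }
  kept <- per[ok, ]
  group <- list(
    psych_vs_0 = t_test(kept$psychophysical_bias, sides = "greater"),
    oculo_vs_0 = t_test(kept$oculomotor_bias),
    paired = t_test(kept$psychophysical_bias, kept$oculomotor_bias,
                    paired = TRUE))
  list(participants = per, group = group,
       config = list(n_participants = n_participants, seed = seed,
                     response_bias = response_bias,
                     perceptual_bias = perceptual_bias, cohort = ch))
}

# ---------------------------------------------------------------------------
# Experiments 3 and 4 chains

#' Reversal-aligned gaze analysis of one free-viewing session
#'
#' Computes the per-sample gaze distance to the percept-A diagnostic point,
#' aligns windows around phase-1 reversals, and averages within participant
#' by the post-reversal percept.
#'
#' @param sess One participant's output of [gen_exp3_session()].
#' @param window Alignment window, ms.
#' @param decimate Keep every k-th sample (1 = native rate).
#' @return List: `time`, `mean_a`, `mean_b` (participant-mean distance
#'   curves by post-reversal percept), `n_reversals`, `n_dropped`.
#' @export
reversal_gaze_analysis <- function(sess, window = c(-1000, 1000),
                                   decimate = 10L) {
  obs <- sess$observer
  out_time <- NULL
  acc <- list(a = NULL, b = NULL)
  n_rev <- 0L
  n_drop <- 0L
  for (trial in sess$sessions) {
    if (nrow(trial$reversals) == 0L) next
    tr <- trial$trace
    keep <- seq(1L, length(tr$t), by = decimate)
    d <- distance_to_region(
      eye_trace(tr$t[keep], tr$x[keep], tr$y[keep]),
      obs$diagnostic_point_a)
    al <- align_to_reversals(tr$t[keep], d, trial$reversals$time,
                             window = window,
                             labels = trial$reversals$percept_after)
    n_rev <- n_rev + nrow(trial$reversals)
    n_drop <- n_drop + al$n_dropped
    out_time <- al$time
    for (lab in c("a", "b")) {
      rows <- al$rows[al$labels == lab, , drop = FALSE]
      if (nrow(rows)) acc[[lab]] <- rbind(acc[[lab]], rows)
    }
  }
  list(time = out_time,
       mean_a = if (!is.null(acc$a)) colMeans(acc$a),
       mean_b = if (!is.null(acc$b)) colMeans(acc$b),
       n_reversals = n_rev, n_dropped = n_drop)
}

#' Run the free-viewing pipeline on a simulated cohort
#'
#' Per participant, gaze distances to the percept-A diagnostic region are
#' aligned to spontaneous reversals and averaged by post-reversal percept;
#' the two participant-mean curves feed the cluster-based permutation test.
#' Intentional-phase fixations (mean gaze in phases 2-3) feed the
#' label-permutation test on gaze positions.
#'
#' @param n_participants Cohort size.
#' @param seed Master seed.
#' @param observer Template [observer_exp3()] applied to every participant.
#' @param n_trials Trials per participant.
#' @param n_perm Permutations for both tests.
#' @param decimate Trace decimation for the aligned analysis.
#' @return List: `cluster` (a `cluster_result`), `fixation_perm` (a
#'   `gaze_perm_result`), `curves`, `config`.
#' @export
run_exp3 <- function(n_participants = 16L, seed = 1L,
                     observer = observer_exp3(), n_trials = 34L,
                     n_perm = 1000L, decimate = 10L) {
  n_participants <- stop_if_not_count(n_participants, "n_participants")
  seeds <- derive_seeds(seed, n_participants)
  curves_a <- curves_b <- NULL
  fix_a <- fix_b <- matrix(NA_real_, n_participants, 2)
  tme <- NULL
  for (i in seq_len(n_participants)) {
    sess <- gen_exp3_session(observer,
                             session_spec(3, seed = seeds[i],
                                          n_trials = n_trials))
    rga <- reversal_gaze_analysis(sess, decimate = decimate)
    if (!is.null(rga$mean_a) && !is.null(rga$mean_b)) {
      curves_a <- rbind(curves_a, rga$mean_a)
      curves_b <- rbind(curves_b, rga$mean_b)
      tme <- rga$time
    }
    # intentional phases: mean gaze per instructed percept
    ga <- gb <- c(0, 0); na <- nb <- 0L
    for (trial in sess$sessions) {
      for (ph in 2:3) {
        sel <- trial$phase == ph
        pt <- c(mean(trial$trace$x[sel]), mean(trial$trace$y[sel]))
        if (trial$instructed[ph - 1L] == "a") {
          ga <- ga + pt; na <- na + 1L
        } else {
          gb <- gb + pt; nb <- nb + 1L
        }
      }
    }
    fix_a[i, ] <- ga / na
    fix_b[i, ] <- gb / nb
  }
  if (is.null(curves_a) || nrow(curves_a) < 2L) {
    stop("too few participants with reversals for the cluster test",
         call. = FALSE)
  }
  cluster <- cluster_permutation(curves_a, curves_b, time = tme,
                                 n_perm = n_perm, seed = seed)
  fixation_perm <- gaze_label_permutation(fix_a, fix_b,
                                          statistic = "centroid_distance",
                                          n_perm = n_perm, seed = seed)
  list(cluster = cluster, fixation_perm = fixation_perm,
       curves = list(time = tme, a = curves_a, b = curves_b),
       config = list(n_participants = n_participants, seed = seed,
                     n_trials = n_trials, n_perm = n_perm))
}

#' Run the forced-fixation pipeline on a simulated cohort
#'
#' Illusion block: per-participant proportion of reports congruent with the
#' fixated diagnostic region, tested against chance (t-test and Wilcoxon).
#' Composite block: one psychometric fit per fixation condition per
#' participant; PSE differences tested with a paired t-test.
#'
#' @param n_participants Cohort size.
#' @param seed Master seed.
#' @param observer Template [observer_exp4()].
#' @return List: `participants`, `group` (`illusion_t`,
#'   `illusion_wilcoxon`, `pse_t`), `config`.
#' @export
run_exp4 <- function(n_participants = 24L, seed = 1L,
                     observer = observer_exp4()) {
  n_participants <- stop_if_not_count(n_participants, "n_participants")
  seeds <- derive_seeds(seed, n_participants)
  per <- lapply(seq_len(n_participants), function(i) {
    sess <- gen_exp4_session(observer, session_spec(4, seed = seeds[i]))
    fit_a <- fit_psychometric(
      level = sess$composite$proportion[sess$composite$fixation == "a"],
      response = sess$composite$report_face[sess$composite$fixation == "a"])
    fit_b <- fit_psychometric(
      level = sess$composite$proportion[sess$composite$fixation == "b"],
      response = sess$composite$report_face[sess$composite$fixation == "b"])
    data.frame(participant = i,
               prop_congruent = mean(sess$illusion$report_congruent),
               pse_eyes = if (fit_a$converged) pse(fit_a) else NA_real_,
               pse_house = if (fit_b$converged) pse(fit_b) else NA_real_)
  })
  per <- do.call(rbind, per)
  ok <- stats::complete.cases(per)
  kept <- per[ok, ]
  group <- list(
    illusion_t = t_test(kept$prop_congruent, mu0 = 0.5, sides = "greater"),
    illusion_wilcoxon = wilcoxon_signed_rank(kept$prop_congruent,
                                             mu0 = 0.5, sides = "greater"),
    pse_t = t_test(kept$pse_house, kept$pse_eyes, paired = TRUE),
    mean_gap = mean(kept$pse_house - kept$pse_eyes))
  list(participants = per, group = group,
       config = list(n_participants = n_participants, seed = seed))
}

# ---------------------------------------------------------------------------
# Flat key-value run configuration

#' Read a flat key-value configuration file
#'
#' Lines of the form `key = value` or `key: value`; `#` starts a comment.
#' Values that parse as numbers become numeric.
#'
#' @param path Configuration file.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  raw <- readLines(path)
  raw <- sub("#.*$", "", raw)
  raw <- trimws(raw)
  raw <- raw[nzchar(raw)]
  out <- list()
  for (ln in raw) {
    m <- regmatches(ln, regexec("^([^=:]+)[=:](.*)$", ln))[[1]]
    if (length(m) != 3L) stop("malformed config line: ", ln, call. = FALSE)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    out[[key]] <- if (!is.na(num)) num else val
  }
  out
}

#' Write a result bundle as JSON
#'
#' Serialises group statistics (t-tests, permutation results) with the
#' resolved configuration for exact replay.
#'
#' @param bundle A result list from one of the `run_exp*` functions.
#' @param path Output JSON path.
#' @export
write_result_json <- function(bundle, path) {
  strip <- function(x) {
    if (inherits(x, "gb_ttest")) {
      list(t = x$t, df = x$df, p = x$p, sides = x$sides,
           cohens_d = x$cohens_d, d_ci_95 = x$d_ci, bf10 = x$bf10)
    } else if (inherits(x, "cluster_result")) {
      list(t_sum = x$t_sum, t_crit = x$t_crit, p = x$p, window = x$window)
    } else if (inherits(x, "gaze_perm_result")) {
      list(delta_gaze = x$delta_gaze, delta_gaze_crit = x$delta_gaze_crit,
           p = x$p)
    } else if (inherits(x, "lm")) {
      list(coefficients = stats::coef(x))
    } else if (is.list(x) && !is.data.frame(x)) {
      lapply(x, strip)
    } else if (is.data.frame(x)) {
      NULL  # tables go to CSV, not the JSON record
    } else {
      x
    }
  }
  jsonlite::write_json(strip(bundle), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}
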