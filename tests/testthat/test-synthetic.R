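test_that("the detection session reproduces the printed architecture", {
  sess <- gen_exp1_session(observer_exp1(), session_spec(1, seed = 3))
  expect_identical(nrow(sess$trials), 500L)
  expect_identical(nrow(sess$detection), 400L)
  expect_identical(nrow(sess$attention), 100L)
  expect_identical(unname(table(sess$attention$location)["high"]), 50L)
  expect_identical(unname(table(sess$attention$location)["low"]), 50L)
  # probed location balanced; digit presence balanced per disc
  expect_true(all(table(sess$detection$location) == 200L))
  expect_identical(sum(sess$detection$present_high), 200L)
  expect_identical(sum(sess$detection$present_low), 200L)
  # scores follow the printed rule on every trial
  ok <- vapply(seq_len(400), function(i) {
    d <- sess$detection[i, ]
    d$score == score_trial(d$response, d$digit_present, d$digit_value)
  }, logical(1))
  expect_true(all(ok))
})

test_that("sessions are deterministic in (observer, spec, seed)", {
  a <- gen_exp1_session(observer_exp1(), session_spec(1, seed = 99))
  b <- gen_exp1_session(observer_exp1(), session_spec(1, seed = 99))
  expect_identical(a$trials, b$trials)
  c2 <- gen_exp2_session(observer_exp2(), session_spec(2, seed = 5),
                         traces = FALSE)
  d2 <- gen_exp2_session(observer_exp2(), session_spec(2, seed = 5),
                         traces = FALSE)
  expect_identical(c2$trials, d2$trials)
  e4 <- gen_exp4_session(observer_exp4(), session_spec(4, seed = 8))
  f4 <- gen_exp4_session(observer_exp4(), session_spec(4, seed = 8))
  expect_identical(e4$composite, f4$composite)
})

test_that("value-conditioned digits match the printed distribution", {
  d_high <- withr::with_seed(1, sample_digit("high", 1e5))
  expect_gt(mean(d_high > 5), 0.70)
  expect_lt(mean(d_high > 5), 0.80)
  expect_identical(names(which.max(table(d_high))), "7")
  d_low <- withr::with_seed(2, sample_digit("low", 1e5))
  expect_gt(mean(d_low > 5), 0.20)
  expect_lt(mean(d_low > 5), 0.30)
  expect_identical(names(which.max(table(d_low))), "3")
  expect_false(any(d_high == 5) || any(d_low == 5))
  expect_error(digit_probs("high", p_high = 0.4), "cannot satisfy")
})

test_that("the speed-judgment block structure matches the printed design", {
  sess <- gen_exp2_session(observer_exp2(), session_spec(2, seed = 1),
                           traces = FALSE)
  b1 <- sess$trials[sess$trials$block == 1, ]
  expect_identical(nrow(b1), 216L)
  counts <- table(b1$v_comp)
  expect_true(all(counts[c("7.5", "8", "8.5")] == 36L))
  expect_true(all(counts[c("4", "6", "7", "9", "10", "12")] == 18L))
  expect_true(all(b1$duration %in% c(540, 720, 900)))
  # order x duration balance within each velocity
  tab <- table(b1$v_comp, b1$order, b1$duration)
  expect_true(all(tab[c("7.5", "8", "8.5"), , ] == 6L))
  expect_true(all(tab[c("4", "6", "7", "9", "10", "12"), , ] == 3L))
})

test_that("a noise-free unit-gain observer is ideal downstream", {
  obs <- observer_exp2(pursuit_gain = 1, motor_noise_sd = 0,
                       sensory_noise_sd = 0, response_bias = 0,
                       perceptual_bias = 0)
  sess <- gen_exp2_session(obs, session_spec(2, seed = 2), traces = FALSE)
  neq <- sess$trials$v_comp != 8
  expect_identical(sess$trials$report_comp_faster[neq],
                   sess$trials$v_comp[neq] > 8)
})

test_that("a pure response bias separates report from pursuit estimates", {
  # closed form of the generating model: the report PSEs shift by the
  # response bias while the internal estimates (which drive pursuit) stay
  # unbiased
  obs <- observer_exp2(response_bias = 1.2, perceptual_bias = 0,
                       sensory_noise_sd = 0.8)
  sess <- gen_exp2_session(obs, session_spec(2, seed = 3),
                           reward_order = "first", traces = FALSE)
  tr <- sess$trials
  fits <- lapply(split(tr, list(tr$biased, tr$order)), function(d) {
    fit_psychometric(level = d$v_comp, response = d$report_comp_faster)
  })
  p <- vapply(fits, pse, numeric(1))
  psych <- bias_index(p[["FALSE.standard_first"]],
                      p[["FALSE.standard_second"]],
                      p[["TRUE.standard_first"]],
                      p[["TRUE.standard_second"]], "first")
  expect_equal(psych, 2 * 1.2, tolerance = 0.5)
  # internal estimates are unbiased between intervals
  biased <- tr[tr$biased, ]
  est_first_minus_second <- biased$est_interval1 - biased$est_interval2
  v_first_minus_second <- ifelse(biased$order == "standard_first",
                                 8 - biased$v_comp, biased$v_comp - 8)
  expect_lt(abs(mean(est_first_minus_second - v_first_minus_second)), 0.15)
})

test_that("the free-viewing session has the printed trial count and phases", {
  obs <- observer_exp3(reversal_rate = 0.4)
  sess <- gen_exp3_session(obs, session_spec(3, seed = 4, n_trials = 34L))
  expect_identical(length(sess$sessions), 34L)
  s1 <- sess$sessions[[1]]
  expect_setequal(unique(s1$phase), 1:3)
  expect_identical(sort(s1$instructed), c("a", "b"))
  # the final hold marker sits 2500 ms before the end
  expect_equal(unname(s1$trace$markers["hold_onset"]),
               max(s1$trace$t) - 2499, tolerance = 2)
})

test_that("a zero reversal rate yields no reversals and an empty alignment", {
  obs <- observer_exp3(reversal_rate = 1e-9)
  sess <- gen_exp3_session(obs, session_spec(3, seed = 5, n_trials = 3L))
  n_rev <- sum(vapply(sess$sessions, function(s) nrow(s$reversals),
                      integer(1)))
  expect_identical(n_rev, 0L)
  rga <- reversal_gaze_analysis(sess)
  expect_identical(rga$n_reversals, 0L)
  expect_null(rga$mean_a)
})

test_that("gaze approaches the upcoming percept before the report flips", {
  obs <- observer_exp3(reversal_rate = 0.3, gaze_lead = 300,
                       fixation_jitter_sd = 0.2)
  sess <- gen_exp3_session(obs, session_spec(3, seed = 6, n_trials = 12L))
  rga <- reversal_gaze_analysis(sess)
  pre <- rga$time < 0 & rga$time > -250
  # distance to region A is already smaller pre-flip for A-reversals
  expect_lt(mean(rga$mean_a[pre]), mean(rga$mean_b[pre]))
})

test_that("the forced-fixation blocks match the printed design", {
  sess <- gen_exp4_session(observer_exp4(), session_spec(4, seed = 7))
  expect_identical(nrow(sess$illusion), 40L)
  expect_true(all(table(sess$illusion$stimulus, sess$illusion$fixation) == 5L))
  expect_identical(nrow(sess$composite), 560L)
  expect_true(all(table(sess$composite$fixation) == 280L))
  tab <- table(sess$composite$proportion,
               sess$composite$fixation)
  hard <- c("0.42", "0.48", "0.5", "0.52", "0.58")
  easy <- c("0.2", "0.33", "0.66", "0.8")
  expect_true(all(tab[hard, ] == 40L))
  expect_true(all(tab[easy, ] == 20L))
})

test_that("equal fixation PSEs produce a near-zero downstream gap", {
  obs <- observer_exp4(pse_fix_a = 0.46, pse_fix_b = 0.46)
  sess <- gen_exp4_session(obs, session_spec(4, seed = 8))
  comp <- sess$composite
  f_a <- fit_psychometric(level = comp$proportion[comp$fixation == "a"],
                          response = comp$report_face[comp$fixation == "a"])
  f_b <- fit_psychometric(level = comp$proportion[comp$fixation == "b"],
                          response = comp$report_face[comp$fixation == "b"])
  expect_lt(abs(pse_difference_exp4(f_a, f_b)), 0.02)
})

test_that("session specs validate their inputs", {
  expect_error(session_spec(5), "1..4")
  expect_error(session_spec(1, seed = 1, n_em_trials = 10.5), "integer")
  expect_error(gen_exp1_session(observer_exp1(),
                                session_spec(1, n_attention_trials = 7L)),
               "evenly")
  expect_error(observer_exp1(endpoint_sd = 0), "endpoint_sd")
  expect_error(observer_exp2(pursuit_gain = 1.5), "pursuit_gain")
  expect_error(observer_exp4(pse_fix_a = 1.2), "pse_fix_a")
})
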