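# Signal-detection analysis: d-prime and criterion per value location,
# trial scoring, and the gaze-endpoint residualisation that asks whether a
# sensitivity difference survives controlling for where people looked.

#' Sensitivity and criterion from detection counts
#'
#' Computes `d' = qnorm(H) - qnorm(F)` and criterion
#' `c = -(qnorm(H) + qnorm(F)) / 2` from hit and false-alarm counts. Extreme
#' rates (0 or 1) make the quantiles infinite; the log-linear correction adds
#' 0.5 to every cell and 1 to every denominator.
#'
#' @param hits,misses,false_alarms,correct_rejections Non-negative counts.
#' @param correction `"log_linear"` applies the +0.5/+1 correction whenever a
#'   rate is 0 or 1 (or always if `always_correct`); `"none"` errors on
#'   extreme rates.
#' @param always_correct Apply the log-linear correction unconditionally.
#' @return List with `dprime`, `criterion`, `hit_rate`, `fa_rate`,
#'   `corrected` (logical flag).
#' @export
dprime_criterion <- function(hits, misses, false_alarms, correct_rejections,
                             correction = c("log_linear", "none"),
                             always_correct = FALSE) {
  correction <- match.arg(correction)
  counts <- c(hits = hits, misses = misses, false_alarms = false_alarms,
              correct_rejections = correct_rejections)
  if (any(!is.finite(counts)) || any(counts < 0)) {
    stop("all counts must be non-negative numbers", call. = FALSE)
  }
  n_signal <- hits + misses
  n_noise <- false_alarms + correct_rejections
  if (n_signal == 0 || n_noise == 0) {
    stop("need at least one signal and one noise trial", call. = FALSE)
  }
  h <- hits / n_signal
  f <- false_alarms / n_noise
  extreme <- h %in% c(0, 1) || f %in% c(0, 1)
  corrected <- FALSE
  if ((extreme && correction == "log_linear") ||
      (always_correct && correction == "log_linear")) {
    h <- (hits + 0.5) / (n_signal + 1)
    f <- (false_alarms + 0.5) / (n_noise + 1)
    corrected <- TRUE
  } else if (extreme) {
    stop("hit or false-alarm rate is 0 or 1; use correction = \"log_linear\"",
         call. = FALSE)
  }
  zh <- stats::qnorm(h)
  zf <- stats::qnorm(f)
  list(dprime = zh - zf, criterion = -(zh + zf) / 2,
       hit_rate = h, fa_rate = f, corrected = corrected)
}

#' Score a single digit-detection trial
#'
#' Correct "absent" responses earn 5 points; correct "present" responses earn
#' the digit's value; any incorrect response costs 5 points. Session totals
#' convert to money at 500 points per euro.
#'
#' @param response `"present"` or `"absent"`.
#' @param digit_present Logical, whether a digit was embedded.
#' @param digit_value Digit value in `{1,2,3,4,6,7,8,9}`; required when
#'   `digit_present` is TRUE, ignored otherwise.
#' @return Integer points for the trial.
#' @export
score_trial <- function(response, digit_present, digit_value = NA) {
  response <- match.arg(response, c("present", "absent"))
  if (!is.logical(digit_present) || length(digit_present) != 1L ||
      is.na(digit_present)) {
    stop("`digit_present` must be TRUE or FALSE", call. = FALSE)
  }
  if (digit_present) {
    if (is.na(digit_value) || !(digit_value %in% c(1:4, 6:9))) {
      stop("`digit_value` must be in {1,2,3,4,6,7,8,9} when a digit is present",
           call. = FALSE)
    }
    if (response == "present") as.integer(digit_value) else -5L
  } else {
    if (response == "absent") 5L else -5L
  }
}

#' Compare sensitivity between value locations after controlling for gaze
#'
#' Regresses per-participant d-prime on the mean signed vertical saccade
#' endpoint (positive towards the high-value location) in a single pooled
#' model with location-specific slopes and a common intercept:
#' `d' = a + b_high * endpoint * I(high) + b_low * endpoint * I(low)`.
#' The common intercept is essential: with separate per-location
#' intercepts, any mean d-prime difference would be absorbed by the
#' intercepts and the residual comparison would be zero by construction.
#' With a shared intercept, the residuals retain whatever part of the
#' sensitivity difference the gaze-sensitivity regression cannot explain.
#'
#' Two group tests are returned: a paired test on the residual difference
#' (does a sensitivity difference survive controlling for gaze?) and a
#' reduction test on `raw difference - residual difference` (did
#' controlling for gaze significantly reduce the difference?).
#'
#' @param dprime_high,dprime_low Numeric vectors, d-prime per participant at
#'   the high- and low-value location.
#' @param endpoints Mean signed vertical endpoint per participant, degrees.
#' @param sides Sidedness for both tests (`"greater"` tests
#'   residual_high > residual_low and raw > residual difference).
#' @return List with the pooled regression `fit`, `residuals` (per
#'   participant, per location), and the two `t_test` results
#'   (`residual_test`, `reduction_test`).
#' @export
residualize_dprime <- function(dprime_high, dprime_low, endpoints,
                               sides = "greater") {
  n <- length(endpoints)
  if (length(dprime_high) != n || length(dprime_low) != n) {
    stop("inputs must have one value per participant", call. = FALSE)
  }
  if (n < 3L) stop("need at least 3 participants", call. = FALSE)
  if (stats::var(endpoints) == 0) {
    stop("endpoints are constant; regression on gaze is degenerate",
         call. = FALSE)
  }
  dp <- c(dprime_high, dprime_low)
  x_high <- c(endpoints, rep(0, n))
  x_low <- c(rep(0, n), endpoints)
  fit <- stats::lm(dp ~ x_high + x_low)
  res <- stats::resid(fit)
  res_high <- res[seq_len(n)]
  res_low <- res[n + seq_len(n)]
  raw_diff <- dprime_high - dprime_low
  res_diff <- res_high - res_low
  list(
    fit = fit,
    residuals = data.frame(high = res_high, low = res_low),
    residual_test = t_test(res_high, res_low, paired = TRUE, sides = sides),
    reduction_test = t_test(raw_diff - res_diff, sides = sides)
  )
}
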