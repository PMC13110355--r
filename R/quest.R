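# Bayesian adaptive (QUEST) contrast staircase.
#
# The staircase maintains a discretised posterior over the log10 Michelson
# contrast threshold of an assumed Weibull psychometric function. Intensities
# are placed at the posterior mean and the threshold is read out as the
# posterior mean, mapped back to linear contrast.

#' Initialise a QUEST staircase state
#'
#' The prior over the threshold is Gaussian in log10 contrast, centred at
#' `log10(prior_mean)` with standard deviation `prior_sd` log units,
#' discretised on a regular grid and normalised.
#'
#' @param prior_mean Prior threshold guess, linear Michelson contrast.
#' @param prior_sd Prior standard deviation in log10-contrast units.
#' @param clamp Length-2 vector: admissible range of proposed contrasts.
#' @param grid_n Number of grid points for the posterior support.
#' @param grid_range Length-2 vector of log10 contrast bounds for the grid.
#' @param beta,guess,lapse Assumed Weibull slope, guess rate and lapse rate.
#' @return An object of class `quest_state`.
#' @export
quest_init <- function(prior_mean = 0.2, prior_sd = 0.3,
                       clamp = c(0.01, 0.9), grid_n = 500L,
                       grid_range = c(-3, 0.5),
                       beta = 3.5, guess = 0.5, lapse = 0.02) {
  stop_if_not_number(prior_mean, "prior_mean", lower = 1e-6)
  stop_if_not_number(prior_sd, "prior_sd", lower = 1e-6)
  if (length(clamp) != 2L || any(!is.finite(clamp)) ||
      clamp[1] <= 0 || clamp[2] >= 1 || clamp[1] >= clamp[2]) {
    stop("`clamp` must be an increasing pair within (0, 1)", call. = FALSE)
  }
  grid_n <- stop_if_not_count(grid_n, "grid_n", lower = 3L)
  if (grid_range[1] >= grid_range[2]) stop("empty grid", call. = FALSE)

  grid <- seq(grid_range[1], grid_range[2], length.out = grid_n)
  prior <- stats::dnorm(grid, mean = log10(prior_mean), sd = prior_sd)
  prior <- prior / sum(prior)

  structure(
    list(grid = grid, prior = prior, posterior = prior,
         beta = beta, guess = guess, lapse = lapse,
         clamp = clamp,
         history = data.frame(intensity = numeric(0), correct = logical(0))),
    class = "quest_state")
}

# Weibull probability-correct at log10 intensity x for log10 threshold t.
quest_psychometric <- function(x, threshold, beta, guess, lapse) {
  guess + (1 - guess - lapse) * (1 - exp(-10 ^ (beta * (x - threshold))))
}

#' Update a QUEST posterior with one trial outcome
#'
#' Pointwise Bayes: the posterior is multiplied by the Weibull likelihood of
#' the observed binary outcome at the presented intensity, then renormalised.
#'
#' @param state A `quest_state`.
#' @param intensity Presented linear Michelson contrast, within the clamp.
#' @param correct Logical, whether the response was correct.
#' @return The updated `quest_state`.
#' @export
quest_update <- function(state, intensity, correct) {
  stopifnot(inherits(state, "quest_state"))
  stop_if_not_number(intensity, "intensity",
                     lower = state$clamp[1], upper = state$clamp[2])
  if (!is.logical(correct) || length(correct) != 1L || is.na(correct)) {
    stop("`correct` must be TRUE or FALSE", call. = FALSE)
  }
  p_correct <- quest_psychometric(log10(intensity), state$grid,
                                  state$beta, state$guess, state$lapse)
  lik <- if (correct) p_correct else 1 - p_correct
  post <- state$posterior * lik
  total <- sum(post)
  if (total <= 0 || !is.finite(total)) {
    stop("posterior update degenerate (zero likelihood everywhere)",
         call. = FALSE)
  }
  state$posterior <- post / total
  state$history <- rbind(state$history,
                         data.frame(intensity = intensity, correct = correct))
  state
}

#' Next intensity proposed by the staircase
#'
#' Posterior-mean placement: the mean of the posterior over log10 threshold,
#' mapped to linear contrast and clamped to the admissible range.
#'
#' @param state A `quest_state`.
#' @param rule `"mean"` (default) or `"mode"` placement.
#' @return Proposed linear Michelson contrast.
#' @export
quest_next <- function(state, rule = c("mean", "mode")) {
  stopifnot(inherits(state, "quest_state"))
  rule <- match.arg(rule)
  logc <- if (rule == "mean") {
    sum(state$grid * state$posterior)
  } else {
    state$grid[which.max(state$posterior)]
  }
  min(max(10 ^ logc, state$clamp[1]), state$clamp[2])
}

#' Threshold estimate from the posterior mean
#'
#' @param state A `quest_state`.
#' @return Threshold estimate in linear Michelson contrast (the posterior
#'   mean in log10 space, exponentiated; unclamped).
#' @export
quest_estimate <- function(state) {
  stopifnot(inherits(state, "quest_state"))
  10 ^ sum(state$grid * state$posterior)
}

#' Run a staircase against a response-generating function
#'
#' Convenience driver: proposes, queries `respond(intensity)` for a logical
#' outcome, updates, for `n_trials` trials.
#'
#' @param state A `quest_state`.
#' @param respond Function of one argument (intensity) returning TRUE/FALSE.
#' @param n_trials Number of trials.
#' @return Final `quest_state` (history holds the trial stream).
#' @export
quest_run <- function(state, respond, n_trials) {
  n_trials <- stop_if_not_count(n_trials, "n_trials")
  for (i in seq_len(n_trials)) {
    x <- quest_next(state)
    state <- quest_update(state, x, isTRUE(respond(x)))
  }
  state
}

#' Attentional imbalance between two contrast thresholds
#'
#' Normalised threshold difference `(m_low - m_high) / (m_low + m_high)`.
#' Values above zero indicate higher thresholds (worse contrast sensitivity)
#' at the low-value location.
#'
#' @param m_low,m_high Positive contrast thresholds at the low- and
#'   high-value location.
#' @return Imbalance score in (-1, 1).
#' @export
attentional_imbalance <- function(m_low, m_high) {
  stop_if_not_number(m_low, "m_low")
  stop_if_not_number(m_high, "m_high")
  if (m_low <= 0 || m_high <= 0) {
    stop("thresholds must be positive", call. = FALSE)
  }
  (m_low - m_high) / (m_low + m_high)
}
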