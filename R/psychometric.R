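# Psychometric / oculometric function fitting and the PSE-based bias
# indices. The model is a cumulative Gaussian with bounded guess and lapse
# rates, fit by penalised maximum likelihood with deterministic multi-start.

#' Bin trial-level binary responses by stimulus level
#'
#' @param level Stimulus level per trial.
#' @param response Logical (or 0/1) response per trial.
#' @return Data frame with `level`, `n`, `k` sorted by level.
#' @export
bin_responses <- function(level, response) {
  if (length(level) != length(response)) stop("lengths differ", call. = FALSE)
  response <- as.logical(response)
  lv <- sort(unique(level))
  data.frame(level = lv,
             n = vapply(lv, function(l) sum(level == l), integer(1)),
             k = vapply(lv, function(l) sum(response[level == l]),
                        integer(1)))
}

psy_fun <- function(x, mu, sigma, gamma, lambda) {
  gamma + (1 - gamma - lambda) * stats::pnorm((x - mu) / sigma)
}

# Negative penalised log-likelihood. gamma and lambda carry a weak
# Beta(1, 19) prior that keeps small-n fits off the asymptote boundary.
psy_nll <- function(par, level, n, k) {
  mu <- par[1]; sigma <- exp(par[2])
  # clamp to the admissible asymptote range: L-BFGS-B probes finite
  # differences just outside its box, where the Beta log-prior is -Inf
  gamma <- min(max(par[3], 0), 0.1)
  lambda <- min(max(par[4], 0), 0.1)
  p <- psy_fun(level, mu, sigma, gamma, lambda)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  ll <- sum(k * log(p) + (n - k) * log(1 - p))
  prior <- stats::dbeta(pmin(gamma / 0.1, 1 - 1e-9), 1, 19, log = TRUE) +
    stats::dbeta(pmin(lambda / 0.1, 1 - 1e-9), 1, 19, log = TRUE)
  -(ll + prior)
}

#' Fit a cumulative-Gaussian psychometric function
#'
#' Maximum-likelihood fit of
#' `psi(x) = gamma + (1 - gamma - lambda) * Phi((x - mu) / sigma)` with
#' `gamma, lambda` bounded in `[0, 0.1]` and stabilised by a weak
#' Beta(1, 19) prior. Optimisation uses L-BFGS-B from five deterministic
#' starting points. Degenerate data (all responses identical, or fewer than
#' three levels) yield `converged = FALSE` with a diagnostic, never a silent
#' number.
#'
#' @param data Data frame with columns `level`, `n`, `k` (see
#'   [bin_responses()]), or trial-level vectors via `level`/`response`.
#' @param level,response Optional trial-level alternative to `data`.
#' @param fix_asymptotes If TRUE, fix `gamma = lambda = 0`.
#' @return Object of class `psy_fit`: `mu`, `sigma`, `gamma`, `lambda`,
#'   `loglik`, `converged`, `pse`, `diagnostic`, plus the binned `data`.
#' @export
fit_psychometric <- function(data = NULL, level = NULL, response = NULL,
                             fix_asymptotes = FALSE) {
  if (is.null(data)) data <- bin_responses(level, response)
  stopifnot(all(c("level", "n", "k") %in% names(data)))
  if (any(data$k < 0 | data$k > data$n)) {
    stop("counts must satisfy 0 <= k <= n", call. = FALSE)
  }
  data <- data[data$n > 0, ]
  out <- structure(
    list(mu = NA_real_, sigma = NA_real_, gamma = NA_real_,
         lambda = NA_real_, loglik = NA_real_, converged = FALSE,
         pse = NA_real_, diagnostic = "", data = data),
    class = "psy_fit")
  if (nrow(data) < 3L) {
    out$diagnostic <- "fewer than 3 distinct stimulus levels"
    return(out)
  }
  prop <- data$k / data$n
  if (all(data$k == 0) || all(data$k == data$n)) {
    out$diagnostic <- "all responses identical; location unidentified"
    return(out)
  }
  rng <- diff(range(data$level))
  w <- stats::weighted.mean(data$level, data$n * prop * (1 - prop) + 1e-9)
  starts <- list(
    c(w, log(rng / 4)),
    c(stats::weighted.mean(data$level, data$n), log(rng / 2)),
    c(min(data$level) + rng / 3, log(rng / 8)),
    c(max(data$level) - rng / 3, log(rng / 3)),
    c(w, log(rng))
  )
  lower <- c(min(data$level) - 2 * rng, log(rng * 1e-3), 0, 0)
  upper <- c(max(data$level) + 2 * rng, log(rng * 10), 0.1, 0.1)
  # fixed parameters cannot sit in the L-BFGS-B box (equal bounds break its
  # finite-difference gradient); optimise the active subset only
  active <- if (fix_asymptotes) 1:2 else 1:4
  objective <- function(p_act) {
    par <- c(p_act, 0, 0)[1:4]
    psy_nll(par, data$level, data$n, data$k)
  }
  best <- NULL
  for (s in starts) {
    par0 <- c(s, 0.01, 0.01)[active]
    fit <- tryCatch(
      stats::optim(par0, objective, method = "L-BFGS-B",
                   lower = lower[active], upper = upper[active],
                   control = list(maxit = 500L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (is.null(best)) {
    out$diagnostic <- "optimisation failed from all starts"
    return(out)
  }
  best$par <- c(best$par, 0, 0)[1:4]
  mu <- best$par[1]; sigma <- exp(best$par[2])
  # Honest convergence: the location must be identified within the tested
  # range, not pinned at a box bound.
  at_bound <- mu <= lower[1] + 1e-6 || mu >= upper[1] - 1e-6 ||
    best$par[2] >= upper[2] - 1e-6
  out$mu <- mu
  out$sigma <- sigma
  out$gamma <- best$par[3]
  out$lambda <- best$par[4]
  p <- pmin(pmax(psy_fun(data$level, mu, sigma, out$gamma, out$lambda),
                 1e-12), 1 - 1e-12)
  out$loglik <- sum(data$k * log(p) + (data$n - data$k) * log(1 - p))
  out$converged <- best$convergence == 0 && !at_bound
  if (!out$converged) {
    out$diagnostic <- if (at_bound) "parameter at box boundary" else
      paste("optimiser code", best$convergence)
  }
  out$pse <- mu
  out
}

#' Point of subjective equality of a fitted function
#'
#' Defined as the location parameter `mu`, i.e. the stimulus level where the
#' unscaled sigmoid crosses 0.5. This definition is invariant under the
#' lapse and guess rates (a property the lapse-scaled 50% point lacks).
#'
#' @param fit A converged `psy_fit`.
#' @return The PSE in stimulus units.
#' @export
pse <- function(fit) {
  stopifnot(inherits(fit, "psy_fit"))
  if (!fit$converged) {
    stop("PSE requested from a non-converged fit: ", fit$diagnostic,
         call. = FALSE)
  }
  fit$mu
}

#' @export
print.psy_fit <- function(x, ...) {
  if (x$converged) {
    cat(sprintf(
      "Psychometric fit: mu = %.4g, sigma = %.4g, gamma = %.3g, lambda = %.3g\n",
      x$mu, x$sigma, x$gamma, x$lambda))
    cat(sprintf("  loglik = %.4f, PSE = %.4g\n", x$loglik, x$pse))
  } else {
    cat("Psychometric fit: NOT converged --", x$diagnostic, "\n")
  }
  invisible(x)
}

#' Reward-referenced PSE bias index
#'
#' The bias index is the PSE difference between the two stimulus-order
#' conditions in the biased block, relative to the same difference in the
#' unbiased block, signed so that positive values indicate favouring the
#' highly rewarded stimulus:
#' `s * [(pse_o1_biased - pse_o2_biased) - (pse_o1_unbiased -
#' pse_o2_unbiased)]` with `s = +1` when the first-presented stimulus was
#' highly rewarded and `s = -1` when the second was.
#'
#' Sign truth table (o1 = standard-first fits, comparison second): a bias
#' favouring the first interval inflates the comparison PSE when the
#' standard comes first and deflates it when the standard comes second, so
#' the bracketed difference is positive; with `reward_order = "first"` that
#' must count as favouring the reward, hence `s = +1`.
#'
#' @param pse_o1_unbiased,pse_o2_unbiased PSEs from the unbiased block
#'   (standard first / standard second).
#' @param pse_o1_biased,pse_o2_biased PSEs from the biased block.
#' @param reward_order `"first"` or `"second"`: which presentation interval
#'   carried the high reward.
#' @return Bias in stimulus units (positive = favouring the reward).
#' @export
bias_index <- function(pse_o1_unbiased, pse_o2_unbiased,
                       pse_o1_biased, pse_o2_biased,
                       reward_order = c("first", "second")) {
  reward_order <- match.arg(reward_order)
  vals <- c(pse_o1_unbiased, pse_o2_unbiased, pse_o1_biased, pse_o2_biased)
  if (any(!is.finite(vals))) {
    stop("all four PSEs must be finite (converged fits)", call. = FALSE)
  }
  s <- if (reward_order == "first") 1 else -1
  s * ((pse_o1_biased - pse_o2_biased) -
         (pse_o1_unbiased - pse_o2_unbiased))
}

#' PSE difference between two forced-fixation conditions
#'
#' `pse(fit_house) - pse(fit_eyes)`: positive values mean that less face
#' signal was needed for subjective equality when fixating the eye region.
#'
#' @param fit_eyes,fit_house Converged `psy_fit` objects for the two
#'   fixation conditions.
#' @return PSE difference in face-proportion units.
#' @export
pse_difference_exp4 <- function(fit_eyes, fit_house) {
  pse(fit_house) - pse(fit_eyes)
}
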