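# Group-level inference: t-tests with Cohen's d and noncentral-t confidence
# intervals, default-prior (JZS) Bayes factors, regressions, Wilcoxon
# signed-rank tests, and motivation-quality questionnaire scoring.

#' t-test with effect size, noncentral-t CI and default-prior Bayes factor
#'
#' One-sample, paired or two-sample Student t-test. Cohen's d is
#' `mean / sd` for one-sample and paired designs and the pooled-SD
#' standardised mean difference for two samples; its 95% confidence interval
#' is obtained by inverting the noncentral-t distribution of the observed
#' statistic. The Bayes factor uses the JZS default prior (Cauchy on the
#' standardised effect, scale `sqrt(2)/2`).
#'
#' @param x Numeric sample (or first sample / differences).
#' @param y Optional second sample.
#' @param paired Logical; with `y`, treat as paired differences `x - y`.
#' @param sides `"two.sided"`, `"greater"` or `"less"` (direction of the
#'   alternative for `x - y` or `x - mu0`).
#' @param mu0 Null value (one-sample only).
#' @param conf_level Confidence level for the d interval.
#' @return List of class `gb_ttest`: `t`, `df`, `p`, `sides`, `cohens_d`,
#'   `d_ci`, `bf10`, `n`.
#' @export
t_test <- function(x, y = NULL, paired = FALSE,
                   sides = c("two.sided", "greater", "less"), mu0 = 0,
                   conf_level = 0.95) {
  sides <- match.arg(sides)
  x <- as.numeric(x)
  if (anyNA(x) || (!is.null(y) && anyNA(y))) {
    stop("missing values are not handled; remove them explicitly",
         call. = FALSE)
  }
  if (!is.null(y) && paired) {
    if (length(x) != length(y)) stop("paired samples differ in length",
                                     call. = FALSE)
    x <- x - y
    y <- NULL
  }
  if (is.null(y)) {
    n <- length(x)
    if (n < 2L) stop("need at least 2 observations", call. = FALSE)
    s <- stats::sd(x)
    if (s == 0) stop("zero variance sample", call. = FALSE)
    d <- (mean(x) - mu0) / s
    tt <- stats::t.test(x, mu = mu0, alternative = sides)
    n_eff <- n
    df <- n - 1
  } else {
    n1 <- length(x); n2 <- length(y)
    if (n1 < 2L || n2 < 2L) stop("need at least 2 observations per group",
                                 call. = FALSE)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) /
      (n1 + n2 - 2)
    if (sp2 == 0) stop("zero pooled variance", call. = FALSE)
    d <- (mean(x) - mean(y)) / sqrt(sp2)
    tt <- stats::t.test(x, y, alternative = sides, var.equal = TRUE)
    n_eff <- n1 * n2 / (n1 + n2)
    df <- n1 + n2 - 2
  }
  tstat <- unname(tt$statistic)
  d_ci <- d_confint(tstat, df, n_eff, conf_level)
  structure(
    list(t = tstat, df = unname(tt$parameter), p = tt$p.value, sides = sides,
         cohens_d = d, d_ci = d_ci,
         bf10 = jzs_bf10(tstat, n1 = if (is.null(y)) length(x) else length(x),
                         n2 = if (is.null(y)) NULL else length(y)),
         n = if (is.null(y)) length(x) else c(length(x), length(y))),
    class = "gb_ttest")
}

# CI for Cohen's d by inverting the noncentral-t distribution: find the
# noncentrality parameters whose upper/lower tail probability at the observed
# t equals (1 - conf)/2, then rescale by sqrt(n_eff).
d_confint <- function(tstat, df, n_eff, conf_level = 0.95) {
  alpha <- (1 - conf_level) / 2
  bound <- function(target) {
    # pt(ncp) warns about its ~1e-8 series precision; well inside the
    # root-finding tolerance
    f <- function(ncp) suppressWarnings(stats::pt(tstat, df, ncp = ncp)) -
      target
    lo <- tstat - 10 - 10 * abs(tstat)
    hi <- tstat + 10 + 10 * abs(tstat)
    stats::uniroot(f, c(lo, hi), tol = 1e-8)$root
  }
  c(bound(1 - alpha), bound(alpha)) / sqrt(n_eff)
}

#' Default-prior (JZS) Bayes factor for a t statistic
#'
#' Computes the Jeffreys-Zellner-Siow Bayes factor in favour of the
#' alternative by marginalising the noncentral-t likelihood over a Cauchy
#' prior on the standardised effect size:
#' `BF10 = integral dt(t; df, ncp = delta * sqrt(N)) dCauchy(delta; 0, r)
#' / dt(t; df, 0)`, with effective `N = n1` (one-sample/paired) or
#' `n1 n2 / (n1 + n2)` (two-sample).
#'
#' @param t Observed t statistic.
#' @param n1 First (or only) sample size.
#' @param n2 Optional second sample size.
#' @param rscale Cauchy prior scale (default `sqrt(2)/2`).
#' @return The Bayes factor BF10 (a positive number).
#' @export
jzs_bf10 <- function(t, n1, n2 = NULL, rscale = sqrt(2) / 2) {
  stop_if_not_number(t, "t")
  n1 <- stop_if_not_count(n1, "n1", lower = 2L)
  if (is.null(n2)) {
    n_eff <- n1
    df <- n1 - 1
  } else {
    n2 <- stop_if_not_count(n2, "n2", lower = 2L)
    n_eff <- n1 * n2 / (n1 + n2)
    df <- n1 + n2 - 2
  }
  integrand <- function(delta) {
    # dt(ncp) warns about its ~1e-8 series precision; far tighter than the
    # quadrature tolerance used here
    suppressWarnings(stats::dt(t, df, ncp = delta * sqrt(n_eff))) *
      stats::dcauchy(delta, 0, rscale)
  }
  marg <- stats::integrate(integrand, -Inf, Inf, rel.tol = 1e-9,
                           abs.tol = 0, subdivisions = 500L)
  if (marg$message != "OK") {
    stop("Bayes factor quadrature failed: ", marg$message, call. = FALSE)
  }
  marg$value / stats::dt(t, df)
}

#' Simple linear regression with standardised slope
#'
#' Ordinary least squares of `y` on `x`, reporting the standardised slope
#' (beta for z-scored variables), the F-test of the slope and Pearson's r.
#'
#' @param y,x Numeric vectors of equal length (n >= 3).
#' @return List: `beta_std`, `intercept`, `slope`, `F`, `df`, `p`, `r`.
#' @export
linregress <- function(y, x) {
  if (length(y) != length(x)) stop("lengths differ", call. = FALSE)
  if (length(y) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::var(x) == 0) stop("`x` is constant", call. = FALSE)
  fit <- stats::lm(y ~ x)
  an <- stats::anova(fit)
  r <- stats::cor(x, y)
  list(beta_std = unname(stats::coef(fit)[2] * stats::sd(x) / stats::sd(y)),
       intercept = unname(stats::coef(fit)[1]),
       slope = unname(stats::coef(fit)[2]),
       F = an$`F value`[1], df = c(1, an$Df[2]), p = an$`Pr(>F)`[1],
       r = r)
}

#' Wilcoxon signed-rank test
#'
#' Signed-rank test of symmetry about `mu0`. Zero differences are dropped
#' (Wilcoxon's original treatment). The exact null distribution is used for
#' n <= 25 without ties; otherwise the normal approximation with continuity
#' correction.
#'
#' @param x Numeric sample.
#' @param mu0 Hypothesised centre.
#' @param sides Alternative hypothesis direction.
#' @return List: `W` (signed-rank statistic), `p`, `n_used`, `exact`.
#' @export
wilcoxon_signed_rank <- function(x, mu0 = 0,
                                 sides = c("two.sided", "greater", "less")) {
  sides <- match.arg(sides)
  d <- as.numeric(x) - mu0
  d <- d[d != 0]
  n <- length(d)
  if (n == 0L) stop("all differences are zero", call. = FALSE)
  ties <- any(duplicated(abs(d)))
  exact <- n <= 25L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(d, mu = 0, alternative = sides, exact = exact,
                       correct = TRUE))
  list(W = unname(wt$statistic), p = wt$p.value, n_used = n, exact = exact)
}

#' Score the 24-item relative autonomy questionnaire
#'
#' Items are grouped into six subscales of four items each, in the fixed
#' order INT (intrinsic), IDE (identified), IJP (positive introjection),
#' EXT (external), AMO (amotivated), IJN (negative introjection). The first
#' three subscales combine into the autonomous composite, the last three
#' into the controlled composite; self-concordance is autonomous minus
#' controlled, z-standardised across the supplied sample.
#'
#' @param items Numeric matrix, participants x 24 items (columns 1-4 = INT,
#'   5-8 = IDE, ..., 21-24 = IJN). No missing values.
#' @param composite `"mean"` (mean of subscale means, default) or `"sum"`
#'   (sum of subscale means).
#' @return List: `subscales` (participants x 6 matrix of subscale means),
#'   `autonomous`, `controlled`, `self_concordance_raw`,
#'   `self_concordance_z`.
#' @export
crai_score <- function(items, composite = c("mean", "sum")) {
  composite <- match.arg(composite)
  items <- as.matrix(items)
  if (ncol(items) != 24L) stop("expected 24 item columns", call. = FALSE)
  if (anyNA(items)) stop("missing item responses; no imputation is done",
                         call. = FALSE)
  labels <- c("INT", "IDE", "IJP", "EXT", "AMO", "IJN")
  sub <- sapply(seq_len(6), function(s) {
    rowMeans(items[, (4 * s - 3):(4 * s), drop = FALSE])
  })
  sub <- matrix(sub, nrow = nrow(items), dimnames = list(NULL, labels))
  comb <- if (composite == "mean") {
    function(m) rowMeans(m)
  } else {
    function(m) rowSums(m)
  }
  autonomous <- comb(sub[, 1:3, drop = FALSE])
  controlled <- comb(sub[, 4:6, drop = FALSE])
  raw <- autonomous - controlled
  if (length(raw) > 1L && stats::sd(raw) == 0) {
    stop("self-concordance has zero variance; cannot z-standardise",
         call. = FALSE)
  }
  z <- if (length(raw) > 1L) as.numeric(scale(raw)) else NA_real_
  list(subscales = sub, autonomous = autonomous, controlled = controlled,
       self_concordance_raw = raw, self_concordance_z = z)
}

#' Cronbach's alpha internal-consistency coefficient
#'
#' `alpha = k/(k-1) * (1 - sum(item variances) / variance of total score)`.
#'
#' @param item_matrix Numeric matrix, respondents x items (>= 2 each).
#' @return Alpha coefficient.
#' @export
cronbach_alpha <- function(item_matrix) {
  m <- as.matrix(item_matrix)
  if (nrow(m) < 2L || ncol(m) < 2L) {
    stop("need at least 2 respondents and 2 items", call. = FALSE)
  }
  total_var <- stats::var(rowSums(m))
  if (total_var == 0) stop("zero total-score variance", call. = FALSE)
  k <- ncol(m)
  k / (k - 1) * (1 - sum(apply(m, 2, stats::var)) / total_var)
}
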