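new_test_result <- function(method, statistic, df, p_value, effect_size,
                            effect_label, bayes_factor, bf_label, n) {
  stopifnot(p_value >= 0, p_value <= 1)
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, effect_size = effect_size,
                 effect_label = effect_label, bayes_factor = bayes_factor,
                 bf_label = bf_label, n = n),
            class = "td_test_result")
}

#' @export
print.td_test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.3f, df = %s, p = %.4g, %s = %.3f, %s = %.3g, n = %s\n",
              x$method, x$statistic,
              if (is.null(x$df)) "NA" else format(round(x$df, 2)),
              x$p_value, x$effect_label, x$effect_size,
              x$bf_label, x$bayes_factor, paste(x$n, collapse = "/")))
  invisible(x)
}

# noncentral t density; R warns about limited tail precision far beyond
# the accuracy the quadratures need, so the warning is silenced here
dt_ncp <- function(x, df, ncp) suppressWarnings(stats::dt(x, df, ncp = ncp))

#' Default JZS Bayes factor for t-designs
#'
#' BF10 for a one-sample, paired or two-sample t-design under the default
#' Jeffreys-Zellner-Siow prior: a Cauchy(0, `rscale`) prior on the
#' standardised effect size. Computed by numerical integration of the
#' noncentral-t marginal likelihood over the prior, divided by the central-t
#' likelihood under the null. BF01 is the reciprocal.
#'
#' @param t Observed t statistic.
#' @param n Sample size (one-sample/paired: number of observations or
#'   pairs; independent: first group size).
#' @param n2 Second group size (independent design only).
#' @param design `"one_sample"`, `"paired"` or `"independent"`.
#' @param rscale Cauchy prior scale (default 0.707, the conventional
#'   medium setting).
#' @return BF10 (evidence for the alternative over the null).
#' @export
jzs_bayes_factor <- function(t, n, n2 = NULL,
                             design = c("one_sample", "paired", "independent"),
                             rscale = sqrt(2) / 2) {
  design <- match.arg(design)
  if (design == "independent") {
    if (is.null(n2)) stop("independent design needs n2")
    n_eff <- n * n2 / (n + n2)
    df <- n + n2 - 2
  } else {
    n_eff <- n
    df <- n - 1
  }
  if (df < 1) stop("not enough observations for the design")
  num <- stats::integrate(function(delta)
    dt_ncp(t, df, delta * sqrt(n_eff)) * stats::dcauchy(delta, 0, rscale),
    -Inf, Inf, rel.tol = 1e-9, abs.tol = 0)
  if (num$message != "OK")
    stop("JZS marginal likelihood integration failed: ", num$message)
  num$value / stats::dt(t, df)
}

#' One-sample contagion test with a normality gate
#'
#' Tests whether signed divergence values differ from zero. A Shapiro-Wilk
#' test at p < 0.05 routes non-normal data to the Wilcoxon signed-rank
#' test; otherwise a one-sample t-test is used. Cohen's d (mean / SD) and
#' the JZS BF10 (computed on the t equivalent, an approximation when the
#' Wilcoxon branch is taken) are attached.
#'
#' @param values Signed divergence per participant, one agent direction.
#' @param direction Label carried into the method string.
#' @return A `td_test_result`.
#' @export
contagion_one_sample <- function(values, direction = "") {
  n <- length(values)
  if (n < 3) stop("need at least 3 values")
  s <- stats::sd(values)
  if (s == 0) stop("degenerate data: zero variance")
  d <- mean(values) / s
  t_equiv <- mean(values) / (s / sqrt(n))
  bf <- jzs_bayes_factor(t_equiv, n, design = "one_sample")
  normal <- stats::shapiro.test(values)$p.value >= 0.05
  if (normal) {
    tt <- stats::t.test(values, mu = 0)
    new_test_result(paste("one-sample t", direction), unname(tt$statistic),
                    unname(tt$parameter), tt$p.value, d, "d", bf, "BF10", n)
  } else {
    wt <- suppressWarnings(stats::wilcox.test(values, mu = 0))
    new_test_result(paste("Wilcoxon signed-rank", direction),
                    unname(wt$statistic), NULL, wt$p.value, d, "d",
                    bf, "BF10 (approx)", n)
  }
}

winsorize <- function(x, trim) {
  if (trim == 0) return(x)
  lo <- stats::quantile(x, trim, type = 1)
  hi <- stats::quantile(x, 1 - trim, type = 1)
  pmin(pmax(x, lo), hi)
}

win_var <- function(x, trim) stats::var(winsorize(x, trim))

# E[winsorized variance] / variance under normality; rescales the
# winsorized variance into a consistent estimate of the usual variance
win_consistency <- function(trim) {
  if (trim == 0) return(1)
  cc <- stats::qnorm(1 - trim)
  1 - 2 * trim - 2 * cc * stats::dnorm(cc) + 2 * trim * cc^2
}

#' Yuen's trimmed-mean t-test
#'
#' Robust comparison of two samples using trimmed means and Winsorized
#' variances: the independent variant with Welch-style fractional degrees
#' of freedom, or the paired variant on Winsorized (co)variances of the
#' two columns. With `trim = 0` the independent variant reduces exactly to
#' Welch's t-test. The effect size is the explanatory measure xi: the
#' square root of the variance of the group trimmed means (as fitted
#' values) over a consistency-rescaled Winsorized variance of the pooled
#' data, capped at 1.
#'
#' @param x,y Numeric samples (paired: equal length, same participants).
#' @param trim Trim proportion in \[0, 0.5); default 0.2.
#' @param paired Paired or independent design.
#' @return A `td_test_result` (effect size xi for independent, robust d
#'   for paired).
#' @export
yuen_t <- function(x, y, trim = 0.2, paired = FALSE) {
  if (trim < 0 || trim >= 0.5) stop("trim must lie in [0, 0.5)")
  n1 <- length(x); n2 <- length(y)
  if (min(n1, n2) < 4) stop("each sample needs at least 4 observations")
  g1 <- floor(trim * n1); g2 <- floor(trim * n2)
  h1 <- n1 - 2 * g1; h2 <- n2 - 2 * g2
  if (h1 < 2 || h2 < 2) stop("trim too large for the sample size")
  tm1 <- mean(x, trim = trim); tm2 <- mean(y, trim = trim)
  if (paired) {
    if (n1 != n2) stop("paired samples must have equal length")
    xw <- winsorize(x, trim); yw <- winsorize(y, trim)
    q1 <- (n1 - 1) * stats::var(xw)
    q2 <- (n1 - 1) * stats::var(yw)
    q3 <- (n1 - 1) * stats::cov(xw, yw)
    df <- h1 - 1
    se <- sqrt((q1 + q2 - 2 * q3) / (h1 * (h1 - 1)))
    if (se == 0) stop("degenerate data: zero variance of differences")
    tstat <- (tm1 - tm2) / se
    sw <- sqrt(win_var(x - y, trim) / win_consistency(trim))
    es <- mean(x - y, trim = trim) / sw
    es_label <- "robust d"
  } else {
    d1 <- (n1 - 1) * win_var(x, trim) / (h1 * (h1 - 1))
    d2 <- (n2 - 1) * win_var(y, trim) / (h2 * (h2 - 1))
    tstat <- (tm1 - tm2) / sqrt(d1 + d2)
    df <- (d1 + d2)^2 / (d1^2 / (h1 - 1) + d2^2 / (h2 - 1))
    yhat <- c(rep(tm1, n1), rep(tm2, n2))
    denom <- win_var(c(x, y), trim) / win_consistency(trim)
    es <- if (denom == 0) 0 else sqrt(min(stats::var(yhat) / denom, 1))
    es_label <- "xi"
  }
  p <- 2 * stats::pt(-abs(tstat), df)
  bf <- jzs_bayes_factor(tstat, if (paired) n1 else h1,
                         if (paired) NULL else h2,
                         design = if (paired) "paired" else "independent")
  new_test_result(if (paired) "Yuen paired trimmed-mean t"
                  else "Yuen independent trimmed-mean t",
                  tstat, df, p, es, es_label, bf, "BF10 (approx)",
                  c(n1, n2))
}

#' Paired test of agent direction on accuracy
#'
#' Paired t-test of percent accuracy for the impulsive versus patient
#' agent, with Cohen's d on the differences and the paired JZS BF10.
#'
#' @param impulsive,patient Paired percent accuracies.
#' @return A `td_test_result`.
#' @export
accuracy_direction_test <- function(impulsive, patient) {
  n <- length(impulsive)
  if (n < 3 || length(patient) != n)
    stop("need paired samples of length >= 3")
  diffs <- impulsive - patient
  sdd <- stats::sd(diffs)
  if (sdd == 0) stop("degenerate data: zero variance of differences")
  tt <- stats::t.test(impulsive, patient, paired = TRUE)
  d <- mean(diffs) / sdd
  bf <- jzs_bayes_factor(unname(tt$statistic), n, design = "paired")
  new_test_result("paired t (direction on accuracy)", unname(tt$statistic),
                  unname(tt$parameter), tt$p.value, d, "d", bf, "BF10", n)
}

#' Correlation between divergence and accuracy
#'
#' Pearson correlation with a two-sided test; the Bayes factor is a BIC
#' approximation from the corresponding simple regression (labelled
#' approximate).
#'
#' @param dkl,accuracy Paired numeric vectors.
#' @return A `td_test_result` (statistic = r).
#' @export
dkl_accuracy_correlation <- function(dkl, accuracy) {
  n <- length(dkl)
  if (n < 4 || length(accuracy) != n) stop("need paired vectors, n >= 4")
  if (stats::sd(dkl) == 0 || stats::sd(accuracy) == 0)
    stop("degenerate data: zero variance")
  ct <- stats::cor.test(dkl, accuracy)
  m1 <- stats::lm(dkl ~ accuracy)
  m0 <- stats::lm(dkl ~ 1)
  bf <- exp((stats::BIC(m0) - stats::BIC(m1)) / 2)
  new_test_result("Pearson correlation", unname(ct$estimate),
                  unname(ct$parameter), ct$p.value, unname(ct$estimate),
                  "r", bf, "BF10 (BIC approx)", n)
}

#' Regression of divergence on group, accuracy and AQ subscales
#'
#' Ordinary least squares predicting signed divergence from a study-group
#' indicator, percent accuracy and the five AQ subscale scores.
#' Coefficients are reported standardised (all variables scaled to unit
#' SD) alongside t and p per predictor, the model R-squared, overall F
#' test, and a BIC-approximate BF10 against the intercept-only model.
#'
#' @param data `data.frame` with columns `dkl`, `group_indicator`,
#'   `accuracy`, and the five subscales `social_skills`,
#'   `attention_switching`, `attention_to_detail`, `communication`,
#'   `imagination`.
#' @return List: `coefficients` (data frame: term, beta, t, p),
#'   `r_squared`, `f_statistic`, `df`, `p_value`, `bf10_approx`, `n`.
#' @export
aq_regression <- function(data) {
  predictors <- c("group_indicator", "accuracy", .AQ_SUBSCALES)
  need <- c("dkl", predictors)
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("missing columns: ", paste(miss, collapse = ", "))
  n <- nrow(data)
  if (n <= length(predictors) + 1) stop("too few rows for the predictor set")
  zs <- as.data.frame(lapply(data[need], function(col) {
    s <- stats::sd(col)
    if (s == 0) col - mean(col) else (col - mean(col)) / s
  }))
  fml <- stats::as.formula(paste("dkl ~", paste(predictors, collapse = " + ")))
  raw <- stats::lm(fml, data = data[need])
  mm <- stats::model.matrix(raw)
  qrr <- qr(mm)
  if (qrr$rank < ncol(mm)) {
    bad <- colnames(mm)[-seq_len(qrr$rank)]
    stop("rank-deficient design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  fit <- stats::lm(fml, data = zs)
  sm <- summary(fit)
  coefs <- data.frame(term = rownames(sm$coefficients)[-1],
                      estimate = unname(stats::coef(raw)[-1]),
                      beta = sm$coefficients[-1, 1],
                      t = sm$coefficients[-1, 3],
                      p = sm$coefficients[-1, 4], row.names = NULL)
  fstat <- sm$fstatistic
  m0 <- stats::lm(dkl ~ 1, data = zs)
  list(coefficients = coefs,
       r_squared = sm$r.squared,
       f_statistic = unname(fstat[1]),
       df = unname(fstat[2:3]),
       p_value = unname(stats::pf(fstat[1], fstat[2], fstat[3],
                                  lower.tail = FALSE)),
       bf10_approx = exp((stats::BIC(m0) - stats::BIC(fit)) / 2),
       n = n)
}

#' Select a matched control subset
#'
#' Picks one control per case: exact gender match, agent-direction
#' compatibility (a case with two same-direction agents cannot be matched
#' to a control whose two agents both lie in the opposite direction), then
#' nearest age, with random tie-breaking under the ambient RNG and no
#' control reused.
#'
#' @param nt Control pool `data.frame` with `participant_id`, `age`,
#'   `gender`, `agent1_direction`, `agent2_direction`.
#' @param asc Case sample, same columns.
#' @return The matched subset of `nt`, one row per case, in case order.
#' @export
match_controls <- function(nt, asc) {
  if (nrow(nt) < nrow(asc)) stop("control pool smaller than case sample")
  used <- character()
  picks <- character(nrow(asc))
  unmatched <- character()
  for (i in seq_len(nrow(asc))) {
    a <- asc[i, ]
    cand <- nt[nt$gender == a$gender & !(nt$participant_id %in% used), ,
               drop = FALSE]
    if (a$agent1_direction == a$agent2_direction) {
      opp <- setdiff(c("impulsive", "patient"), a$agent1_direction)
      if (length(opp) == 1L) {
        both_opp <- cand$agent1_direction == opp & cand$agent2_direction == opp
        cand <- cand[!both_opp, , drop = FALSE]
      }
    }
    if (!nrow(cand)) { unmatched <- c(unmatched, a$participant_id); next }
    dist <- abs(cand$age - a$age)
    best <- which(dist == min(dist))
    pick <- cand$participant_id[best[sample.int(length(best), 1L)]]
    picks[i] <- pick
    used <- c(used, pick)
  }
  if (length(unmatched))
    stop("no feasible control for: ", paste(unmatched, collapse = ", "))
  nt[match(picks, nt$participant_id), , drop = FALSE]
}

#' Equivalence bound from a power analysis
#'
#' The absolute standardised effect size d at which a two-sided two-sample
#' t-test with `n_per_group` per group attains the given power at level
#' `alpha`, found by inverting the noncentral-t power function. Used to
#' set interval-null equivalence bounds (+/- d).
#'
#' @param n_per_group Group size.
#' @param power Target power in (0, 1).
#' @param alpha Significance level.
#' @return The d bound (>= 0).
#' @export
equivalence_bound_from_power <- function(n_per_group, power = 0.33,
                                         alpha = 0.05) {
  stopifnot(n_per_group >= 2, power > 0, power < 1, alpha > 0, alpha < 1)
  if (power <= alpha) return(0)
  pw <- stats::power.t.test(n = n_per_group, power = power,
                            sig.level = alpha, sd = 1,
                            type = "two.sample", alternative = "two.sided")
  pw$delta
}

#' Interval-null equivalence Bayes factor
#'
#' Compares the hypothesis that the standardised two-sample effect size
#' lies inside +/- `bound` against the hypothesis that it lies outside,
#' under a Cauchy(0, `rscale`) prior: the ratio of posterior to prior odds
#' of the interval, with the posterior over delta proportional to the
#' noncentral-t likelihood of the observed pooled-variance t times the
#' prior. Large values support equivalence.
#'
#' @param x,y The two samples.
#' @param bound Equivalence half-width on the d scale (from
#'   [equivalence_bound_from_power()]).
#' @param rscale Cauchy prior scale.
#' @return BF (inside vs outside the bounds).
#' @export
interval_null_bf <- function(x, y, bound, rscale = sqrt(2) / 2) {
  stopifnot(bound > 0)
  n1 <- length(x); n2 <- length(y)
  df <- n1 + n2 - 2
  sp <- sqrt(((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / df)
  tobs <- (mean(x) - mean(y)) / (sp * sqrt(1 / n1 + 1 / n2))
  n_eff <- 1 / (1 / n1 + 1 / n2)
  dens <- function(delta)
    dt_ncp(tobs, df, delta * sqrt(n_eff)) * stats::dcauchy(delta, 0, rscale)
  quad <- function(f, lo, hi) {
    r <- stats::integrate(f, lo, hi, rel.tol = 1e-8, subdivisions = 500L)
    if (r$message != "OK") stop("integration failed: ", r$message)
    r$value
  }
  # tails computed as total minus interior: the interior quadrature is
  # well-conditioned while a near-empty tail defeats relative tolerance
  post_total <- quad(dens, -Inf, Inf)
  post_in <- min(quad(dens, -bound, bound), post_total)
  post_out <- max(post_total - post_in, post_total * 1e-15,
                  .Machine$double.xmin)
  prior_in <- stats::pcauchy(bound, 0, rscale) -
    stats::pcauchy(-bound, 0, rscale)
  prior_out <- 1 - prior_in
  (post_in / post_out) / (prior_in / prior_out)
}
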