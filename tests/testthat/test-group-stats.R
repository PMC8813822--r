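test_that("one-sample contagion test matches the t formula", {
  res <- contagion_one_sample(c(1, 2, 3))
  expect_equal(res$statistic, 2 / (1 / sqrt(3)))
  expect_equal(res$effect_size, 2)  # mean / sd = 2 / 1
  # null-centred symmetric data
  res0 <- contagion_one_sample(c(-1, 0, 1))
  expect_gt(res0$p_value, 0.9)
  expect_equal(res0$effect_size, 0)
  expect_error(contagion_one_sample(rep(2, 5)), "zero variance")
  expect_error(contagion_one_sample(c(1, 2)), "at least 3")
})

test_that("the normality gate routes to the signed-rank test", {
  set.seed(61)
  skewed <- rexp(40)^3
  expect_match(contagion_one_sample(skewed)$method, "Wilcoxon")
  expect_match(contagion_one_sample(rnorm(40))$method, "one-sample t")
})

test_that("yuen with zero trim reduces to Welch", {
  set.seed(62)
  for (i in 1:25) {
    x <- rnorm(sample(10:30, 1)); y <- rnorm(sample(10:30, 1), 0.3)
    yu <- yuen_t(x, y, trim = 0)
    we <- t.test(x, y)
    expect_equal(yu$statistic, unname(we$statistic), tolerance = 1e-8)
    expect_equal(yu$df, unname(we$parameter), tolerance = 1e-8)
    expect_equal(yu$p_value, we$p.value, tolerance = 1e-8)
  }
})

test_that("yuen matches a step-by-step trimmed-mean oracle", {
  x <- c(1.2, 3.4, 2.2, 9.9, 0.3, 2.8)
  y <- c(4.1, 5.0, 3.9, 4.4, 12.0, 4.8)
  tr <- 0.2
  g <- floor(tr * 6); h <- 6 - 2 * g
  winv <- function(v) {
    sv <- sort(v)
    w <- pmin(pmax(v, sv[g + 1]), sv[6 - g])
    var(w)
  }
  d1 <- (6 - 1) * winv(x) / (h * (h - 1))
  d2 <- (6 - 1) * winv(y) / (h * (h - 1))
  t_hand <- (mean(x, trim = tr) - mean(y, trim = tr)) / sqrt(d1 + d2)
  df_hand <- (d1 + d2)^2 / (d1^2 / (h - 1) + d2^2 / (h - 1))
  res <- yuen_t(x, y, trim = tr)
  expect_equal(res$statistic, t_hand, tolerance = 1e-12)
  expect_equal(res$df, df_hand, tolerance = 1e-12)
  expect_equal(res$p_value, 2 * pt(-abs(t_hand), df_hand), tolerance = 1e-12)
})

test_that("identical groups give a null yuen result", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8)
  res <- yuen_t(x, x)
  expect_equal(res$statistic, 0)
  expect_equal(res$effect_size, 0)
  expect_error(yuen_t(x, x, trim = 0.5), "trim")
  expect_error(yuen_t(1:3, 1:3), "at least 4")
  # paired variant: zero variance of differences is degenerate
  expect_error(yuen_t(x, x, paired = TRUE), "degenerate")
  set.seed(63)
  res_p <- yuen_t(x + rnorm(8, 1), x, paired = TRUE)
  expect_equal(res_p$method, "Yuen paired trimmed-mean t")
  expect_gt(res_p$statistic, 0)
})

test_that("direction effect on accuracy behaves like a paired t", {
  set.seed(64)
  pat <- rnorm(20, 78, 6)
  imp <- pat + 5 + rnorm(20, 0, 0.5)
  res <- accuracy_direction_test(imp, pat)
  expect_lt(res$p_value, 0.05)
  expect_gt(res$effect_size, 1)
  tt <- t.test(imp, pat, paired = TRUE)
  expect_equal(res$statistic, unname(tt$statistic))
  expect_error(accuracy_direction_test(pat, pat), "zero variance")
})

test_that("divergence-accuracy correlation matches the r formula", {
  x <- c(1, 3, 4, 8)
  y <- c(2, 5, 5, 9)
  res <- dkl_accuracy_correlation(x, y)
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(res$statistic, r_hand, tolerance = 1e-12)
  expect_equal(dkl_accuracy_correlation(x, x)$statistic, 1)
  expect_error(dkl_accuracy_correlation(x, rep(1, 4)), "zero variance")
  # independent vectors: small |r| typically
  set.seed(65)
  res0 <- dkl_accuracy_correlation(rnorm(100), rnorm(100))
  expect_lt(abs(res0$statistic), 0.3)
})

test_that("the AQ regression recovers exact linear structure", {
  set.seed(66)
  n <- 40
  dat <- data.frame(group_indicator = rep(0:1, each = n / 2),
                    accuracy = rnorm(n, 75, 8),
                    social_skills = rnorm(n, 22, 4),
                    attention_switching = rnorm(n, 25, 4),
                    attention_to_detail = rnorm(n, 25, 4),
                    communication = rnorm(n, 21, 4),
                    imagination = rnorm(n, 22, 5))
  dat$dkl <- 2 * dat$accuracy
  res <- suppressWarnings(aq_regression(dat))  # perfect fit by design
  expect_equal(res$r_squared, 1)
  acc_row <- res$coefficients[res$coefficients$term == "accuracy", ]
  expect_equal(acc_row$estimate, 2, tolerance = 1e-10)
  others <- res$coefficients[res$coefficients$term != "accuracy", ]
  expect_true(all(abs(others$estimate) < 1e-10))
  # small-data oracle via the normal equations
  dat$dkl <- dat$accuracy - 0.5 * dat$communication + rnorm(n)
  res <- aq_regression(dat)
  X <- cbind(1, as.matrix(dat[c("group_indicator", "accuracy",
                                "social_skills", "attention_switching",
                                "attention_to_detail", "communication",
                                "imagination")]))
  beta_hat <- solve(t(X) %*% X, t(X) %*% dat$dkl)
  expect_equal(res$coefficients$estimate, unname(beta_hat[-1, 1]),
               tolerance = 1e-8)
  # perfect collinearity is reported with the offending column
  dat$imagination <- dat$communication
  expect_error(aq_regression(dat), "imagination")
})

test_that("control matching honours gender, age and direction rules", {
  nt <- data.frame(
    participant_id = sprintf("nt%02d", 1:8),
    age = c(20, 22, 25, 30, 22, 28, 21, 35),
    gender = c("female", "female", "male", "male",
               "female", "male", "female", "male"),
    agent1_direction = c("impulsive", "patient", "impulsive", "impulsive",
                         "impulsive", "patient", "patient", "impulsive"),
    agent2_direction = c("patient", "impulsive", "patient", "impulsive",
                         "patient", "patient", "impulsive", "impulsive"))
  asc <- data.frame(participant_id = c("a1", "a2"),
                    age = c(22, 30), gender = c("female", "male"),
                    agent1_direction = c("patient", "impulsive"),
                    agent2_direction = c("patient", "patient"))
  set.seed(70)
  m <- match_controls(nt, asc)
  expect_equal(nrow(m), 2)
  expect_equal(m$gender, asc$gender)
  # a1 has two patient agents: nt with two impulsive agents is barred even
  # at equal age distance; exact-age candidates are nt02/nt05 (age 22)
  expect_true(m$participant_id[1] %in% c("nt02", "nt05"))
  expect_equal(m$age[2], 30)
  # seeded tie-break is reproducible
  set.seed(70)
  expect_identical(match_controls(nt, asc)$participant_id,
                   m$participant_id)
  # infeasible case is named
  asc_bad <- asc; asc_bad$gender <- c("female", "other")
  expect_error(match_controls(nt, asc_bad), "a2")
})

test_that("equivalence bound inverts the noncentral-t power function", {
  d80 <- equivalence_bound_from_power(64, 0.80, 0.05)
  expect_equal(round(d80, 1), 0.5)
  # oracle: the returned bound really attains the requested power
  pwr <- power.t.test(n = 64, delta = d80, sd = 1, sig.level = 0.05)$power
  expect_equal(pwr, 0.80, tolerance = 1e-6)
  # monotone decreasing in n, increasing in power
  ns <- c(10, 20, 40, 80)
  bounds_n <- sapply(ns, equivalence_bound_from_power, power = 0.33)
  expect_true(all(diff(bounds_n) < 0))
  pws <- c(0.2, 0.4, 0.6, 0.8)
  bounds_p <- sapply(pws, function(p) equivalence_bound_from_power(20, p))
  expect_true(all(diff(bounds_p) > 0))
  expect_equal(equivalence_bound_from_power(20, power = 0.05, alpha = 0.05), 0)
})

test_that("interval-null Bayes factor separates equivalent from distinct", {
  set.seed(71)
  x <- rnorm(200); y <- rnorm(200)
  expect_gt(interval_null_bf(x, y, 0.7), 3)
  y2 <- rnorm(200, 2)   # true d = 2, far outside +/- 0.7
  expect_lt(interval_null_bf(x, y2, 0.7), 1 / 3)
  # very wide bounds push the BF towards infinity
  expect_gt(interval_null_bf(x, y, 50), 1e3)
})

test_that("JZS Bayes factor matches independent quadrature", {
  expect_lt(jzs_bayes_factor(0, 30), 1)
  # monotone in |t| at fixed n
  bfs <- sapply(c(0, 1, 2, 3, 4), jzs_bayes_factor, n = 25)
  expect_true(all(diff(bfs) > 0))
  # reciprocal identity
  expect_equal(jzs_bayes_factor(2.1, 30) * (1 / jzs_bayes_factor(2.1, 30)), 1)
  # independent trapezoid quadrature of the marginal likelihood
  for (spec in list(list(t = 2.5, n = 20, n2 = NULL, design = "one_sample"),
                    list(t = 1.2, n = 15, n2 = 18, design = "independent"))) {
    n_eff <- if (spec$design == "independent")
      spec$n * spec$n2 / (spec$n + spec$n2) else spec$n
    df <- if (spec$design == "independent") spec$n + spec$n2 - 2 else
      spec$n - 1
    delta <- seq(-10, 10, by = 0.002)
    integrand <- suppressWarnings(
      dt(spec$t, df, ncp = delta * sqrt(n_eff))) *
      dcauchy(delta, 0, sqrt(2) / 2)
    marg <- sum(integrand) * 0.002
    oracle <- marg / dt(spec$t, df)
    got <- jzs_bayes_factor(spec$t, spec$n, spec$n2, spec$design)
    expect_equal(got, oracle, tolerance = 1e-3)
  }
  expect_error(jzs_bayes_factor(1, 10, design = "independent"), "n2")
})
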