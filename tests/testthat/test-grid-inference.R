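test_that("uniform prior is flat, normalised and maximum-entropy", {
  g <- param_grid(100, 50)
  prior <- init_uniform_prior(g)
  expect_equal(dim(prior$mass), c(100, 50))
  expect_true(all(prior$mass == 1 / 5000))
  expect_equal(sum(prior$mass), 1, tolerance = 1e-12)
  expect_equal(-sum(prior$mass * log(prior$mass)), log(5000))
  expect_error(init_uniform_prior(list()), "param_grid")
})

test_that("grid axes span the stated parameter ranges", {
  g <- param_grid(11, 5)
  expect_equal(range(g$logk), c(-4, 0))
  expect_equal(range(g$logbeta), c(-1, 1))
  expect_true(all(diff(g$logk) > 0) && all(diff(g$logbeta) > 0))
  expect_equal(g$k, 10^g$logk)
})

test_that("trial likelihood agrees with a nodewise brute-force oracle", {
  g <- param_grid(13, 7)
  pair <- choice_pairs(6, 14, 28)
  for (mode in c("free", "fixed_at_1")) {
    for (ch in c("LL", "SS")) {
      lik <- trial_likelihood(pair, ch, g, mode)
      oracle <- matrix(NA_real_, 13, 7)
      for (i in 1:13) for (j in 1:7) {
        k <- 10^g$logk[i]
        beta <- if (mode == "fixed_at_1") 1 else 10^g$logbeta[j]
        v_ll <- 14 / (1 + k * 28)
        p_ll <- 1 / (1 + exp(-beta * (v_ll - 6)))
        oracle[i, j] <- if (ch == "LL") p_ll else 1 - p_ll
      }
      expect_equal(lik, oracle, tolerance = 1e-14)
      # open interval mathematically; the logistic saturates in doubles
      expect_true(all(lik >= 0 & lik <= 1))
    }
  }
  # nodewise complement
  expect_equal(trial_likelihood(pair, "LL", g) +
                 trial_likelihood(pair, "SS", g),
               matrix(1, 13, 7))
})

test_that("posterior updates are proportional to prior times likelihood", {
  g <- param_grid(21, 11)
  prior <- init_uniform_prior(g)
  pair <- choice_pairs(4, 16, 60)
  post <- update_posterior(prior, pair, "LL")
  lik <- trial_likelihood(pair, "LL", g)
  expect_equal(post$mass, lik * prior$mass / sum(lik * prior$mass),
               tolerance = 1e-14)
  expect_equal(sum(post$mass), 1, tolerance = 1e-12)
  expect_equal(post$trial_index, 1L)
  expect_true(all(post$mass >= 0))
})

test_that("sequential updating equals one batch update", {
  g <- param_grid(31, 15)
  set.seed(31)
  for (rep in 1:5) {
    trials <- random_trials(15, runif(1, -3.5, -0.5), runif(1, -0.5, 0.5))
    mode <- sample(c("free", "fixed_at_1"), 1)
    seq_post <- run_block(init_uniform_prior(g), trials, mode)
    batch <- matrix(1, 31, 15)
    for (i in seq_len(nrow(trials)))
      batch <- batch * trial_likelihood(trials[i, ], trials$choice[i], g, mode)
    batch <- batch / sum(batch)
    expect_equal(seq_post$mass, batch, tolerance = 1e-8)
  }
})

test_that("final posterior is invariant to trial order", {
  g <- param_grid(21, 11)
  set.seed(17)
  trials <- random_trials(12, -1.5, 0.2)
  p1 <- run_block(init_uniform_prior(g), trials)
  p2 <- run_block(init_uniform_prior(g), trials[sample(12), ])
  expect_equal(p1$mass, p2$mass, tolerance = 1e-10)
})

test_that("run_block base case equals a single update", {
  g <- param_grid(21, 11)
  trials <- choice_pairs(5, 15, 14)
  trials$choice <- "LL"
  expect_equal(run_block(init_uniform_prior(g), trials)$mass,
               update_posterior(init_uniform_prior(g), trials, "LL")$mass)
  expect_error(run_block(init_uniform_prior(g), trials[0, ]), "non-empty")
})

test_that("fifty self trials recover the generating log k within 0.5", {
  set.seed(202)
  res <- simulate_self_block(-2.4, 0.1, 50, GRID_COARSE)
  expect_lt(abs(res$estimates$logk_mean - (-2.4)), 0.5)
})

test_that("beta clamping leaves the log beta marginal untouched", {
  g <- param_grid(21, 11)
  set.seed(3)
  trials <- random_trials(10, -2, 0)
  post <- run_block(init_uniform_prior(g), trials, "fixed_at_1")
  expect_equal(colSums(post$mass), rep(1 / 11, 11), tolerance = 1e-12)
})

test_that("the block schedule resets and carries priors as specified", {
  g <- param_grid(31, 15)
  set.seed(41)
  blocks <- lapply(1:5, function(i) random_trials(8, -2, 0))
  make_trials <- function(bl) do.call(rbind, Map(function(tr, b) {
    tr$block <- b; tr
  }, bl, list("Self1", "Other1", "Self2", "Other2", "Self3")))
  fit <- fit_session(make_trials(blocks), g)
  expect_named(fit$posteriors, c("Self1", "Other1", "Self2", "Other2", "Self3"))
  for (p in fit$posteriors) expect_equal(sum(p$mass), 1, tolerance = 1e-12)
  # Self2 starts from a uniform prior: changing Other1 entirely must not
  # move the Self2 posterior
  blocks2 <- blocks
  blocks2[[2]] <- random_trials(8, -0.5, 0.5)
  fit2 <- fit_session(make_trials(blocks2), g)
  expect_equal(fit$posteriors$Self2$mass, fit2$posteriors$Self2$mass)
  # Other2's prior is exactly the end-of-Self2 posterior
  expected <- run_block(
    {
      pr <- fit$posteriors$Self2; pr$trial_index <- 0L; pr
    }, blocks[[4]], "fixed_at_1")
  expect_equal(fit$posteriors$Other2$mass, expected$mass, tolerance = 1e-12)
  # order violations are schema errors
  bad <- make_trials(blocks)
  bad$block[bad$block == "Other1"] <- "Other2"
  expect_error(fit_session(bad, g), "order")
})

test_that("point estimates match brute-force moments", {
  g <- param_grid(21, 11)
  expect_equal(point_estimates(init_uniform_prior(g))$logk_mean, -2)
  # point mass
  pm <- init_uniform_prior(g)
  pm$mass[] <- 0; pm$mass[8, 4] <- 1
  est <- point_estimates(pm)
  expect_equal(est$logk_mean, g$logk[8])
  expect_equal(est$logk_map, g$logk[8])
  expect_equal(est$logk_variance, 0)
  # random posterior vs explicit weighted sums
  set.seed(6)
  post <- run_block(init_uniform_prior(g), random_trials(10, -1.8, 0))
  est <- point_estimates(post)
  w <- post$mass
  mu_k <- sum(outer(g$logk, rep(1, 11)) * w)
  expect_equal(est$logk_mean, mu_k, tolerance = 1e-12)
  expect_equal(est$logk_variance,
               sum((outer(g$logk, rep(1, 11)) - mu_k)^2 * w),
               tolerance = 1e-12)
  mu_b <- sum(outer(rep(1, 21), g$logbeta) * w)
  expect_equal(est$logbeta_mean, mu_b, tolerance = 1e-12)
})

test_that("posterior export is a lossless long format", {
  g <- param_grid(9, 5)
  set.seed(2)
  post <- run_block(init_uniform_prior(g), random_trials(5, -2, 0))
  df <- posterior_to_df(post)
  expect_equal(nrow(df), 45)
  expect_equal(sum(df$mass), 1, tolerance = 1e-12)
  expect_equal(matrix(df$mass, 9, 5), post$mass)
})
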