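#' Discrete parameter grid over (log k, log beta)
#'
#' Evenly spaced grid spanning log k in \[-4, 0\] and log beta in \[-1, 1\].
#' The default 101 x 51 resolution quantises log k below 0.05; coarser grids
#' are useful in simulation-heavy tests.
#'
#' @param n_logk,n_logbeta Number of nodes per axis (>= 2).
#' @return A `param_grid` list with axes `logk`, `logbeta` and their linear
#'   counterparts `k = 10^logk`, `beta = 10^logbeta`.
#' @export
param_grid <- function(n_logk = 101L, n_logbeta = 51L) {
  stopifnot(n_logk >= 2L, n_logbeta >= 2L)
  logk <- seq(.LOGK_RANGE[1], .LOGK_RANGE[2], length.out = n_logk)
  logbeta <- seq(.LOGBETA_RANGE[1], .LOGBETA_RANGE[2], length.out = n_logbeta)
  structure(list(logk = logk, logbeta = logbeta,
                 k = 10^logk, beta = 10^logbeta),
            class = "param_grid")
}

new_posterior <- function(grid, mass, block_label, trial_index) {
  structure(list(grid = grid, mass = mass,
                 block_label = block_label, trial_index = trial_index),
            class = "grid_posterior")
}

#' Uniform prior over the parameter grid
#'
#' @param grid A [param_grid()].
#' @param block_label Block this prior opens (default `"Self1"`).
#' @return A `grid_posterior`: grid, normalised mass matrix
#'   (rows = log k nodes, columns = log beta nodes), block label, and a
#'   trial counter starting at 0.
#' @export
init_uniform_prior <- function(grid, block_label = "Self1") {
  if (!inherits(grid, "param_grid") || !length(grid$logk) || !length(grid$logbeta))
    stop("grid must be a non-empty param_grid")
  n <- length(grid$logk) * length(grid$logbeta)
  mass <- matrix(1 / n, length(grid$logk), length(grid$logbeta))
  new_posterior(grid, mass, block_label, 0L)
}

#' Per-node likelihood of one observed choice
#'
#' Evaluates, at every grid node, the probability of the observed choice
#' under hyperbolic value and softmax with that node's (k, beta). With
#' `beta_mode = "fixed_at_1"` the inverse temperature is 1 at every node
#' (the log beta axis carries no information), as used for Other blocks
#' where the participant chooses on behalf of an agent known to act with
#' beta = 1.
#'
#' @param pair One-row pair table (`ss_amount`, `ll_amount`,
#'   `ll_delay_days`).
#' @param choice `"SS"` or `"LL"`.
#' @param grid A [param_grid()].
#' @param beta_mode `"free"` or `"fixed_at_1"`.
#' @return Likelihood matrix matching the grid, all values in (0, 1).
#' @export
trial_likelihood <- function(pair, choice, grid, beta_mode = c("free", "fixed_at_1")) {
  beta_mode <- match.arg(beta_mode)
  if (!choice %in% c("SS", "LL")) stop("choice must be 'SS' or 'LL'")
  vd <- pair$ll_amount[1L] / (1 + grid$k * pair$ll_delay_days[1L]) -
    pair$ss_amount[1L]
  if (beta_mode == "fixed_at_1") {
    p_ll <- stats::plogis(vd)
    lik <- matrix(p_ll, length(grid$logk), length(grid$logbeta))
  } else {
    lik <- stats::plogis(outer(vd, grid$beta))
  }
  if (choice == "SS") lik <- 1 - lik
  lik
}

#' Single Bayesian update
#'
#' Posterior proportional to prior times the trial likelihood, renormalised;
#' the trial counter advances by one.
#'
#' @param prior A `grid_posterior`.
#' @param pair,choice,beta_mode As in [trial_likelihood()].
#' @return Updated `grid_posterior`.
#' @export
update_posterior <- function(prior, pair, choice, beta_mode = "free") {
  lik <- trial_likelihood(pair, choice, prior$grid, beta_mode)
  mass <- prior$mass * lik
  s <- sum(mass)
  if (!is.finite(s) || s <= 0)
    stop("posterior mass degenerated to zero; inputs inconsistent with grid")
  new_posterior(prior$grid, mass / s, prior$block_label,
                prior$trial_index + 1L)
}

#' Fold updates over a block of trials
#'
#' Applies [update_posterior()] to each (pair, choice) in order and returns
#' the end-of-block posterior — the object the divergence measure consumes.
#' Because the posterior is a normalised product of likelihoods, the result
#' is invariant to trial order.
#'
#' @param prior Opening `grid_posterior` for the block.
#' @param trials `data.frame` with pair columns plus `choice`.
#' @param beta_mode `"free"` (Self blocks) or `"fixed_at_1"` (Other blocks).
#' @param keep_trajectory If `TRUE`, also return the posterior after every
#'   trial.
#' @return The final `grid_posterior`, or (with trajectory) a list
#'   `list(posterior, trajectory)`.
#' @export
run_block <- function(prior, trials, beta_mode = "free",
                      keep_trajectory = FALSE) {
  if (!nrow(trials)) stop("trials must be non-empty")
  post <- prior
  traj <- if (keep_trajectory) vector("list", nrow(trials)) else NULL
  for (i in seq_len(nrow(trials))) {
    post <- update_posterior(post, trials[i, ], trials$choice[i], beta_mode)
    if (keep_trajectory) traj[[i]] <- post
  }
  if (keep_trajectory) list(posterior = post, trajectory = traj) else post
}

.BLOCK_ORDER <- c("Self1", "Other1", "Self2", "Other2", "Self3")

#' Fit the five-block prior schedule to one participant's trial log
#'
#' Runs the grid learner over the canonical block sequence Self1, Other1,
#' Self2, Other2, Self3 with the prior carryover and reset schedule:
#' Self1 starts from a uniform prior; each Other block inherits the
#' posterior from the preceding Self block (own priors seed learning about
#' the other); Self2 and Self3 restart from a uniform prior so the agents'
#' strong posteriors do not contaminate Self estimation. Beta is a free
#' parameter in Self blocks and clamped to 1 in Other blocks, where the log
#' k marginal tracks beliefs about the agent.
#'
#' @param trials One participant's trial log containing `block`, the pair
#'   columns and `choice`, with all five blocks present.
#' @param grid A [param_grid()].
#' @return List with `posteriors` (named end-of-block `grid_posterior`s)
#'   and `summaries` (one [point_estimates()] row per block).
#' @export
fit_session <- function(trials, grid = param_grid()) {
  blocks <- unique(as.character(trials$block))
  if (!identical(blocks, .BLOCK_ORDER))
    stop("expected blocks in order ", paste(.BLOCK_ORDER, collapse = ", "),
         "; got ", paste(blocks, collapse = ", "))
  posteriors <- vector("list", 5L)
  names(posteriors) <- .BLOCK_ORDER
  prev_self <- NULL
  for (b in .BLOCK_ORDER) {
    is_self <- startsWith(b, "Self")
    prior <- if (is_self) init_uniform_prior(grid, b) else {
      p <- prev_self
      p$block_label <- b
      p$trial_index <- 0L
      p
    }
    bt <- trials[trials$block == b, , drop = FALSE]
    post <- run_block(prior, bt, if (is_self) "free" else "fixed_at_1")
    posteriors[[b]] <- post
    if (is_self) prev_self <- post
  }
  summaries <- do.call(rbind, lapply(.BLOCK_ORDER, function(b) {
    cbind(data.frame(block = b), as.data.frame(point_estimates(posteriors[[b]])))
  }))
  list(posteriors = posteriors, summaries = summaries)
}

#' Marginal summaries of a grid posterior
#'
#' Marginal posterior means, MAP nodes and variances for log k and log
#' beta, by direct weighted sums over the grid. The marginal mean of log k
#' is the canonical point estimate of a participant's discount rate;
#' precision is the reciprocal variance.
#'
#' @param posterior A `grid_posterior`.
#' @return Named list: `logk_mean`, `logk_map`, `logk_variance`,
#'   `logbeta_mean`, `logbeta_variance`.
#' @export
point_estimates <- function(posterior) {
  g <- posterior$grid
  mk <- rowSums(posterior$mass)
  mb <- colSums(posterior$mass)
  logk_mean <- sum(g$logk * mk)
  logbeta_mean <- sum(g$logbeta * mb)
  list(logk_mean = logk_mean,
       logk_map = g$logk[which.max(mk)],
       logk_variance = sum((g$logk - logk_mean)^2 * mk),
       logbeta_mean = logbeta_mean,
       logbeta_variance = sum((g$logbeta - logbeta_mean)^2 * mb))
}

#' Export a posterior as a long data frame
#'
#' One row per grid node (`logk`, `logbeta`, `mass`), suitable for writing
#' to CSV and plotting posterior curves.
#'
#' @param posterior A `grid_posterior`.
#' @return `data.frame` with `logk`, `logbeta`, `mass`.
#' @export
posterior_to_df <- function(posterior) {
  g <- posterior$grid
  data.frame(logk = rep(g$logk, times = length(g$logbeta)),
             logbeta = rep(g$logbeta, each = length(g$logk)),
             mass = as.vector(posterior$mass))
}
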