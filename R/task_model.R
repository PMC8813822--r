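#' Allowed delays for the larger-later option
#'
#' The delayed option is offered at one of seven delays: tomorrow, 1 week,
#' 2 weeks, 4 weeks, 6 weeks, 2 months, or 3 months, expressed in days
#' (months counted as 30-day units).
#'
#' @return Integer vector of delays in days.
#' @export
delay_set <- function() c(1L, 7L, 14L, 28L, 42L, 60L, 90L)

# magnitude bounds in GBP; options are integer pounds
.MAG_MIN <- 1L
.MAG_MAX <- 20L

# parameter ranges on the base-10 log scale
.LOGK_RANGE <- c(-4, 0)
.LOGBETA_RANGE <- c(-1, 1)

#' Discounting parameters on the log scale
#'
#' Bundles a discount rate and a softmax inverse temperature, both on the
#' base-10 logarithm scale. `log_k` must lie in \[-4, 0\] (k in \[1e-4, 1\]):
#' -4 is near-total insensitivity to delay, 0 is very steep discounting.
#' `log_beta` must lie in \[-1, 1\]; values near -1 give noisy choices.
#'
#' @param log_k Base-10 log discount rate.
#' @param log_beta Base-10 log inverse temperature.
#' @return A `discount_params` list with elements `log_k` and `log_beta`.
#' @export
discount_params <- function(log_k, log_beta) {
  stopifnot(is.numeric(log_k), length(log_k) == 1L, is.finite(log_k),
            is.numeric(log_beta), length(log_beta) == 1L, is.finite(log_beta))
  if (log_k < .LOGK_RANGE[1] || log_k > .LOGK_RANGE[2])
    stop("log_k must lie in [", .LOGK_RANGE[1], ", ", .LOGK_RANGE[2], "]")
  if (log_beta < .LOGBETA_RANGE[1] || log_beta > .LOGBETA_RANGE[2])
    stop("log_beta must lie in [", .LOGBETA_RANGE[1], ", ", .LOGBETA_RANGE[2], "]")
  structure(list(log_k = log_k, log_beta = log_beta),
            class = "discount_params")
}

#' Hyperbolic subjective value
#'
#' Computes V = M / (1 + k D): the present subjective value of a reward of
#' magnitude `magnitude` delivered after `delay_days` days, under hyperbolic
#' discounting with rate `k`. A zero delay returns the magnitude unchanged,
#' so the smaller-sooner option is always worth its face value.
#'
#' @param magnitude Reward magnitude (GBP); must be positive. Vectorised.
#' @param delay_days Delay in days; must be non-negative. Vectorised.
#' @param k Discount rate (linear scale, not log); must be positive.
#' @return Subjective value, same units as `magnitude`.
#' @examples
#' subjective_value(8, 0, 0.05)    # 8: no delay, no discount
#' subjective_value(20, 1, 1)      # 10
#' @export
subjective_value <- function(magnitude, delay_days, k) {
  if (any(!is.finite(magnitude)) || any(magnitude <= 0))
    stop("magnitude must be positive and finite")
  if (any(!is.finite(delay_days)) || any(delay_days < 0))
    stop("delay_days must be non-negative and finite")
  if (any(!is.finite(k)) || any(k <= 0))
    stop("k must be positive and finite")
  magnitude / (1 + k * delay_days)
}

#' Softmax probability of choosing the larger-later option
#'
#' Logistic choice rule P(LL) = 1 / (1 + exp(-beta (V_LL - V_SS))). The
#' probability of the smaller-sooner option is its complement. Equal values
#' give P = 0.5 (the indifference point).
#'
#' @param v_ll Subjective value of the larger-later option. Vectorised.
#' @param v_ss Subjective value of the smaller-sooner option. Vectorised.
#' @param beta Inverse temperature (linear scale); must be positive.
#' @return Probability of choosing the larger-later option, in (0, 1).
#' @export
choice_prob_ll <- function(v_ll, v_ss, beta) {
  if (any(!is.finite(beta)) || any(beta <= 0))
    stop("beta must be positive and finite")
  stats::plogis(beta * (v_ll - v_ss))
}

#' Build a table of choice pairs
#'
#' Light constructor validating the smaller-sooner / larger-later structure:
#' integer magnitudes in \[1, 20\], the SS option immediate, the LL option
#' strictly larger and delayed by a member of [delay_set()].
#'
#' @param ss_amount,ll_amount Integer magnitudes (GBP).
#' @param ll_delay_days Delay of the larger-later option, from [delay_set()].
#' @return `data.frame` with columns `ss_amount`, `ll_amount`,
#'   `ll_delay_days`, one row per pair.
#' @export
choice_pairs <- function(ss_amount, ll_amount, ll_delay_days) {
  n <- length(ss_amount)
  stopifnot(length(ll_amount) == n, length(ll_delay_days) == n)
  bad_mag <- ss_amount < .MAG_MIN | ss_amount > .MAG_MAX |
    ll_amount < .MAG_MIN | ll_amount > .MAG_MAX |
    ss_amount != round(ss_amount) | ll_amount != round(ll_amount)
  if (any(bad_mag))
    stop("magnitudes must be integers in [", .MAG_MIN, ", ", .MAG_MAX, "]")
  if (any(ll_amount <= ss_amount))
    stop("ll_amount must exceed ss_amount")
  if (any(!(ll_delay_days %in% delay_set())))
    stop("ll_delay_days must belong to the delay set {",
         paste(delay_set(), collapse = ", "), "}")
  data.frame(ss_amount = as.integer(ss_amount),
             ll_amount = as.integer(ll_amount),
             ll_delay_days = as.integer(ll_delay_days))
}

# P(LL) for each row of a pair table under scalar (log_k, log_beta)
pair_prob_ll <- function(pairs, log_k, log_beta) {
  k <- 10^log_k
  beta <- 10^log_beta
  v_ll <- pairs$ll_amount / (1 + k * pairs$ll_delay_days)
  stats::plogis(beta * (v_ll - pairs$ss_amount))
}

#' Simulate choices for a set of pairs
#'
#' Draws an SS/LL choice for each pair by a Bernoulli draw with the softmax
#' probability implied by the supplied parameters. Uses the ambient RNG
#' stream, so results are reproducible under `set.seed()`.
#'
#' @param pairs Pair table as returned by [choice_pairs()] or
#'   [generate_choice_pairs()].
#' @param log_k,log_beta Parameters on the base-10 log scale.
#' @return Character vector of `"SS"` / `"LL"`, one per pair.
#' @export
simulate_choice <- function(pairs, log_k, log_beta) {
  p_ll <- pair_prob_ll(pairs, log_k, log_beta)
  ifelse(stats::runif(nrow(pairs)) < p_ll, "LL", "SS")
}

#' Generate adaptive choice pairs near the indifference point
#'
#' Produces `n_trials` smaller-sooner / larger-later pairs with integer
#' magnitudes in \[1, 20\] and delays from [delay_set()]. Pairs are sampled
#' uniformly and filtered so that, under the supplied running parameter
#' estimate, the predicted P(LL) stays within 0.4 of the indifference point
#' for at least half the set (in practice almost all pairs pass). This keeps
#' the likelihood informative about log k at every plausible value; a fully
#' random pair set would waste most trials on foregone conclusions.
#'
#' @param n_trials Number of pairs to generate.
#' @param log_k,log_beta Current running estimate used for the
#'   informativeness filter (base-10 log scale).
#' @param max_tries Rejection attempts per pair before accepting the best
#'   candidate seen so far.
#' @return Pair table (`ss_amount`, `ll_amount`, `ll_delay_days`).
#' @export
generate_choice_pairs <- function(n_trials, log_k, log_beta,
                                  max_tries = 40L) {
  stopifnot(n_trials > 0)
  draw_candidates <- function(m) {
    ss <- sample.int(.MAG_MAX - 1L, m, replace = TRUE)        # 1..19
    ll <- ss + vapply(.MAG_MAX - ss,
                      function(r) sample.int(r, 1L), integer(1))
    d <- sample(delay_set(), m, replace = TRUE)
    data.frame(ss_amount = ss, ll_amount = ll, ll_delay_days = d)
  }
  out <- vector("list", n_trials)
  for (i in seq_len(n_trials)) {
    cand <- draw_candidates(max_tries)
    dev <- abs(pair_prob_ll(cand, log_k, log_beta) - 0.5)
    hit <- which(dev < 0.4)
    j <- if (length(hit)) hit[1L] else which.min(dev)
    out[[i]] <- cand[j, , drop = FALSE]
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
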