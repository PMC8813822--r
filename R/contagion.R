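#' Kullback-Leibler divergence between discrete distributions
#'
#' D(p || q) = sum p_i log(p_i / q_i), non-negative and zero only when the
#' distributions coincide. Zero-probability q nodes are floored at `eps`
#' (then q is renormalised) so the divergence stays finite on truncated
#' grids; p nodes with zero mass contribute nothing.
#'
#' @param p,q Probability vectors on the same support.
#' @param base `"nats"` (natural log, default) or `"bits"`.
#' @param eps Floor applied to q before the log ratio.
#' @return Divergence in the chosen unit.
#' @export
kl_divergence <- function(p, q, base = c("nats", "bits"), eps = 1e-30) {
  base <- match.arg(base)
  if (length(p) != length(q))
    stop("p and q must share the same support")
  if (any(p < 0) || any(q < 0)) stop("distributions must be non-negative")
  q <- pmax(q, eps)
  q <- q / sum(q)
  nz <- p > 0
  d <- sum(p[nz] * log(p[nz] / q[nz]))
  if (base == "bits") d <- d / log(2)
  max(d, 0)
}

#' Marginal distribution of log k
#'
#' Collapses a grid posterior over the (nuisance) log beta axis, returning
#' the one-dimensional distribution over log k that the divergence measure
#' compares.
#'
#' @param posterior A `grid_posterior`.
#' @return Numeric vector of masses over the log k axis, summing to 1.
#' @export
marginal_logk <- function(posterior) {
  m <- rowSums(posterior$mass)
  m / sum(m)
}

#' Signed divergence between bracketing Self-block posteriors
#'
#' The contagion statistic: the KL divergence of the post-exposure Self
#' posterior from the pre-exposure one (both marginalised to log k),
#' carrying a sign. A shift of the posterior-mean log k in the direction of
#' the agent makes the value positive; a shift away makes it negative; no
#' shift gives 0. The magnitude reflects both how far the peak moved and
#' how the precision changed.
#'
#' @param self_pre,self_post End-of-Self-block `grid_posterior`s bracketing
#'   the agent's Other block (Self1/Self2 around Other1; Self2/Self3 around
#'   Other2).
#' @param agent_logk The agent's log k.
#' @param base,eps Passed to [kl_divergence()].
#' @return Signed divergence (nats by default).
#' @export
signed_dkl <- function(self_pre, self_post, agent_logk,
                       base = "nats", eps = 1e-30) {
  pre_mean <- point_estimates(self_pre)$logk_mean
  post_mean <- point_estimates(self_post)$logk_mean
  mag <- kl_divergence(marginal_logk(self_post), marginal_logk(self_pre),
                       base = base, eps = eps)
  shift <- post_mean - pre_mean
  toward <- agent_logk - pre_mean
  s <- sign(shift) * sign(toward)
  if (shift == 0) s <- 0
  s * mag
}

# For ingested trial logs the agent parameters are not part of the CSV
# schema; re-derive them. Candidates are the Self1 posterior mean +/- 1
# (clipped). When the trial log is available each Other block's agent
# choices are fitted directly (uniform prior, beta = 1) and the candidate
# nearer that estimate wins; without trials, fall back to the participant's
# own fitted Other-block posterior mean (noisier, since it tracks the
# participant's gradual learning of the agent).
infer_agents_from_fit <- function(fit, trials = NULL) {
  self1 <- point_estimates(fit$posteriors$Self1)$logk_mean
  cand <- c(clip_logk(self1 + 1), clip_logk(self1 - 1))
  lapply(stats::setNames(c("Other1", "Other2"), c("Other1", "Other2")),
         function(b) {
           ref <- if (!is.null(trials)) {
             bt <- trials[trials$block == b, , drop = FALSE]
             bt$choice <- bt$agent_choice
             ap <- run_block(init_uniform_prior(fit$posteriors$Self1$grid, b),
                             bt, "fixed_at_1")
             point_estimates(ap)$logk_mean
           } else {
             point_estimates(fit$posteriors[[b]])$logk_mean
           }
           lk <- cand[which.min(abs(cand - ref))]
           new_agent(paste0("agent_", b), lk, self1)
         })
}

#' Contagion records for one fitted session
#'
#' Builds one record per non-degenerate agent: Other1 is bracketed by the
#' Self1 and Self2 posteriors, Other2 by Self2 and Self3. Each record
#' carries the signed divergence, the raw posterior-mean shift in log k
#' (sharing the divergence's sign rule), the percent accuracy in that Other
#' block, and the agent's direction and distance. Degenerate agents (log k
#' equal to the participant's after clipping) are flagged and excluded from
#' divergence computation.
#'
#' @param fit Output of [fit_session()].
#' @param agents Optional named list (`Other1`, `Other2`) of `agent_spec`s;
#'   when omitted they are re-derived from the fit (and the trial log, if
#'   supplied).
#' @param accuracy Named numeric (`Other1`, `Other2`) percent accuracies.
#' @param participant_id,group Identifiers copied into the records.
#' @param trials Optional trial log used to re-derive agents from the
#'   recorded agent choices.
#' @return `data.frame`, one row per agent: `participant_id`, `group`,
#'   `block`, `direction`, `agent_logk`, `distance`, `signed_dkl`,
#'   `shift_logk`, `accuracy_pct`, `degenerate`.
#' @export
session_contagion <- function(fit, agents = NULL, accuracy,
                              participant_id = "p1", group = "NT",
                              trials = NULL) {
  if (is.null(agents)) agents <- infer_agents_from_fit(fit, trials)
  if (!all(c("Other1", "Other2") %in% names(agents)))
    stop("agents must be named Other1 and Other2")
  brackets <- list(Other1 = c("Self1", "Self2"),
                   Other2 = c("Self2", "Self3"))
  rows <- lapply(c("Other1", "Other2"), function(b) {
    ag <- agents[[b]]
    pre <- fit$posteriors[[brackets[[b]][1]]]
    post <- fit$posteriors[[brackets[[b]][2]]]
    degen <- ag$direction == "degenerate"
    pre_mean <- point_estimates(pre)$logk_mean
    post_mean <- point_estimates(post)$logk_mean
    raw_shift <- post_mean - pre_mean
    sgn <- sign(raw_shift) * sign(ag$log_k - pre_mean)
    data.frame(participant_id = participant_id, group = group, block = b,
               direction = ag$direction, agent_logk = ag$log_k,
               distance = ag$distance,
               signed_dkl = if (degen) NA_real_ else
                 signed_dkl(pre, post, ag$log_k),
               shift_logk = if (degen) NA_real_ else sgn * abs(raw_shift),
               accuracy_pct = unname(accuracy[[b]]),
               degenerate = degen)
  })
  do.call(rbind, rows)
}

#' Cohort-level exclusion rules
#'
#' Applies, in order: (a) the outlier fence — participants whose mean
#' signed divergence across their records lies more than 3 cohort standard
#' deviations from the cohort mean are removed entirely; (b) the
#' same-direction rule — when both of a participant's agents share a
#' direction (possible near the log k boundaries), only the agent with the
#' greater distance from the participant's own discount rate is retained.
#' Degenerate-agent records are dropped first (no divergence is defined for
#' them). Every decision is logged.
#'
#' @param records Cohort `data.frame` of [session_contagion()] rows.
#' @return List: `records` (retained rows), `log` (`data.frame` of
#'   participant, action, reason).
#' @export
apply_exclusions <- function(records) {
  log_rows <- list()
  note <- function(pid, action, reason)
    data.frame(participant_id = pid, action = action, reason = reason)

  degen <- records$degenerate | is.na(records$signed_dkl)
  for (pid in unique(records$participant_id[degen]))
    log_rows[[length(log_rows) + 1L]] <-
      note(pid, "drop_record", "degenerate agent direction")
  records <- records[!degen, , drop = FALSE]

  pm <- tapply(records$signed_dkl, records$participant_id, mean)
  if (length(pm) < 3L) stop("need at least 3 participants")
  fence <- mean(pm) + c(-3, 3) * stats::sd(pm)
  out_ids <- names(pm)[pm < fence[1] | pm > fence[2]]
  for (pid in out_ids)
    log_rows[[length(log_rows) + 1L]] <-
      note(pid, "exclude_participant",
           sprintf("mean signed D_KL %.3f outside 3-SD fence [%.3f, %.3f]",
                   pm[[pid]], fence[1], fence[2]))
  records <- records[!(records$participant_id %in% out_ids), , drop = FALSE]

  keep <- rep(TRUE, nrow(records))
  for (pid in unique(records$participant_id)) {
    idx <- which(records$participant_id == pid)
    if (length(idx) == 2L &&
        records$direction[idx[1]] == records$direction[idx[2]]) {
      drop_i <- idx[which.min(records$distance[idx])]
      keep[drop_i] <- FALSE
      log_rows[[length(log_rows) + 1L]] <-
        note(pid, "drop_record",
             sprintf("two %s agents; kept greatest distance %.3f",
                     records$direction[idx[1]], max(records$distance[idx])))
    }
  }
  records <- records[keep, , drop = FALSE]
  rownames(records) <- NULL
  log_df <- if (length(log_rows)) do.call(rbind, log_rows) else
    data.frame(participant_id = character(), action = character(),
               reason = character())
  list(records = records, log = log_df)
}
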