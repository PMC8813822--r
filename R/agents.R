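clip_logk <- function(x) pmin(pmax(x, .LOGK_RANGE[1]), .LOGK_RANGE[2])

new_agent <- function(agent_id, log_k, participant_logk) {
  d <- log_k - participant_logk
  direction <- if (d > 0) "impulsive" else if (d < 0) "patient" else "degenerate"
  structure(list(agent_id = agent_id, log_k = log_k, beta = 1,
                 direction = direction, distance = abs(d)),
            class = "agent_spec")
}

#' Derive the two simulated agents from a participant's estimate
#'
#' Each agent's log k is the participant's log k plus or minus one, clipped
#' into \[-4, 0\]; the agent acts with softmax inverse temperature fixed at
#' 1. The +1 agent discounts more steeply (impulsive), the -1 agent less
#' (patient). `order_flag` counterbalances which target is met first as
#' Other1. When clipping collapses a target onto the participant's own log
#' k the direction is `"degenerate"` and downstream analysis flags the
#' record instead of computing a divergence for it.
#'
#' @param participant_logk Participant's log k (typically the Self1
#'   posterior mean).
#' @param order_flag Logical; `TRUE` puts the impulsive (+1) agent first.
#' @return List of two `agent_spec`s named `Other1`, `Other2`; each carries
#'   `log_k`, `beta = 1`, `direction` and the absolute `distance` to the
#'   participant.
#' @export
derive_agents <- function(participant_logk, order_flag = TRUE) {
  stopifnot(participant_logk >= .LOGK_RANGE[1],
            participant_logk <= .LOGK_RANGE[2])
  imp <- new_agent("agent_impulsive", clip_logk(participant_logk + 1),
                   participant_logk)
  pat <- new_agent("agent_patient", clip_logk(participant_logk - 1),
                   participant_logk)
  ord <- if (isTRUE(order_flag)) list(imp, pat) else list(pat, imp)
  names(ord) <- c("Other1", "Other2")
  ord
}

#' Simulate an agent's choices
#'
#' The agent chooses by the same hyperbolic-value softmax as participants,
#' at its own log k with beta = 1. Choices are sampled (not argmaxed), so
#' even a learner that knows the agent's parameters exactly cannot predict
#' every choice.
#'
#' @param pairs Pair table.
#' @param agent An `agent_spec`.
#' @return Character vector of `"SS"`/`"LL"`.
#' @export
agent_choice <- function(pairs, agent) {
  stopifnot(inherits(agent, "agent_spec"))
  simulate_choice(pairs, agent$log_k, log_beta = 0)  # beta = 10^0 = 1
}

#' Score trial feedback
#'
#' Feedback is `"correct"` when the participant's choice on the agent's
#' behalf matches the agent's own (sampled) choice, else `"incorrect"`.
#'
#' @param participant_choice,agent_choice `"SS"`/`"LL"` vectors.
#' @return Character vector of `"correct"`/`"incorrect"`.
#' @export
score_feedback <- function(participant_choice, agent_choice) {
  ok <- c(participant_choice, agent_choice) %in% c("SS", "LL")
  if (!all(ok)) stop("choices must be 'SS' or 'LL'")
  ifelse(participant_choice == agent_choice, "correct", "incorrect")
}

#' Percent accuracy over a block
#'
#' Matches divided by trials, times 100 — the percentage form makes blocks
#' of 30 and 50 trials comparable.
#'
#' @param feedback Vector of `"correct"`/`"incorrect"`.
#' @return Percent accuracy in \[0, 100\].
#' @export
block_accuracy <- function(feedback) {
  100 * mean(feedback == "correct")
}
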