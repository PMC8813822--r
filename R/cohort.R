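# Population defaults per group: log k and log beta means/SDs from the
# observed NT and ASC samples, AQ subscale score distributions (Likert
# scoring, 10 items per subscale scored 1-4, so each total lies in [10, 40]).
.GROUP_DEFAULTS <- list(
  NT = list(logk_mean = -1.68, logk_sd = 0.67,
            logbeta_mean = -0.19, logbeta_sd = 0.35,
            age_mean = 21.41, age_sd = 2.09, p_female = 0.60),
  ASC = list(logk_mean = -2.28, logk_sd = 0.78,
             logbeta_mean = -0.08, logbeta_sd = 0.52,
             age_mean = 22.33, age_sd = 3.63, p_female = 2 / 3)
)

.AQ_SUBSCALES <- c("social_skills", "attention_switching",
                   "attention_to_detail", "communication", "imagination")
.AQ_PARAMS <- list(
  NT = list(mean = c(22.28, 25.26, 25.10, 21.47, 21.75),
            sd = c(4.50, 3.93, 4.21, 4.68, 4.85)),
  ASC = list(mean = c(29.83, 33.17, 29.42, 31.67, 25.42),
             sd = c(4.13, 3.66, 4.58, 3.89, 3.83))
)

# truncated-normal draws by rejection; sd = 0 collapses to the mean
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  if (sd < 0) stop("sd must be non-negative")
  if (sd == 0) return(rep(pmin(pmax(mean, lo), hi), n))
  out <- numeric(n)
  need <- seq_len(n)
  while (length(need)) {
    draw <- stats::rnorm(length(need), mean, sd)
    ok <- draw >= lo & draw <= hi
    out[need[ok]] <- draw[ok]
    need <- need[!ok]
  }
  out
}

#' Configuration for a synthetic cohort
#'
#' Bundles the population parameters and task settings used to generate a
#' cohort of simulated participants. Defaults for the log k / log beta
#' population distributions follow the observed group statistics (see
#' `group`); the generative contagion strengths default to a modest shift
#' with a patient-direction bias (alpha_patient = 0.4 >
#' alpha_impulsive = 0.25).
#'
#' @param n_participants Cohort size.
#' @param group `"NT"` or `"ASC"` (selects population defaults).
#' @param trials_per_block 30 or 50 trials per block.
#' @param alpha_impulsive,alpha_patient Contagion strengths in \[0, 1\]:
#'   after each Other block the true log k moves
#'   `alpha * (agent log k - log k)` toward that agent.
#' @param logk_mean,logk_sd,logbeta_mean,logbeta_sd Population parameters;
#'   `NULL` takes the group default.
#' @param n_logk,n_logbeta Grid resolution for the in-task learner and the
#'   analysis fits.
#' @param seed Master seed recorded in all outputs.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_participants = 30L, group = c("NT", "ASC"),
                          trials_per_block = 30L,
                          alpha_impulsive = 0.25, alpha_patient = 0.4,
                          logk_mean = NULL, logk_sd = NULL,
                          logbeta_mean = NULL, logbeta_sd = NULL,
                          n_logk = 101L, n_logbeta = 51L, seed = 1L) {
  group <- match.arg(group)
  if (!trials_per_block %in% c(30L, 50L))
    stop("trials_per_block must be 30 or 50")
  stopifnot(alpha_impulsive >= 0, alpha_impulsive <= 1,
            alpha_patient >= 0, alpha_patient <= 1, n_participants >= 1)
  def <- .GROUP_DEFAULTS[[group]]
  cfg <- list(n_participants = as.integer(n_participants), group = group,
              trials_per_block = as.integer(trials_per_block),
              alpha_impulsive = alpha_impulsive,
              alpha_patient = alpha_patient,
              logk_mean = logk_mean %||% def$logk_mean,
              logk_sd = logk_sd %||% def$logk_sd,
              logbeta_mean = logbeta_mean %||% def$logbeta_mean,
              logbeta_sd = logbeta_sd %||% def$logbeta_sd,
              n_logk = as.integer(n_logk), n_logbeta = as.integer(n_logbeta),
              seed = as.integer(seed))
  class(cfg) <- "cohort_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write a cohort configuration as YAML
#'
#' @param path File path.
#' @param config A `cohort_config`.
#' @return `read_cohort_config` returns a `cohort_config`;
#'   `write_cohort_config` returns `path` invisibly.
#' @export
read_cohort_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(cohort_config, raw)
}

#' @rdname read_cohort_config
#' @export
write_cohort_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Sample one participant's ground truth
#'
#' True log k and log beta are drawn from normals truncated to the
#' parameter ranges, with the population mean/SD from the config.
#'
#' @param config A [cohort_config()].
#' @param participant_id Identifier for the spec.
#' @param order_flag Counterbalance bit: `TRUE` makes Other1 the impulsive
#'   agent.
#' @return A `participant_spec` list with the true parameters, contagion
#'   strengths, AQ subscale scores and group label.
#' @export
sample_participant <- function(config, participant_id = "p1",
                               order_flag = TRUE) {
  aq <- sample_aq(config$group, 1L)
  demo <- .GROUP_DEFAULTS[[config$group]]
  structure(list(
    participant_id = participant_id, group = config$group,
    true_log_k = rtrunc_norm(1, config$logk_mean, config$logk_sd,
                             .LOGK_RANGE[1], .LOGK_RANGE[2]),
    true_log_beta = rtrunc_norm(1, config$logbeta_mean, config$logbeta_sd,
                                .LOGBETA_RANGE[1], .LOGBETA_RANGE[2]),
    alpha_impulsive = config$alpha_impulsive,
    alpha_patient = config$alpha_patient,
    order_flag = order_flag,
    age = round(rtrunc_norm(1, demo$age_mean, demo$age_sd, 18, 60)),
    gender = sample(c("female", "male"), 1L,
                    prob = c(demo$p_female, 1 - demo$p_female)),
    aq = stats::setNames(as.numeric(aq), colnames(aq))),
    class = "participant_spec")
}

#' Sample Autism-Spectrum Quotient subscale scores
#'
#' Five subscale totals (Likert scoring: 10 items each, 1-4 per item) drawn
#' from normals with the group's observed means and SDs, rounded to
#' integers and clipped to the feasible range \[10, 40\].
#'
#' @param group `"NT"` or `"ASC"`.
#' @param n Number of participants.
#' @return `n x 5` matrix with subscale columns.
#' @export
sample_aq <- function(group = c("NT", "ASC"), n = 1L) {
  group <- match.arg(group)
  par <- .AQ_PARAMS[[group]]
  out <- vapply(seq_along(.AQ_SUBSCALES), function(j) {
    pmin(pmax(round(stats::rnorm(n, par$mean[j], par$sd[j])), 10), 40)
  }, numeric(n))
  out <- matrix(out, nrow = n)
  colnames(out) <- .AQ_SUBSCALES
  out
}

# participant's softmax response on the agent's behalf: beta = 1 at the
# current posterior-mean estimate of the agent's log k
respond_for_agent <- function(pairs, est_logk) {
  simulate_choice(pairs, est_logk, log_beta = 0)
}

#' Simulate one participant's five-block session
#'
#' Generates the full Self1, Other1, Self2, Other2, Self3 trial log.
#' Self-block choices are sampled from the participant's true parameters;
#' choice pairs adapt trial-by-trial to an online grid estimate (log beta
#' taken as 0.3 before the first Self trial of each block). The two agents
#' are derived from the online Self1 posterior mean (+1 / -1, clipped,
#' order counterbalanced). During Other blocks the participant tracks the
#' agent with the same grid learner (prior carried over from the preceding
#' Self block, beta clamped to 1), responds by sampling the beta = 1
#' softmax at its current posterior-mean estimate of the agent's log k,
#' and updates on the agent's revealed choice. After each Other block the
#' true log k shifts `alpha * (agent log k - log k)` toward that agent —
#' the generative contagion the analysis must recover.
#'
#' @param spec A [sample_participant()] spec.
#' @param config A [cohort_config()].
#' @param grid Optional [param_grid()]; defaults to the config resolution.
#' @return List: `trials` (schema data frame), `agents` (named list of
#'   `agent_spec`), `truth` (one-row data frame of ground-truth values,
#'   including the post-shift log k before Self2 and Self3).
#' @export
simulate_session <- function(spec, config, grid = NULL) {
  if (is.null(grid)) grid <- param_grid(config$n_logk, config$n_logbeta)
  nt <- config$trials_per_block
  true_logk <- spec$true_log_k
  true_logbeta <- spec$true_log_beta
  agents <- NULL
  logk_by_block <- c(Self1 = true_logk, Self2 = NA_real_, Self3 = NA_real_)
  rows <- vector("list", 5L)
  prev_self_post <- NULL

  for (bi in seq_along(.BLOCK_ORDER)) {
    b <- .BLOCK_ORDER[bi]
    is_self <- startsWith(b, "Self")
    if (is_self) {
      post <- init_uniform_prior(grid, b)
      logk_by_block[[b]] <- true_logk
    } else {
      post <- prev_self_post
      post$block_label <- b
      post$trial_index <- 0L
      agent <- agents[[b]]
    }
    ss <- ll <- dl <- integer(nt)
    ch <- ach <- fb <- character(nt)
    for (t in seq_len(nt)) {
      est <- point_estimates(post)
      if (is_self) {
        est_logbeta <- if (t == 1L) 0.3 else est$logbeta_mean
        pair <- generate_choice_pairs(1L, est$logk_mean, est_logbeta)
        choice <- simulate_choice(pair, true_logk, true_logbeta)
        post <- update_posterior(post, pair, choice, "free")
        a_ch <- NA_character_; f <- NA_character_
      } else {
        pair <- generate_choice_pairs(1L, est$logk_mean, 0)
        a_ch <- agent_choice(pair, agent)
        choice <- respond_for_agent(pair, est$logk_mean)
        f <- score_feedback(choice, a_ch)
        post <- update_posterior(post, pair, a_ch, "fixed_at_1")
      }
      ss[t] <- pair$ss_amount; ll[t] <- pair$ll_amount
      dl[t] <- pair$ll_delay_days
      ch[t] <- choice; ach[t] <- a_ch; fb[t] <- f
    }
    rows[[bi]] <- data.frame(
      participant_id = spec$participant_id, group = spec$group, block = b,
      trial = seq_len(nt), ss_amount = ss, ll_amount = ll,
      ll_delay_days = dl, choice = ch, agent_id = if (is_self) NA_character_
      else agent$agent_id, agent_choice = ach, feedback = fb)
    if (is_self) {
      prev_self_post <- post
      if (b == "Self1")
        agents <- derive_agents(point_estimates(post)$logk_mean,
                                spec$order_flag)
    } else {
      alpha <- switch(agent$direction,
                      impulsive = spec$alpha_impulsive,
                      patient = spec$alpha_patient,
                      0)
      true_logk <- clip_logk(true_logk + alpha * (agent$log_k - true_logk))
    }
  }

  truth <- data.frame(
    participant_id = spec$participant_id, group = spec$group,
    true_log_k = spec$true_log_k, true_log_beta = spec$true_log_beta,
    log_k_self2 = logk_by_block[["Self2"]],
    log_k_self3 = logk_by_block[["Self3"]],
    alpha_impulsive = spec$alpha_impulsive,
    alpha_patient = spec$alpha_patient,
    order_flag = spec$order_flag,
    age = spec$age, gender = spec$gender,
    agent1_logk = agents$Other1$log_k,
    agent1_direction = agents$Other1$direction,
    agent2_logk = agents$Other2$log_k,
    agent2_direction = agents$Other2$direction)
  truth <- cbind(truth, as.data.frame(t(spec$aq)))
  list(trials = do.call(rbind, rows), agents = agents, truth = truth)
}

#' Simulate and fit a single Self block
#'
#' Lean path for parameter-recovery studies: one block of adaptive trials
#' answered from fixed true parameters, fitted online from a uniform prior
#' with beta free. Pairs adapt to the running posterior mean exactly as in
#' the full session.
#'
#' @param log_k,log_beta True parameters (base-10 log scale).
#' @param n_trials Number of trials.
#' @param grid A [param_grid()].
#' @return List: `trials` (pair + choice data frame), `posterior`
#'   (end-of-block `grid_posterior`), `estimates` ([point_estimates()]).
#' @export
simulate_self_block <- function(log_k, log_beta, n_trials = 50L,
                                grid = param_grid()) {
  post <- init_uniform_prior(grid)
  ss <- ll <- dl <- integer(n_trials)
  ch <- character(n_trials)
  for (t in seq_len(n_trials)) {
    est <- point_estimates(post)
    est_logbeta <- if (t == 1L) 0.3 else est$logbeta_mean
    pair <- generate_choice_pairs(1L, est$logk_mean, est_logbeta)
    choice <- simulate_choice(pair, log_k, log_beta)
    post <- update_posterior(post, pair, choice, "free")
    ss[t] <- pair$ss_amount; ll[t] <- pair$ll_amount
    dl[t] <- pair$ll_delay_days; ch[t] <- choice
  }
  list(trials = data.frame(ss_amount = ss, ll_amount = ll,
                           ll_delay_days = dl, choice = ch),
       posterior = post, estimates = point_estimates(post))
}

#' Simulate a full cohort in memory
#'
#' Seeds the RNG from the config, draws each participant's ground truth
#' (counterbalancing the agent order by alternation) and simulates their
#' session.
#'
#' @param config A [cohort_config()].
#' @return List: `trials` (stacked schema data frame), `truth` (one row per
#'   participant), `config`.
#' @export
simulate_cohort <- function(config) {
  set.seed(config$seed)
  grid <- param_grid(config$n_logk, config$n_logbeta)
  trials <- vector("list", config$n_participants)
  truth <- vector("list", config$n_participants)
  for (i in seq_len(config$n_participants)) {
    spec <- sample_participant(config, sprintf("%s%03d", config$group, i),
                               order_flag = (i %% 2L == 1L))
    sess <- simulate_session(spec, config, grid)
    trials[[i]] <- sess$trials
    truth[[i]] <- sess$truth
  }
  list(trials = do.call(rbind, trials), truth = do.call(rbind, truth),
       config = config)
}

#' Generate a cohort and write it to disk
#'
#' Writes the trial log (schema: participant_id, group, block, trial,
#' ss_amount, ll_amount, ll_delay_days, choice, agent_id, agent_choice,
#' feedback) and the ground-truth table as CSV, plus the config (seed
#' included) as YAML, into `dir`.
#'
#' @param config A [cohort_config()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the [simulate_cohort()] result with `$paths` added.
#' @export
generate_cohort <- function(config, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cohort <- simulate_cohort(config)
  paths <- list(trials = file.path(dir, "trials.csv"),
                truth = file.path(dir, "truth.csv"),
                config = file.path(dir, "cohort_config.yaml"))
  write_trials(cohort$trials, paths$trials)
  utils::write.csv(cohort$truth, paths$truth, row.names = FALSE)
  write_cohort_config(config, paths$config)
  cohort$paths <- paths
  invisible(cohort)
}

#' Fit every session in a cohort and extract contagion records
#'
#' Splits the trial log by participant, fits the five-block schedule,
#' computes percent accuracy in each Other block from the feedback column,
#' and assembles the cohort's contagion records. Agents are re-derived
#' from each participant's fit unless a truth table is supplied.
#'
#' @param trials Cohort trial log (schema data frame).
#' @param grid A [param_grid()].
#' @param truth Optional truth table from [simulate_cohort()]; when given,
#'   the true agent parameters are used instead of re-derived ones.
#' @return Cohort records `data.frame` (one row per participant x agent).
#' @export
cohort_contagion <- function(trials, grid = param_grid(), truth = NULL) {
  ids <- unique(trials$participant_id)
  recs <- lapply(ids, function(pid) {
    tr <- trials[trials$participant_id == pid, , drop = FALSE]
    fit <- fit_session(tr, grid)
    acc <- vapply(c("Other1", "Other2"), function(b)
      block_accuracy(tr$feedback[tr$block == b]), numeric(1))
    agents <- NULL
    if (!is.null(truth)) {
      tt <- truth[truth$participant_id == pid, , drop = FALSE]
      self1 <- point_estimates(fit$posteriors$Self1)$logk_mean
      agents <- list(Other1 = new_agent("agent_Other1", tt$agent1_logk, self1),
                     Other2 = new_agent("agent_Other2", tt$agent2_logk, self1))
    }
    session_contagion(fit, agents = agents, accuracy = acc,
                      participant_id = pid, group = tr$group[1],
                      trials = tr)
  })
  out <- do.call(rbind, recs)
  rownames(out) <- NULL
  out
}
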