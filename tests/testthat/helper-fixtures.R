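# Shared fixtures: grids built once; small constructors for hand-made
# posteriors and contagion records.

GRID_FULL <- param_grid()          # 101 x 51, the analysis default
GRID_COARSE <- param_grid(41, 21)  # cheap grid for simulation-heavy tests

# posterior with independent Gaussian-shaped mass over the two axes
gaussian_posterior <- function(grid, logk_mu, logk_sd = 0.3,
                               logbeta_mu = 0, logbeta_sd = 0.3,
                               block_label = "Self1") {
  mass <- outer(stats::dnorm(grid$logk, logk_mu, logk_sd),
                stats::dnorm(grid$logbeta, logbeta_mu, logbeta_sd))
  mass <- mass / sum(mass)
  structure(list(grid = grid, mass = mass, block_label = block_label,
                 trial_index = 0L),
            class = "grid_posterior")
}

# random trial block: adaptive-ish pairs with choices from fixed params
random_trials <- function(n, log_k = -2, log_beta = 0) {
  pairs <- generate_choice_pairs(n, log_k, log_beta)
  pairs$choice <- simulate_choice(pairs, log_k, log_beta)
  pairs
}

# cohort records table for exclusion-rule tests
make_records <- function(pid, direction, signed_dkl, distance = 1,
                         accuracy = 75, degenerate = FALSE) {
  data.frame(participant_id = pid, group = "NT",
             block = rep_len(c("Other1", "Other2"), length(pid)),
             direction = direction, agent_logk = NA_real_,
             distance = distance, signed_dkl = signed_dkl,
             shift_logk = signed_dkl / 10, accuracy_pct = accuracy,
             degenerate = degenerate)
}
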