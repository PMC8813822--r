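.TRIAL_COLUMNS <- c("participant_id", "group", "block", "trial",
                    "ss_amount", "ll_amount", "ll_delay_days", "choice",
                    "agent_id", "agent_choice", "feedback")

#' Read a trial-log CSV
#'
#' Validates the fixed schema (participant_id, group, block, trial,
#' ss_amount, ll_amount, ll_delay_days, choice, agent_id, agent_choice,
#' feedback) and the value domains, naming the offending column and line
#' on failure.
#'
#' @param path CSV path.
#' @return Trial-log `data.frame`.
#' @export
read_trials <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(.TRIAL_COLUMNS, names(df))
  if (length(miss))
    stop("trial CSV ", path, " missing column(s): ",
         paste(miss, collapse = ", "))
  df <- df[.TRIAL_COLUMNS]
  bad_choice <- which(!df$choice %in% c("SS", "LL"))
  if (length(bad_choice))
    stop("invalid choice value at line ", bad_choice[1] + 1L,
         " (must be SS or LL)")
  bad_block <- which(!df$block %in% .BLOCK_ORDER)
  if (length(bad_block))
    stop("invalid block value at line ", bad_block[1] + 1L)
  bad_fb <- which(!(is.na(df$feedback) |
                      df$feedback %in% c("correct", "incorrect")))
  if (length(bad_fb))
    stop("invalid feedback value at line ", bad_fb[1] + 1L)
  df
}

#' Write a trial-log CSV
#'
#' @param trials Trial-log `data.frame` with the schema columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_trials <- function(trials, path) {
  miss <- setdiff(.TRIAL_COLUMNS, names(trials))
  if (length(miss))
    stop("trials missing column(s): ", paste(miss, collapse = ", "))
  utils::write.csv(trials[.TRIAL_COLUMNS], path, row.names = FALSE,
                   na = "NA")
  invisible(path)
}

#' Write a markdown summary of a stats list
#'
#' Renders the test results and descriptives from [run_pipeline()] as a
#' small markdown report (a descriptives table plus one row per test).
#'
#' @param stats Named list mixing `td_test_result`s and data frames, as
#'   produced by [run_pipeline()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_stats_report <- function(stats, path) {
  lines <- c("# Analysis summary", "")
  if (!is.null(stats$descriptives)) {
    d <- stats$descriptives
    lines <- c(lines, "## Descriptives", "",
               "| direction | n | mean signed D_KL | SD | mean accuracy % |",
               "|---|---|---|---|---|",
               sprintf("| %s | %d | %.3f | %.3f | %.2f |", d$direction, d$n,
                       d$mean_signed_dkl, d$sd_signed_dkl,
                       d$mean_accuracy_pct), "")
  }
  tests <- Filter(function(x) inherits(x, "td_test_result"), stats)
  if (length(tests)) {
    lines <- c(lines, "## Tests", "",
               "| analysis | method | statistic | df | p | effect | BF | n |",
               "|---|---|---|---|---|---|---|---|")
    for (nm in names(tests)) {
      r <- tests[[nm]]
      lines <- c(lines, sprintf(
        "| %s | %s | %.3f | %s | %.4g | %s = %.3f | %s = %.3g | %s |",
        nm, r$method, r$statistic,
        if (is.null(r$df)) "" else format(round(r$df, 2)), r$p_value,
        r$effect_label, r$effect_size, r$bf_label, r$bayes_factor,
        paste(r$n, collapse = "/")))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Simulates (or ingests) a cohort, fits every session, computes contagion
#' records, applies the exclusion rules, runs the core statistics
#' (one-sample contagion tests per agent direction, the paired robust
#' direction test on divergence, the paired direction test on accuracy,
#' and divergence-accuracy correlations per direction), and writes the
#' trial CSV, the records CSV, the exclusion log, posterior-marginal
#' snapshots for the first participants, a markdown/JSON stats report and
#' a seed-stamped run manifest into `out_dir`.
#'
#' @param config A [cohort_config()]; ignored when `trials_csv` is given
#'   except for the grid resolution and seed.
#' @param out_dir Output directory; `NULL` skips all file output.
#' @param trials_csv Optional path to an existing trial log to ingest
#'   instead of simulating.
#' @return List: `records`, `excluded` (exclusion log), `stats` (named
#'   list of `td_test_result`s and summaries), `trials`, `truth` (NULL
#'   for ingested data), `config`.
#' @export
run_pipeline <- function(config = cohort_config(), out_dir = NULL,
                         trials_csv = NULL) {
  grid <- param_grid(config$n_logk, config$n_logbeta)
  if (is.null(trials_csv)) {
    cohort <- simulate_cohort(config)
    trials <- cohort$trials
    truth <- cohort$truth
  } else {
    trials <- read_trials(trials_csv)
    truth <- NULL
  }
  set.seed(config$seed + 1L)  # analysis-stage draws (tie-breaks) only
  records <- cohort_contagion(trials, grid)
  excl <- apply_exclusions(records)
  kept <- excl$records

  stats_out <- list()
  for (dir in c("impulsive", "patient")) {
    v <- kept$signed_dkl[kept$direction == dir]
    if (length(v) >= 3)
      stats_out[[paste0("contagion_", dir)]] <- contagion_one_sample(v, dir)
  }
  wide <- merge(
    kept[kept$direction == "impulsive",
         c("participant_id", "signed_dkl", "accuracy_pct")],
    kept[kept$direction == "patient",
         c("participant_id", "signed_dkl", "accuracy_pct")],
    by = "participant_id", suffixes = c("_imp", "_pat"))
  if (nrow(wide) >= 5) {
    stats_out$direction_on_dkl <-
      yuen_t(wide$signed_dkl_imp, wide$signed_dkl_pat, paired = TRUE)
    stats_out$direction_on_accuracy <-
      accuracy_direction_test(wide$accuracy_pct_imp, wide$accuracy_pct_pat)
    stats_out$dkl_accuracy_impulsive <-
      dkl_accuracy_correlation(wide$signed_dkl_imp, wide$accuracy_pct_imp)
    stats_out$dkl_accuracy_patient <-
      dkl_accuracy_correlation(wide$signed_dkl_pat, wide$accuracy_pct_pat)
  }
  stats_out$descriptives <- do.call(rbind, lapply(
    split(kept, kept$direction), function(d)
      data.frame(direction = d$direction[1], n = nrow(d),
                 mean_signed_dkl = mean(d$signed_dkl),
                 sd_signed_dkl = stats::sd(d$signed_dkl),
                 mean_accuracy_pct = mean(d$accuracy_pct))))
  rownames(stats_out$descriptives) <- NULL

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    write_trials(trials, file.path(out_dir, "trials.csv"))
    # end-of-block log k marginals for a few participants, for plotting
    # posterior-shift curves
    snap_ids <- utils::head(unique(trials$participant_id), 3L)
    snaps <- do.call(rbind, lapply(snap_ids, function(pid) {
      fit <- fit_session(trials[trials$participant_id == pid, ], grid)
      do.call(rbind, lapply(names(fit$posteriors), function(b)
        data.frame(participant_id = pid, block = b, logk = grid$logk,
                   mass = marginal_logk(fit$posteriors[[b]]))))
    }))
    utils::write.csv(snaps, file.path(out_dir, "posterior_snapshots.csv"),
                     row.names = FALSE)
    write_stats_report(stats_out, file.path(out_dir, "stats.md"))
    if (requireNamespace("jsonlite", quietly = TRUE)) {
      tests <- Filter(function(x) inherits(x, "td_test_result"), stats_out)
      jsonlite::write_json(
        list(tests = lapply(tests, unclass),
             descriptives = stats_out$descriptives),
        file.path(out_dir, "stats.json"), auto_unbox = TRUE, digits = NA)
    }
    utils::write.csv(kept, file.path(out_dir, "contagion_records.csv"),
                     row.names = FALSE)
    utils::write.csv(excl$log, file.path(out_dir, "exclusion_log.csv"),
                     row.names = FALSE)
    utils::write.csv(stats_out$descriptives,
                     file.path(out_dir, "descriptives.csv"),
                     row.names = FALSE)
    manifest <- c(sprintf("seed: %d", config$seed),
                  sprintf("n_participants: %d", config$n_participants),
                  sprintf("group: %s", config$group),
                  sprintf("trials_per_block: %d", config$trials_per_block),
                  sprintf("grid: %d x %d", config$n_logk, config$n_logbeta),
                  sprintf("package: tdcontagion %s",
                          as.character(utils::packageVersion("tdcontagion"))))
    writeLines(manifest, file.path(out_dir, "manifest.txt"))
  }
  list(records = records, kept = kept, excluded = excl$log,
       stats = stats_out, trials = trials, truth = truth, config = config)
}
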