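#!/usr/bin/env Rscript
# Step 3 — the within-NT statistical battery.
#
# One-sample contagion tests per agent direction (Shapiro-gated t /
# Wilcoxon, JZS Bayes factors), the robust paired test of direction on
# D_KL, the paired direction test on accuracy, D_KL-accuracy correlations,
# and the AQ regression on the two NT cohorts collapsed (study indicator,
# accuracy and the five AQ subscales predicting D_KL, per direction).
# Outputs: results/stats/*.csv and a printed summary.

suppressMessages(library(tdcontagion))

dir.create("results/stats", recursive = TRUE, showWarnings = FALSE)
res_rows <- list()
note <- function(sample, analysis, r)
  data.frame(sample = sample, analysis = analysis, method = r$method,
             statistic = r$statistic,
             df = if (is.null(r$df)) NA_real_ else r$df,
             p = r$p_value, effect = r$effect_size,
             effect_label = r$effect_label, bf = r$bayes_factor,
             n = paste(r$n, collapse = "/"))

recs <- lapply(c(study1 = "study1", study2 = "study2"), function(nm)
  read.csv(file.path("results/contagion", paste0(nm, "_records.csv"))))

for (nm in names(recs)) {
  rr <- recs[[nm]]
  for (d in c("impulsive", "patient")) {
    r <- contagion_one_sample(rr$signed_dkl[rr$direction == d], d)
    cat(sprintf("%s %-9s: ", nm, d)); print(r)
    res_rows[[length(res_rows) + 1]] <- note(nm, paste("contagion", d), r)
  }
  wide <- merge(rr[rr$direction == "impulsive",
                   c("participant_id", "signed_dkl", "accuracy_pct")],
                rr[rr$direction == "patient",
                   c("participant_id", "signed_dkl", "accuracy_pct")],
                by = "participant_id", suffixes = c("_imp", "_pat"))
  r <- yuen_t(wide$signed_dkl_imp, wide$signed_dkl_pat, paired = TRUE)
  res_rows[[length(res_rows) + 1]] <- note(nm, "direction on D_KL", r)
  r <- accuracy_direction_test(wide$accuracy_pct_imp, wide$accuracy_pct_pat)
  res_rows[[length(res_rows) + 1]] <- note(nm, "direction on accuracy", r)
  for (d in c("imp", "pat")) {
    r <- dkl_accuracy_correlation(wide[[paste0("signed_dkl_", d)]],
                                  wide[[paste0("accuracy_pct_", d)]])
    res_rows[[length(res_rows) + 1]] <-
      note(nm, paste("D_KL ~ accuracy", d), r)
  }
}

# AQ regression on the collapsed NT cohorts, per agent direction
truth <- rbind(
  cbind(read.csv("results/cohorts/study1/truth.csv"), study = 0),
  cbind(read.csv("results/cohorts/study2/truth.csv"), study = 1))
all_recs <- rbind(cbind(recs$study1, study = 0), cbind(recs$study2, study = 1))
aq_cols <- c("social_skills", "attention_switching", "attention_to_detail",
             "communication", "imagination")
merged <- merge(all_recs, truth[c("participant_id", "study", aq_cols)],
                by = c("participant_id", "study"))
reg_rows <- list()
for (d in c("impulsive", "patient")) {
  md <- merged[merged$direction == d, ]
  dat <- data.frame(dkl = md$signed_dkl, group_indicator = md$study,
                    accuracy = md$accuracy_pct, md[aq_cols])
  fit <- aq_regression(dat)
  cat(sprintf("AQ regression (%s): R2 = %.3f, F(%d, %d) = %.2f, p = %.3f\n",
              d, fit$r_squared, fit$df[1], fit$df[2], fit$f_statistic,
              fit$p_value))
  reg_rows[[d]] <- cbind(direction = d, fit$coefficients,
                         r_squared = fit$r_squared, p_model = fit$p_value)
}

write.csv(do.call(rbind, res_rows), "results/stats/nt_battery.csv",
          row.names = FALSE)
write.csv(do.call(rbind, reg_rows), "results/stats/aq_regression.csv",
          row.names = FALSE)
cat("done\n")
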