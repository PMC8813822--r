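#!/usr/bin/env Rscript
# Step 1 — simulate the three study-sized cohorts.
#
# Two neurotypical (NT) cohorts mirror the two study samples: a 48-person
# cohort run at 50 trials per block and a 98-person cohort at 30 trials
# per block. A 12-person ASC cohort (30 trials) mirrors the clinical
# sample. All use the package's default generative contagion strengths
# (alpha_patient = 0.4, alpha_impulsive = 0.25). Trial logs, ground truth
# and configs are written under results/cohorts/.

suppressMessages(library(tdcontagion))

out <- "results/cohorts"
configs <- list(
  study1 = cohort_config(n_participants = 48, group = "NT",
                         trials_per_block = 50, seed = 101),
  study2 = cohort_config(n_participants = 98, group = "NT",
                         trials_per_block = 30, seed = 102),
  asc = cohort_config(n_participants = 12, group = "ASC",
                      trials_per_block = 30, seed = 103)
)

for (nm in names(configs)) {
  dir <- file.path(out, nm)
  co <- generate_cohort(configs[[nm]], dir)
  cat(sprintf("%s: %d participants x %d trial rows -> %s\n", nm,
              configs[[nm]]$n_participants, nrow(co$trials), dir))
  cat(sprintf("  true log k: mean %.2f (sd %.2f)\n",
              mean(co$truth$true_log_k), sd(co$truth$true_log_k)))
}
cat("done\n")
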