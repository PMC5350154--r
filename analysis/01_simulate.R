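#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic cohort.
#
# Builds the 16-pair stimulus set, schedules 7 x 160 balanced trials per
# subject, and simulates choices/RTs for 22 observers whose parameters are
# jittered around the cohort defaults (shrinkage weight ~0.8, small
# response bias toward "f2 > f1"). Writes one trial CSV per subject plus
# the stimulus set. EEG epochs are regenerated on demand by the later
# stages (stage 4) rather than stored.

suppressPackageStartupMessages(library(betachoice))

seed <- 1L
dir.create("results/trials", recursive = TRUE, showWarnings = FALSE)

ss <- build_stimulus_set()
write.csv(ss, "results/stimulus_set.csv", row.names = FALSE)
cat(sprintf("stimulus set: %d pairs, f2 %d-%d Hz, mean f2 %g Hz (f2>f1) / %g Hz (f2<f1)\n",
            nrow(ss), min(ss$f2), max(ss$f2),
            mean(ss$f2[ss$delta > 0]), mean(ss$f2[ss$delta < 0])))

coh <- simulate_cohort(n_subjects = 22, n_blocks = 7, trials_per_block = 160,
                       seed = seed)
for (s in coh) {
  write_trials(s$trials, sprintf("results/trials/subject_%02d.csv", s$id))
}
obs <- data.frame(
  subject = vapply(coh, `[[`, integer(1), "id"),
  sigma_like = vapply(coh, function(s) s$observer$sigma_like, numeric(1)),
  sigma_prior = vapply(coh, function(s) s$observer$sigma_prior, numeric(1)),
  bias = vapply(coh, function(s) s$observer$bias, numeric(1)),
  mapping = vapply(coh, `[[`, character(1), "mapping")
)
write.csv(obs, "results/generating_observers.csv", row.names = FALSE)

acc <- vapply(coh, function(s) mean(s$trials$correct), numeric(1))
cat(sprintf("cohort: %d subjects x %d trials, mean accuracy %.1f%% (range %.1f-%.1f%%)\n",
            length(coh), nrow(coh[[1]]$trials), 100 * mean(acc),
            100 * min(acc), 100 * max(acc)))
cat("wrote results/trials/subject_XX.csv and results/generating_observers.csv\n")
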