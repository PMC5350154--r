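#!/usr/bin/env Rscript
# Stage 2 — behavioural summaries.
#
# Proportions correct per frequency-difference level with the 2x2
# within-subject factorial tests (difficulty x sign, logit scale), median
# RTs per cell with the 2x2x2 factorial (correctness x difficulty x sign),
# and signal-detection criterion shifts, overall and after an RT median
# split. Reads the trial tables written by stage 1.

suppressPackageStartupMessages(library(betachoice))

files <- sort(Sys.glob("results/trials/subject_*.csv"))
stopifnot(length(files) > 0)
trials <- lapply(files, read_trials)
n_subj <- length(trials)

## per-condition proportions correct
pcr <- do.call(rbind, lapply(seq_along(trials), function(i) {
  cbind(subject = i, pcr_table(trials[[i]]))
}))
write.csv(pcr, "results/behavior_pcr.csv", row.names = FALSE)
grand <- aggregate(pcr ~ condition, pcr, mean)
cat("grand-mean PCR (%):\n")
print(transform(grand, pcr = round(100 * pcr, 1)), row.names = FALSE)

## 2x2 factorial on logit-PCR: difficulty x sign
cells22 <- expand.grid(difficulty = c("hard", "easy"),
                       sign = c("negative", "positive"))
pcr_cells <- t(vapply(trials, function(tr) {
  vapply(seq_len(nrow(cells22)), function(j) {
    sel <- (abs(tr$delta) == ifelse(cells22$difficulty[j] == "easy", 4, 2)) &
      (sign(tr$delta) == ifelse(cells22$sign[j] == "positive", 1, -1))
    logit_prop(mean(tr$correct[sel]), sum(sel))
  }, numeric(1))
}, numeric(4)))
aov_pcr <- within_factorial_test(pcr_cells, cells22)
write.csv(aov_pcr, "results/behavior_anova_pcr.csv", row.names = FALSE)
cat("\nlogit-PCR factorial (difficulty x sign):\n")
print(aov_pcr, row.names = FALSE)

## 2x2x2 factorial on median RTs
cells3 <- expand.grid(correctness = c("incorrect", "correct"),
                      difficulty = c("hard", "easy"),
                      sign = c("negative", "positive"))
rt_cells <- t(vapply(trials, function(tr) {
  vapply(seq_len(nrow(cells3)), function(j) {
    sel <- (tr$correct == (cells3$correctness[j] == "correct")) &
      (abs(tr$delta) == ifelse(cells3$difficulty[j] == "easy", 4, 2)) &
      (sign(tr$delta) == ifelse(cells3$sign[j] == "positive", 1, -1))
    median(tr$rt_ms[sel])
  }, numeric(1))
}, numeric(8)))
aov_rt <- within_factorial_test(rt_cells, cells3)
write.csv(aov_rt, "results/behavior_anova_rt.csv", row.names = FALSE)
cat("\nmedian-RT factorial (correctness x difficulty x sign):\n")
print(aov_rt, row.names = FALSE)

## criterion shifts, overall and by RT median split
cs <- do.call(rbind, lapply(seq_along(trials), function(i) {
  rbind(cbind(subject = i, criterion_shift(trials[[i]])),
        cbind(subject = i, criterion_shift(trials[[i]], split = "rt_median")))
}))
write.csv(cs, "results/behavior_criterion.csv", row.names = FALSE)
for (sp in c("all", "fast", "slow")) {
  v <- cs$shift_toward_greater[cs$split == sp]
  tt <- t.test(v)
  cat(sprintf("criterion shift toward 'f2>f1' (%s trials): %.3f (t(%d) = %.2f, p = %.4g)\n",
              sp, mean(v), n_subj - 1, tt$statistic, tt$p.value))
}
fast_slow <- t.test(cs$shift_toward_greater[cs$split == "fast"],
                    cs$shift_toward_greater[cs$split == "slow"], paired = TRUE)
cat(sprintf("fast vs slow shift difference: p = %.3g (paired t-test)\n",
            fast_slow$p.value))
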