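cohort_trials <- function(n_subjects = 8, seed = 1, ...) {
  lapply(simulate_cohort(n_subjects = n_subjects, n_blocks = 2,
                         trials_per_block = 160, seed = seed, ...),
         `[[`, "trials")
}

test_that("PCR tables are exact and ordered by difficulty", {
  tr <- schedule_session(1, 32, seed = 1)
  tr$choice <- ifelse(tr$delta > 0, "f2>f1", "f2<f1")
  tr$correct <- TRUE
  tab <- pcr_table(tr)
  expect_true(all(tab$pcr == 1))

  # contraction-biased observer: easier pairs are judged more accurately
  obs <- observer_params(0.14, 0.28, 0.028)
  big <- simulate_behavior(schedule_session(7, 160, seed = 2), obs, seed = 3)
  tb <- pcr_table(big)
  g <- function(cond) tb$pcr[tb$condition == cond]
  expect_gt(g("delta_+4"), g("delta_+2"))
  expect_gt(g("delta_-4"), g("delta_-2"))
  expect_gt(g("easy"), g("hard"))

  expect_equal(logit_prop(0.5), 0)
  expect_equal(logit_prop(1, n = 10), log((10.5 / 11) / (1 - 10.5 / 11)))
  expect_error(logit_prop(1), "required")
})

test_that("factorial effects equal squared paired t and vanish for equal cells", {
  # 2x2 within design, 10 subjects
  set.seed(4)
  cells <- data.frame(difficulty = rep(c("easy", "hard"), 2),
                      sign = rep(c("pos", "neg"), each = 2))
  vals <- matrix(rnorm(40, mean = 70, sd = 5), nrow = 10)
  vals[, cells$difficulty == "easy"] <- vals[, cells$difficulty == "easy"] + 8
  res <- within_factorial_test(vals, cells)
  expect_setequal(res$effect, c("difficulty", "sign", "difficulty:sign"))

  # independent paired-t oracle for the difficulty main effect
  d_easy <- rowMeans(vals[, cells$difficulty == "easy"])
  d_hard <- rowMeans(vals[, cells$difficulty == "hard"])
  tt <- t.test(d_easy - d_hard)
  row <- res[res$effect == "difficulty", ]
  expect_equal(abs(row$t), abs(unname(tt$statistic)), tolerance = 1e-10)
  expect_equal(row$F, unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(row$p, tt$p.value, tolerance = 1e-10)

  # identical cells: all effects zero with p = 1
  const <- matrix(5, nrow = 6, ncol = 4)
  res0 <- within_factorial_test(const, cells)
  expect_true(all(res0$estimate == 0))
  expect_true(all(res0$p == 1))

  # 2x2x2 design is supported (RT-style analysis)
  cells3 <- expand.grid(correct = c("yes", "no"), difficulty = c("e", "h"),
                        sign = c("p", "n"))
  vals3 <- matrix(rnorm(8 * 8, 600, 30), nrow = 8)
  res3 <- within_factorial_test(vals3, cells3)
  expect_equal(nrow(res3), 7)  # 3 mains + 3 two-way + 1 three-way
  expect_error(within_factorial_test(vals[, 1:3], cells), "every column")
})

test_that("criterion shift follows the SDT convention with correction", {
  # symmetric performance: c = 0
  tr <- schedule_session(1, 32, seed = 5)
  tr$choice <- ifelse(tr$delta > 0, "f2>f1", "f2<f1")
  sym <- criterion_shift(tr)
  expect_equal(sym$criterion_c, 0, tolerance = 1e-12)

  # hit = 0.84, fa = 0.50 -> c close to -0.497
  n <- 50
  tr2 <- data.frame(delta = rep(c(2, -2), each = n),
                    choice = c(rep("f2>f1", 42), rep("f2<f1", 8),
                               rep("f2>f1", 25), rep("f2<f1", 25)))
  cs <- criterion_shift(tr2)
  expect_equal(cs$hit_rate, 0.84)
  expect_equal(cs$fa_rate, 0.50)
  expect_equal(cs$criterion_c, -(qnorm(0.84) + qnorm(0.5)) / 2,
               tolerance = 1e-12)
  expect_equal(cs$criterion_c, -0.497, tolerance = 1e-3)
  expect_equal(cs$shift_toward_greater, -cs$criterion_c)

  # antisymmetry under swapping the stimulus-class labels
  tr_swap <- tr2
  tr_swap$delta <- -tr_swap$delta
  tr_swap$choice <- ifelse(tr_swap$choice == "f2>f1", "f2<f1", "f2>f1")
  expect_equal(criterion_shift(tr_swap)$criterion_c, -cs$criterion_c,
               tolerance = 1e-12)

  # extreme rates get the log-linear correction and stay in (0, 1)
  tr3 <- data.frame(delta = rep(c(2, -2), each = 10),
                    choice = rep("f2>f1", 20))
  cs3 <- criterion_shift(tr3)
  expect_true(cs3$corrected)
  expect_true(cs3$hit_rate < 1 && cs3$fa_rate < 1)
  expect_error(criterion_shift(data.frame(delta = c(2, 2),
                                          choice = c("f2>f1", "f2<f1"))),
               "both stimulus classes")
})

test_that("fast trials carry the response bias under an RT-linked generator", {
  # make the "f2>f1" bias operate mainly on fast responses, as in decisions
  # under time pressure, and recover the fast/slow criterion dissociation
  set.seed(6)
  shifts <- t(vapply(1:12, function(s) {
    tr <- schedule_session(2, 160, seed = s)
    n <- nrow(tr)
    fast <- runif(n) < 0.5
    p_gt <- choice_probability(tr$f1, tr$f2,
                               observer_params(0.14, 0.28, 0))
    p_gt <- ifelse(fast, pnorm(qnorm(p_gt) + 0.45), pnorm(qnorm(p_gt) - 0.15))
    tr$choice <- ifelse(runif(n) < p_gt, "f2>f1", "f2<f1")
    tr$rt_ms <- ifelse(fast, 450, 700) + runif(n, -40, 40)
    cs <- criterion_shift(tr, split = "rt_median")
    c(fast = cs$shift_toward_greater[cs$split == "fast"],
      slow = cs$shift_toward_greater[cs$split == "slow"])
  }, numeric(2)))
  expect_gt(mean(shifts[, "fast"]), mean(shifts[, "slow"]))
  expect_lt(t.test(shifts[, "fast"], shifts[, "slow"],
                   paired = TRUE)$p.value, 0.01)
})

test_that("RT-amplitude correlations behave at the deterministic extremes", {
  tr <- data.frame(rt_ms = c(300, 400, 500, 600, 700),
                   choice = rep("f2>f1", 5))
  res_id <- rt_amplitude_correlation(list(tr, tr), list(tr$rt_ms, tr$rt_ms))
  expect_equal(unname(attr(res_id, "rho")[, "all"]), c(1, 1))
  res_neg <- rt_amplitude_correlation(list(tr, tr), list(-tr$rt_ms, -tr$rt_ms))
  expect_equal(unname(attr(res_neg, "rho")[, "all"]), c(-1, -1))
  expect_error(rt_amplitude_correlation(list(tr[1:2, ]), list(c(1, 2))),
               "fewer than 3")
  expect_error(rt_amplitude_correlation(list(tr), list(1:3)),
               "one amplitude per trial")
})

test_that("per-choice correlation test is calibrated when RT and amplitude
           are conditionally independent given choice", {
  # both variables depend on choice, but are independent within a choice
  frac_sig <- vapply(1:40, function(s) {
    set.seed(1000 + s)
    subj <- lapply(1:10, function(i) {
      n <- 120
      gt <- runif(n) < 0.5
      tr <- data.frame(rt_ms = 500 - 60 * gt + rnorm(n, 0, 50),
                       choice = ifelse(gt, "f2>f1", "f2<f1"))
      amp <- 1 + 0.5 * gt + rnorm(n, 0, 0.3)
      list(tr = tr, amp = amp)
    })
    res <- rt_amplitude_correlation(lapply(subj, `[[`, "tr"),
                                    lapply(subj, `[[`, "amp"),
                                    scope = "per_choice")
    any(res$p < 0.05)
  }, logical(1))
  # two tests at alpha 0.05 under the null: any-significant rate ~ 0.1
  expect_lte(mean(frac_sig), 0.25)
})

test_that("subgroup reruns select the intended subjects", {
  subjects <- simulate_cohort(n_subjects = 8, n_blocks = 1,
                              trials_per_block = 160, seed = 3)
  count_fun <- function(group) length(group)

  all_run <- subgroup_rerun(subjects, count_fun, "all")
  expect_equal(all_run$all$subjects, 1:8)
  expect_equal(all_run$all$result, 8)

  map_run <- subgroup_rerun(subjects, count_fun, "mapping")
  expect_setequal(names(map_run), c("right_means_greater",
                                    "right_means_smaller"))
  expect_equal(sort(unname(unlist(lapply(map_run, `[[`, "subjects")))), 1:8)

  lb <- subgroup_rerun(subjects, count_fun, "low_bias")
  shifts <- vapply(subjects, function(s) {
    criterion_shift(s$trials)$shift_toward_greater
  }, numeric(1))
  expect_equal(lb$low_bias$subjects, which(shifts < 0.1))
})
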