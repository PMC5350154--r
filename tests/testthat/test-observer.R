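test_that("posterior mean shrinks toward the prior and matches quadrature", {
  p <- observer_params(0.1, 0.2, 0)
  w <- shrinkage_weight(p)
  expect_equal(w, 0.04 / 0.05)

  # uninformative prior: no shrinkage
  p_flat <- observer_params(0.1, 1e6, 0)
  expect_equal(posterior_mean_f1(20, p_flat), 20, tolerance = 1e-6)

  # equal precision: log-midpoint of observation and prior mean
  p_eq <- observer_params(0.1, 0.1, 0)
  expect_equal(log(posterior_mean_f1(16, p_eq)),
               (log(16) + p_eq$prior_mean) / 2, tolerance = 1e-10)

  # quadrature oracle over a parameter grid
  for (sl in c(0.05, 0.12, 0.3)) {
    for (sp in c(0.08, 0.2, 0.6)) {
      pp <- observer_params(sl, sp, 0)
      for (f1 in c(16, 20, 24, 28)) {
        expect_equal(posterior_mean_f1(f1, pp),
                     quad_posterior_mean_f1(f1, sl, sp, pp$prior_mean),
                     tolerance = 1e-6)
        # convex combination: strictly between f1 and the prior mean
        lf <- log(posterior_mean_f1(f1, pp))
        rng <- range(log(f1), pp$prior_mean)
        if (abs(log(f1) - pp$prior_mean) > 1e-12) {
          expect_gt(lf, rng[1])
          expect_lt(lf, rng[2])
        }
      }
    }
  }
})

test_that("choice probability is calibrated against the sampling oracle", {
  p <- observer_params(0.12, 0.2, 0.05)
  # symmetric decision point
  p0 <- observer_params(0.12, 0.2, 0)
  f1p <- posterior_mean_f1(20, p0)
  expect_equal(choice_probability(20, f1p, p0), 0.5, tolerance = 1e-12)

  # saturated bias
  p_inf <- observer_params(0.12, 0.2, 1e6)
  expect_gt(choice_probability(20, 18, p_inf), 1 - 1e-12)

  # Monte-Carlo oracle (1e6 draws; MC se < 5e-4, assert within ~4 se)
  ss <- build_stimulus_set()
  for (i in c(1, 4, 7, 12, 16)) {
    mc <- mc_choice_prob(ss$f1[i], ss$f2[i], p, n = 1e6, seed = 100 + i)
    expect_lt(abs(choice_probability(ss$f1[i], ss$f2[i], p) - mc), 2e-3)
  }

  # monotone in f2 and in bias
  f2_grid <- seq(12.5, 32, by = 0.5)
  pr <- choice_probability(20, f2_grid, p)
  expect_true(all(diff(pr) > 0))
  biases <- seq(-1, 1, by = 0.1)
  pr_b <- vapply(biases, function(b) {
    choice_probability(20, 22, observer_params(0.12, 0.2, b))
  }, numeric(1))
  expect_true(all(diff(pr_b) > 0))
})

test_that("negative log-likelihood is additive, clipped, and chance-correct", {
  tr <- simulate_behavior(schedule_session(1, 64, seed = 1),
                          observer_params(0.14, 0.28, 0.028), seed = 2)
  # sigma_d -> inf forces P = 0.5 everywhere: NLL = n log 2
  p_wide <- observer_params(1e6, 0.2, 0)
  expect_equal(negative_log_likelihood(p_wide, tr), nrow(tr) * log(2),
               tolerance = 1e-6)

  # additivity over trials
  p <- observer_params(0.1, 0.25, 0.05)
  per_trial <- vapply(seq_len(nrow(tr)), function(i) {
    negative_log_likelihood(p, tr[i, , drop = FALSE])
  }, numeric(1))
  expect_equal(negative_log_likelihood(p, tr), sum(per_trial),
               tolerance = 1e-8)

  # stays finite under extreme parameters
  p_tight <- observer_params(1e-3, 10, 2)
  expect_true(is.finite(negative_log_likelihood(p_tight, tr)))
  expect_error(negative_log_likelihood(p, tr[0, ]), "empty")
})

test_that("generating parameters beat perturbed ones in likelihood", {
  gen <- observer_params(0.12, 0.24, 0.05)
  pert <- observer_params(0.2, 0.1, -0.2)
  wins <- vapply(1:30, function(s) {
    tr <- simulate_behavior(schedule_session(7, 160, seed = s), gen,
                            seed = 1000 + s)
    negative_log_likelihood(gen, tr) < negative_log_likelihood(pert, tr)
  }, logical(1))
  expect_gt(mean(wins), 0.9)
})

test_that("fitting flags degenerate all-identical choices", {
  tr <- schedule_session(1, 32, seed = 1)
  tr$choice <- "f2>f1"
  fit <- fit_observer(tr, "spfd", n_starts = 4, seed = 1)
  expect_true(fit$boundary)
  expect_equal(fit$params$bias, 2, tolerance = 1e-3)
})

test_that("model comparison penalises complexity and is unit at identity", {
  # identical fits give BF = 1
  tr <- simulate_behavior(schedule_session(2, 160, seed = 5),
                          observer_params(0.14, 0.28, 0.028), seed = 6)
  fit_s <- fit_observer(tr, "spfd", seed = 1)
  fake_null <- fit_s
  fake_null$model <- "null"
  expect_equal(bayes_factor(fit_s, fake_null)$bf, 1)

  # data from the null generator: BF mostly at or below 1
  bf_null <- vapply(1:12, function(s) {
    trn <- schedule_session(2, 160, seed = s)
    set.seed(s + 500)
    pgt <- pnorm((log(trn$f2) - log(trn$f1)) / (sqrt(2) * 0.14))
    trn$choice <- ifelse(runif(nrow(trn)) < pgt, "f2>f1", "f2<f1")
    trn$correct <- (trn$choice == "f2>f1") == (trn$delta > 0)
    bayes_factor(fit_observer(trn, "spfd", n_starts = 5, seed = s),
                 fit_observer(trn, "null", n_starts = 5, seed = s))$bf
  }, numeric(1))
  expect_gt(mean(bf_null <= 1), 0.5)

  fit_n <- fit_observer(tr, "null", seed = 1)
  fit_n$n_trials <- fit_n$n_trials - 1L
  expect_error(bayes_factor(fit_s, fit_n), "different data")
})

test_that("SPFD levels partition the line with the printed edges", {
  # direct boundary checks on the level rule
  p <- observer_params(0.1, 0.2, 0)
  mk <- function(s) {
    # invert spfd to a (f1, f2) pair with the requested SPFD at f1 = 20
    lf1p <- log(posterior_mean_f1(20, p))
    data.frame(f1 = 20, f2 = exp(lf1p + s))
  }
  expect_equal(spfd_levels(mk(-0.20), p)$level, 1L)
  expect_equal(spfd_levels(mk(-0.12), p)$level, 2L)
  expect_equal(spfd_levels(mk(-0.05), p)$level, 3L)
  expect_equal(spfd_levels(mk(0.05), p)$level, 4L)
  expect_equal(spfd_levels(mk(0.12), p)$level, 5L)
  expect_equal(spfd_levels(mk(0.30), p)$level, 6L)

  # every trial of a full session lands in exactly one level
  tr <- simulate_behavior(schedule_session(7, 160, seed = 3),
                          observer_params(0.14, 0.28, 0.028), seed = 4)
  lv <- spfd_levels(tr, observer_params(0.14, 0.28, 0.028))
  expect_true(all(lv$level %in% 1:6))
  expect_equal(length(lv$level), nrow(tr))
  # with the cohort-default observer all six levels are populated
  expect_setequal(unique(lv$level), 1:6)
})
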