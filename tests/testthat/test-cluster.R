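# toy tfr_array: 2 channels x 3 freqs x 4 times x n trials
toy_tfr <- function(values_by_trial) {
  n <- length(values_by_trial)
  x <- array(NA_real_, c(2, 3, 4, n))
  for (k in seq_len(n)) x[, , , k] <- values_by_trial[[k]]
  structure(x, class = "tfr_array", freqs = 24:26,
            times_ms = seq(-600, -450, by = 50), channels = c("FC2", "FC4"))
}

toy_trials <- function(delta, correct) {
  data.frame(delta = delta, correct = correct)
}

test_that("condition means equal naive per-cell averages", {
  set.seed(3)
  vals <- lapply(1:12, function(k) array(rnorm(24), c(2, 3, 4)))
  tfr <- toy_tfr(vals)
  tr <- toy_trials(delta = rep(c(-2, 2), 6),
                   correct = rep(c(TRUE, TRUE, FALSE), 4))
  cm <- condition_means(tfr, tr)
  # naive loop oracle
  cells <- list(lt_correct = tr$delta < 0 & tr$correct,
                gt_correct = tr$delta > 0 & tr$correct,
                lt_incorrect = tr$delta < 0 & !tr$correct,
                gt_incorrect = tr$delta > 0 & !tr$correct)
  for (nm in names(cells)) {
    sel <- which(cells[[nm]])
    naive <- Reduce(`+`, vals[sel]) / length(sel)
    expect_equal(cm$maps[[nm]], naive, tolerance = 1e-12)
    expect_equal(unname(cm$n_trials[nm]), length(sel))
  }

  # all trials identical: every cell mean equals that map
  m0 <- array(2, c(2, 3, 4))
  cm0 <- condition_means(toy_tfr(rep(list(m0), 8)),
                         toy_trials(rep(c(-2, 2), 4),
                                    rep(c(TRUE, FALSE), each = 4)))
  for (nm in names(cm0$maps)) expect_equal(cm0$maps[[nm]], m0)
})

test_that("contrasts follow the printed weights and fail on missing cells", {
  mk_means <- function(a, b, c, d) {
    maps <- list(lt_correct = array(a, c(1, 2, 2)),
                 gt_correct = array(b, c(1, 2, 2)),
                 lt_incorrect = array(c, c(1, 2, 2)),
                 gt_incorrect = array(d, c(1, 2, 2)))
    structure(list(maps = maps,
                   n_trials = c(lt_correct = 5L, gt_correct = 5L,
                                lt_incorrect = 5L, gt_incorrect = 5L),
                   channels = "FC2", freqs = 1:2, times_ms = 1:2,
                   valid = NULL),
              class = "condition_means")
  }
  m <- mk_means(1.5, 2.5, 4, 0.5)
  ci <- apply_contrast(m, contrast_spec("interaction"))
  expect_equal(unique(as.numeric(ci)), -1.5 + 2.5 + 4 - 0.5)
  # difference-of-differences identity (choice contrast within each class)
  dd <- (2.5 - 1.5) + (4 - 0.5)
  expect_equal(unique(as.numeric(ci)), dd)
  # equal means give a zero image
  expect_equal(unique(as.numeric(
    apply_contrast(mk_means(2, 2, 2, 2), contrast_spec("interaction")))), 0)

  # empty incorrect cell: explicit error for the interaction, fine for
  # correct-only
  m$n_trials["gt_incorrect"] <- 0L
  expect_error(apply_contrast(m, contrast_spec("interaction")), "gt_incorrect")
  expect_silent(apply_contrast(m, contrast_spec("correct_only")))
  expect_error(contrast_spec("custom", weights = c(1, 2)), "4 finite")
})

test_that("group t map matches the textbook formula and is antisymmetric", {
  set.seed(5)
  imgs <- lapply(1:8, function(i) array(rnorm(12, mean = 0.4), c(1, 3, 4)))
  tmap <- group_t_map(imgs)
  # direct formula on one bin
  v <- vapply(imgs, function(m) m[1, 2, 3], numeric(1))
  expect_equal(tmap[1, 2, 3], mean(v) / (sd(v) / sqrt(8)), tolerance = 1e-12)
  expect_equal(attr(tmap, "df"), 7L)
  # sign flip of all subjects negates t
  neg <- group_t_map(lapply(imgs, function(m) -m))
  expect_equal(as.numeric(neg), -as.numeric(tmap), tolerance = 1e-12)
  # all-zero images: flagged, not spurious
  zero <- group_t_map(lapply(1:4, function(i) array(0, c(1, 2, 2))))
  expect_true(all(is.na(zero)))
  expect_error(group_t_map(imgs[1]), "2 subjects")
})

test_that("cluster permutation finds injected effects where injected", {
  chans <- c("FC2", "FC4", "C4", "CP4")
  adj <- channel_adjacency()
  dims <- c(4, 10, 12)
  # effect block: channels 1-2, freqs 4-6, times 5-8
  block <- as.matrix(expand.grid(1:2, 4:6, 5:8))
  bl_idx <- block[, 1] + (block[, 2] - 1) * dims[1] +
    (block[, 3] - 1) * dims[1] * dims[2]
  imgs <- make_contrast_images(12, dims, chans, effect = 2.5,
                               effect_bins = bl_idx, seed = 11)
  res <- cluster_permutation(imgs, adj, threshold_p = 0.001, n_perm = 300,
                             seed = 2)
  sig <- Filter(function(cl) cl$significant && cl$sign > 0, res$clusters)
  expect_gte(length(sig), 1)
  big <- sig[[which.max(vapply(sig, `[[`, numeric(1), "mass"))]]
  overlap <- length(intersect(big$ids, bl_idx)) / nrow(block)
  expect_gte(overlap, 0.5)
  # and the cluster stays essentially inside the injected block
  expect_gte(length(intersect(big$ids, bl_idx)) / nrow(big$bins), 0.5)

  # all-zero contrasts: empty result
  zero_imgs <- lapply(1:6, function(i) {
    a <- array(0, dims)
    attr(a, "channels") <- chans
    a
  })
  res0 <- cluster_permutation(zero_imgs, adj, n_perm = 50, seed = 1)
  expect_length(res0$clusters, 0)

  # determinism and argument validation
  res_b <- cluster_permutation(imgs, adj, threshold_p = 0.001, n_perm = 300,
                               seed = 2)
  expect_identical(vapply(res$clusters, `[[`, numeric(1), "p_cluster"),
                   vapply(res_b$clusters, `[[`, numeric(1), "p_cluster"))
  expect_error(cluster_permutation(imgs, adj, n_perm = 0), "n_perm")
  expect_error(cluster_permutation(imgs, adj, threshold_p = 2), "threshold_p")
})

test_that("global sign flip swaps positive and negative cluster families", {
  chans <- c("FC2", "FC4")
  adj <- channel_adjacency()
  dims <- c(2, 8, 8)
  bl <- c(1, 2, 1 + dims[1], 2 + dims[1])
  imgs <- make_contrast_images(10, dims, chans, effect = 3,
                               effect_bins = bl, seed = 21)
  res_pos <- cluster_permutation(imgs, adj, threshold_p = 0.01, n_perm = 200,
                                 seed = 5)
  flipped <- lapply(imgs, function(m) {
    out <- -m
    attr(out, "channels") <- chans
    out
  })
  res_neg <- cluster_permutation(flipped, adj, threshold_p = 0.01,
                                 n_perm = 200, seed = 5)
  expect_equal(as.numeric(res_neg$t_map), -as.numeric(res_pos$t_map),
               tolerance = 1e-12)
  signs_pos <- sort(vapply(res_pos$clusters, `[[`, numeric(1), "sign"))
  signs_neg <- sort(-vapply(res_neg$clusters, `[[`, numeric(1), "sign"))
  expect_equal(signs_pos, signs_neg)
})

test_that("Monte-Carlo p agrees with exhaustive sign-flip enumeration", {
  chans <- c("FC2", "FC4", "C4")
  adj <- channel_adjacency()
  dims <- c(3, 4, 5)
  bl <- c(1, 1 + dims[1])
  # two regimes: a mid-range p and a tail p (10 subjects => 1024 patterns)
  for (case_seed in c(33, 36)) {
    imgs <- make_contrast_images(10, dims, chans, effect = 0.9,
                                 effect_bins = bl, seed = case_seed)
    p_exact <- enumerate_signflip_p(imgs, chans, adj, threshold_p = 0.05)
    res <- cluster_permutation(imgs, adj, threshold_p = 0.05, n_perm = 500,
                               seed = 9)
    masses <- vapply(res$clusters, function(cl) abs(cl$mass), numeric(1))
    p_mc <- res$clusters[[which.max(masses)]]$p_cluster
    se <- sqrt(p_exact * (1 - p_exact) / 500)
    expect_lt(abs(p_mc - p_exact), 4 * se + 2 / 500)
  }
})

test_that("conjunction requires the effect in both trial classes", {
  chans <- c("FC2", "FC4", "C4", "CP4")
  adj <- channel_adjacency()
  dims <- c(4, 8, 10)
  block <- as.matrix(expand.grid(1:2, 3:5, 4:7))
  bl_idx <- block[, 1] + (block[, 2] - 1) * dims[1] +
    (block[, 3] - 1) * dims[1] * dims[2]
  corr <- make_contrast_images(12, dims, chans, effect = 2.5,
                               effect_bins = bl_idx, seed = 41)
  inc_eff <- make_contrast_images(12, dims, chans, effect = 2.5,
                                  effect_bins = bl_idx, seed = 42)
  inc_null <- make_contrast_images(12, dims, chans, effect = 0, seed = 43)

  both <- conjunction(corr, inc_eff, adj, threshold_p = 0.01,
                      channel_restriction = c("FC2", "FC4"),
                      n_perm = 200, seed = 3)
  expect_true(both$overlap)
  # min-t never exceeds either input t map
  expect_true(all(both$min_t <= both$correct$t_map + 1e-12, na.rm = TRUE))
  expect_true(all(both$min_t <= both$incorrect$t_map + 1e-12, na.rm = TRUE))

  onesided <- conjunction(corr, inc_null, adj, threshold_p = 0.01,
                          channel_restriction = c("FC2", "FC4"),
                          n_perm = 200, seed = 3)
  expect_false(onesided$overlap)
  expect_error(conjunction(corr, inc_eff, adj,
                           channel_restriction = character(0)),
               "at least one channel")
})

test_that("between-group t map detects group differences and not their absence", {
  chans <- c("FC2", "FC4")
  dims <- c(2, 6, 6)
  a <- make_contrast_images(8, dims, chans, effect = 1.5,
                            effect_bins = 1:4, seed = 51)
  b_same <- make_contrast_images(8, dims, chans, effect = 1.5,
                                 effect_bins = 1:4, seed = 52)
  b_diff <- make_contrast_images(8, dims, chans, effect = -1.5,
                                 effect_bins = 1:4, seed = 53)
  t_same <- between_group_t_map(a, b_same)
  t_diff <- between_group_t_map(a, b_diff)
  crit <- qt(0.995, df = attr(t_same, "df"))
  expect_lt(mean(abs(as.numeric(t_same)[1:4]) > crit), 0.5)
  expect_true(all(abs(as.numeric(t_diff)[1:4]) > crit))
})
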