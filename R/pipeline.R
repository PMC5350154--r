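#' Subject-level TF contrasts for the choice analysis
#'
#' Runs one subject through the sensor-level pipeline: preprocessing
#' (common-average reference, 0.5-48 Hz zero-phase band-pass), per-trial
#' Morlet amplitude maps, 3 Hz x 300 ms FWHM smoothing, condition means
#' over the stimulus-class x correctness cells, and the three choice
#' contrasts (interaction, correct-only, incorrect-only). Also extracts the
#' single-trial band amplitude used by the RT-correlation control.
#'
#' @param subject A list with `trials` and `epochs` (as produced by
#'   [simulate_cohort()]).
#' @param cfg A [tfr_config()].
#' @param band,amp_window_ms Band (Hz) and window (ms) for the single-trial
#'   amplitude summary.
#' @param amp_channels Channels for the amplitude summary.
#' @param do_preprocess Apply [preprocess()] first (default TRUE).
#' @return A list: `interaction`, `correct_only`, `incorrect_only` (contrast
#'   images), `condition_means`, `trial_amplitude`, `trials`, `tfr`
#'   (per-trial smoothed maps).
#' @export
subject_choice_maps <- function(subject, cfg = tfr_config(),
                                band = c(24, 32),
                                amp_window_ms = c(-750, -450),
                                amp_channels = c("FC2", "FC4"),
                                do_preprocess = TRUE) {
  ep <- if (do_preprocess) preprocess(subject$epochs) else subject$epochs
  tfr <- morlet_tfr(ep, cfg)
  tfr <- smooth_tfr(tfr, cfg$smoothing_fwhm, time_step_ms = cfg$time_step_ms)
  cm <- condition_means(tfr, subject$trials)
  list(
    interaction = apply_contrast(cm, contrast_spec("interaction")),
    correct_only = apply_contrast(cm, contrast_spec("correct_only")),
    incorrect_only = apply_contrast(cm, contrast_spec("incorrect_only")),
    condition_means = cm,
    trial_amplitude = trial_band_amplitude(tfr, band, amp_window_ms,
                                           amp_channels),
    trials = subject$trials,
    tfr = tfr
  )
}

#' Group-level choice analysis: interaction cluster test, conjunction,
#' SPFD time courses
#'
#' The full sensor-level inference chain over a cohort: per-subject choice
#' contrasts, the sign-flip cluster permutation test on the interaction
#' contrast (cluster-defining p < 0.001, FWE-corrected over channels,
#' frequencies and time), a conjunction analysis of the correct-only and
#' incorrect-only contrasts (cluster-defining p = 0.01, corrected only over
#' the channels spanning the interaction clusters), and grand-average
#' band-amplitude time courses split into six SPFD levels for correct
#' trials and the two choice classes for incorrect trials (SPFD levels use
#' each subject's fitted observer model).
#'
#' @param subjects Cohort list (each element with `trials`, `epochs`).
#' @param cfg A [tfr_config()].
#' @param adjacency Channel adjacency (defaults to the template montage).
#' @param n_perm Permutations for both cluster tests.
#' @param threshold_p,conj_threshold_p Cluster-defining thresholds for the
#'   interaction and conjunction stages.
#' @param alpha Cluster-level FWE threshold.
#' @param band Band for time courses and trial amplitudes (Hz).
#' @param amp_window_ms Window for single-trial amplitudes (ms).
#' @param amp_channels Channels for single-trial amplitudes.
#' @param fit_spfd Fit the observer model per subject for the SPFD level
#'   time courses (default TRUE; set FALSE to skip the slowest stage).
#' @param seed Seed for the permutation draws and fits.
#' @return A list of class `choice_analysis`: `subject_maps` (per-subject
#'   contrasts, without the full TFR arrays), `interaction`
#'   (cluster_result), `conjunction` (conjunction_result or NULL if no
#'   significant interaction cluster), `cluster_channels`,
#'   `timecourses` (list `correct_by_level`, `incorrect_by_choice`,
#'   `times_ms`), `trial_amplitudes`, `observer_fits`.
#' @export
run_choice_analysis <- function(subjects, cfg = tfr_config(),
                                adjacency = channel_adjacency(),
                                n_perm = 500, threshold_p = 0.001,
                                conj_threshold_p = 0.01, alpha = 0.05,
                                band = c(24, 32),
                                amp_window_ms = c(-750, -450),
                                amp_channels = c("FC2", "FC4"),
                                fit_spfd = TRUE, seed = 1L) {
  maps <- lapply(subjects, subject_choice_maps, cfg = cfg, band = band,
                 amp_window_ms = amp_window_ms, amp_channels = amp_channels)

  inter_imgs <- lapply(maps, `[[`, "interaction")
  res_inter <- cluster_permutation(inter_imgs, adjacency,
                                   threshold_p = threshold_p,
                                   n_perm = n_perm, alpha = alpha,
                                   seed = seed)
  sig_pos <- Filter(function(cl) cl$significant && cl$sign > 0,
                    res_inter$clusters)
  cluster_channels <- if (length(sig_pos)) {
    sort(unique(res_inter$channels[unlist(lapply(sig_pos, function(cl)
      cl$bins[, "channel"]))]))
  } else character(0)

  res_conj <- NULL
  if (length(cluster_channels)) {
    res_conj <- conjunction(lapply(maps, `[[`, "correct_only"),
                            lapply(maps, `[[`, "incorrect_only"),
                            adjacency, threshold_p = conj_threshold_p,
                            channel_restriction = cluster_channels,
                            n_perm = n_perm, alpha = alpha, seed = seed + 1L)
  }

  # SPFD-level time courses (correct trials) and 2-class (incorrect)
  fits <- NULL
  tc_correct <- NULL
  tc_incorrect <- NULL
  times_ms <- attr(maps[[1]]$tfr, "times_ms")
  tc_channels <- if (length(cluster_channels)) cluster_channels else amp_channels
  if (fit_spfd) {
    fits <- lapply(seq_along(subjects), function(i) {
      fit_observer(subjects[[i]]$trials, "spfd", seed = seed + i)
    })
    level_tc <- function(i) {
      tr <- subjects[[i]]$trials
      lv <- spfd_levels(tr, fits[[i]]$params)
      g_corr <- ifelse(tr$correct, lv$level, NA)
      g_inc <- ifelse(!tr$correct, tr$choice, NA)
      list(
        correct = safe_group_tc(maps[[i]]$tfr, factor(g_corr, levels = 1:6),
                                band, tc_channels),
        incorrect = safe_group_tc(maps[[i]]$tfr,
                                  factor(g_inc, levels = c("f2<f1", "f2>f1")),
                                  band, tc_channels)
      )
    }
    tcs <- lapply(seq_along(subjects), level_tc)
    tc_correct <- grand_mean_tc(lapply(tcs, `[[`, "correct"))
    tc_incorrect <- grand_mean_tc(lapply(tcs, `[[`, "incorrect"))
  }

  structure(list(
    subject_maps = lapply(maps, function(m) m[c("interaction", "correct_only",
                                                "incorrect_only")]),
    interaction = res_inter,
    conjunction = res_conj,
    cluster_channels = cluster_channels,
    timecourses = list(correct_by_level = tc_correct,
                       incorrect_by_choice = tc_incorrect,
                       times_ms = times_ms,
                       channels = tc_channels),
    trial_amplitudes = lapply(maps, `[[`, "trial_amplitude"),
    trials = lapply(subjects, `[[`, "trials"),
    observer_fits = fits
  ), class = "choice_analysis")
}

# per-subject group time course tolerating empty levels (returns NA rows)
safe_group_tc <- function(tfr, groups, band, channels) {
  n_t <- length(attr(tfr, "times_ms"))
  out <- matrix(NA_real_, nlevels(groups), n_t,
                dimnames = list(levels(groups), attr(tfr, "times_ms")))
  present <- levels(groups)[tabulate(groups, nbins = nlevels(groups)) > 0]
  if (length(present)) {
    keep <- !is.na(groups) & groups %in% present
    sub_groups <- factor(groups[keep], levels = present)
    x <- unclass(tfr)[, , , keep, drop = FALSE]
    attrs <- attributes(tfr)
    tfr_sub <- structure(x, class = "tfr_array", freqs = attrs$freqs,
                         times_ms = attrs$times_ms, channels = attrs$channels)
    out[present, ] <- band_timecourse(tfr_sub, sub_groups, band, channels)
  }
  out
}

# average a list of (level x time) matrices over subjects, ignoring missing
grand_mean_tc <- function(tc_list) {
  arr <- simplify2array(tc_list)
  apply(arr, c(1, 2), mean, na.rm = TRUE)
}
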