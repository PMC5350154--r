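#' Configuration for the synthetic EEG generator
#'
#' Describes the three signal components of a simulated response-locked
#' epoch: 1/f background noise in every channel; a steady-state evoked
#' sinusoid at the trial's f2 frequency during the f2 presentation interval
#' (placed at -rt .. -rt + duration relative to saccade onset, so
#' stimulus- and response-locking are both coherent) in contralateral
#' somatosensory channels; and a band-limited 24-32 Hz component in
#' designated right-frontal channels whose envelope inside the effect
#' window is larger by `effect_amp` whenever the trial's choice is
#' "f2 > f1", regardless of correctness.
#'
#' @param channels Channel labels (must exist in the template montage).
#' @param fs Sampling rate in Hz.
#' @param window_ms Epoch bounds relative to saccade onset.
#' @param beta_effect List: `channels`, `band` (Hz, within 4-48),
#'   `window_ms` (within the epoch), `base_amp` (RMS of the band-limited
#'   component for "f2 < f1" choices), `effect_amp` (additional RMS for
#'   "f2 > f1" choices), `ramp_ms` (raised-cosine envelope ramps).
#' @param ssep List: `channels`, `gain` (sinusoid amplitude), `duration_ms`
#'   (f2 presentation length).
#' @param noise List: `level` (background RMS), `exponent` (1/f^exponent
#'   power slope).
#' @param include_heog Add an "HEOG" channel carrying a saccade step at
#'   time 0 (sign follows the saccade direction).
#' @param heog_gain Step amplitude of the hEOG saccade.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(channels = montage_positions()$channel,
                       fs = 512,
                       window_ms = c(-2500, 1000),
                       beta_effect = list(channels = c("FC2", "FC4"),
                                          band = c(24, 32),
                                          window_ms = c(-750, -450),
                                          base_amp = 0.4,
                                          effect_amp = 0.4,
                                          ramp_ms = 100),
                       ssep = list(channels = c("C4", "CP4"),
                                   gain = 0.5,
                                   duration_ms = 250),
                       noise = list(level = 1, exponent = 1),
                       include_heog = FALSE,
                       heog_gain = 50) {
  montage_positions(channels)  # validates labels
  stopifnot(beta_effect$base_amp >= 0, beta_effect$effect_amp >= 0,
            ssep$gain >= 0, noise$level >= 0)
  if (beta_effect$band[1] < 4 || beta_effect$band[2] > 48) {
    stop("beta_effect band must lie within 4-48 Hz")
  }
  if (beta_effect$window_ms[1] < window_ms[1] ||
      beta_effect$window_ms[2] > window_ms[2]) {
    stop("effect window lies outside the epoch")
  }
  bad <- setdiff(c(beta_effect$channels, ssep$channels), channels)
  if (length(bad)) stop("effect channel(s) not in montage subset: ",
                        paste(bad, collapse = ", "))
  structure(list(channels = channels, fs = fs, window_ms = window_ms,
                 beta_effect = beta_effect, ssep = ssep, noise = noise,
                 include_heog = include_heog, heog_gain = heog_gain),
            class = "sim_config")
}

#' Simulate response-locked EEG epochs for completed trials
#'
#' @param trials Completed trial table (from [simulate_behavior()]); `rt_ms`
#'   and `choice` are used to place the SSEP and scale the beta component.
#' @param config A [sim_config()].
#' @param seed Integer seed; regeneration with identical config and seed is
#'   bit-identical.
#' @return An [epoch_array()], trials aligned one-to-one with `trials`.
#' @export
simulate_eeg <- function(trials, config, seed = 1L) {
  if (anyNA(trials$choice) || anyNA(trials$rt_ms)) {
    stop("trials must be completed (choice and rt_ms filled)")
  }
  chans <- config$channels
  if (config$include_heog) chans <- c(chans, "HEOG")
  n_ch <- length(chans)
  fs <- config$fs
  n_samp <- round(diff(config$window_ms) / 1000 * fs)
  n_tr <- nrow(trials)
  t_ms <- config$window_ms[1] + (seq_len(n_samp) - 1) / fs * 1000
  rng <- local_rng(seed)

  # --- 1/f background noise, all channels -------------------------------
  n_noise_ch <- length(config$channels)
  white <- matrix(rng$rnorm(n_samp * n_noise_ch * n_tr), nrow = n_samp)
  freqs <- fs * c(0:(n_samp %/% 2), rev(seq_len(n_samp - n_samp %/% 2 - 1))) / n_samp
  shape <- c(0, freqs[-1]^(-config$noise$exponent / 2))
  shape <- shape / sqrt(mean(shape^2))      # unit output variance
  spec <- stats::mvfft(white) * shape
  x <- Re(stats::mvfft(spec, inverse = TRUE)) / n_samp * config$noise$level
  data <- array(0, dim = c(n_ch, n_samp, n_tr),
                dimnames = list(chans, NULL, NULL))
  data[seq_len(n_noise_ch), , ] <-
    aperm(array(x, dim = c(n_samp, n_noise_ch, n_tr)), c(2, 1, 3))

  # --- SSEP at f2 during the stimulus interval --------------------------
  if (config$ssep$gain > 0 && length(config$ssep$channels)) {
    idx_ssep <- match(config$ssep$channels, chans)
    phases <- rng$runif(n_tr, 0, 2 * pi)
    for (k in seq_len(n_tr)) {
      on_ms <- -trials$rt_ms[k]
      off_ms <- on_ms + config$ssep$duration_ms
      sel <- t_ms >= on_ms & t_ms < off_ms
      if (!any(sel)) next
      wave <- config$ssep$gain *
        sin(2 * pi * trials$f2[k] * (t_ms[sel] - on_ms) / 1000 + phases[k])
      for (ci in idx_ssep) data[ci, sel, k] <- data[ci, sel, k] + wave
    }
  }

  # --- choice-selective band-limited component --------------------------
  be <- config$beta_effect
  if ((be$base_amp > 0 || be$effect_amp > 0) && length(be$channels)) {
    idx_beta <- match(be$channels, chans)
    env <- cosine_window(t_ms, be$window_ms, be$ramp_ms)
    in_win <- t_ms >= be$window_ms[1] & t_ms < be$window_ms[2]
    bf <- signal::butter(4, be$band / (fs / 2), type = "pass")
    amp_tr <- be$base_amp + ifelse(trials$choice == "f2>f1", be$effect_amp, 0)
    for (k in seq_len(n_tr)) {
      for (ci in idx_beta) {
        nb <- signal::filtfilt(bf, rng$rnorm(n_samp))
        rms <- sqrt(mean(nb[in_win]^2))
        if (rms > 0) nb <- nb / rms
        data[ci, , k] <- data[ci, , k] + amp_tr[k] * env * nb
      }
    }
  }

  # --- hEOG saccade step ------------------------------------------------
  if (config$include_heog) {
    hi <- match("HEOG", chans)
    step_sign <- ifelse(trials$saccade_dir == "right", 1, -1)
    for (k in seq_len(n_tr)) {
      data[hi, , k] <- step_sign[k] * config$heog_gain * (t_ms >= 0) +
        0.02 * config$heog_gain * rng$rnorm(n_samp)
    }
  }

  epoch_array(data, chans, fs, config$window_ms)
}

# raised-cosine gate over [window_ms], with ramp_ms on/off ramps
cosine_window <- function(t_ms, window_ms, ramp_ms) {
  env <- numeric(length(t_ms))
  core <- t_ms >= window_ms[1] & t_ms < window_ms[2]
  env[core] <- 1
  if (ramp_ms > 0) {
    up <- t_ms >= window_ms[1] - ramp_ms & t_ms < window_ms[1]
    env[up] <- 0.5 * (1 + cos(pi * (window_ms[1] - t_ms[up]) / ramp_ms))
    dn <- t_ms >= window_ms[2] & t_ms < window_ms[2] + ramp_ms
    env[dn] <- 0.5 * (1 + cos(pi * (t_ms[dn] - window_ms[2]) / ramp_ms))
  }
  env
}

#' Detect saccade onset in a horizontal EOG trace
#'
#' Smooths the trace with a centred moving average, differentiates it, and
#' returns the first sample at which the absolute derivative exceeds a
#' threshold for a sustained run. With the default `threshold = NULL` the
#' criterion is `6 * mad` of the derivative (falling back to `6 * sd` when
#' the mad is zero).
#'
#' @param trace Numeric hEOG trace of one trial.
#' @param fs Sampling rate in Hz.
#' @param threshold Absolute derivative threshold (units/s); NULL for the
#'   robust default.
#' @param sustain_ms Minimum duration the derivative must stay above
#'   threshold.
#' @param smooth_ms Moving-average width.
#' @return Onset sample index (1-based), or `NA_integer_` if no event.
#' @export
detect_saccade_onset <- function(trace, fs, threshold = NULL,
                                 sustain_ms = 6, smooth_ms = 10) {
  w <- max(1L, round(smooth_ms / 1000 * fs))
  if (length(trace) <= w + 1) stop("trace shorter than the smoothing window")
  sm <- stats::filter(trace, rep(1 / w, w), sides = 2)
  sm[is.na(sm)] <- trace[is.na(sm)]
  dv <- abs(diff(as.numeric(sm)) * fs)
  if (is.null(threshold)) {
    threshold <- 6 * stats::mad(dv)
    if (threshold == 0) threshold <- 6 * stats::sd(dv)
  }
  above <- dv > threshold
  need <- max(1L, round(sustain_ms / 1000 * fs))
  r <- rle(above)
  ends <- cumsum(r$lengths)
  ok <- which(r$values & r$lengths >= need)
  if (!length(ok)) return(NA_integer_)
  run <- (ends[ok[1]] - r$lengths[ok[1]] + 1L):ends[ok[1]]
  # peak derivative within the run marks the step centre (+1 aligns the
  # forward difference onto the trace samples)
  as.integer(run[which.max(dv[run])] + 1L)
}

#' Simulate a full synthetic cohort
#'
#' Generates per-subject trial tables (and optionally epoched EEG) under
#' subject-specific observer parameters drawn around the cohort-level
#' generating values. Response mappings alternate across subjects so both
#' saccade-to-choice assignments are represented.
#'
#' @param n_subjects Number of subjects (default 22).
#' @param n_blocks,trials_per_block Session layout per subject.
#' @param observer_base Cohort-level [observer_params()]. The defaults
#'   (sigma_like 0.14, sigma_prior 0.28 giving shrinkage weight w = 0.8,
#'   bias 0.028) produce roughly 74-75% correct overall, about 82% vs 68%
#'   for easy vs hard pairs, about 78% vs 71% for positive vs negative
#'   differences, and a mean criterion shift near 0.12 toward "f2 > f1" -
#'   the behavioural profile characteristic of this task.
#' @param observer_sd List of between-subject jitter scales:
#'   `log_sigma` (lognormal sd on both sigmas) and `bias` (normal sd;
#'   default 0.034 so roughly half the cohort shows little or opposite
#'   bias).
#' @param rt An [rt_model()].
#' @param eeg_config A [sim_config()] to also generate epochs, or NULL for
#'   behaviour only.
#' @param seed Integer seed; subject-level seeds are derived from it.
#' @return A list of subjects, each a list with `id`, `observer`, `trials`
#'   and (if requested) `epochs`.
#' @export
simulate_cohort <- function(n_subjects = 22, n_blocks = 7,
                            trials_per_block = 160,
                            observer_base = observer_params(0.14, 0.28, 0.028),
                            observer_sd = list(log_sigma = 0.15, bias = 0.034),
                            rt = rt_model(),
                            eeg_config = NULL,
                            seed = 1L) {
  rng <- local_rng(seed * 7919L)
  lapply(seq_len(n_subjects), function(i) {
    obs <- observer_params(
      observer_base$sigma_like * exp(rng$rnorm(1, 0, observer_sd$log_sigma)),
      observer_base$sigma_prior * exp(rng$rnorm(1, 0, observer_sd$log_sigma)),
      observer_base$bias + rng$rnorm(1, 0, observer_sd$bias),
      observer_base$prior_mean)
    mapping <- if (i %% 2 == 1) "right_means_greater" else "right_means_smaller"
    s_seed <- seed * 1000L + i
    trials <- schedule_session(n_blocks, trials_per_block, seed = s_seed)
    trials <- simulate_behavior(trials, obs, rt, mapping, seed = s_seed + 1L)
    out <- list(id = i, observer = obs, trials = trials, mapping = mapping)
    if (!is.null(eeg_config)) {
      out$epochs <- simulate_eeg(trials, eeg_config, seed = s_seed + 2L)
    }
    out
  })
}

#' Desk-scale EEG configuration for cohort analyses
#'
#' The default simulation geometry for full-cohort runs: a 16-channel
#' montage subset spanning the right-frontal effect channels (FC2, FC4),
#' the contralateral somatosensory SSEP channels (C4, CP4) and distant
#' left-hemisphere/midline control sites, with response-locked epochs from
#' -1500 to 100 ms. The window keeps the full choice-effect interval
#' (-750 to -450 ms) and the f2 stimulus interval (placed at -rt) with
#' valid wavelet support across the 10-45 Hz analysis range while keeping
#' a 22-subject cohort simulation to desk scale.
#'
#' @param ... Overrides passed to [sim_config()].
#' @return A [sim_config()].
#' @export
cohort_eeg_config <- function(...) {
  args <- list(...)
  defaults <- list(
    channels = c("F3", "Fz", "F4", "FC3", "FCz", "FC2", "FC4", "C3", "Cz",
                 "C4", "CP3", "CPz", "CP4", "P3", "Pz", "P4"),
    window_ms = c(-1500, 100)
  )
  do.call(sim_config, utils::modifyList(defaults, args))
}

#' Analysis frequency grid matched to the desk-scale epochs
#'
#' TFR configuration whose lowest frequency (10 Hz, 700 ms wavelet) still
#' has valid support inside the [cohort_eeg_config()] epoch window.
#'
#' @param ... Overrides passed to [tfr_config()].
#' @return A [tfr_config()].
#' @export
cohort_tfr_config <- function(...) {
  args <- list(...)
  defaults <- list(freqs = 10:45)
  do.call(tfr_config, utils::modifyList(defaults, args))
}
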