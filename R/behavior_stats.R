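#' Proportions correct by condition
#'
#' Proportion of correct responses per physical frequency-difference level
#' (-4, -2, +2, +4 Hz) plus the sign and difficulty margins.
#'
#' @param trials Labelled trial table of one subject (columns `delta`,
#'   `correct`).
#' @return A data.frame with `condition`, `n`, `pcr` (proportion in [0,1]).
#' @export
pcr_table <- function(trials) {
  if (anyNA(trials$correct)) stop("trials must be labelled")
  conds <- list(
    `delta_-4` = trials$delta == -4, `delta_-2` = trials$delta == -2,
    `delta_+2` = trials$delta == 2, `delta_+4` = trials$delta == 4,
    negative = trials$delta < 0, positive = trials$delta > 0,
    easy = abs(trials$delta) == 4, hard = abs(trials$delta) == 2,
    all = rep(TRUE, nrow(trials))
  )
  empty <- names(conds)[!vapply(conds, any, logical(1))]
  if (length(empty)) stop("empty condition(s): ", paste(empty, collapse = ", "))
  data.frame(
    condition = names(conds),
    n = vapply(conds, sum, integer(1)),
    pcr = vapply(conds, function(s) mean(trials$correct[s]), numeric(1)),
    row.names = NULL
  )
}

#' Logit transform with extreme-proportion correction
#'
#' `log(p / (1 - p))`, applying the log-linear (+0.5 / +1) correction
#' `(x + 0.5) / (n + 1)` whenever the raw proportion is 0 or 1 (the same
#' rule used for extreme signal-detection rates).
#'
#' @param p Proportion(s) in [0, 1].
#' @param n Trial count(s) behind each proportion (needed only when a
#'   proportion is extreme).
#' @return Logit value(s).
#' @export
logit_prop <- function(p, n = NULL) {
  extreme <- p <= 0 | p >= 1
  if (any(extreme)) {
    if (is.null(n)) stop("n is required to correct extreme proportions")
    n <- rep_len(n, length(p))
    p[extreme] <- (p[extreme] * n[extreme] + 0.5) / (n[extreme] + 1)
  }
  log(p / (1 - p))
}

#' Within-subject factorial tests via difference-score contrasts
#'
#' Main effects and interactions of fully-crossed 2-level within-subject
#' factors. Each effect is the paired t test of the per-subject difference
#' score built from the +/- 1 product coding of the involved factors, so
#' for 2-level effects F equals the squared paired t. Estimates are on the
#' scale of marginal-mean differences (high minus low level).
#'
#' @param values Matrix or data.frame, subjects x cells.
#' @param cell_factors data.frame with one row per cell (same order as the
#'   columns of `values`) and one 2-level column per factor.
#' @return A data.frame with `effect`, `estimate`, `t`, `df`, `F`, `p`.
#' @export
within_factorial_test <- function(values, cell_factors) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stop("need at least 2 subjects")
  if (anyNA(values)) stop("incomplete cells")
  if (ncol(values) != nrow(cell_factors)) {
    stop("cell_factors must describe every column of values")
  }
  fnames <- names(cell_factors)
  codes <- lapply(cell_factors, function(f) {
    f <- factor(f)
    if (nlevels(f) != 2) stop("all factors must have exactly 2 levels")
    ifelse(f == levels(f)[2], 1, -1)
  })
  n_cells <- nrow(cell_factors)
  effects <- unlist(lapply(seq_along(fnames), function(k) {
    utils::combn(fnames, k, paste, collapse = ":", simplify = FALSE)
  }))
  rows <- lapply(effects, function(eff) {
    members <- strsplit(eff, ":")[[1]]
    w <- Reduce(`*`, codes[members])
    # scale so the score is a difference of marginal means
    w <- w / (n_cells / 2)
    d <- values %*% w
    if (stats::sd(d) < 1e-12) {
      # constant difference scores (e.g. identical cells): no evidence
      # against zero when the constant is zero, certainty otherwise
      tstat <- if (abs(mean(d)) < 1e-12) 0 else sign(mean(d)) * Inf
      pval <- if (tstat == 0) 1 else 0
      data.frame(effect = eff, estimate = mean(d), t = tstat,
                 df = nrow(values) - 1, F = tstat^2, p = pval)
    } else {
      tt <- stats::t.test(d)
      data.frame(effect = eff, estimate = mean(d),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 F = unname(tt$statistic)^2, p = tt$p.value)
    }
  })
  do.call(rbind, rows)
}

#' Signal-detection criterion, optionally split by RT median
#'
#' "f2 > f1" stimuli are treated as signal: the hit rate is
#' P(choose "f2>f1" | f2 > f1) and the false-alarm rate is
#' P(choose "f2>f1" | f2 < f1). The criterion is
#' `c = -(z(hit) + z(fa)) / 2`; a liberal tendency toward "f2 > f1"
#' choices makes c negative, so the reported `shift_toward_greater = -c`
#' is positive for a bias toward "f2 > f1". Extreme rates (0 or 1) are
#' corrected by the log-linear (+0.5 / +1) rule. With
#' `split = "rt_median"` the subject's trials are median-split on RT and a
#' criterion is returned for fast and slow trials separately.
#'
#' @param trials Trial table of one subject (columns `delta`, `choice`,
#'   and `rt_ms` for the split).
#' @param split `"none"` (default) or `"rt_median"`.
#' @return A data.frame of class `sdt_result`: `split`, `hit_rate`,
#'   `fa_rate`, `criterion_c`, `shift_toward_greater`, `corrected`.
#' @export
criterion_shift <- function(trials, split = c("none", "rt_median")) {
  split <- match.arg(split)
  one <- function(tr, label) {
    sig <- tr$delta > 0
    if (!any(sig) || all(sig)) stop("both stimulus classes must be present")
    rate <- function(sel) {
      x <- sum(tr$choice[sel] == "f2>f1")
      n <- sum(sel)
      corrected <- x == 0 || x == n
      p <- if (corrected) (x + 0.5) / (n + 1) else x / n
      list(p = p, corrected = corrected)
    }
    h <- rate(sig)
    f <- rate(!sig)
    cc <- -(stats::qnorm(h$p) + stats::qnorm(f$p)) / 2
    data.frame(split = label, hit_rate = h$p, fa_rate = f$p,
               criterion_c = cc, shift_toward_greater = -cc,
               corrected = h$corrected || f$corrected)
  }
  out <- if (split == "none") {
    one(trials, "all")
  } else {
    med <- stats::median(trials$rt_ms)
    rbind(one(trials[trials$rt_ms <= med, , drop = FALSE], "fast"),
          one(trials[trials$rt_ms > med, , drop = FALSE], "slow"))
  }
  class(out) <- c("sdt_result", class(out))
  out
}

#' Single-trial RT vs band-amplitude correlation, tested across subjects
#'
#' For each subject, the rank (Spearman, default) correlation between
#' single-trial RTs and single-trial band amplitudes; the per-subject
#' coefficients are then tested against zero with a one-sample t test.
#' With `scope = "per_choice"` the correlation is computed within each
#' choice category separately, removing the choice-linked covariation of
#' both variables.
#'
#' @param trial_list List of per-subject trial tables (columns `rt_ms`,
#'   `choice`).
#' @param amplitude_list List of per-subject amplitude vectors aligned with
#'   the trials.
#' @param scope `"all"` or `"per_choice"`.
#' @param method `"spearman"` (default) or `"pearson"`.
#' @return A data.frame with one row per scope: `scope`, `mean_rho`, `t`,
#'   `df`, `p`; attribute `rho` holds the subjects x scopes coefficient
#'   matrix.
#' @export
rt_amplitude_correlation <- function(trial_list, amplitude_list,
                                     scope = c("all", "per_choice"),
                                     method = c("spearman", "pearson")) {
  scope <- match.arg(scope)
  method <- match.arg(method)
  scopes <- if (scope == "all") list(all = function(tr) rep(TRUE, nrow(tr)))
            else list(`f2>f1` = function(tr) tr$choice == "f2>f1",
                      `f2<f1` = function(tr) tr$choice == "f2<f1")
  rho <- vapply(seq_along(trial_list), function(i) {
    tr <- trial_list[[i]]
    amp <- amplitude_list[[i]]
    if (length(amp) != nrow(tr)) stop("one amplitude per trial is required")
    vapply(scopes, function(sel_fun) {
      sel <- sel_fun(tr)
      if (sum(sel) < 3) stop("fewer than 3 trials in scope")
      stats::cor(tr$rt_ms[sel], amp[sel], method = method)
    }, numeric(1))
  }, numeric(length(scopes)))
  rho <- matrix(rho, ncol = length(scopes), byrow = TRUE,
                dimnames = list(NULL, names(scopes)))
  out <- do.call(rbind, lapply(colnames(rho), function(sc) {
    r <- rho[, sc]
    if (length(r) < 2 || stats::sd(r) < 1e-12) {
      tstat <- if (abs(mean(r)) < 1e-12) 0 else sign(mean(r)) * Inf
      data.frame(scope = sc, mean_rho = mean(r), t = tstat,
                 df = length(r) - 1, p = if (tstat == 0) 1 else 0)
    } else {
      tt <- stats::t.test(r)
      data.frame(scope = sc, mean_rho = mean(r),
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value)
    }
  }))
  attr(out, "rho") <- rho
  out
}

#' Mean band amplitude per trial in a TF window
#'
#' Single-trial summary used for RT-amplitude control analyses: the mean TF
#' amplitude over a frequency band, a time window and a channel set.
#'
#' @param tfr A `tfr_array`.
#' @param band `c(low, high)` in Hz.
#' @param window_ms `c(start, end)` in ms relative to saccade onset.
#' @param channels Channel labels.
#' @return Numeric vector, one amplitude per trial.
#' @export
trial_band_amplitude <- function(tfr, band = c(24, 32),
                                 window_ms = c(-750, -450),
                                 channels = attr(tfr, "channels")) {
  ch_idx <- match(channels, attr(tfr, "channels"))
  if (anyNA(ch_idx)) stop("unknown channel label(s)")
  f_idx <- which(attr(tfr, "freqs") >= band[1] & attr(tfr, "freqs") <= band[2])
  t_idx <- which(attr(tfr, "times_ms") >= window_ms[1] &
                 attr(tfr, "times_ms") <= window_ms[2])
  sub <- unclass(tfr)[ch_idx, f_idx, t_idx, , drop = FALSE]
  apply(sub, 4, mean, na.rm = TRUE)
}

#' Re-run an analysis on subject subgroups
#'
#' Repeats an arbitrary cohort-level analysis on subsets of subjects:
#' `"all"` (identity), `"low_bias"` (subjects whose criterion shift toward
#' "f2 > f1" is below `shift_threshold`, i.e. unbiased or oppositely
#' biased), or `"mapping"` (split by the saccade-to-choice response
#' mapping, two groups).
#'
#' @param subjects List of per-subject objects, each with at least
#'   `trials` (and `mapping` for the mapping split).
#' @param analysis_fun Function taking a list of subjects and returning the
#'   analysis result for that group.
#' @param selector `"all"`, `"low_bias"` or `"mapping"`.
#' @param shift_threshold Criterion-shift cut-off for `"low_bias"`
#'   (default 0.1).
#' @return A named list with one element per subgroup: `subjects` (indices)
#'   and `result`.
#' @export
subgroup_rerun <- function(subjects, analysis_fun,
                           selector = c("all", "low_bias", "mapping"),
                           shift_threshold = 0.1) {
  selector <- match.arg(selector)
  groups <- switch(selector,
    all = list(all = seq_along(subjects)),
    low_bias = {
      shifts <- vapply(subjects, function(s) {
        criterion_shift(s$trials)$shift_toward_greater
      }, numeric(1))
      list(low_bias = which(shifts < shift_threshold))
    },
    mapping = {
      maps <- vapply(subjects, `[[`, character(1), "mapping")
      split(seq_along(subjects), maps)
    })
  lapply(groups, function(idx) {
    if (length(idx) < 2) stop("subgroup has fewer than 2 subjects")
    list(subjects = idx, result = analysis_fun(subjects[idx]))
  })
}
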