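#' Time-frequency analysis configuration
#'
#' Morlet transform settings: frequencies of interest (default 4-48 Hz in
#' 1 Hz steps), a fixed number of cycles per wavelet (7, so the analysis
#' segment at frequency f spans `n_cycles / f` seconds: 700 ms at 10 Hz,
#' 350 ms at 20 Hz), a 50 ms time step, the square-root transform from
#' power to spectral amplitude, and the 3 Hz x 300 ms FWHM Gaussian
#' smoothing applied to the amplitude maps.
#'
#' @param freqs Analysis frequencies in Hz.
#' @param n_cycles Cycles per wavelet (>= 1).
#' @param time_step_ms Spacing of TF time bins in ms.
#' @param smoothing_fwhm `c(freq_hz, time_ms)` FWHM of the Gaussian
#'   smoothing kernel.
#' @param band Default band for time-course extraction (upper beta,
#'   24-32 Hz).
#' @return A list of class `tfr_config`.
#' @export
tfr_config <- function(freqs = 4:48, n_cycles = 7, time_step_ms = 50,
                       smoothing_fwhm = c(3, 300), band = c(24, 32)) {
  stopifnot(n_cycles >= 1, time_step_ms > 0, all(freqs > 0))
  if (band[1] < min(freqs) || band[2] > max(freqs)) {
    stop("band must lie within the analysis frequency range")
  }
  structure(list(freqs = freqs, n_cycles = n_cycles,
                 time_step_ms = time_step_ms,
                 smoothing_fwhm = smoothing_fwhm, band = band),
            class = "tfr_config")
}

#' Morlet segment length
#'
#' Length of the analysis segment at frequency `f`: `n_cycles / f` seconds.
#'
#' @param f Frequency in Hz (vectorised).
#' @param n_cycles Cycles per wavelet.
#' @return Segment length in ms.
#' @export
segment_length_ms <- function(f, n_cycles = 7) {
  n_cycles / f * 1000
}

#' Per-trial Morlet time-frequency amplitude maps
#'
#' For every frequency, a complex Morlet wavelet spanning `n_cycles` cycles
#' (Gaussian envelope, unit total energy so amplitudes are comparable
#' across frequencies) is correlated with the epoch at every 50 ms step.
#' Power (squared modulus) is square-root transformed once, yielding
#' spectral amplitude. Time bins whose wavelet support exceeds the epoch
#' are marked invalid (NA) rather than zero-padded.
#'
#' @param epochs An [epoch_array()].
#' @param config A [tfr_config()].
#' @return A `tfr_array`: numeric array channels x frequencies x time bins
#'   x trials with attributes `freqs`, `times_ms` (bin centres relative to
#'   saccade onset), `channels`, and `valid` (frequency x time logical mask
#'   of bins with full wavelet support).
#' @export
morlet_tfr <- function(epochs, config = tfr_config()) {
  fs <- epochs$fs
  d <- dim(epochs$data)
  n_samp <- d[2]
  step <- config$time_step_ms
  t0 <- epochs$window_ms[1]
  centers_ms <- seq(ceiling(epochs$window_ms[1] / step) * step,
                    floor((epochs$window_ms[2] - 1000 / fs) / step) * step,
                    by = step)
  n_t <- length(centers_ms)
  center_idx <- round((centers_ms - t0) / 1000 * fs) + 1L
  longest <- round(config$n_cycles / min(config$freqs) * fs)
  if (longest > n_samp) {
    stop("epoch shorter than the longest wavelet (",
         signif(segment_length_ms(min(config$freqs), config$n_cycles)),
         " ms at ", min(config$freqs), " Hz)")
  }
  n_f <- length(config$freqs)
  xmat <- matrix(aperm(epochs$data, c(2, 1, 3)), nrow = n_samp)
  out <- array(NA_real_, dim = c(d[1], n_f, n_t, d[3]))
  valid <- matrix(FALSE, n_f, n_t)
  for (fi in seq_len(n_f)) {
    f <- config$freqs[fi]
    L <- round(config$n_cycles / f * fs)
    tau <- (seq_len(L) - (L + 1) / 2) / fs
    sigma_t <- config$n_cycles / (2 * pi * f)
    g <- exp(-tau^2 / (2 * sigma_t^2))
    wc <- g * cos(2 * pi * f * tau)
    ws <- g * sin(2 * pi * f * tau)
    nrm <- sqrt(sum(wc^2 + ws^2))
    wc <- wc / nrm
    ws <- ws / nrm
    starts <- center_idx - (L %/% 2)
    ok <- starts >= 1 & starts + L - 1 <= n_samp
    if (!any(ok)) next
    valid[fi, ok] <- TRUE
    Wc <- matrix(0, n_samp, sum(ok))
    Ws <- matrix(0, n_samp, sum(ok))
    for (j in seq_along(which(ok))) {
      s <- starts[which(ok)[j]]
      Wc[s:(s + L - 1), j] <- wc
      Ws[s:(s + L - 1), j] <- ws
    }
    amp <- sqrt(crossprod(xmat, Wc)^2 + crossprod(xmat, Ws)^2)
    # rows of amp run channel-fastest, then trial
    amp <- array(amp, dim = c(d[1], d[3], sum(ok)))
    out[, fi, which(ok), ] <- aperm(amp, c(1, 3, 2))
  }
  structure(out, class = "tfr_array", freqs = config$freqs,
            times_ms = centers_ms, channels = epochs$channel_names,
            valid = valid)
}

#' Smooth TF amplitude maps with a Gaussian kernel
#'
#' Separable Gaussian convolution along the frequency and time axes with
#' the stated full widths at half maximum. Kernels have unit sum; at map
#' boundaries and around invalid bins the convolution is renormalised over
#' the valid support, which avoids amplitude bleed-off at the edges.
#' Invalid bins remain NA.
#'
#' @param tfr A `tfr_array` from [morlet_tfr()] (or any array whose second
#'   and third dimensions are frequency and time, with matching attributes).
#' @param fwhm `c(freq_hz, time_ms)`; both must be positive.
#' @param freq_step_hz,time_step_ms Bin geometry (defaults 1 Hz, 50 ms).
#' @return The smoothed array, attributes preserved.
#' @export
smooth_tfr <- function(tfr, fwhm = c(3, 300), freq_step_hz = 1,
                       time_step_ms = 50) {
  if (any(fwhm <= 0)) stop("FWHM values must be positive")
  d <- dim(tfr)
  att <- attributes(tfr)
  kf <- gauss_kernel(fwhm[1] / freq_step_hz)
  kt <- gauss_kernel(fwhm[2] / time_step_ms)
  x <- unclass(tfr)
  x <- smooth_along(x, 2L, kf)
  x <- smooth_along(x, 3L, kt)
  attributes(x) <- att
  x
}

gauss_kernel <- function(fwhm_bins) {
  sd <- fwhm_bins / (2 * sqrt(2 * log(2)))
  h <- max(1L, ceiling(3 * sd))
  k <- exp(-(-h:h)^2 / (2 * sd^2))
  k / sum(k)
}

# Renormalised (NA-aware, truncated) convolution along one array axis.
smooth_along <- function(x, axis, kernel) {
  d <- dim(x)
  perm <- c(axis, seq_along(d)[-axis])
  xp <- aperm(x, perm)
  m <- matrix(xp, nrow = d[axis])
  v <- !is.na(m)
  m0 <- ifelse(v, m, 0)
  n <- d[axis]
  h <- (length(kernel) - 1L) / 2L
  K <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- max(1L, i - h):min(n, i + h)
    K[i, j] <- kernel[j - i + h + 1L]
  }
  num <- K %*% m0
  den <- K %*% (v * 1)
  res <- num / den
  res[!v] <- NA_real_
  out <- array(res, dim = d[perm])
  aperm(out, order(perm))
}

#' Band-limited amplitude time courses by trial group
#'
#' Averages TF amplitude over a frequency band, a channel set, and the
#' trials of each group (e.g. the six SPFD levels for correct trials, or
#' the two choice classes for incorrect trials), yielding one amplitude
#' time course per group.
#'
#' @param tfr A `tfr_array` (channels x freqs x times x trials).
#' @param groups Factor (or vector coercible to one) of length n_trials;
#'   NA trials are dropped.
#' @param band `c(low, high)` in Hz.
#' @param channels Channel labels to average over.
#' @return A matrix groups x time bins (dimnames: group levels, bin centre
#'   times in ms); NA where the band contains no valid bins.
#' @export
band_timecourse <- function(tfr, groups, band = c(24, 32),
                            channels = attr(tfr, "channels")) {
  if (!is.factor(groups)) groups <- factor(groups)
  ch_idx <- match(channels, attr(tfr, "channels"))
  if (anyNA(ch_idx)) stop("unknown channel label(s)")
  f_idx <- which(attr(tfr, "freqs") >= band[1] & attr(tfr, "freqs") <= band[2])
  if (!length(f_idx)) stop("band contains no analysis frequencies")
  if (any(tabulate(groups, nbins = nlevels(groups)) == 0)) {
    stop("empty trial group")
  }
  sub <- unclass(tfr)[ch_idx, f_idx, , , drop = FALSE]
  out <- t(vapply(levels(groups), function(g) {
    tr <- which(groups == g)
    apply(sub[, , , tr, drop = FALSE], 3, mean)
  }, numeric(dim(sub)[3])))
  dimnames(out) <- list(levels(groups), attr(tfr, "times_ms"))
  out
}
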