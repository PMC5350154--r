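---
title: "Methods: models, statistics and simulation design in betachoice"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, statistics and simulation design in betachoice}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(betachoice)
```

## The scientific problem

In a vibrotactile two-alternative forced-choice task, two flutter
frequencies f1 and f2 (f1 in {16, 20, 24, 28} Hz, f2 = f1 ± 2 or ± 4 Hz)
are presented in sequence and the participant reports whether f2 > f1 or
f2 < f1 with a horizontal saccade. Two phenomena structure the data. First,
behaviour shows a *contraction bias*: the remembered f1 is pulled toward the
centre of the stimulus range, so choices track a subjectively perceived
frequency difference (SPFD) rather than the physical difference. Second,
upper-beta-band (24–32 Hz) EEG amplitude over right-frontal sensors is
modulated by the upcoming *choice* — higher for "f2 > f1" decisions —
several hundred milliseconds before the response, for correct and incorrect
trials alike.

`betachoice` implements the full analysis chain for such experiments —
observer-model fitting, Morlet time–frequency analysis, factorial
contrasts, sign-flip cluster-based permutation testing, conjunction
inference, and the behavioural control statistics — together with a seeded
synthetic-data generator that produces trial tables and epoched EEG
carrying exactly the statistical structure the analysis assumes. Because no
raw data from this paradigm are publicly deposited, the generator is the
test bed: every stage is validated on ground truth it generated.

## The Bayesian observer model

The observer encodes log f1 through a Gaussian sensory channel with sd
$\sigma_\ell$ and combines it with a Gaussian prior over log frequency
(sd $\sigma_p$, mean $\mu$). The posterior mean

$$\log f_1' = w \log f_1 + (1 - w)\,\mu, \qquad
  w = \frac{\sigma_p^2}{\sigma_p^2 + \sigma_\ell^2}$$

is the contracted estimate $f_1'$. The decision variable is the SPFD,
$\log f_2 - \log f_1'$, plus an additive response bias $b$; the choice
"f2 > f1" is made when a noisy comparison of the two representations is
positive:

$$P(\text{``f2 > f1''}) =
  \Phi\!\left(\frac{\log f_2 - \log f_1' + b}{\sqrt{2}\,\sigma_\ell}\right).$$

Design choices worth spelling out:

* **Model scale.** All computation is in log-frequency space; SPFD levels
  are differences of log frequencies. The prior mean defaults to the mean
  log frequency of all stimuli in the 16-pair set (f1 and f2 pooled,
  `prior_mean_log("all")`); centring on the f1 values only is selectable
  (`"f1"`) since either reading of "centred over the presented
  frequencies" is defensible. With the default set the two options differ
  by < 0.01 log units.
* **Comparison noise.** The probit scale is fixed at
  $\sigma_d = \sqrt{2}\sigma_\ell$ — both stimulus representations carry
  the same sensory noise — keeping exactly three free parameters
  ($\sigma_\ell$, $\sigma_p$, $b$). The alternative of propagating the
  shrinkage-attenuated f1 noise ($\sigma_d = \sigma_\ell\sqrt{1 + w^2}$) is
  available via `noise = "shrunk"` but non-default; it re-scales
  $\sigma_\ell$ without changing the fit's likelihood surface shape.
* **Fitting.** Per-subject maximum likelihood with L-BFGS-B from 10 seeded
  random starts; sigmas are optimised on the log scale within
  [1e-3, 10] log units, bias within [−2, 2]; likelihood contributions are
  clipped at 1e-9. Because only 16 distinct pairs exist, the likelihood is
  aggregated per pair, making each evaluation 16 probit calls — a full
  session fit takes well under a second. Degenerate data (all choices
  identical) drive the bias to its bound; the fit is flagged
  (`boundary = TRUE`).
* **Model comparison.** The null model scores choices by the physical
  log difference with bias and noise only (2 parameters). Bayes factors
  use the BIC approximation $\exp((\mathrm{BIC}_0 - \mathrm{BIC}_1)/2)$ —
  an approximation to a complexity-corrected Bayes factor, chosen because
  it is fully determined by the fits. Calibration on synthetic data: a
  strongly contracted observer ($w = 0.5$) at 1120 trials clears BF > 20 in
  ~100% of runs, while null-generated data stay at BF ≤ 1 in the majority,
  so the conventional strong-evidence reading of BF > 20 behaves sensibly
  here.
* **SPFD levels.** Six bins with interior edges −0.18, −0.09, 0, 0.09,
  0.17 (right-closed); edges are configurable.

## Time–frequency analysis

Epochs are response-locked (saccade onset at t = 0), re-referenced to the
common average, and band-passed 0.5–48 Hz with zero-phase Butterworth
filters (order 2 high-pass, order 6 low-pass; the forward–backward pass
doubles the effective order, putting 60 Hz more than 20 dB down while
leaving 10 Hz within 5%). The Morlet transform uses 7-cycle wavelets on a
1 Hz × 50 ms grid: the analysis segment at frequency $f$ spans $7/f$
seconds (700 ms at 10 Hz, 350 ms at 20 Hz). Power is square-root
transformed to amplitude — once, before smoothing — and amplitude maps are
smoothed with a separable 3 Hz × 300 ms FWHM Gaussian kernel.

Two numerical choices the transform leaves open:

* **Wavelet normalisation** is unit total energy, so amplitudes are
  comparable across frequencies and linear in signal amplitude (checked to
  1% in the tests).
* **Edge policy.** Time bins whose wavelet support extends beyond the
  epoch are flagged invalid (NA) and excluded from all statistics rather
  than zero-padded; smoothing renormalises the truncated kernel over valid
  bins, so no amplitude bleeds off at map edges (interior mass is conserved
  to 1e-6).

## Group statistics

For each subject, single-trial maps are averaged in the four cells of the
stimulus-class × correctness design and contrasted with [−1 1 1 −1] (cell
order: f2<f1/correct, f2>f1/correct, f2<f1/incorrect, f2>f1/incorrect).
Because the choice equals the stimulus class on correct trials and its
opposite on incorrect trials, this interaction contrast is exactly the
"chose f2>f1 minus chose f2<f1" amplitude difference — and it cancels, at
equal cell weights, the steady-state-evoked confound that f2 is higher on
average (25 Hz) for f2>f1 than for f2<f1 stimuli (19 Hz).

Inference uses sign-flip cluster-based permutation testing: a one-sample t
per TF bin across subjects, a two-sided cluster-defining threshold of
p < 0.001, clusters of adjacent bins scored by mass (sum of t). Adjacency
is ±1 bin along frequency, ±1 bin along time (no TF diagonals), and
template-montage channel neighbours at the same bin; the 64-channel
template uses synthetic 2-D positions on the 10-20 grid with a distance
threshold chosen to give a median of ~6 neighbours. The null distribution
is the maximum absolute cluster mass over 500 whole-map subject-level sign
flips; using the common two-sided maximum (rather than per-sign nulls each
at α) is what keeps the family-wise error of the two cluster families
together at the nominal 0.05 — measured at 0.05–0.06 over 200 null cohorts
in the calibration test. Permutation p values include the observed
statistic, so p ≥ 1/(1+N). With 10 subjects the Monte-Carlo p agrees with
exhaustive enumeration of all 2^10 sign patterns within binomial error
(the enumeration is an independent oracle in the test suite).

The conjunction analysis repeats the cluster test separately for the
correct-only ([−1 1 0 0]) and incorrect-only ([0 0 1 −1]) contrasts at a
cluster-defining threshold of 0.01, corrected only over the channels
spanning the interaction clusters, and reports the overlap of the
significant clusters plus the element-wise minimum-t map — rejecting the
conjunction null only where both classes show the effect. This is the
control that defeats the SSEP confound, which can mimic the choice effect
only on correct trials.

## The synthetic-data generator

The generator is a first-class module that encodes the study conditions:

* **Task structure:** 16 pairs, near-exact balancing within blocks
  (7 × 160 = 1120 trials per subject, each pair 70 times). The task
  description specifies random f1 draws only; balancing was chosen so the
  25/19 Hz mean-f2 split holds exactly per dataset, not just in
  expectation.
* **Choices** come from the observer model itself. Cohort defaults
  ($\sigma_\ell = 0.14$, $\sigma_p = 0.28$, i.e. $w = 0.8$; $b = 0.028$;
  between-subject lognormal jitter 0.15 on the sigmas and sd 0.034 on the
  bias) were set once to reproduce the behavioural profile characteristic
  of this task: ~74–75% correct overall, ~82% vs ~68% for easy vs hard
  pairs, ~78% vs ~71% for positive vs negative differences, a mean
  criterion shift of ~0.11 toward "f2 > f1" with roughly half the cohort
  below 0.1, and all six SPFD levels populated for every subject.
* **RTs** are shifted lognormal with a −50 ms shift for "f2 > f1" choices —
  the simplest mechanism that yields the observed crossover (faster
  "f2 > f1" choices for correct *and* incorrect trials, hence a
  correctness × sign interaction in the RT factorial). It deliberately
  does not model a correct/incorrect main RT effect or any
  evidence-accumulation process.
* **EEG epochs** are 1/f background noise (exponent 1) in every channel,
  plus an SSEP sinusoid at the trial's f2 during the 250 ms stimulus
  interval placed at −RT relative to the saccade (channels C4/CP4,
  contralateral to left-hand stimulation) — reproducing the confound the
  conjunction must defeat — plus a 24–32 Hz band-limited component in
  FC2/FC4 whose envelope in the −750..−450 ms window has RMS 0.4 for
  "f2 < f1" and 0.8 for "f2 > f1" choices, regardless of correctness.
  Injected effects are recovered by an independent band-pass +
  rectification envelope oracle before any pipeline code touches them.
* **Saccade detection** (for hEOG traces) thresholds a smoothed derivative
  at 6 robust SDs sustained for 6 ms; the task description gives no
  values, so these are configurable defaults.

What the generator does **not** emulate: volume conduction and realistic
scalp topographies (effects are channel-local), eye-blink and muscle
artifacts, non-stationary background spectra, learning or fatigue across
blocks, and any RT–amplitude coupling (so the RT-correlation control is
calibrated under a true null). Passing tests therefore demonstrate that the
pipeline recovers what it assumes — choice-locked band-limited amplitude
differences — not that real EEG satisfies those assumptions.

## Problem sizes

Full-session behaviour (1120 trials/subject, 22 subjects) is used wherever
EEG is not needed. EEG cohorts run at desk scale: 22 subjects × 160
trials, a 16-channel montage subset spanning the effect channels, the SSEP
channels and distant control sites, epochs −1500..100 ms at 512 Hz, and a
10–45 Hz analysis grid (the 10 Hz wavelet still has full support inside
the epoch). These sizes keep a complete cohort simulation-plus-analysis
run in the low minutes while preserving every structural element the
statistics rely on: the effect window, the stimulus interval, the full
upper-beta band and room around it, and both cluster families. The
permutation count (500), cluster thresholds (0.001; conjunction 0.01) and
FWE level (0.05) match the analysis they implement.

## Known limitations

* The BIC Bayes factor is an approximation; only its threshold behaviour
  (BF > 20) is calibrated, not its numeric value.
* Sign-flip permutation assumes symmetric subject-level contrast
  distributions under the null; the generator satisfies this by
  construction.
* The template montage carries synthetic positions: adjacency is
  structurally sensible but not faithful to any digitised cap.
* Band-limited effect injection is stationary within the effect window;
  burst-like beta dynamics are not modelled.
* The observer model is fit per subject; no hierarchical pooling.
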