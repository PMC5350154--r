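#' Observer-model parameters
#'
#' The Bayesian observer perceives the first frequency f1 through a noisy
#' sensory channel (log-normal likelihood, sd `sigma_like` in log-frequency
#' units) and combines it with a Gaussian prior over log frequency (sd
#' `sigma_prior`, centred on `prior_mean`). The subjectively perceived
#' frequency difference (SPFD) on a trial is log f2 minus the posterior mean
#' of log f1; an additive `bias` on this decision variable captures an
#' overall tendency toward "f2 > f1" responses. Three parameters are free;
#' `prior_mean` is fixed by the stimulus set.
#'
#' @param sigma_like Sensory likelihood sd for f1, log-frequency units (> 0).
#' @param sigma_prior Prior sd, log-frequency units (> 0).
#' @param bias Additive response bias on the decision variable (finite);
#'   positive values favour "f2 > f1" choices.
#' @param prior_mean Centre of the prior in log-frequency units; defaults to
#'   the mean log frequency of all stimuli in the 16-pair set (f1 and f2
#'   values pooled, see [prior_mean_log()]).
#' @return An object of class `observer_params`.
#' @export
observer_params <- function(sigma_like, sigma_prior, bias = 0,
                            prior_mean = prior_mean_log()) {
  if (!is.finite(sigma_like) || sigma_like <= 0) stop("sigma_like must be > 0")
  if (!is.finite(sigma_prior) || sigma_prior <= 0) stop("sigma_prior must be > 0")
  if (!is.finite(bias)) stop("bias must be finite")
  structure(list(sigma_like = sigma_like, sigma_prior = sigma_prior,
                 bias = bias, prior_mean = prior_mean),
            class = "observer_params")
}

#' Prior centre implied by the stimulus set
#'
#' Mean of log frequency over the presented stimuli. By default both f1 and
#' f2 values of all 16 pairs are pooled ("centred over all presented
#' frequencies"); `on = "f1"` restricts to the four f1 values.
#'
#' @param on "all" (default) or "f1".
#' @return Scalar, log-frequency units.
#' @export
prior_mean_log <- function(on = c("all", "f1")) {
  on <- match.arg(on)
  pairs <- build_stimulus_set()
  freqs <- switch(on, all = c(pairs$f1, pairs$f2), f1 = unique(pairs$f1))
  mean(log(freqs))
}

#' Posterior-mean estimate of the first frequency
#'
#' Under a Gaussian prior and Gaussian likelihood in log-frequency space the
#' posterior mean of log f1 is the precision-weighted convex combination
#' `w * log(f1_obs) + (1 - w) * prior_mean` with shrinkage weight
#' `w = sigma_prior^2 / (sigma_prior^2 + sigma_like^2)`. The returned value
#' f1' is therefore contracted from the observed f1 toward the centre of the
#' stimulus range (contraction bias).
#'
#' @param f1_obs Observed f1 in Hz (vectorised).
#' @param params An [observer_params()] object.
#' @return f1' in Hz, same length as `f1_obs`.
#' @export
posterior_mean_f1 <- function(f1_obs, params) {
  exp(posterior_mean_logf1(log(f1_obs), params))
}

posterior_mean_logf1 <- function(log_f1, params) {
  w <- shrinkage_weight(params)
  w * log_f1 + (1 - w) * params$prior_mean
}

#' Shrinkage weight of the observer model
#'
#' @param params An [observer_params()] object.
#' @return `sigma_prior^2 / (sigma_prior^2 + sigma_like^2)`, in (0, 1).
#' @export
shrinkage_weight <- function(params) {
  params$sigma_prior^2 / (params$sigma_prior^2 + params$sigma_like^2)
}

#' Subjectively perceived frequency difference (SPFD)
#'
#' `log(f2) - log(f1')` per trial: the decision variable of the observer
#' model before bias and comparison noise.
#'
#' @param f1,f2 Stimulus frequencies in Hz (vectorised).
#' @param params An [observer_params()] object.
#' @return SPFD in log-frequency units.
#' @export
spfd <- function(f1, f2, params) {
  log(f2) - posterior_mean_logf1(log(f1), params)
}

#' Probability of choosing "f2 > f1"
#'
#' Probit link on the biased SPFD: `P = pnorm((spfd + bias) / sigma_d)`.
#' The comparison noise is `sigma_d = sqrt(2) * sigma_like` by default (both
#' stimulus representations carry the same sensory noise), keeping exactly
#' three free parameters. `noise = "shrunk"` instead propagates the
#' shrinkage-attenuated f1 noise, `sigma_d = sigma_like * sqrt(1 + w^2)`.
#'
#' @param f1,f2 Stimulus frequencies in Hz (vectorised).
#' @param params An [observer_params()] object.
#' @param noise Comparison-noise convention, `"equal"` (default) or
#'   `"shrunk"`.
#' @return P("f2 > f1") in (0, 1), strictly increasing in f2 and in bias.
#' @export
choice_probability <- function(f1, f2, params, noise = c("equal", "shrunk")) {
  noise <- match.arg(noise)
  stats::pnorm((spfd(f1, f2, params) + params$bias) / comparison_sd(params, noise))
}

comparison_sd <- function(params, noise = "equal") {
  if (noise == "shrunk") {
    params$sigma_like * sqrt(1 + shrinkage_weight(params)^2)
  } else {
    sqrt(2) * params$sigma_like
  }
}

# Choice probability of the physical-difference null model: probit on
# log f2 - log f1 with bias; sigma_d = sqrt(2) * sigma_like.
null_choice_probability <- function(f1, f2, sigma_like, bias) {
  stats::pnorm((log(f2) - log(f1) + bias) / (sqrt(2) * sigma_like))
}

#' Negative log-likelihood of observed choices
#'
#' Sum over trials of -log P(observed choice) under the observer model (or
#' the physical-difference null model). Probabilities are clipped to
#' `[eps, 1 - eps]` with `eps = 1e-9` so the result stays finite at the
#' parameter bounds. Internally trials are aggregated over the unique
#' stimulus pairs, so each evaluation costs one probit call per pair.
#'
#' @param params An [observer_params()] object, or for `model = "null"` a
#'   list with `sigma_like` and `bias`.
#' @param trials Trial table with columns `f1`, `f2`, `choice`
#'   ("f2>f1"/"f2<f1").
#' @param model `"spfd"` (default) or `"null"`.
#' @param noise Passed to [choice_probability()].
#' @return Scalar NLL.
#' @export
negative_log_likelihood <- function(params, trials, model = c("spfd", "null"),
                                    noise = "equal") {
  model <- match.arg(model)
  if (nrow(trials) == 0) stop("trials is empty")
  if (anyNA(trials$choice)) stop("all trials must have a recorded choice")
  agg <- aggregate_choices(trials)
  p <- if (model == "spfd") {
    choice_probability(agg$f1, agg$f2, params, noise = noise)
  } else {
    null_choice_probability(agg$f1, agg$f2, params$sigma_like, params$bias)
  }
  eps <- 1e-9
  p <- pmin(pmax(p, eps), 1 - eps)
  -sum(agg$n_gt * log(p) + agg$n_lt * log(1 - p))
}

aggregate_choices <- function(trials) {
  key <- paste(trials$f1, trials$f2)
  gt <- trials$choice == "f2>f1"
  n_gt <- tapply(gt, key, sum)
  n_all <- tapply(gt, key, length)
  f <- do.call(rbind, strsplit(names(n_gt), " "))
  data.frame(f1 = as.numeric(f[, 1]), f2 = as.numeric(f[, 2]),
             n_gt = as.vector(n_gt), n_lt = as.vector(n_all - n_gt))
}

#' Fit the observer model (or null model) by maximum likelihood
#'
#' Bounded quasi-Newton (L-BFGS-B) optimisation of the negative
#' log-likelihood from multiple seeded random starts. Sigmas are optimised
#' on the log scale within [1e-3, 10] (log-frequency units); bias within
#' [-2, 2]. Deterministic for a fixed seed.
#'
#' @param trials Trial table of one subject (columns `f1`, `f2`, `choice`).
#' @param model `"spfd"` (three free parameters) or `"null"` (two).
#' @param n_starts Number of random restarts (default 10).
#' @param seed Seed for the restart draws.
#' @param noise Passed to [choice_probability()].
#' @return A list of class `observer_fit`: `params` ([observer_params()] or
#'   null-model list), `nll`, `n_params`, `n_trials`, `bic`, `converged`
#'   (any start converged), `boundary` (TRUE if the best fit sits on a
#'   parameter bound, e.g. for degenerate all-identical choices), `model`,
#'   and the per-start table `starts`.
#' @export
fit_observer <- function(trials, model = c("spfd", "null"), n_starts = 10,
                         seed = 1L, noise = "equal") {
  model <- match.arg(model)
  if (nrow(trials) == 0) stop("trials is empty")
  bounds_sigma <- c(1e-3, 10)
  bounds_bias <- c(-2, 2)
  agg <- aggregate_choices(trials)  # precompute once; closure below reuses it
  nll_fun <- function(theta) {
    p <- if (model == "spfd") {
      pars <- observer_params(exp(theta[1]), exp(theta[2]), theta[3])
      choice_probability(agg$f1, agg$f2, pars, noise = noise)
    } else {
      null_choice_probability(agg$f1, agg$f2, exp(theta[1]), theta[2])
    }
    eps <- 1e-9
    p <- pmin(pmax(p, eps), 1 - eps)
    -sum(agg$n_gt * log(p) + agg$n_lt * log(1 - p))
  }
  n_par <- if (model == "spfd") 3L else 2L
  lower <- c(rep(log(bounds_sigma[1]), n_par - 1L), bounds_bias[1])
  upper <- c(rep(log(bounds_sigma[2]), n_par - 1L), bounds_bias[2])
  rng <- local_rng(seed)
  # starts span plausible sensory noise (sigma in [0.01, 1] log-units) and
  # moderate bias; the bounds above still constrain the optimiser itself
  starts <- cbind(
    matrix(rng$runif(n_starts * (n_par - 1L), log(0.01), log(1)),
           nrow = n_starts),
    rng$runif(n_starts, -0.5, 0.5)
  )
  fits <- lapply(seq_len(n_starts), function(i) {
    res <- tryCatch(
      stats::optim(starts[i, ], nll_fun, method = "L-BFGS-B",
                   lower = lower, upper = upper,
                   control = list(maxit = 500)),
      error = function(e) NULL)
    res
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0) stop("all optimisation starts failed")
  nlls <- vapply(fits, function(f) f$value, numeric(1))
  best <- fits[[which.min(nlls)]]
  theta <- best$par
  tol <- 1e-6
  on_bound <- any(abs(theta - lower) < tol) || any(abs(theta - upper) < tol)
  params <- if (model == "spfd") {
    observer_params(exp(theta[1]), exp(theta[2]), theta[3])
  } else {
    list(sigma_like = exp(theta[1]), bias = theta[2])
  }
  n <- nrow(trials)
  structure(list(
    params = params, nll = best$value, n_params = n_par, n_trials = n,
    bic = 2 * best$value + n_par * log(n),
    converged = any(vapply(fits, function(f) f$convergence == 0, logical(1))),
    boundary = on_bound, model = model,
    starts = data.frame(nll = nlls)
  ), class = "observer_fit")
}

#' Bayes factor for the SPFD model against the physical-difference null
#'
#' BIC approximation: `BF = exp((BIC_null - BIC_spfd) / 2)`, which penalises
#' the SPFD model's extra parameter. Values above 1 favour the SPFD model;
#' the conventional strong-evidence criterion used with this task is
#' BF > 20.
#'
#' @param fit_spfd,fit_null [fit_observer()] results fitted on the same
#'   trials.
#' @return A list of class `model_comparison` with `loglik_spfd`,
#'   `loglik_null`, `n_params` (named vector), `bic_spfd`, `bic_null`, `bf`.
#' @export
bayes_factor <- function(fit_spfd, fit_null) {
  if (fit_spfd$model != "spfd" || fit_null$model != "null") {
    stop("expected one 'spfd' fit and one 'null' fit")
  }
  if (fit_spfd$n_trials != fit_null$n_trials) {
    stop("models were fitted on different data")
  }
  structure(list(
    loglik_spfd = -fit_spfd$nll, loglik_null = -fit_null$nll,
    n_params = c(spfd = fit_spfd$n_params, null = fit_null$n_params),
    bic_spfd = fit_spfd$bic, bic_null = fit_null$bic,
    bf = exp((fit_null$bic - fit_spfd$bic) / 2)
  ), class = "model_comparison")
}

#' Assign trials to SPFD levels
#'
#' Bins the subjectively perceived frequency difference of each trial into
#' six levels: below -0.18; -0.18 to -0.09; -0.09 to 0; 0 to 0.09; 0.09 to
#' 0.17; above 0.17 (log-frequency units, symmetric around the
#' chance-performance point SPFD = 0). Interior edges are
#' right-closed.
#'
#' @param trials Trial table with `f1`, `f2`.
#' @param params Fitted [observer_params()].
#' @param edges Interior bin edges (default `c(-0.18, -0.09, 0, 0.09, 0.17)`).
#' @return A data.frame with `f1_prime` (Hz), `spfd` (log units) and
#'   `level` (integer 1-6) per trial.
#' @export
spfd_levels <- function(trials, params,
                        edges = c(-0.18, -0.09, 0, 0.09, 0.17)) {
  s <- spfd(trials$f1, trials$f2, params)
  lev <- as.integer(cut(s, breaks = c(-Inf, edges, Inf), right = TRUE))
  data.frame(f1_prime = posterior_mean_f1(trials$f1, params),
             spfd = s, level = lev)
}
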