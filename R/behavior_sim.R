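#' Response-time model for simulated choices
#'
#' RTs (from f2 onset) are drawn from a shifted lognormal,
#' `rt = base_ms + shift + rlnorm(meanlog, sigma)`, where `shift` is
#' `choice_shift_ms` for "f2 > f1" choices and 0 otherwise. A negative
#' `choice_shift_ms` makes "f2 > f1" choices systematically faster for both
#' correct and incorrect trials, the crossover pattern this task shows
#' behaviourally. Defaults put median RTs near 550 ms ("f2 > f1") and
#' 600 ms ("f2 < f1").
#'
#' @param base_ms Non-decision base time in ms.
#' @param choice_shift_ms Additive shift for "f2 > f1" choices (ms).
#' @param meanlog,sdlog Lognormal parameters of the stochastic component.
#' @return A list of class `rt_model`.
#' @export
rt_model <- function(base_ms = 250, choice_shift_ms = -50,
                     meanlog = log(350), sdlog = 0.25) {
  if (base_ms + min(choice_shift_ms, 0) <= 0) {
    stop("base_ms + choice_shift_ms must stay positive")
  }
  structure(list(base_ms = base_ms, choice_shift_ms = choice_shift_ms,
                 meanlog = meanlog, sdlog = sdlog), class = "rt_model")
}

#' Simulate choices, correctness, RTs and saccades for scheduled trials
#'
#' Each trial's choice is a Bernoulli draw with P("f2 > f1") from
#' [choice_probability()] under the given observer; correctness follows from
#' the physical delta; the saccade direction follows from the choice under
#' the subject's response mapping; RTs come from the shifted-lognormal
#' [rt_model()] with a choice-dependent shift.
#'
#' @param trials Trial stubs from [schedule_session()].
#' @param observer An [observer_params()] object (generating parameters).
#' @param rt An [rt_model()] object.
#' @param mapping `"right_means_greater"` (right saccade reports
#'   "f2 > f1") or `"right_means_smaller"`; counterbalanced across subjects
#'   in the task design.
#' @param seed Integer seed.
#' @return The trial table with `choice`, `correct`, `rt_ms`, `saccade_dir`
#'   and `mapping` filled in.
#' @export
simulate_behavior <- function(trials, observer, rt = rt_model(),
                              mapping = c("right_means_greater",
                                          "right_means_smaller"),
                              seed = 1L) {
  mapping <- match.arg(mapping)
  n <- nrow(trials)
  p_gt <- choice_probability(trials$f1, trials$f2, observer)
  rng <- local_rng(seed)
  chose_gt <- rng$runif(n) < p_gt
  trials$choice <- ifelse(chose_gt, "f2>f1", "f2<f1")
  trials$correct <- chose_gt == (trials$delta > 0)
  shift <- ifelse(chose_gt, rt$choice_shift_ms, 0)
  trials$rt_ms <- rt$base_ms + shift + rng$rlnorm(n, rt$meanlog, rt$sdlog)
  right_reports_gt <- mapping == "right_means_greater"
  trials$saccade_dir <- ifelse(chose_gt == right_reports_gt, "right", "left")
  trials$mapping <- mapping
  trials
}

#' Write / read a trial table as CSV
#'
#' Plain-text round trip for trial tables: all columns produced by
#' [schedule_session()] and [simulate_behavior()] are preserved with their
#' types.
#'
#' @param trials Trial table.
#' @param path File path.
#' @return `read_trials` returns the trial table; `write_trials` its path,
#'   invisibly.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  if ("correct" %in% names(tr)) tr$correct <- as.logical(tr$correct)
  tr
}
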