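#' Build the 16-pair vibrotactile stimulus set
#'
#' Every combination of a base frequency f1 in {16, 20, 24, 28} Hz with a
#' comparison frequency f2 = f1 +/- 2 or +/- 4 Hz. This is the complete
#' stimulus set of the two-alternative frequency-comparison task: 16 pairs,
#' f2 spanning 12-32 Hz, with mean f2 of 25 Hz among pairs where f2 > f1 and
#' 19 Hz among pairs where f2 < f1.
#'
#' @return A data.frame with one row per pair and columns `f1`, `f2`,
#'   `delta` (f2 - f1), `sign` ("positive"/"negative") and `difficulty`
#'   ("easy" for |delta| = 4, "hard" for |delta| = 2), in a fixed
#'   deterministic order (by f1, then delta).
#' @export
build_stimulus_set <- function() {
  f1 <- c(16, 20, 24, 28)
  deltas <- c(-4, -2, 2, 4)
  grid <- expand.grid(delta = deltas, f1 = f1)[, c("f1", "delta")]
  out <- data.frame(
    f1 = grid$f1,
    f2 = grid$f1 + grid$delta,
    delta = grid$delta,
    sign = ifelse(grid$delta > 0, "positive", "negative"),
    difficulty = ifelse(abs(grid$delta) == 4, "easy", "hard"),
    stringsAsFactors = FALSE
  )
  out$pair_id <- seq_len(nrow(out))
  out
}

#' Schedule a balanced session of comparison trials
#'
#' Assigns stimulus pairs to `n_blocks` x `trials_per_block` trials with
#' near-exact balancing: when the block length is divisible by 16 every pair
#' occurs equally often in every block; otherwise the remainder trials are
#' filled by sampling pairs without replacement, so any two pair counts
#' differ by at most one per block. Trial order within each block is
#' shuffled by the seed.
#'
#' @param n_blocks Number of blocks (default 7).
#' @param trials_per_block Trials per block (default 160).
#' @param seed Integer seed controlling shuffling (and remainder sampling).
#' @return A data.frame of trial stubs: `block`, `trial_index` (1..total),
#'   stimulus columns from [build_stimulus_set()], and empty response
#'   columns (`choice`, `correct`, `rt_ms`, `saccade_dir`) to be filled by
#'   [simulate_behavior()].
#' @export
schedule_session <- function(n_blocks = 7, trials_per_block = 160, seed = 1L) {
  if (n_blocks < 1 || trials_per_block < 1) {
    stop("n_blocks and trials_per_block must be positive")
  }
  pairs <- build_stimulus_set()
  n_pairs <- nrow(pairs)
  rng <- local_rng(seed)
  blocks <- lapply(seq_len(n_blocks), function(b) {
    base <- rep(seq_len(n_pairs), trials_per_block %/% n_pairs)
    rem <- trials_per_block %% n_pairs
    if (rem > 0) base <- c(base, rng$sample(seq_len(n_pairs), rem))
    idx <- base[rng$sample(length(base), length(base))]
    cbind(block = b, pairs[idx, , drop = FALSE])
  })
  out <- do.call(rbind, blocks)
  rownames(out) <- NULL
  out$trial_index <- seq_len(nrow(out))
  out$choice <- NA_character_
  out$correct <- NA
  out$rt_ms <- NA_real_
  out$saccade_dir <- NA_character_
  out
}

# Seed-scoped RNG so package functions never disturb the caller's RNG state.
local_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  with_state <- function(fn) {
    force(fn)
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) {
          if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
        } else {
          assign(".Random.seed", old, envir = globalenv())
        }
      })
      fn(...)
    }
  }
  env$sample <- with_state(function(x, size) sample(x, size))
  env$runif <- with_state(stats::runif)
  env$rnorm <- with_state(stats::rnorm)
  env$rlnorm <- with_state(stats::rlnorm)
  env$rbinom <- with_state(stats::rbinom)
  env
}
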