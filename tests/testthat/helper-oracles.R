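# Independent oracles used across the suite. These deliberately avoid the
# package's own computation paths.

# Posterior mean of f1 by brute-force quadrature of prior x likelihood on a
# fine grid in log-frequency space.
quad_posterior_mean_f1 <- function(f1_obs, sigma_like, sigma_prior, prior_mean,
                                   n_grid = 20001L) {
  grid <- seq(prior_mean - 8 * sigma_prior, prior_mean + 8 * sigma_prior,
              length.out = n_grid)
  post <- dnorm(grid, prior_mean, sigma_prior) *
    dnorm(log(f1_obs), grid, sigma_like)
  exp(sum(grid * post) / sum(post))
}

# Choice probability by Monte-Carlo: equal sensory noise on log f2 and on
# the remembered posterior-mean representation of f1.
mc_choice_prob <- function(f1, f2, params, n = 1e6, seed = 42) {
  set.seed(seed)
  w <- params$sigma_prior^2 / (params$sigma_prior^2 + params$sigma_like^2)
  lf1p <- w * log(f1) + (1 - w) * params$prior_mean
  d <- (log(f2) + rnorm(n, 0, params$sigma_like)) -
    (lf1p + rnorm(n, 0, params$sigma_like)) + params$bias
  mean(d > 0)
}

# Band-limited envelope oracle: band-pass + rectification + smoothing,
# independent of the package's Morlet path.
envelope_oracle <- function(trace, fs, band) {
  bf <- signal::butter(4, band / (fs / 2), type = "pass")
  y <- signal::filtfilt(bf, trace)
  r <- abs(y)
  w <- max(1L, round(0.05 * fs))
  as.numeric(stats::filter(r, rep(1 / w, w), sides = 2))
}

# Naive flood-fill clustering over suprathreshold bins of a (ch, f, t) t
# map; channel adjacency given as neighbour label lists. Returns the
# maximum cluster mass for each sign, c(pos, neg), with neg as magnitude.
naive_max_cluster_mass <- function(tmap, t_crit, chans, adjacency) {
  dims <- dim(tmap)
  coord <- function(id) {
    id0 <- id - 1
    c(id0 %% dims[1] + 1, (id0 %/% dims[1]) %% dims[2] + 1,
      id0 %/% (dims[1] * dims[2]) + 1)
  }
  max_mass <- c(pos = 0, neg = 0)
  for (sgn in c(1, -1)) {
    sel <- if (sgn > 0) which(tmap > t_crit) else which(tmap < -t_crit)
    visited <- rep(FALSE, length(sel))
    for (s in seq_along(sel)) {
      if (visited[s]) next
      queue <- s
      visited[s] <- TRUE
      members <- integer(0)
      while (length(queue)) {
        cur <- queue[1]
        queue <- queue[-1]
        members <- c(members, cur)
        cc <- coord(sel[cur])
        for (t in seq_along(sel)) {
          if (visited[t]) next
          ct <- coord(sel[t])
          same_ch <- cc[1] == ct[1]
          tf_adj <- (same_ch && cc[2] == ct[2] && abs(cc[3] - ct[3]) == 1) ||
                    (same_ch && cc[3] == ct[3] && abs(cc[2] - ct[2]) == 1)
          ch_adj <- cc[2] == ct[2] && cc[3] == ct[3] &&
            chans[ct[1]] %in% adjacency[[chans[cc[1]]]]
          if (tf_adj || ch_adj) {
            visited[t] <- TRUE
            queue <- c(queue, t)
          }
        }
      }
      mass <- abs(sum(tmap[sel[members]]))
      key <- if (sgn > 0) "pos" else "neg"
      max_mass[key] <- max(max_mass[key], mass)
    }
  }
  max_mass
}

# Exact sign-flip p-value for the largest observed cluster: enumerates all
# 2^n sign patterns, computing each permutation t map and its max absolute
# cluster mass with the naive clustering above.
enumerate_signflip_p <- function(images, chans, adjacency, threshold_p) {
  n <- length(images)
  X <- t(vapply(images, as.numeric, numeric(length(images[[1]]))))
  dims <- dim(images[[1]])
  t_crit <- qt(1 - threshold_p / 2, df = n - 1)
  tmap_of <- function(signs) {
    Xs <- X * signs
    m <- colMeans(Xs)
    s <- apply(Xs, 2, sd)
    tv <- m / (s / sqrt(n))
    array(tv, dim = dims)
  }
  obs_mass <- max(naive_max_cluster_mass(tmap_of(rep(1, n)), t_crit,
                                         chans, adjacency))
  count <- 0L
  total <- 2^n
  for (k in 0:(total - 1)) {
    signs <- ifelse(bitwAnd(k, 2^(0:(n - 1))) > 0, -1, 1)
    mm <- max(naive_max_cluster_mass(tmap_of(signs), t_crit, chans, adjacency))
    if (mm >= obs_mass) count <- count + 1L
  }
  count / total
}

# Small labelled TFR stack for cluster-module unit tests: per-subject
# per-trial maps with optional effect injected into a bin block.
make_contrast_images <- function(n_subj, dims, chans, effect = 0,
                                 effect_bins = NULL, seed = 1) {
  set.seed(seed)
  lapply(seq_len(n_subj), function(i) {
    img <- array(rnorm(prod(dims)), dim = dims)
    if (!is.null(effect_bins) && effect != 0) {
      img[effect_bins] <- img[effect_bins] + effect
    }
    attr(img, "channels") <- chans
    img
  })
}
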