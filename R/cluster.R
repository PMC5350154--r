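#' Factorial contrast specification over the 2x2 design
#'
#' Weights over the four cells of the stimulus-class x correctness design,
#' in the fixed cell order (f2<f1, correct), (f2>f1, correct),
#' (f2<f1, incorrect), (f2>f1, incorrect). The interaction preset
#' `[-1 1 1 -1]` contrasts the participant's actual choices ("f2 > f1"
#' minus "f2 < f1") pooling correct and incorrect trials, because on
#' incorrect trials the choice is opposite to the stimulus class. The
#' single-class presets `[-1 1 0 0]` and `[0 0 1 -1]` isolate the choice
#' contrast within correct and incorrect trials and together form the
#' conjunction.
#'
#' @param preset "interaction", "correct_only", "incorrect_only", or
#'   "custom" with explicit `weights`.
#' @param weights Length-4 numeric weights for `preset = "custom"`.
#' @return A list of class `contrast_spec` with `weights` (named) and
#'   `name`.
#' @export
contrast_spec <- function(preset = c("interaction", "correct_only",
                                     "incorrect_only", "custom"),
                          weights = NULL) {
  preset <- match.arg(preset)
  w <- switch(preset,
              interaction = c(-1, 1, 1, -1),
              correct_only = c(-1, 1, 0, 0),
              incorrect_only = c(0, 0, 1, -1),
              custom = weights)
  if (length(w) != 4 || !all(is.finite(w))) {
    stop("weights must be 4 finite numbers")
  }
  names(w) <- c("lt_correct", "gt_correct", "lt_incorrect", "gt_incorrect")
  structure(list(weights = w, name = preset), class = "contrast_spec")
}

#' Per-subject condition-mean TF maps
#'
#' Averages single-trial TF maps within each cell of the 2x2 design
#' (stimulus class f2<f1 / f2>f1 crossed with correctness). Cells with no
#' trials are flagged missing (all-NA map) rather than silently zeroed;
#' [apply_contrast()] errors if a needed cell is missing.
#'
#' @param tfr A `tfr_array` (channels x freqs x times x trials).
#' @param trials Trial table aligned with the trial axis (uses `delta`,
#'   `correct`).
#' @return A list of class `condition_means`: `maps` (list of four 3-D
#'   arrays in contrast cell order), `n_trials` (named counts), and the TF
#'   geometry attributes of the input.
#' @export
condition_means <- function(tfr, trials) {
  if (nrow(trials) != dim(tfr)[4]) {
    stop("trial table does not align with the trial axis")
  }
  if (anyNA(trials$correct)) stop("all trials must be labelled")
  cells <- list(
    lt_correct = trials$delta < 0 & trials$correct,
    gt_correct = trials$delta > 0 & trials$correct,
    lt_incorrect = trials$delta < 0 & !trials$correct,
    gt_incorrect = trials$delta > 0 & !trials$correct
  )
  x <- unclass(tfr)
  maps <- lapply(cells, function(sel) {
    if (!any(sel)) {
      array(NA_real_, dim = dim(x)[1:3])
    } else {
      rowMeans(x[, , , sel, drop = FALSE], dims = 3)
    }
  })
  structure(list(maps = maps, n_trials = vapply(cells, sum, integer(1)),
                 channels = attr(tfr, "channels"),
                 freqs = attr(tfr, "freqs"),
                 times_ms = attr(tfr, "times_ms"),
                 valid = attr(tfr, "valid")),
            class = "condition_means")
}

#' Apply a factorial contrast to condition means
#'
#' Weighted sum of the four cell-mean maps; with the interaction preset the
#' result equals the difference of choice differences,
#' (gt_correct - lt_correct) + (lt_incorrect - gt_incorrect), i.e. the
#' "f2 > f1"-choice minus "f2 < f1"-choice amplitude difference per TF bin.
#'
#' @param means A [condition_means()] result.
#' @param spec A [contrast_spec()].
#' @return A 3-D contrast image (channels x freqs x times) with TF geometry
#'   attributes.
#' @export
apply_contrast <- function(means, spec) {
  needed <- names(spec$weights)[spec$weights != 0]
  empty <- needed[means$n_trials[needed] == 0]
  if (length(empty)) {
    stop("contrast '", spec$name, "' needs trials in cell(s): ",
         paste(empty, collapse = ", "))
  }
  img <- Reduce(`+`, Map(function(w, m) if (w == 0) 0 else w * m,
                         spec$weights, means$maps))
  structure(img, channels = means$channels, freqs = means$freqs,
            times_ms = means$times_ms, valid = means$valid)
}

#' Group-level one-sample t map
#'
#' Per-bin one-sample t statistic of the subject contrast images against
#' zero (df = n - 1). Bins invalid for any subject are excluded listwise;
#' zero-variance bins are flagged NA.
#'
#' @param images List of per-subject contrast images (equal dimensions).
#' @return A t-statistic array of the common dimensions, attributes
#'   preserved from the first image, with attribute `df`.
#' @export
group_t_map <- function(images) {
  n <- length(images)
  if (n < 2) stop("need at least 2 subjects")
  X <- t(vapply(images, as.numeric, numeric(length(images[[1]]))))
  m <- colMeans(X)
  s <- sqrt((colSums(X^2) - n * m^2) / (n - 1))
  t <- m / (s / sqrt(n))
  t[!is.finite(t)] <- NA_real_
  out <- array(t, dim = dim(images[[1]]))
  out <- copy_tf_attrs(out, images[[1]])
  attr(out, "df") <- n - 1L
  out
}

copy_tf_attrs <- function(out, src) {
  for (a in c("channels", "freqs", "times_ms", "valid")) {
    v <- attr(src, a)
    if (!is.null(v)) attr(out, a) <- v
  }
  out
}

#' Sign-flip cluster-based permutation test
#'
#' Group inference over channel x frequency x time contrast images with
#' family-wise error control. Observed bins exceeding the two-sided
#' cluster-defining threshold (|t| above the `threshold_p` quantile,
#' df = n-1) are grouped into clusters of adjacent bins — adjacency is
#' +/- 1 bin along frequency, +/- 1 bin along time, and the channel
#' neighbour lists at the same TF bin — and each cluster is scored by its
#' mass (sum of member t values). The null distribution is the maximum
#' absolute cluster mass, over clusters of either sign, in each of
#' `n_perm` whole-map subject-level sign flips, so the two-sided
#' family-wise error across the positive and negative cluster families
#' together is controlled at `alpha`. Positive and negative clusters are
#' formed and reported separately. Permutation p values include the
#' observed statistic: p = (1 + #{null >= |mass|}) / (1 + n_perm).
#'
#' @param images List of per-subject contrast images (channels x freqs x
#'   times, with `channels` attribute).
#' @param adjacency Channel adjacency from [channel_adjacency()].
#' @param threshold_p Cluster-defining two-sided p threshold (default
#'   0.001).
#' @param n_perm Number of sign-flip permutations (default 500).
#' @param alpha Cluster-level FWE threshold (default 0.05).
#' @param seed Seed for the sign flips.
#' @return A list of class `cluster_result`: `clusters` (each with `bins`
#'   matrix of (channel, freq, time) indices, `mass`, `sign`, `p_cluster`,
#'   `significant`), `t_map`, `t_crit`, `null_max` (per-permutation maximum
#'   absolute cluster mass), `null_max_pos`, `null_max_neg`, `threshold_p`,
#'   `alpha`, `n_perm`.
#' @export
cluster_permutation <- function(images, adjacency, threshold_p = 0.001,
                                n_perm = 500, alpha = 0.05, seed = 1L) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (threshold_p <= 0 || threshold_p >= 1) stop("threshold_p must be in (0,1)")
  n <- length(images)
  if (n < 2) stop("need at least 2 subjects")
  chans <- attr(images[[1]], "channels")
  if (!all(chans %in% names(adjacency))) {
    stop("adjacency does not cover all channels")
  }
  dims <- dim(images[[1]])
  nb_idx <- lapply(chans, function(ch) match(intersect(adjacency[[ch]], chans), chans))
  t_obs_map <- group_t_map(images)
  t_crit <- stats::qt(1 - threshold_p / 2, df = n - 1)

  X <- t(vapply(images, as.numeric, numeric(prod(dims))))
  valid <- colSums(is.na(X)) == 0
  sdev <- rep(FALSE, ncol(X))
  sdev[valid] <- apply(X[, valid, drop = FALSE], 2, stats::sd) > 0
  valid <- valid & sdev
  Xv <- X[, valid, drop = FALSE]
  ids_valid <- which(valid)
  t_obs <- as.numeric(t_obs_map)[valid]

  obs <- cluster_components(ids_valid, t_obs, t_crit, dims, nb_idx)

  rng <- local_rng(seed)
  signs <- matrix(sign(rng$runif(n_perm * n) - 0.5), nrow = n_perm)
  signs[signs == 0] <- 1
  colSS <- colSums(Xv^2)
  M <- signs %*% Xv / n
  Tm <- M / sqrt(sweep(-n * M^2, 2, colSS, `+`) / ((n - 1) * n))
  null_max_pos <- numeric(n_perm)
  null_max_neg <- numeric(n_perm)
  supra_any <- abs(Tm) > t_crit
  hit_rows <- which(rowSums(supra_any) > 0)
  for (r in hit_rows) {
    sel <- supra_any[r, ]
    mm <- max_cluster_mass(ids_valid[sel], Tm[r, sel], t_crit, dims, nb_idx)
    null_max_pos[r] <- mm[1]
    null_max_neg[r] <- mm[2]
  }
  null_max <- pmax(null_max_pos, null_max_neg)
  clusters <- lapply(obs, function(cl) {
    p <- (1 + sum(null_max >= abs(cl$mass))) / (1 + n_perm)
    cl$p_cluster <- p
    cl$significant <- p < alpha
    cl$bins <- cbind(channel = (cl$ids - 1) %% dims[1] + 1,
                     freq = ((cl$ids - 1) %/% dims[1]) %% dims[2] + 1,
                     time = (cl$ids - 1) %/% (dims[1] * dims[2]) + 1)
    cl
  })
  structure(list(clusters = clusters, t_map = t_obs_map, t_crit = t_crit,
                 null_max = null_max,
                 null_max_pos = null_max_pos, null_max_neg = null_max_neg,
                 threshold_p = threshold_p, alpha = alpha, n_perm = n_perm,
                 channels = chans),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat(sprintf("cluster_result: %d cluster(s), threshold_p = %g, %d permutations\n",
              length(x$clusters), x$threshold_p, x$n_perm))
  for (cl in x$clusters) {
    cat(sprintf("  %s cluster: %d bins, mass %.2f, p = %.4f%s\n",
                if (cl$sign > 0) "positive" else "negative",
                nrow(cl$bins), cl$mass, cl$p_cluster,
                if (cl$significant) " *" else ""))
  }
  invisible(x)
}

# Connected components of suprathreshold bins; returns per-cluster list
# with linear ids, mass and sign. Positive and negative families are
# clustered separately.
cluster_components <- function(ids, tvals, t_crit, dims, nb_idx) {
  out <- list()
  for (sgn in c(1, -1)) {
    sel <- if (sgn > 0) tvals > t_crit else tvals < -t_crit
    if (!any(sel)) next
    comp <- connected_sets(ids[sel], dims, nb_idx)
    tv <- tvals[sel]
    for (members in comp) {
      out[[length(out) + 1L]] <- list(
        ids = ids[sel][members],
        mass = sum(tv[members]),
        sign = sgn)
    }
  }
  out
}

max_cluster_mass <- function(ids, tvals, t_crit, dims, nb_idx) {
  mp <- 0
  mn <- 0
  pos <- tvals > t_crit
  if (any(pos)) {
    comp <- connected_sets(ids[pos], dims, nb_idx)
    mp <- max(vapply(comp, function(m) sum(tvals[pos][m]), numeric(1)))
  }
  neg <- tvals < -t_crit
  if (any(neg)) {
    comp <- connected_sets(ids[neg], dims, nb_idx)
    mn <- max(vapply(comp, function(m) -sum(tvals[neg][m]), numeric(1)))
  }
  c(mp, mn)
}

# Union-find over a set of linear (channel, freq, time) grid indices.
# Neighbours: same channel +/-1 freq, same channel +/-1 time, channel
# neighbours at identical freq and time. Returns a list of index vectors
# into `ids`.
connected_sets <- function(ids, dims, nb_idx) {
  k <- length(ids)
  if (k == 1) return(list(1L))
  pos <- integer(prod(dims))
  pos[ids] <- seq_len(k)
  parent <- seq_len(k)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  unite <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[rj] <<- ri
  }
  id0 <- ids - 1L
  ch <- id0 %% dims[1] + 1L
  fr <- (id0 %/% dims[1]) %% dims[2] + 1L
  ti <- id0 %/% (dims[1] * dims[2]) + 1L
  step_f <- dims[1]
  step_t <- dims[1] * dims[2]
  for (i in seq_len(k)) {
    if (fr[i] < dims[2]) {
      j <- pos[ids[i] + step_f]
      if (j > 0) unite(i, j)
    }
    if (ti[i] < dims[3]) {
      j <- pos[ids[i] + step_t]
      if (j > 0) unite(i, j)
    }
    for (nb in nb_idx[[ch[i]]]) {
      if (nb > ch[i]) {
        j <- pos[ids[i] + (nb - ch[i])]
        if (j > 0) unite(i, j)
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  unname(split(seq_len(k), roots))
}

#' Conjunction analysis between correct and incorrect trials
#'
#' Runs the cluster permutation test separately for the correct-trial and
#' incorrect-trial choice contrasts, restricted to a listed channel set
#' (typically the channels spanning the interaction cluster), and reports
#' the per-class clusters, the bins shared by significant clusters of both
#' classes, and the element-wise minimum of the two group t maps — the test
#' statistic of the conjunction null, which is rejected only where both
#' classes show the effect.
#'
#' @param correct_images,incorrect_images Per-subject contrast image lists
#'   from the same subjects in the same order.
#' @param adjacency Channel adjacency.
#' @param threshold_p Cluster-defining threshold (default 0.01).
#' @param channel_restriction Channels over which to correct; must be
#'   non-empty.
#' @param n_perm,alpha,seed As in [cluster_permutation()].
#' @return A list of class `conjunction_result`: `correct`, `incorrect`
#'   (cluster_result objects), `min_t` (element-wise minimum t map over the
#'   restricted channels), `overlap_bins` (matrix of bins common to
#'   significant positive clusters of both classes), `overlap` (TRUE if any
#'   such bin exists).
#' @export
conjunction <- function(correct_images, incorrect_images, adjacency,
                        threshold_p = 0.01, channel_restriction,
                        n_perm = 500, alpha = 0.05, seed = 1L) {
  if (missing(channel_restriction) || length(channel_restriction) == 0) {
    stop("channel_restriction must name at least one channel")
  }
  if (length(correct_images) != length(incorrect_images)) {
    stop("image sets must come from the same subjects")
  }
  sub_c <- lapply(correct_images, restrict_channels, channel_restriction)
  sub_i <- lapply(incorrect_images, restrict_channels, channel_restriction)
  res_c <- cluster_permutation(sub_c, adjacency, threshold_p, n_perm, alpha,
                               seed = seed)
  res_i <- cluster_permutation(sub_i, adjacency, threshold_p, n_perm, alpha,
                               seed = seed + 1L)
  min_t <- pmin(res_c$t_map, res_i$t_map)
  attributes(min_t) <- attributes(res_c$t_map)
  sig_ids <- function(res) {
    ids <- lapply(Filter(function(cl) cl$significant && cl$sign > 0,
                         res$clusters), `[[`, "ids")
    if (length(ids)) unlist(ids) else integer(0)
  }
  common <- intersect(sig_ids(res_c), sig_ids(res_i))
  dims <- dim(res_c$t_map)
  overlap_bins <- cbind(channel = (common - 1) %% dims[1] + 1,
                        freq = ((common - 1) %/% dims[1]) %% dims[2] + 1,
                        time = (common - 1) %/% (dims[1] * dims[2]) + 1)
  structure(list(correct = res_c, incorrect = res_i, min_t = min_t,
                 overlap_bins = overlap_bins,
                 overlap = nrow(overlap_bins) > 0,
                 channels = channel_restriction),
            class = "conjunction_result")
}

restrict_channels <- function(img, channels) {
  chans <- attr(img, "channels")
  idx <- match(channels, chans)
  if (anyNA(idx)) stop("unknown channel in restriction")
  out <- img[idx, , , drop = FALSE]
  attr(out, "channels") <- channels
  attr(out, "freqs") <- attr(img, "freqs")
  attr(out, "times_ms") <- attr(img, "times_ms")
  out
}

#' Between-group two-sample t map
#'
#' Independent two-sample t statistic per TF bin between two groups of
#' subject contrast images (pooled variance), e.g. the two response-mapping
#' subgroups.
#'
#' @param images_a,images_b Lists of contrast images.
#' @return A t map with attribute `df`.
#' @export
between_group_t_map <- function(images_a, images_b) {
  na <- length(images_a)
  nb <- length(images_b)
  if (na < 2 || nb < 2) stop("need at least 2 subjects per group")
  A <- t(vapply(images_a, as.numeric, numeric(length(images_a[[1]]))))
  B <- t(vapply(images_b, as.numeric, numeric(length(images_b[[1]]))))
  ma <- colMeans(A); mb <- colMeans(B)
  va <- apply(A, 2, stats::var); vb <- apply(B, 2, stats::var)
  sp <- sqrt(((na - 1) * va + (nb - 1) * vb) / (na + nb - 2))
  t <- (ma - mb) / (sp * sqrt(1 / na + 1 / nb))
  t[!is.finite(t)] <- NA_real_
  out <- array(t, dim = dim(images_a[[1]]))
  out <- copy_tf_attrs(out, images_a[[1]])
  attr(out, "df") <- na + nb - 2L
  out
}
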