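#' Template 64-channel montage
#'
#' A 64-channel label set from the extended 10-20 system with synthetic 2-D
#' template positions derived from the row/column structure of the labelling
#' scheme (anterior-posterior rows Fp, AF, F, FC, C, CP, P, PO, O, I at
#' fixed y steps; left/right columns from the electrode number at fixed x
#' steps). The positions are a regular template for neighbourhood
#' construction, not digitised electrode coordinates.
#'
#' @param channels Optional subset of labels to keep (order preserved).
#' @return A data.frame with `channel`, `x`, `y`.
#' @export
montage_positions <- function(channels = NULL) {
  labels <- c(
    "Fp1", "AF7", "AF3", "F1", "F3", "F5", "F7", "FT7", "FC5", "FC3", "FC1",
    "C1", "C3", "C5", "T7", "TP7", "CP5", "CP3", "CP1", "P1", "P3", "P5",
    "P7", "P9", "PO7", "PO3", "O1", "Iz", "Oz", "POz", "Pz", "CPz",
    "Fpz", "Fp2", "AF8", "AF4", "AFz", "Fz", "F2", "F4", "F6", "F8", "FT8",
    "FC6", "FC4", "FC2", "FCz", "Cz", "C2", "C4", "C6", "T8", "TP8", "CP6",
    "CP4", "CP2", "P2", "P4", "P6", "P8", "P10", "PO8", "PO4", "O2"
  )
  row_y <- c(Fp = 3.2, AF = 2.4, F = 1.6, FC = 0.8, C = 0, CP = -0.8,
             P = -1.6, PO = -2.4, O = -3.2, I = -3.8)
  parse_one <- function(lab) {
    m <- regmatches(lab, regexec("^([A-Za-z]+?)(z|[0-9]+)$", lab))[[1]]
    row <- m[2]
    col <- m[3]
    # lateral temporal labels belong to the neighbouring rows
    row <- switch(row, T = "C", FT = "FC", TP = "CP", row)
    y <- row_y[[row]]
    if (col == "z") {
      x <- 0
    } else {
      num <- as.numeric(col)
      mag <- 0.8 * ceiling(num / 2)
      x <- if (num %% 2 == 1) -mag else mag
    }
    c(x = x, y = y)
  }
  xy <- t(vapply(labels, parse_one, numeric(2)))
  out <- data.frame(channel = labels, x = xy[, 1], y = xy[, 2],
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(channels)) {
    missing <- setdiff(channels, out$channel)
    if (length(missing)) stop("unknown channel label(s): ",
                              paste(missing, collapse = ", "))
    out <- out[match(channels, out$channel), , drop = FALSE]
    rownames(out) <- NULL
  }
  out
}

#' Channel adjacency from template positions
#'
#' Neighbours are channel pairs within `dist_threshold` of each other in the
#' 2-D template layout. The default threshold (1.2 template units, i.e.
#' 1.5 x the grid step) links each interior channel to its lateral and
#' diagonal neighbours, giving a median of about 6 neighbours over the full
#' 64-channel montage. The result is symmetric and irreflexive.
#'
#' @param positions A data.frame from [montage_positions()].
#' @param dist_threshold Maximum neighbour distance in template units.
#' @return A named list: for each channel, the character vector of its
#'   neighbours.
#' @export
channel_adjacency <- function(positions = montage_positions(),
                              dist_threshold = 1.2) {
  d <- as.matrix(stats::dist(positions[, c("x", "y")]))
  nb <- lapply(seq_len(nrow(d)), function(i) {
    positions$channel[d[i, ] <= dist_threshold & seq_len(ncol(d)) != i]
  })
  names(nb) <- positions$channel
  nb
}
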