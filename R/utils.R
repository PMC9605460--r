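# Internal helpers shared across modules.

#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
NULL

# Euclidean length of each step along an ordered polyline given as a
# two-column matrix; returns numeric of length nrow(xy) - 1.
step_lengths <- function(xy) {
  d <- diff(xy)
  sqrt(rowSums(d^2))
}

# Cumulative arc-length positions (starting at 0) along a polyline.
arc_positions <- function(xy) {
  c(0, cumsum(step_lengths(xy)))
}

# Coerce segment points (tibble with x/y or row/col, matrix, or data.frame)
# to an n x 2 numeric matrix with columns x, y.  Raster (row, col) input is
# mapped to x = col, y = row; all metrics are invariant to this reflection.
as_xy <- function(points) {
  if (is.matrix(points)) {
    stopifnot(ncol(points) == 2)
    xy <- points
  } else if (is.data.frame(points)) {
    nms <- names(points)
    if (all(c("x", "y") %in% nms)) {
      xy <- cbind(points$x, points$y)
    } else if (all(c("row", "col") %in% nms)) {
      xy <- cbind(points$col, points$row)
    } else {
      abort("points must have columns x/y or row/col")
    }
  } else {
    abort("points must be a matrix or data frame")
  }
  storage.mode(xy) <- "double"
  colnames(xy) <- c("x", "y")
  xy
}

# Gaussian smoothing of polyline coordinates with reflection padding.
# `sigma` is expressed in the same length unit as the coordinates; it is
# converted to a kernel width in samples using the mean point spacing.
smooth_polyline <- function(xy, sigma) {
  if (sigma <= 0 || nrow(xy) < 3) return(xy)
  spacing <- mean(step_lengths(xy))
  if (!is.finite(spacing) || spacing <= 0) return(xy)
  s <- sigma / spacing                      # kernel sd in samples
  r <- max(1L, ceiling(3 * s))
  k <- stats::dnorm(seq(-r, r), sd = s)
  k <- k / sum(k)
  n <- nrow(xy)
  pad <- function(v) {
    # reflect about the end samples so endpoints stay anchored
    head_pad <- 2 * v[1] - v[seq(min(r, n - 1) + 1, 2)]
    tail_pad <- 2 * v[n] - v[seq(n - 1, max(n - r, 1))]
    if (r > n - 1) { # short polylines: repeat edge values
      head_pad <- c(rep(head_pad[1], r - length(head_pad)), head_pad)
      tail_pad <- c(tail_pad, rep(tail_pad[length(tail_pad)], r - length(tail_pad)))
    }
    c(head_pad, v, tail_pad)
  }
  sm <- function(v) stats::filter(pad(v), k, sides = 2)[(r + 1):(r + n)]
  cbind(x = sm(xy[, 1]), y = sm(xy[, 2]))
}

# Deterministic representative of a pixel cluster: centroid snapped to the
# nearest member pixel (ties broken by row, then col order).
cluster_representative <- function(px) {
  ctr <- colMeans(px)
  d <- (px[, 1] - ctr[1])^2 + (px[, 2] - ctr[2])^2
  ord <- order(d, px[, 1], px[, 2])
  px[ord[1], , drop = TRUE]
}
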