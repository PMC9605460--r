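# Fixture builders shared across tests: all constructed in code, seeded.

# Ordered 1-px raster line between two (row, col) pixels (Bresenham-like via
# dense sampling); returns an n x 2 integer matrix of unique pixels.
raster_line <- function(from, to) {
  n <- max(abs(to - from)) * 3 + 2
  r <- round(seq(from[1], to[1], length.out = n))
  c <- round(seq(from[2], to[2], length.out = n))
  unique(cbind(r, c))
}

# Paint a list of pixel matrices onto a logical canvas.
paint <- function(shape, ...) {
  m <- matrix(FALSE, shape[1], shape[2])
  for (px in list(...)) m[px] <- TRUE
  m
}

# Y-shaped 1-px skeleton: two long arms and one short arm meeting at a
# center pixel.
y_skeleton <- function(long = 30, short = 3) {
  ctr <- c(40, 40)
  arm1 <- raster_line(ctr, ctr + c(-long, 0))
  arm2 <- raster_line(ctr, ctr + c(long, -long))   # diagonal
  arm3 <- raster_line(ctr, ctr + c(0, short))
  paint(c(80, 80), arm1, arm2, arm3)
}

# Random vessel-tree mask: a wiggly trunk with 2-4 side branches, stroked at
# thickness 3. Deterministic per seed.
random_tree_mask <- function(seed) {
  set.seed(seed)
  n <- 81
  x <- seq(10, 90, length.out = n)
  y <- 50 + cumsum(stats::rnorm(n, 0, 0.6))
  trunk <- cbind(x = x, y = y)
  shape <- c(120, 120)
  mask <- rasterize_curve(trunk, shape = shape, thickness = 3)
  n_branch <- sample(2:4, 1)
  for (b in seq_len(n_branch)) {
    at <- sample(seq(15, n - 15), 1)
    ang <- stats::runif(1, pi / 5, pi / 2.2) * sample(c(-1, 1), 1)
    len <- stats::runif(1, 15, 30)
    t <- seq(0, len, by = 0.5)
    br <- cbind(x = trunk[at, 1] + t * cos(ang),
                y = trunk[at, 2] + t * sin(ang))
    br <- br[br[, 1] > 2 & br[, 1] < 117 & br[, 2] > 2 & br[, 2] < 117, ,
             drop = FALSE]
    if (nrow(br) > 4) {
      mask <- mask | rasterize_curve(br, shape = shape, thickness = 3)
    }
  }
  mask
}

# Well-separated 4-class Gaussian feature set for classifier tests.
gaussian_blob_features <- function(n_per_class = 100, seed = 1,
                                   separation = 6) {
  set.seed(seed)
  rows <- lapply(1:4, function(g) {
    tibble::tibble(
      f1 = stats::rnorm(n_per_class, g * separation),
      f2 = stats::rnorm(n_per_class, -g * separation),
      f3 = stats::rnorm(n_per_class, (g %% 2) * separation),
      grade = g
    )
  })
  out <- dplyr::bind_rows(rows)
  out$grade <- factor(out$grade, levels = 1:4, ordered = TRUE)
  out
}

# Fixture curves (smooth point lists) reused by identity/invariance tests.
fixture_curves <- function() {
  list(
    s_curve = sample_curve(curve_spec("composite_S", radii = c(1, 1),
                                      step = 0.01))$points,
    arc = sample_curve(curve_spec("circular_arc", radius = 5, angle = pi,
                                  step = 0.05))$points,
    sine = sample_curve(curve_spec("sine", amplitude = 2, frequency = 1,
                                   span = 4 * pi, step = 0.02))$points,
    spiral = sample_curve(curve_spec("spiral", a = 2, b = 0.6, turns = 1.5,
                                     step = 0.05))$points
  )
}

# Point-list metric profile: no coordinate smoothing, fine resampling.
record_smooth <- function(points, step = 0.05, ...) {
  compute_record(points, step = step, smooth_sigma = 0, eps_kappa = 1e-3, ...)
}

# Scale-aware closeness: absolute for near-zero values, relative otherwise.
expect_close <- function(a, b, tol = 1e-9, label = NULL) {
  testthat::expect_lt(abs(a - b), tol * max(1, abs(b)),
                      label = label %||% "difference")
}
`%||%` <- function(x, y) if (is.null(x)) y else x
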