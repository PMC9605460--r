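#' Describe an analytic test curve
#'
#' Builds a specification for a parametric plane curve with known (closed-form
#' or quadrature-grade) arc length, chord, curvature and inflection count.
#' These curves are the ground-truth substrate for validating the tortuosity
#' metrics: a straight line, a circular arc, a sinusoid, an Archimedean
#' spiral, and an "S" composed of two mirrored semicircles.
#'
#' @param family One of `"line"`, `"circular_arc"`, `"sine"`, `"spiral"`,
#'   `"composite_S"`.
#' @param length Line length (family `"line"`).
#' @param radius Arc radius (family `"circular_arc"`).
#' @param angle Subtended angle in radians (family `"circular_arc"`).
#' @param amplitude,frequency,span Sinusoid `y = amplitude * sin(frequency * x)`
#'   over `x` in `[0, span]`.
#' @param a,b Archimedean spiral `r = a + b * phi` parameters.
#' @param turns Number of spiral turns.
#' @param radii Length-2 numeric: the two semicircle radii of the composite S.
#' @param step Arc-length sampling step for [sample_curve()].
#' @return An object of class `curve_spec`.
#' @seealso [sample_curve()]
#' @export
curve_spec <- function(family = c("line", "circular_arc", "sine", "spiral",
                                  "composite_S"),
                       length = 10, radius = 5, angle = pi,
                       amplitude = 2, frequency = 1, span = 2 * pi,
                       a = 1, b = 0.5, turns = 2,
                       radii = c(1, 1), step = 0.1) {
  family <- match.arg(family)
  bad <- function(msg) abort(paste0("invalid curve_spec: ", msg))
  if (step <= 0) bad("step must be positive")
  switch(family,
    line = if (length <= 0) bad("length must be positive"),
    circular_arc = {
      if (radius <= 0) bad("radius must be positive")
      if (angle <= 0 || angle > 2 * pi) bad("angle must be in (0, 2*pi]")
    },
    sine = {
      if (amplitude < 0) bad("amplitude must be non-negative")
      if (frequency <= 0 || span <= 0) bad("frequency and span must be positive")
    },
    spiral = if (a < 0 || b <= 0 || turns <= 0) bad("spiral needs a >= 0, b > 0, turns > 0"),
    composite_S = if (any(radii <= 0) || length(radii) != 2) bad("radii must be 2 positive values")
  )
  structure(
    list(family = family, length = length, radius = radius, angle = angle,
         amplitude = amplitude, frequency = frequency, span = span,
         a = a, b = b, turns = turns, radii = radii, step = step),
    class = "curve_spec"
  )
}

#' Sample an analytic curve and its ground-truth tortuosity values
#'
#' Evaluates the curve of a [curve_spec()] at (approximately) uniform
#' arc-length spacing and returns the ordered points together with an oracle
#' record of analytic quantities, computed independently of the metric
#' estimators: arc length (closed form, or adaptive quadrature for the
#' sinusoid and spiral), chord, arc/chord ratio, total curvature
#' \eqn{\int |C| ds} is not reported — the signed total \eqn{\int C\,ds} is —
#' and the exact count of curvature sign changes.
#'
#' @param spec A [curve_spec()].
#' @return A list with `points` (tibble of `x`, `y`) and `oracle` (one-row
#'   tibble: `arc`, `chord`, `dm`, `total_curvature`, `max_abs_curvature`,
#'   `inflections`).
#' @examples
#' sc <- sample_curve(curve_spec("circular_arc", radius = 5, angle = pi))
#' sc$oracle
#' @export
sample_curve <- function(spec) {
  stopifnot(inherits(spec, "curve_spec"))
  st <- spec$step
  out <- switch(spec$family,
    line = {
      x <- seq(0, spec$length, by = st)
      if (x[length(x)] < spec$length) x <- c(x, spec$length)
      list(points = tibble(x = x, y = 0),
           arc = spec$length, chord = spec$length,
           total_curvature = 0, max_abs_curvature = 0, inflections = 0L)
    },
    circular_arc = {
      r <- spec$radius; th <- spec$angle
      t <- seq(0, th, by = st / r)
      if (t[length(t)] < th) t <- c(t, th)
      list(points = tibble(x = r * sin(t), y = r * (1 - cos(t))),
           arc = r * th, chord = 2 * r * sin(th / 2),
           total_curvature = th, max_abs_curvature = 1 / r,
           inflections = 0L)
    },
    sine = {
      A <- spec$amplitude; w <- spec$frequency; L <- spec$span
      dlen <- function(x) sqrt(1 + (A * w * cos(w * x))^2)
      arc <- stats::integrate(dlen, 0, L, subdivisions = 2000L,
                              rel.tol = 1e-10)$value
      # uniform arc-length parameterization via dense inversion
      xs <- seq(0, L, length.out = max(2000L, ceiling(20 * L / st)))
      cs <- c(0, cumsum((dlen(xs[-1]) + dlen(xs[-length(xs)])) / 2 * diff(xs)))
      s_targets <- unique(c(seq(0, cs[length(cs)], by = st), cs[length(cs)]))
      x <- stats::approx(cs, xs, xout = s_targets)$y
      # inflections: interior zeros of y'' = -A w^2 sin(w x), i.e. x = k*pi/w
      k_max <- floor(L * w / pi - 1e-9)
      infl <- if (A == 0) 0L else max(0L, k_max)
      list(points = tibble(x = x, y = A * sin(w * x)),
           arc = arc, chord = sqrt(L^2 + (A * sin(w * L))^2),
           total_curvature = NA_real_,
           max_abs_curvature = A * w^2, inflections = as.integer(infl))
    },
    spiral = {
      a <- spec$a; b <- spec$b
      phi_max <- 2 * pi * spec$turns
      dlen <- function(p) sqrt((a + b * p)^2 + b^2)
      arc <- stats::integrate(dlen, 0, phi_max, subdivisions = 2000L,
                              rel.tol = 1e-10)$value
      ps <- seq(0, phi_max, length.out = max(2000L, ceiling(20 * arc / st)))
      cs <- c(0, cumsum((dlen(ps[-1]) + dlen(ps[-length(ps)])) / 2 * diff(ps)))
      s_targets <- unique(c(seq(0, cs[length(cs)], by = st), cs[length(cs)]))
      phi <- stats::approx(cs, ps, xout = s_targets)$y
      r <- a + b * phi
      x1 <- r[1] * cos(0); y1 <- r[1] * sin(0)
      xn <- r[length(r)] * cos(phi_max); yn <- r[length(r)] * sin(phi_max)
      list(points = tibble(x = r * cos(phi), y = r * sin(phi)),
           arc = arc, chord = sqrt((xn - x1)^2 + (yn - y1)^2),
           total_curvature = NA_real_,
           max_abs_curvature = if (a > 0) NA_real_ else NA_real_,
           inflections = 0L)
    },
    composite_S = {
      r1 <- spec$radii[1]; r2 <- spec$radii[2]
      # first semicircle bends left, second bends right; both traversed upward
      t1 <- seq(0, pi, by = st / r1)
      if (t1[length(t1)] < pi) t1 <- c(t1, pi)
      p1 <- cbind(x = r1 * sin(t1), y = r1 * (1 - cos(t1)))
      t2 <- seq(0, pi, by = st / r2)
      if (t2[length(t2)] < pi) t2 <- c(t2, pi)
      p2 <- cbind(x = -r2 * sin(t2), y = 2 * r1 + r2 * (1 - cos(t2)))
      pts <- rbind(p1, p2[-1, , drop = FALSE])
      list(points = tibble(x = pts[, 1], y = pts[, 2]),
           arc = pi * (r1 + r2), chord = 2 * (r1 + r2),
           total_curvature = pi / r1 * 0, # signed halves cancel only if r1 == r2
           max_abs_curvature = 1 / min(r1, r2), inflections = 1L)
    }
  )
  oracle <- tibble(
    family = spec$family,
    arc = out$arc, chord = out$chord, dm = out$arc / out$chord,
    total_curvature = out$total_curvature,
    max_abs_curvature = out$max_abs_curvature,
    inflections = out$inflections
  )
  list(points = out$points, oracle = oracle)
}
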