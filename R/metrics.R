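# Fourteen segment-level tortuosity metrics plus signed-curvature summaries.
#
# All metrics operate on an ordered centerline point list. Distances (arc,
# chord) are measured on the raw points; curvature-based quantities are
# measured on a uniform arc-length resampling of the (optionally
# Gaussian-smoothed) polyline, with signed curvature from central finite
# differences.

#' Resample a polyline at uniform arc-length spacing
#'
#' Points are placed on the piecewise-linear interpolant of the input at
#' exactly uniform arc-length spacing `h = total / (n - 1) <= step` (the
#' smallest point count whose spacing does not exceed `step`), with both
#' endpoints preserved. Exact uniformity — rather than multiples of `step`
#' with a short final interval — is required by the finite-difference
#' curvature stencils and by the sum-of-angles metric.
#'
#' @param points Ordered points: matrix or data frame with `x`,`y` (or raster
#'   `row`,`col`) columns.
#' @param step Target spacing in the units of `points`.
#' @return List: `xy` (n x 2 matrix), `s` (arc positions), `step`.
#' @export
resample_uniform <- function(points, step = 1) {
  xy <- as_xy(points)
  if (nrow(xy) < 2) abort("resampling needs at least 2 points")
  s <- arc_positions(xy)
  total <- s[length(s)]
  if (total <= 0) abort("degenerate segment: all points coincide")
  # drop zero-length steps so approx() sees strictly increasing abscissae
  keep <- c(TRUE, diff(s) > 0)
  s_in <- s[keep]; xy <- xy[keep, , drop = FALSE]
  n_out <- max(2L, ceiling(total / step) + 1L)
  targets <- seq(0, total, length.out = n_out)
  out <- cbind(
    x = stats::approx(s_in, xy[, 1], xout = targets)$y,
    y = stats::approx(s_in, xy[, 2], xout = targets)$y
  )
  list(xy = out, s = targets, step = total / (n_out - 1))
}

#' Chord length of a segment
#'
#' Euclidean distance between the first and last centerline points.
#'
#' @param points Ordered points (see [resample_uniform()]).
#' @param pixel_spacing Physical length per pixel.
#' @return Length (0 for a closed segment; downstream ratio metrics are then
#'   undefined and flagged).
#' @export
chord_length <- function(points, pixel_spacing = 1) {
  xy <- as_xy(points)
  if (nrow(xy) < 2) abort("chord needs at least 2 points")
  pixel_spacing * sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
}

#' Arc (geodesic) length of a segment
#'
#' Cumulative path length along the ordered points: for raster chains this is
#' the quasi-Euclidean distance (1 per axial move, sqrt(2) per diagonal
#' move); for general point lists, the sum of Euclidean inter-point
#' distances.
#'
#' @inheritParams chord_length
#' @return Length.
#' @export
arc_length <- function(points, pixel_spacing = 1) {
  xy <- as_xy(points)
  if (nrow(xy) < 2) abort("arc needs at least 2 points")
  pixel_spacing * sum(step_lengths(xy))
}

#' Distance metric (arc/chord ratio)
#'
#' The classic dimensionless tortuosity index: >= 1, equal to 1 only for a
#' straight segment.
#'
#' @param arc,chord Segment arc and chord lengths.
#' @return `arc / chord`.
#' @export
distance_metric <- function(arc, chord) {
  if (chord <= 0) abort("distance metric undefined: zero chord")
  arc / chord
}

#' Signed curvature along a uniformly sampled curve
#'
#' Central finite differences on the uniform arc-length parameterization
#' estimate \eqn{x', y', x'', y''}; the planar signed curvature is
#' \deqn{C = (x' y'' - y' x'') / (x'^2 + y'^2)^{3/2}.}
#' One-sided (second-order) differences are used at the two boundary
#' samples. The sign encodes bend direction and is preserved.
#'
#' @param rs Resampled curve from [resample_uniform()].
#' @return Numeric vector of signed curvature, one value per sample.
#' @export
estimate_curvature <- function(rs) {
  xy <- rs$xy
  n <- nrow(xy)
  if (n < 5) abort("curvature needs at least 5 uniformly spaced points")
  h <- rs$step
  d1 <- function(v) {
    c((-3 * v[1] + 4 * v[2] - v[3]) / (2 * h),
      (v[3:n] - v[1:(n - 2)]) / (2 * h),
      (3 * v[n] - 4 * v[n - 1] + v[n - 2]) / (2 * h))
  }
  d2 <- function(v) {
    c((v[1] - 2 * v[2] + v[3]) / h^2,
      (v[3:n] - 2 * v[2:(n - 1)] + v[1:(n - 2)]) / h^2,
      (v[n] - 2 * v[n - 1] + v[n - 2]) / h^2)
  }
  xp <- d1(xy[, 1]); yp <- d1(xy[, 2])
  xpp <- d2(xy[, 1]); ypp <- d2(xy[, 2])
  (xp * ypp - yp * xpp) / (xp^2 + yp^2)^1.5
}

# Indices (into the resampled curve) at which guarded curvature sign changes
# occur: a change is counted between consecutive samples whose |C| exceeds
# eps_kappa; near-zero samples in between are skipped (noise guard). Flips
# within `boundary_guard` samples of either end are ignored: skeleton tips
# carry stroke-cap curvature artifacts and one-sided estimates.
inflection_indices <- function(curv, eps_kappa = 1e-3, boundary_guard = 0) {
  sig <- which(abs(curv) > eps_kappa)
  if (length(sig) < 2) return(integer(0))
  sgn <- sign(curv[sig])
  flips <- which(sgn[-1] != sgn[-length(sgn)])
  # place the split at the sample of smallest |C| inside the flip interval
  idx <- vapply(flips, function(f) {
    lo <- sig[f]; hi <- sig[f + 1]
    cand <- lo:hi
    cand[which.min(abs(curv[cand]))]
  }, integer(1))
  idx[idx > boundary_guard & idx <= length(curv) - boundary_guard]
}

#' Count curvature inflections along a segment
#'
#' An inflection is a sign change of the signed curvature (the planar
#' manifestation of a Frenet-frame flip). Only changes between curvature
#' values exceeding `eps_kappa` in magnitude are counted, so numerical noise
#' around zero does not create phantom inflections.
#'
#' @param curv Signed curvature from [estimate_curvature()].
#' @param eps_kappa Magnitude threshold (1/length units).
#' @param boundary_guard Number of samples at each end whose sign changes
#'   are ignored (0 for smooth point lists; raster pipelines use a guard of
#'   about twice the smoothing bandwidth to mask skeleton-tip artifacts).
#' @return Integer count >= 0.
#' @export
count_inflections <- function(curv, eps_kappa = 1e-3, boundary_guard = 0) {
  length(inflection_indices(curv, eps_kappa, boundary_guard))
}

#' Split a sampled curve into constant-curvature-sign subsegments
#'
#' The segment is cut at every guarded curvature sign change; each maximal
#' constant-sign run becomes one subsegment, reported with its arc and chord
#' length. A straight (or inflection-free) segment yields a single
#' subsegment.
#'
#' @inheritParams count_inflections
#' @param rs Resampled curve from [resample_uniform()].
#' @return Tibble with one row per subsegment: `subsegment`, `arc`, `chord`.
#' @export
subdivide_segment <- function(rs, curv, eps_kappa = 1e-3, boundary_guard = 0) {
  cuts <- inflection_indices(curv, eps_kappa, boundary_guard)
  n <- nrow(rs$xy)
  bounds <- unique(c(1L, cuts, n))
  bounds <- bounds[order(bounds)]
  purrr::map_dfr(seq_len(length(bounds) - 1), function(k) {
    i <- bounds[k]; j <- bounds[k + 1]
    xy <- rs$xy[i:j, , drop = FALSE]
    tibble(subsegment = k,
           arc = sum(step_lengths(xy)),
           chord = sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2)))
  })
}

#' Tortuosity density
#'
#' With the segment divided into `n` constant-curvature-sign subsegments of
#' arc \eqn{Lcs_i} and chord \eqn{Lxs_i},
#' \deqn{TD = \frac{n-1}{n} \cdot \frac{1}{Arc} \sum_{i=1}^{n}
#'       \left[\frac{Lcs_i}{Lxs_i} - 1\right].}
#' A straight segment gives 0 (single subsegment forces the prefactor to 0).
#'
#' @param subs Subsegment table from [subdivide_segment()].
#' @param arc Whole-segment arc length.
#' @return TD in 1/length units.
#' @export
tortuosity_density <- function(subs, arc) {
  ok <- subs$chord > 0
  if (any(!ok)) warn("degenerate subsegment chord: subsegment skipped in TD/DF")
  n <- nrow(subs)
  if (n == 0 || arc <= 0) return(NA_real_)
  (n - 1) / n * (1 / arc) * sum(subs$arc[ok] / subs$chord[ok] - 1)
}

#' Distance factor
#'
#' Sum of per-subsegment arc/chord ratios over the `n` subsegments;
#' `DF >= n`, with equality only when every subsegment is straight.
#'
#' @inheritParams tortuosity_density
#' @return Dimensionless DF.
#' @export
distance_factor <- function(subs) {
  ok <- subs$chord > 0
  sum(subs$arc[ok] / subs$chord[ok])
}

#' Curvature-integral tortuosity measures
#'
#' Trapezoidal integration of the signed curvature over arc length:
#' total curvature \eqn{\tau_2 = \int C\,ds}, total squared curvature
#' \eqn{\tau_3 = \int C^2 ds}, and their arc- and chord-normalized forms
#' \eqn{\tau_4 = \tau_2/Arc}, \eqn{\tau_5 = \tau_3/Arc},
#' \eqn{\tau_6 = \tau_2/Chord}, \eqn{\tau_7 = \tau_3/Chord}.
#' \eqn{\tau_2} keeps its sign (orientation); use its magnitude for
#' orientation-free comparisons.
#'
#' @param rs Resampled curve.
#' @param curv Signed curvature.
#' @param arc,chord Whole-segment arc and chord lengths.
#' @return Named list `tau2` .. `tau7` (chord-normalized entries `NA` when
#'   `chord` is 0).
#' @export
curvature_integrals <- function(rs, curv, arc, chord) {
  tau2 <- pracma::trapz(rs$s, curv)
  tau3 <- pracma::trapz(rs$s, curv^2)
  list(
    tau2 = tau2, tau3 = tau3,
    tau4 = tau2 / arc, tau5 = tau3 / arc,
    tau6 = if (chord > 0) tau2 / chord else NA_real_,
    tau7 = if (chord > 0) tau3 / chord else NA_real_
  )
}

#' Sum of angles metric
#'
#' At each interior sample the turn angle (180 degrees minus the interior
#' angle between the incoming and outgoing chord vectors) is accumulated and
#' normalized by arc length, capturing tightly coiled vessels. Requires
#' evenly spaced points.
#'
#' @param rs Resampled curve from [resample_uniform()].
#' @param arc Segment arc length.
#' @return SOAM in degrees per unit length.
#' @export
soam <- function(rs, arc) {
  xy <- rs$xy
  n <- nrow(xy)
  if (n < 3) abort("SOAM needs at least 3 points")
  v <- diff(xy)
  len <- sqrt(rowSums(v^2))
  dot <- rowSums(v[-nrow(v), , drop = FALSE] * v[-1, , drop = FALSE])
  cosang <- pmin(1, pmax(-1, dot / (len[-length(len)] * len[-1])))
  turns <- acos(cosang) * 180 / pi
  sum(turns) / arc
}

#' Inflection count metric
#'
#' Extends the arc/chord distance metric by the number of curvature
#' inflections: `ICM = (inflections + 1) * Arc / Chord`, so an S-shaped
#' vessel scores higher than a C-shaped one of identical arc length.
#'
#' @param inflection_count Integer inflection count.
#' @param arc,chord Segment arc and chord lengths.
#' @return Dimensionless ICM (>= DM).
#' @export
icm <- function(inflection_count, arc, chord) {
  if (chord <= 0) abort("ICM undefined: zero chord")
  (inflection_count + 1) * arc / chord
}

#' Signed-curvature summary statistics
#'
#' @param curv Signed curvature values.
#' @return Named list: `sd_avc` (standard deviation of signed curvature) and
#'   `n_avc` (norm, i.e. absolute value, of the mean signed curvature).
#' @export
curvature_summaries <- function(curv) {
  if (length(curv) < 2) return(list(sd_avc = 0, n_avc = 0))
  list(sd_avc = stats::sd(curv), n_avc = abs(mean(curv)))
}

#' Compute the full tortuosity record for one segment
#'
#' Runs the whole metric battery on one ordered centerline: arc and chord
#' length on the raw points, then smoothing, uniform resampling, signed
#' curvature, subsegment division and the fourteen tortuosity metrics plus
#' curvature summaries. Degenerate inputs (closed segments with zero chord)
#' yield `NA` for the ratio metrics and set the `degenerate` flag rather
#' than reporting silent zeros.
#'
#' @param points Ordered centerline points (`x`,`y` or `row`,`col`).
#' @param image_id,segment_id Identifiers copied into the record.
#' @param step Resampling step (same units as the points, after
#'   `pixel_spacing` scaling).
#' @param smooth_sigma Gaussian coordinate-smoothing bandwidth; 0 disables.
#'   The default (3 px) is sized for raster-derived chains, where it pushes
#'   pixel-staircase curvature well below typical vessel curvature; use 0
#'   for already-smooth point lists.
#' @param eps_kappa Inflection noise guard (1/length). The default (0.02/px)
#'   sits at twice the residual staircase-curvature noise floor of smoothed
#'   raster chains; use a small value such as 1e-3 for smooth point lists.
#' @param pixel_spacing Physical length per pixel.
#' @return One-row tibble: identifiers, `n_points`, `arc`, `chord`, `dm`,
#'   `df`, `td`, `tau1`..`tau7`, `soam`, `icm`, `inflection_count`,
#'   `sd_avc`, `n_avc`, `degenerate`.
#' @examples
#' pts <- sample_curve(curve_spec("circular_arc", radius = 20, angle = pi))$points
#' compute_record(pts, smooth_sigma = 0, step = 0.5)
#' @export
compute_record <- function(points, image_id = "image", segment_id = 1L,
                           step = 1, smooth_sigma = 3, eps_kappa = 0.02,
                           pixel_spacing = 1) {
  xy <- as_xy(points) * pixel_spacing
  if (nrow(xy) < 2) abort("segment needs at least 2 points")
  arc <- sum(step_lengths(xy))
  if (arc <= 0) abort("degenerate segment: all points coincide")
  chord <- sqrt(sum((xy[nrow(xy), ] - xy[1, ])^2))
  degenerate <- chord <= .Machine$double.eps^0.5 * max(1, arc)

  sm <- smooth_polyline(xy, smooth_sigma)
  if (smooth_sigma > 0) {
    # the smoothed chain is the length estimate for raster input: raw
    # quasi-Euclidean chains overestimate smooth-curve length by up to ~8%
    arc <- sum(step_lengths(sm))
  }
  rs <- resample_uniform(sm, step)
  if (nrow(rs$xy) < 5) {
    rs <- resample_uniform(sm, max(arc / 8, .Machine$double.eps))
  }
  curv <- estimate_curvature(rs)
  # guard spans the smoothing kernel support: within 3*sigma of a cut end
  # the smoothed curve mixes reflected padding and is not trustworthy
  guard <- if (smooth_sigma > 0) ceiling(3 * smooth_sigma / rs$step) else 0L
  subs <- subdivide_segment(rs, curv, eps_kappa, boundary_guard = guard)
  df <- distance_factor(subs)
  td <- tortuosity_density(subs, arc)
  ci <- curvature_integrals(rs, curv, arc, chord)
  infl <- count_inflections(curv, eps_kappa, boundary_guard = guard)
  cs <- curvature_summaries(curv)

  tibble(
    image_id = image_id, segment_id = segment_id,
    n_points = nrow(xy),
    arc = arc, chord = chord,
    dm = if (degenerate) NA_real_ else arc / chord,
    df = df, td = td,
    tau1 = df - 1,
    tau2 = ci$tau2, tau3 = ci$tau3, tau4 = ci$tau4, tau5 = ci$tau5,
    tau6 = if (degenerate) NA_real_ else ci$tau6,
    tau7 = if (degenerate) NA_real_ else ci$tau7,
    soam = soam(rs, arc),
    icm = if (degenerate) NA_real_ else icm(infl, arc, chord),
    inflection_count = infl,
    sd_avc = cs$sd_avc, n_avc = cs$n_avc,
    degenerate = degenerate
  )
}

#' Tortuosity metrics for every segment of a segment table
#'
#' Applies [compute_record()] to each `(image_id, segment_id)` group of a
#' traced-segment table (as produced by [extract_segments()], or read from a
#' CSV of ordered centerline points).
#'
#' @param segments Tibble with `image_id`, `segment_id`, `point_index` and
#'   either `row`,`col` or `x`,`y` columns.
#' @inheritParams compute_record
#' @return Tibble with one tortuosity record per segment.
#' @export
segment_metrics <- function(segments, step = 1, smooth_sigma = 3,
                            eps_kappa = 0.02, pixel_spacing = 1) {
  stopifnot(all(c("image_id", "segment_id") %in% names(segments)))
  segments |>
    dplyr::arrange(.data$image_id, .data$segment_id, .data$point_index) |>
    dplyr::group_by(.data$image_id, .data$segment_id) |>
    dplyr::group_map(function(g, key) {
      compute_record(g, image_id = key$image_id, segment_id = key$segment_id,
                     step = step, smooth_sigma = smooth_sigma,
                     eps_kappa = eps_kappa, pixel_spacing = pixel_spacing)
    }) |>
    dplyr::bind_rows()
}
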