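# Per-segment tortuosity metrics: exact cases, analytic oracles, invariances.

test_that("chord length follows Euclidean distance and pixel spacing", {
  expect_equal(chord_length(cbind(c(0, 3), c(0, 4))), 5)
  expect_equal(chord_length(cbind(c(1, 4), c(1, 5)), pixel_spacing = 2), 10)
  loop <- cbind(c(0, 1, 0), c(0, 1, 0))
  expect_equal(chord_length(loop), 0)
})

test_that("arc length is quasi-Euclidean on raster chains", {
  horiz <- cbind(rep(5, 11), 0:10)        # 11-px horizontal line (row, col)
  expect_equal(arc_length(data.frame(row = horiz[, 1], col = horiz[, 2])), 10)
  diagonal <- cbind(0:10, 0:10)
  expect_equal(arc_length(data.frame(row = diagonal[, 1], col = diagonal[, 2])),
               10 * sqrt(2))
  lpath <- rbind(cbind(0, 0:5), cbind(1:5, 5)) # 5 right then 5 down
  expect_equal(arc_length(data.frame(row = lpath[, 1], col = lpath[, 2])), 10)
})

test_that("distance metric handles straight, curved and degenerate input", {
  expect_equal(distance_metric(10, 10), 1)
  expect_equal(distance_metric(pi * 5, 10), pi / 2)
  expect_error(distance_metric(10, 0), "zero chord")
  # numeric-quadrature oracle for a full sine period, amplitude 2
  sn <- sample_curve(curve_spec("sine", amplitude = 2, frequency = 1,
                                span = 2 * pi, step = 0.01))
  r <- record_smooth(sn$points, step = 0.05)
  oracle_arc <- stats::integrate(function(x) sqrt(1 + 4 * cos(x)^2),
                                 0, 2 * pi)$value
  expect_equal(r$dm, oracle_arc / sn$oracle$chord, tolerance = 1e-3)
})

test_that("resampling is uniform, endpoint-preserving, length-conserving", {
  rs <- resample_uniform(cbind(x = c(0, 10), y = c(0, 0)), step = 1)
  expect_equal(nrow(rs$xy), 11L)
  expect_equal(rs$xy[, "x"], seq(0, 10))
  expect_true(all(abs(rs$xy[, "y"]) < 1e-12))
  qc <- sample_curve(curve_spec("circular_arc", radius = 10, angle = pi / 2,
                                step = 0.05))
  rs2 <- resample_uniform(qc$points, step = 0.5)
  expect_equal(rs2$s[length(rs2$s)], (pi / 2) * 10, tolerance = 0.01)
  d <- sqrt(rowSums(diff(rs2$xy)^2))
  expect_lt(diff(range(d)), 1e-4)                    # even chord spacing
  expect_error(resample_uniform(cbind(c(1, 1), c(2, 2))), "degenerate")
})

test_that("curvature matches analytic values on circle and sine", {
  qc <- sample_curve(curve_spec("circular_arc", radius = 7, angle = pi,
                                step = 0.02))
  rs <- resample_uniform(qc$points, step = 0.1)
  cv <- estimate_curvature(rs)
  interior <- cv[5:(length(cv) - 4)]
  expect_true(all(abs(abs(interior) - 1 / 7) / (1 / 7) < 0.02))
  # sine crest: |C| = |y''| / (1 + y'^2)^{3/2} = 1 at x = pi/2
  x <- seq(0, pi, by = 0.001)
  rs2 <- resample_uniform(cbind(x = x, y = sin(x)), step = 0.01)
  cv2 <- estimate_curvature(rs2)
  crest <- which.min(abs(rs2$xy[, "x"] - pi / 2))
  expect_equal(abs(cv2[crest]), 1, tolerance = 0.01)
  # straight line: zero curvature everywhere
  rs3 <- resample_uniform(cbind(x = seq(0, 10, 0.5), y = 0), step = 0.5)
  expect_true(all(abs(estimate_curvature(rs3)) < 1e-9))
  expect_error(estimate_curvature(resample_uniform(cbind(c(0, 1), c(0, 0)),
                                                   step = 0.5)),
               "at least 5")
})

test_that("subdivision splits at curvature sign changes", {
  line <- resample_uniform(cbind(x = seq(0, 10, 0.5), y = 0), step = 0.5)
  cv <- estimate_curvature(line)
  expect_equal(nrow(subdivide_segment(line, cv)), 1L)
  # sine over [0, 4pi]: sign runs split at pi, 2pi, 3pi -> 4 subsegments
  sn <- sample_curve(curve_spec("sine", amplitude = 1, frequency = 1,
                                span = 4 * pi, step = 0.01))
  rs <- resample_uniform(sn$points, step = 0.05)
  cv2 <- estimate_curvature(rs)
  expect_equal(count_inflections(cv2, 1e-3), 3L)
  expect_equal(nrow(subdivide_segment(rs, cv2, 1e-3)), 4L)
})

test_that("TD, DF and tau1 agree with hand-evaluated S-curve values", {
  s <- sample_curve(curve_spec("composite_S", radii = c(1, 1), step = 0.01))
  r <- record_smooth(s$points, step = 0.01)
  expect_equal(r$df, pi, tolerance = 0.01)
  expect_equal(r$tau1, pi - 1, tolerance = 0.01)
  expect_equal(r$td, (pi / 2 - 1) / (2 * pi), tolerance = 0.01)
  expect_equal(r$inflection_count, 1L)
  expect_equal(r$icm, pi, tolerance = 0.01)
  # DF >= n for every fixture
  expect_gte(r$df, 2)
})

test_that("curvature integrals match circular-arc closed forms", {
  r0 <- 6; th <- 2.5
  qc <- sample_curve(curve_spec("circular_arc", radius = r0, angle = th,
                                step = 0.02))
  r <- record_smooth(qc$points, step = 0.05)
  expect_equal(abs(r$tau2), th, tolerance = 0.01)
  expect_equal(r$tau3, th / r0, tolerance = 0.01)
  expect_equal(abs(r$tau4), 1 / r0, tolerance = 0.01)
  expect_equal(r$tau5, 1 / r0^2, tolerance = 0.01)
  chord <- 2 * r0 * sin(th / 2)
  expect_equal(abs(r$tau6), th / chord * r0 / r0, tolerance = 0.02)
  expect_equal(r$tau7, (th / r0) / chord, tolerance = 0.02)
})

test_that("SOAM matches the single-elbow and dense-circle oracles", {
  elbow <- rbind(cbind(x = 0:5, y = 0), cbind(x = 5, y = 1:5))
  rs <- resample_uniform(elbow, step = 1)
  expect_equal(soam(rs, arc = 10), 9, tolerance = 1e-9)   # 90 deg / 10 units
  qc <- sample_curve(curve_spec("circular_arc", radius = 8, angle = pi,
                                step = 0.02))
  r <- record_smooth(qc$points, step = 0.1)
  expect_equal(r$soam, (180 / pi) / 8, tolerance = 0.01)
  line <- resample_uniform(cbind(x = seq(0, 10, 0.5), y = 0), step = 0.5)
  expect_equal(soam(line, 10), 0)
})

test_that("curvature summaries behave on line, arc and balanced S", {
  line <- resample_uniform(cbind(x = seq(0, 10, 0.25), y = 0), step = 0.25)
  cs <- curvature_summaries(estimate_curvature(line))
  expect_equal(cs$sd_avc, 0, tolerance = 1e-9)
  expect_equal(cs$n_avc, 0, tolerance = 1e-9)
  qc <- sample_curve(curve_spec("circular_arc", radius = 4, angle = pi,
                                step = 0.02))
  rq <- record_smooth(qc$points, step = 0.05)
  expect_equal(rq$n_avc, 1 / 4, tolerance = 0.01)
  expect_lt(rq$sd_avc, 0.01)
  s <- record_smooth(sample_curve(curve_spec("composite_S", radii = c(1, 1),
                                             step = 0.01))$points, step = 0.01)
  expect_lt(s$n_avc, 0.02)                            # signed halves cancel
})

test_that("straight segments produce the exact trivial record", {
  r <- record_smooth(cbind(x = seq(0, 20, 0.5), y = 0), step = 0.5)
  expect_equal(r$dm, 1)
  expect_equal(r$td, 0)
  for (k in 1:7) expect_equal(r[[paste0("tau", k)]], 0, tolerance = 1e-8)
  expect_equal(r$soam, 0, tolerance = 1e-8)
  expect_equal(r$icm, 1)
  expect_equal(r$inflection_count, 0L)
  expect_false(r$degenerate)
})

test_that("closed segments flag degenerate ratio metrics, never silent zeros", {
  t <- seq(0, 2 * pi, length.out = 500)
  loop <- cbind(x = cos(t), y = sin(t))
  r <- record_smooth(loop, step = 0.05)
  expect_true(r$degenerate)
  expect_true(is.na(r$dm) && is.na(r$icm) && is.na(r$tau6) && is.na(r$tau7))
  expect_false(is.na(r$tau3))                         # arc-normalized still fine
})

test_that("metric formula identities hold on every fixture", {
  for (pts in fixture_curves()) {
    r <- record_smooth(pts, step = 0.02)
    expect_equal(r$icm / r$dm, r$inflection_count + 1, tolerance = 1e-9)
    expect_equal(r$tau4 * r$arc, r$tau2, tolerance = 1e-9)
    expect_equal(r$tau6 * r$chord, r$tau2, tolerance = 1e-9)
    expect_equal(r$tau1, r$df - 1, tolerance = 1e-12)
    expect_gte(r$dm, 1 - 1e-6)
    expect_gte(r$icm, r$dm - 1e-9)
  }
})

test_that("metrics are invariant under rigid motion", {
  pts <- fixture_curves()$sine
  base <- record_smooth(pts, step = 0.05)
  th <- 0.7
  rot <- cbind(x = cos(th) * pts$x - sin(th) * pts$y + 13.7,
               y = sin(th) * pts$x + cos(th) * pts$y - 4.2)
  moved <- record_smooth(rot, step = 0.05)
  for (col in c("arc", "chord", "dm", "df", "td", paste0("tau", c(1, 3, 5, 7)),
                "soam", "icm", "sd_avc", "n_avc")) {
    expect_close(moved[[col]], base[[col]], tol = 1e-9, label = col)
  }
  expect_close(abs(moved$tau2), abs(base$tau2), tol = 1e-9)
  expect_equal(moved$inflection_count, base$inflection_count)
})

test_that("reversal leaves metric magnitudes unchanged", {
  pts <- fixture_curves()$s_curve
  fwd <- record_smooth(pts, step = 0.01)
  rev <- record_smooth(pts[rev(seq_len(nrow(pts))), ], step = 0.01)
  expect_equal(rev$arc, fwd$arc, tolerance = 1e-9)
  expect_equal(rev$dm, fwd$dm, tolerance = 1e-9)
  expect_close(abs(rev$tau2), abs(fwd$tau2), tol = 1e-6)
  expect_equal(rev$tau3, fwd$tau3, tolerance = 1e-6)
  expect_equal(rev$soam, fwd$soam, tolerance = 1e-6)
  expect_equal(rev$inflection_count, fwd$inflection_count)
  expect_equal(rev$df, fwd$df, tolerance = 1e-6)
})

test_that("scale laws: ratios invariant, lengths linear", {
  pts <- fixture_curves()$s_curve
  base <- record_smooth(pts, step = 0.01)
  for (k in c(0.5, 2, 3)) {
    scaled <- record_smooth(data.frame(x = k * pts$x, y = k * pts$y),
                            step = 0.01 * k)
    expect_equal(scaled$arc, k * base$arc, tolerance = 1e-6)
    expect_equal(scaled$chord, k * base$chord, tolerance = 1e-9)
    expect_equal(scaled$dm, base$dm, tolerance = 1e-6)
    expect_equal(scaled$tau1, base$tau1, tolerance = 1e-4)
    expect_equal(scaled$icm, base$icm, tolerance = 1e-6)
    expect_equal(scaled$td * scaled$arc, base$td * base$arc, tolerance = 1e-4)
    expect_equal(scaled$inflection_count, base$inflection_count)
  }
})

test_that("records stay finite over a random spline fixture suite", {
  set.seed(14)
  for (i in 1:10) {
    n_knots <- sample(4:7, 1)
    kx <- sort(stats::runif(n_knots, 0, 100))
    ky <- stats::runif(n_knots, -20, 20)
    x <- seq(min(kx), max(kx), by = 0.25)
    y <- stats::spline(kx, ky, xout = x)$y
    r <- record_smooth(data.frame(x = x, y = y), step = 0.5)
    num <- unlist(r[, c("arc", "chord", "dm", "df", "td", paste0("tau", 1:7),
                        "soam", "icm", "sd_avc", "n_avc")])
    expect_true(all(is.finite(num)))
  }
})

test_that("segment_metrics maps over grouped segment tables", {
  segs <- dplyr::bind_rows(
    tibble::tibble(image_id = "a", segment_id = 1L, point_index = 1:21,
                   row = 5, col = 0:20),
    tibble::tibble(image_id = "a", segment_id = 2L, point_index = 1:21,
                   row = 0:20, col = 0:20)
  )
  rec <- segment_metrics(segs, smooth_sigma = 0, eps_kappa = 1e-3)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$dm, c(1, 1), tolerance = 1e-9)
  expect_equal(rec$arc, c(20, 20 * sqrt(2)), tolerance = 1e-9)
})
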