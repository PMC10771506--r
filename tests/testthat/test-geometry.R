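# B-spline boundaries, equal-angle resampling, temporal interpolation,
# kinematics.

test_that("closed B-spline follows its control polygon", {
  # degree 1 reproduces the polygon exactly
  sq <- cbind(c(0, 1, 1, 0), c(0, 0, 1, 1))
  sb1 <- fit_spline_boundary(sq, degree = 1)
  expect_equal(eval_at <- clotflow:::eval_spline(sb1, c(0, 0.25, 0.5, 0.75)),
               sq, tolerance = 1e-12)
  # rasterized circle, degree 3: arc length within 2% of 2 pi r
  sb3 <- fit_spline_boundary(circle_pts(20, n = 150), degree = 3)
  expect_lt(abs(spline_length(sb3) - 2 * pi * 20) / (2 * pi * 20), 0.02)
  # round-trip: refitting a sampled spline moves points < 0.5 px
  p <- clotflow:::spline_polygon(sb3, 150)
  p2 <- clotflow:::spline_polygon(fit_spline_boundary(p, 3), 150)
  expect_lt(max(sqrt(rowSums((p - p2)^2))), 0.5)
  expect_error(fit_spline_boundary(sq[1:2, ], degree = 3), "degree")
})

test_that("equal-angle resampling intersects rays exactly", {
  sb <- fit_spline_boundary(circle_pts(12, center = c(5, 3)), degree = 3)
  rs <- resample_by_angle(sb, 90)
  r <- sqrt(rowSums(sweep(rs$points, 2, rs$center)^2))
  expect_lt(diff(range(r)), 0.01)
  expect_equal(mean(r), 12, tolerance = 1e-3)
  # ellipse a=20 b=10: ray at angle 0 hits (20, 0) relative to the center
  rse <- resample_by_angle(fit_spline_boundary(ellipse_pts(20, 10)), 36,
                           center = c(0, 0))
  expect_equal(rse$points[1, ], c(20, 0), tolerance = 0.01)
  # recomputed polar angles match the prescribed angles
  ang <- atan2(rse$points[, 2], rse$points[, 1]) %% (2 * pi)
  expect_lt(max(abs(ang[-1] - rse$angles[-1])), 1e-6)
  expect_error(resample_by_angle(sb, 4), "n_rays")
  # center outside the curve: no intersection along some ray
  expect_error(resample_by_angle(sb, 16, center = c(100, 100)), "intersection")
})

test_that("temporal interpolation is linear in the matched samples", {
  s1 <- resample_by_angle(fit_spline_boundary(circle_pts(10)), 90)
  s2 <- resample_by_angle(fit_spline_boundary(circle_pts(20)), 90)
  # identical endpoints: intermediates equal the endpoint
  same <- interpolate_in_time(s1, s1, 3)
  expect_equal(same[[1]]$points, s1$points)
  expect_equal(same[[2]]$points, s1$points)
  # concentric circles: midpoint is the circle of mean radius
  mid <- interpolate_in_time(s1, s2, 2)[[1]]
  expect_equal(sqrt(rowSums(mid$points^2)), rep(15, 90), tolerance = 0.01)
  s3 <- resample_by_angle(fit_spline_boundary(circle_pts(10)), 45)
  expect_error(interpolate_in_time(s1, s3, 2), "mismatched")
})

test_that("kinematics reproduce analytic area and aspect ratio", {
  mk <- function(pts, t) {
    s <- resample_by_angle(fit_spline_boundary(pts), 180); s$time <- t; s
  }
  circ <- lapply(0:4, function(i) mk(circle_pts(10), i * 0.55))
  kin <- compute_kinematics(circ)
  expect_equal(kin$area[1], 100 * pi, tolerance = 0.01 * 100 * pi)
  expect_equal(kin$aspect[1], 1, tolerance = 0.01)
  ell <- lapply(0:4, function(i) mk(ellipse_pts(20, 10, theta = 0.4), i * 0.55))
  expect_equal(compute_kinematics(ell)$aspect[1], 2, tolerance = 0.02)
  # linear growth: positive area rate at all interior times
  grow <- lapply(0:6, function(i) mk(circle_pts(10 + i), i * 0.55))
  kin_g <- compute_kinematics(grow)
  expect_true(all(kin_g$dA_dt[2:6] > 0))
  expect_error(compute_kinematics(grow[1:2]), "3 time points")
})

test_that("analytic ellipse schedules match ground truth within 3%", {
  sched <- make_growth_schedule(8, base_axes = c(14, 9), growth_rate = 0.8,
                                center = c(40, 40))
  samps <- lapply(seq_len(8), function(f) {
    s <- resample_by_angle(
      fit_spline_boundary(ellipse_pts(sched$a[f], sched$b[f],
                                      center = c(40, 40))), 180)
    s$time <- (f - 1) * 0.55
    s
  })
  kin <- compute_kinematics(samps)
  expect_lt(max(abs(kin$area - pi * sched$a * sched$b) /
                  (pi * sched$a * sched$b)), 0.03)
  expect_lt(max(abs(kin$aspect - sched$a / sched$b) / (sched$a / sched$b)),
            0.03)
})

test_that("downsampling check is exact for linear motion and small for smooth growth", {
  mk_series <- function(radii) lapply(seq_along(radii), function(i) {
    s <- fit_spline_boundary(circle_pts(radii[i])); s$time <- (i - 1) * 0.55; s
  })
  # static: distance 0
  expect_equal(as.numeric(downsample_check(mk_series(rep(10, 7)), 90)), 0,
               tolerance = 1e-12)
  # linear growth: linear interpolation is exact
  expect_lt(as.numeric(downsample_check(mk_series(10 + (0:6)), 90)), 1e-9)
  # smooth nonlinear growth: sub-micron interpolation error
  r_t <- 10 + 8 * (1 - exp(-(0:9) / 4))
  expect_lt(as.numeric(downsample_check(mk_series(r_t), 90)), 1.0)
  expect_error(downsample_check(mk_series(rep(10, 4))), "6 frames")
})

test_that("failed frames are bridged when assembling the dynamic domain", {
  spl <- lapply(0:4, function(i) {
    s <- fit_spline_boundary(circle_pts(10 + i, center = c(30, 30)))
    s$time <- i * 0.55
    s
  })
  spl[3] <- list(NULL)          # simulate a failed segmentation at frame 3
  dom <- dynamic_clot_domain(spl, frame_interval = 0.55, n_sub = 5,
                             n_rays = 90)
  b <- dom$overall[[3]]
  r <- sqrt(rowSums(sweep(b$points, 2, b$center)^2))
  expect_equal(mean(r), 12, tolerance = 0.05)  # interpolated between 11 and 13
  # boundary_at interpolates between frames
  mid <- boundary_at(dom, 0.275)
  rm <- sqrt(rowSums(sweep(mid$points, 2, mid$center)^2))
  expect_equal(mean(rm), 10.5, tolerance = 0.05)
})
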