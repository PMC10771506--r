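# Traction loading, solute decay curves, Reynolds number, phase portrait,
# embolization detection, LHS sensitivity.

test_that("pressure force on a closed curve in a constant-pressure field is zero", {
  mesh <- test_mesh(h = 5)
  fl <- uniform_flow(mesh, p = 37)
  tr <- boundary_traction(fl, circle_pts(15, center = c(50, 25), n = 180), mesh)
  expect_lt(tr$pressure_mag, 1e-10)
  expect_lt(tr$shear_mag, 1e-12)
})

test_that("fictitious curve in pure Stokes flow carries near-zero net force", {
  mesh <- test_mesh(h = 2.5)
  fs <- solve_flow_step(mesh, NULL, flow_config(), steady = TRUE)
  tr <- boundary_traction(fs, circle_pts(10, center = c(50, 25), n = 240), mesh)
  # momentum balance: total force ~ 0 relative to the pressure-drop scale
  scale_force <- abs(diff(range(fs$p))) * 20 * 1e-3   # Pa*um -> nN/um
  expect_lt(tr$total_mag, 0.1 * scale_force)
  expect_error(boundary_traction(fs, circle_pts(10, center = c(500, 0)), mesh),
               "outside")
})

test_that("occlusive plug loading is pressure-dominated in the streamwise direction", {
  mesh <- test_mesh(h = 2.5)
  ind <- mark_indicator(mesh, circle_pts(18, center = c(50, 25), n = 200))
  mat <- assemble_material_fields(ind, params = wt_params())
  fs <- solve_flow_step(mesh, mat, flow_config(), steady = TRUE)
  tr <- boundary_traction(fs, circle_pts(18, center = c(50, 25), n = 240), mesh)
  expect_gt(tr$pressure_force[1], 0)            # pushed downstream
  expect_gt(abs(tr$pressure_force[1]), abs(tr$shear_force[1]))
  expect_gt(tr$pressure_mag, tr$shear_mag)
  # vector identity: total = pressure + shear
  expect_equal(tr$total_force, tr$pressure_force + tr$shear_force)
})

test_that("traction integral converges under quadrature refinement", {
  mesh <- test_mesh(h = 2.5)
  ind <- mark_indicator(mesh, circle_pts(15, center = c(50, 25), n = 200))
  mat <- assemble_material_fields(ind, params = wt_params())
  fs <- solve_flow_step(mesh, mat, flow_config(), steady = TRUE)
  f <- vapply(c(60, 120, 240, 480), function(nq)
    boundary_traction(fs, circle_pts(15, center = c(50, 25), n = nq),
                      mesh)$total_mag, numeric(1))
  # Richardson-style: successive differences shrink
  d <- abs(diff(f))
  expect_lt(d[3], d[1])
  expect_lt(abs(f[4] - f[3]) / f[4], 0.01)
})

test_that("decay curve is constant without transport and ordered core vs shell", {
  mesh <- test_mesh(h = 2.5)
  ind_all <- mark_indicator(mesh, circle_pts(15, center = c(50, 25), n = 200))
  ind_core <- mark_indicator(mesh, circle_pts(8, center = c(50, 25), n = 150))
  mat <- assemble_material_fields(ind_all, ind_core, wt_params())
  s0 <- init_uncaging(mesh, ind_all)
  # u = 0, D = 0: curve stays at 1
  mat0 <- mat; mat0$D[] <- 0
  states <- list(s0)
  s <- s0
  for (k in 1:3) {
    s <- solve_transport_step(mesh, mat0, NULL, s, transport_config(dt = 0.05))
    states <- c(states, list(s))
  }
  dc0 <- calb_decay_curve(states, mesh, mat0, "clot")
  expect_equal(dc0$value, rep(1, 4), tolerance = 1e-10)
  # with flow: whole-clot curve non-increasing; core decays slower than shell
  fs <- solve_flow_step(mesh, mat, flow_config(), steady = TRUE)
  states <- list(s0); s <- s0
  for (k in 1:10) {
    s <- suppressWarnings(
      solve_transport_step(mesh, mat, fs, s, transport_config(dt = 0.05)))
    states <- c(states, list(s))
  }
  dc <- calb_decay_curve(states, mesh, mat, "clot")
  expect_true(all(diff(dc$value) <= 1e-12))
  core <- calb_decay_curve(states, mesh, mat, "core")
  shell <- calb_decay_curve(states, mesh, mat, "shell")
  expect_gt(core$value[11], shell$value[11])
  expect_error(calb_decay_curve(states, mesh,
                                local({ m <- mat; m$core[] <- FALSE; m }),
                                "core"),
               "empty region")
})

test_that("Reynolds number sits in the low-Re regime of arteriole flow", {
  expect_equal(reynolds_number(flow_config(), 50),
               1060 * (1.3e-3 / 2) * 50e-6 / 4e-3)
  expect_equal(reynolds_number(flow_config(), 50), 8.6e-3, tolerance = 0.01)
  expect_equal(reynolds_number(flow_config(U_peak_um_s = 0), 50), 0)
  expect_equal(reynolds_number(flow_config(), 100), 1.7e-2, tolerance = 0.02)
  re <- reynolds_number(flow_config(), 50)
  expect_gt(re, 1e-3); expect_lt(re, 1e-1)
})

# Helper: fabricate aligned kinematics + loading series from an area schedule
# with force proportional to area (growing clot carries growing load).
schedule_series <- function(area) {
  t <- (seq_along(area) - 1) * 0.55
  force <- area / 100
  kin <- data.frame(time = t, area = area, aspect = 1,
                    dA_dt = 0, dAR_dt = 0)
  class(kin) <- c("kinematics_series", "data.frame")
  load <- data.frame(time = t, total_mag = force)
  class(load) <- c("loading_series", "data.frame")
  list(kin = kin, load = load)
}

test_that("embolization detector: no false positives on monotone growth", {
  set.seed(3)
  for (k in 1:10) {
    area <- cumsum(runif(25, 0.5, 3)) + 100
    ss <- schedule_series(area)
    pp <- build_phase_portrait(ss$kin, ss$load)
    expect_true(is.na(pp$embolization_index))
  }
})

test_that("embolization detector hits a step drop exactly", {
  sched <- make_growth_schedule(25, mode = "growth_then_embolize",
                                base_axes = c(10, 8), growth_rate = 1,
                                embolize_frame = 15, embolize_fraction = 0.5)
  area <- pi * sched$a * sched$b
  ss <- schedule_series(area)
  pp <- build_phase_portrait(ss$kin, ss$load)
  expect_equal(pp$embolization_index, 15)
  # bounding box spans initiation to the embolization point
  expect_equal(pp$bounding_box$area[2], max(area[1:15]))
})

test_that("larger plug sustaining larger force yields a larger bounding box", {
  mk <- function(base) {
    sched <- make_growth_schedule(25, mode = "growth_then_embolize",
                                  base_axes = base, growth_rate = 1,
                                  embolize_frame = 18,
                                  embolize_fraction = 0.4)
    ss <- schedule_series(pi * sched$a * sched$b)
    build_phase_portrait(ss$kin, ss$load)
  }
  small <- mk(c(8, 6)); large <- mk(c(14, 12))
  expect_gt(diff(large$bounding_box$force), diff(small$bounding_box$force))
  expect_gt(diff(large$bounding_box$area), diff(small$bounding_box$area))
})

test_that("LHS sensitivity: degenerate ranges give zero variability, fixed seed reproduces", {
  scn <- test_scene(n_frames = 2)
  st <- render_stack(scn)$channels$CD41
  degen <- lhs_sensitivity(st, param_ranges = list(percentile = c(80, 80),
                                                   gaussian_sigma = c(1, 1)),
                           n_samples = 10, seed = 2)
  expect_equal(degen$area_cv_pct, 0, tolerance = 1e-10)
  expect_equal(degen$aspect_cv_pct, 0, tolerance = 1e-10)
  s1 <- lhs_sensitivity(st, n_samples = 10, seed = 5)
  s2 <- lhs_sensitivity(st, n_samples = 10, seed = 5)
  expect_identical(s1$samples, s2$samples)
  expect_identical(s1$area, s2$area)
})
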