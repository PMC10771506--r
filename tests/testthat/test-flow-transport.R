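# Stabilised FEM flow and transport: analytic limits and conservation.

test_that("empty channel recovers plane Poiseuille flow within 2%", {
  mesh <- test_mesh(h = 2.5)          # h = d/20
  fs <- solve_flow_step(mesh, NULL, flow_config(), steady = TRUE)
  out_nodes <- mesh$boundary_nodes$outlet
  ctr <- out_nodes[which.min(abs(mesh$nodes[out_nodes, 2] - 25))]
  expect_lt(abs(fs$u[ctr, 1] - 1300) / 1300, 0.02)
  # full outlet profile vs analytic parabola (rms over the profile)
  y <- mesh$nodes[out_nodes, 2]
  ua <- 1300 * (1 - (2 * y / 50 - 1)^2)
  expect_lt(sqrt(mean((fs$u[out_nodes, 1] - ua)^2)) / 1300, 0.02)
  # weak divergence residual is small relative to the velocity scale
  dv <- clotflow:::flow_divergence(mesh, fs)
  expect_lt(max(abs(dv)) * mesh$h / 1300, 0.05)
})

test_that("zero inflow gives a quiescent field with constant pressure", {
  mesh <- test_mesh(h = 5)
  fs <- solve_flow_step(mesh, NULL, flow_config(U_peak_um_s = 0),
                        steady = TRUE)
  expect_equal(max(abs(fs$u)), 0, tolerance = 1e-12)
  expect_lt(diff(range(fs$p)), 1e-9)
})

test_that("refining the mesh reduces the Poiseuille error", {
  err <- vapply(c(5, 2.5), function(h) {
    mesh <- test_mesh(h = h)
    fs <- solve_flow_step(mesh, NULL, flow_config(), steady = TRUE)
    out_nodes <- mesh$boundary_nodes$outlet
    y <- mesh$nodes[out_nodes, 2]
    max(abs(fs$u[out_nodes, 1] - 1300 * (1 - (2 * y / 50 - 1)^2))) / 1300
  }, numeric(1))
  expect_lt(err[2], err[1])
})

test_that("uniform porous slab matches the 1D Darcy-Brinkman pressure gradient within 5%", {
  mesh <- test_mesh(h = 2.5)
  member <- mesh$nodes[, 1] >= 40 & mesh$nodes[, 1] <= 60
  mat <- assemble_material_fields(
    fake_indicator(member),
    params = material_params(phi_core = 0.2, phi_shell = 0.2,
                             D_shell = 0.4, D_core = 0.4))
  fs <- solve_flow_step(mesh, mat, flow_config(), steady = TRUE)
  p_at <- function(x) mean(fs$p[abs(mesh$nodes[, 1] - x) < 1e-6 &
                                  abs(mesh$nodes[, 2] - 25) < 1.3])
  dpdx <- (p_at(55) - p_at(45)) / (10e-6)
  K <- unique(mat$K[member]) * 1e-12          # m^2
  mu <- 4e-3; d <- 50e-6
  Q <- 2 / 3 * 1.3e-3 * d                     # inflow flux, m^2/s
  sqK <- sqrt(K)
  u_plug <- Q / (d - 2 * sqK * tanh(d / (2 * sqK)))
  dpdx_an <- -mu / K * u_plug
  expect_lt(abs(dpdx - dpdx_an) / abs(dpdx_an), 0.05)
  # interior velocity is nearly uniform plug flow
  mid <- which(mesh$nodes[, 1] > 45 & mesh$nodes[, 1] < 55 &
                 mesh$nodes[, 2] > 10 & mesh$nodes[, 2] < 40)
  expect_lt(diff(range(fs$u[mid, 1])) / mean(fs$u[mid, 1]), 0.15)
  expect_error(solve_flow_step(mesh, local({
    m <- mat; m$K[member][1] <- -1; m
  }), flow_config(), steady = TRUE), "permeability")
})

test_that("unsteady stepping converges to the steady state for a static clot", {
  mesh <- test_mesh(h = 5)
  ind <- mark_indicator(mesh, circle_pts(12, center = c(50, 25), n = 100))
  mat <- assemble_material_fields(ind, params = wt_params())
  cfg <- flow_config(dt = 0.05)
  fs <- NULL
  rel <- Inf
  for (k in 1:20) {
    prev <- fs
    fs <- solve_flow_step(mesh, mat, cfg, fs)
    if (!is.null(prev))
      rel <- sqrt(sum((fs$u - prev$u)^2)) / sqrt(sum(fs$u^2))
  }
  expect_lt(rel, 1e-6)
  fss <- solve_flow_step(mesh, mat, cfg, steady = TRUE)
  expect_lt(max(abs(fs$u - fss$u)) / max(abs(fss$u)), 1e-4)
})

test_that("scalar mass is conserved to 1e-10 with closed boundaries", {
  mesh <- test_mesh(h = 2.5)
  ind <- mark_indicator(mesh, circle_pts(15, center = c(50, 25), n = 200))
  mat <- assemble_material_fields(ind, params = wt_params())
  s <- init_uncaging(mesh, ind)
  m0 <- clotflow:::transport_mass(mesh, mat, s)
  cfg <- transport_config(dt = 0.05, inlet_bc = "closed")
  for (k in 1:5) s <- solve_transport_step(mesh, mat, NULL, s, cfg)
  expect_lt(abs(clotflow:::transport_mass(mesh, mat, s) - m0) / m0, 1e-10)
})

test_that("a Gaussian blob advects with the flow speed", {
  mesh <- test_mesh(h = 2.5)
  mat <- assemble_material_fields(fake_indicator(rep(FALSE, nrow(mesh$nodes))),
                                  params = wt_params())
  mat$D[] <- 1e-9                            # D -> 0
  fl <- uniform_flow(mesh, ux = 200)
  c0 <- exp(-((mesh$nodes[, 1] - 25)^2 + (mesh$nodes[, 2] - 25)^2) / 32)
  s <- structure(list(c = c0, time = 0), class = "transport_state")
  cfg <- transport_config(dt = 0.01)
  for (k in 1:10) s <- solve_transport_step(mesh, mat, fl, s, cfg)
  ml <- clotflow:::lumped_areas(mesh)
  cen <- sum(ml * s$c * mesh$nodes[, 1]) / sum(ml * s$c)
  expect_lt(abs((cen - 25) - 200 * 0.1) / (200 * 0.1), 0.02)
})

test_that("uncaging initializes the pulse over the clot and repeats", {
  mesh <- test_mesh(h = 5)
  ind <- mark_indicator(mesh, circle_pts(15, center = c(50, 25), n = 100))
  s <- init_uncaging(mesh, ind)
  expect_true(all(s$c[ind$member] == 1))
  expect_true(all(s$c[!ind$member] == 0))
  # phi-weighted initial mass equals the lumped member mass
  mat <- assemble_material_fields(ind, params = wt_params())
  ml <- clotflow:::lumped_areas(mesh)
  expect_equal(sum(ml[ind$member] * mat$phi[ind$member]),
               sum(ml * mat$phi * s$c))
  # re-pulse resets to 1 after decay
  fs <- solve_flow_step(mesh, mat, flow_config(), steady = TRUE)
  s2 <- suppressWarnings(
    solve_transport_step(mesh, mat, fs, s, transport_config(dt = 0.05)))
  s3 <- init_uncaging(mesh, ind, time = s2$time)
  expect_true(all(s3$c[ind$member] == 1))
  expect_error(init_uncaging(mesh, fake_indicator(rep(FALSE, nrow(mesh$nodes)))),
               "empty clot")
})

test_that("clot-averaged concentration decays monotonically under flow", {
  mesh <- test_mesh(h = 2.5)
  ind <- mark_indicator(mesh, circle_pts(15, center = c(50, 25), n = 200))
  mat <- assemble_material_fields(ind, params = wt_params())
  fs <- solve_flow_step(mesh, mat, flow_config(), steady = TRUE)
  s <- init_uncaging(mesh, ind)
  ml <- clotflow:::lumped_areas(mesh)
  w <- ml[ind$member] * mat$phi[ind$member]
  avg <- function(st) sum(w * st$c[ind$member]) / sum(w)
  vals <- avg(s)
  for (k in 1:8) {
    s <- suppressWarnings(
      solve_transport_step(mesh, mat, fs, s, transport_config(dt = 0.05)))
    vals <- c(vals, avg(s))
  }
  expect_true(all(diff(vals) < 0))
})

test_that("overshoot stays within the stabilised bound when resolved, else warns with Peclet", {
  mesh <- test_mesh(h = 2.5)
  ind <- mark_indicator(mesh, circle_pts(15, center = c(50, 25), n = 200))
  mat <- assemble_material_fields(ind, params = wt_params())
  # resolved regime: slow flow
  fs <- solve_flow_step(mesh, mat, flow_config(U_peak_um_s = 20),
                        steady = TRUE)
  s <- init_uncaging(mesh, ind)
  for (k in 1:5)
    s <- solve_transport_step(mesh, mat, fs, s, transport_config(dt = 0.05))
  expect_gte(min(s$c), -0.05)
  expect_lte(max(s$c), 1.05)
  # under-resolved sharp front: warning carries a cell-Peclet report
  fs2 <- solve_flow_step(mesh, mat, flow_config(), steady = TRUE)
  s2 <- init_uncaging(mesh, ind)
  for (k in 1:3)
    s2 <- suppressWarnings(
      solve_transport_step(mesh, mat, fs2, s2, transport_config(dt = 0.05)))
  expect_warning(
    solve_transport_step(mesh, mat, fs2, s2, transport_config(dt = 0.05)),
    "Peclet")
})

test_that("growing occlusion accelerates the gap flow", {
  mesh <- test_mesh(h = 2.5)
  speeds <- vapply(c(8, 13, 18), function(r) {
    ind <- mark_indicator(mesh, circle_pts(r, center = c(50, 25), n = 150))
    mat <- assemble_material_fields(ind, params = wt_params())
    fs <- solve_flow_step(mesh, mat, flow_config(), steady = TRUE)
    free <- !ind$member
    max(sqrt(rowSums(fs$u[free, ]^2)))
  }, numeric(1))
  expect_true(all(diff(speeds) > 0))
})
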