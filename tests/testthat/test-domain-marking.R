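# Vessel mesh construction, Laplace indicator marking, material fields.

test_that("structured channel mesh has the expected size and tags", {
  mesh <- build_vessel_mesh(100, 50, h = 2.5)
  # triangle count ~ 2 (L/h)(d/h) for the 2-triangles-per-quad splitting
  expect_lt(abs(nrow(mesh$tri) - 2 * (100 / 2.5) * (50 / 2.5)) /
              (2 * (100 / 2.5) * (50 / 2.5)), 0.2)
  expect_true(all(mesh$geom$area > 0))
  # boundary edge lengths per tag sum to the perimeter
  be <- mesh$boundary_edges
  len <- sqrt(rowSums((mesh$nodes[be$n1, ] - mesh$nodes[be$n2, ])^2))
  expect_equal(sum(len), 2 * (100 + 50), tolerance = 1e-9)
  expect_setequal(unique(be$tag), c("inlet", "outlet", "wall"))
  expect_equal(sum(len[be$tag == "inlet"]), 50, tolerance = 1e-9)
})

test_that("halving h quarters the maximum triangle area", {
  a1 <- max(build_vessel_mesh(80, 40, h = 4)$geom$area)
  a2 <- max(build_vessel_mesh(80, 40, h = 2)$geom$area)
  expect_gt(a1 / a2, 2)    # quartered within a factor of 2
  expect_lt(a1 / a2, 8)
  expect_error(build_vessel_mesh(80, 40, h = 10), "h must be")
})

test_that("injury indentation deepens the wall conformingly", {
  mesh <- build_vessel_mesh(100, 50,
                            injury = list(center_x = 50, depth = 6, width = 20),
                            h = 2.5)
  expect_lt(min(mesh$nodes[, 2]), -5)     # pocket extends below y = 0
  expect_true(all(mesh$geom$area > 0))    # still a valid conforming mesh
})

test_that("Laplace indicator agrees with a point-in-polygon oracle up to one element layer", {
  mesh <- test_mesh()
  set.seed(42)
  worst <- 0
  for (k in 1:10) {
    a <- runif(1, 8, 16); b <- runif(1, 8, a); th <- runif(1, 0, pi)
    ctr <- c(runif(1, 30, 70), runif(1, 20, 30))
    poly <- ellipse_pts(a, b, center = ctr, theta = th, n = 200)
    ind <- mark_indicator(mesh, poly)
    # even-odd-rule oracle on the same nodes
    oracle <- ((cos(th) * (mesh$nodes[, 1] - ctr[1]) +
                  sin(th) * (mesh$nodes[, 2] - ctr[2])) / a)^2 +
      ((-sin(th) * (mesh$nodes[, 1] - ctr[1]) +
          cos(th) * (mesh$nodes[, 2] - ctr[2])) / b)^2 <= 1
    dis <- which(ind$member != oracle)
    if (length(dis)) {
      # signed distance of disagreeing nodes from the curve, via dense polygon
      dmin <- vapply(dis, function(i) min(sqrt((poly[, 1] - mesh$nodes[i, 1])^2 +
                                                 (poly[, 2] - mesh$nodes[i, 2])^2)),
                     numeric(1))
      worst <- max(worst, max(dmin))
    }
  }
  expect_lt(worst, sqrt(2) * mesh$h + 1e-9)   # one element layer
})

test_that("indicator marking is bounded by one outward element layer in area", {
  mesh <- test_mesh()
  ind <- mark_indicator(mesh, circle_pts(15, center = c(50, 25), n = 200))
  marked_area <- sum(clotflow:::lumped_areas(mesh)[ind$member])
  expect_gte(marked_area, pi * 15^2 * 0.98)
  expect_lte(marked_area, pi * (15 + sqrt(2) * mesh$h)^2)
})

test_that("outer-boundary Dirichlet wins where the clot hugs the wall", {
  mesh <- test_mesh()
  # circle overlapping the bottom wall
  ind <- mark_indicator(mesh, circle_pts(15, center = c(50, 10), n = 200))
  wall_nodes <- mesh$boundary_nodes$all
  expect_true(all(!ind$member[wall_nodes]))
  # interior of the overlap region is still marked
  inner <- which(abs(mesh$nodes[, 1] - 50) < 5 &
                   abs(mesh$nodes[, 2] - 12) < 3)
  expect_true(all(ind$member[inner]))
})

test_that("unresolvable boundary raises a refinement error", {
  mesh <- test_mesh()
  expect_error(mark_indicator(mesh, cbind(c(500, 501), c(500, 501))),
               "refine")
})

test_that("Kozeny-Carman permeability matches the algebraic law", {
  expect_equal(kozeny_carman(0), 0)
  expect_equal(kozeny_carman(0.2), 0.2^3 / (150 * 0.8^2))
  expect_equal(kozeny_carman(0.2), 8.333e-5, tolerance = 1e-3)
  expect_equal(kozeny_carman(0.5), 3.333e-3, tolerance = 1e-3)
  expect_error(kozeny_carman(1), "phi")
  # monotone increasing in phi
  phis <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(diff(kozeny_carman(phis)) > 0))
})

test_that("material fields assign the case-study values by region", {
  mesh <- test_mesh()
  x <- mesh$nodes[, 1]; y <- mesh$nodes[, 2]
  overall <- fake_indicator((x - 50)^2 + (y - 25)^2 <= 15^2)
  core <- fake_indicator((x - 50)^2 + (y - 25)^2 <= 8^2)
  wt <- assemble_material_fields(overall, core, wt_params())
  i_core <- which(core$member)[1]
  i_shell <- which(overall$member & !core$member)[1]
  i_free <- which(!overall$member)[1]
  expect_equal(wt$phi[i_core], 0.2);  expect_equal(wt$D[i_core], 0.4)
  expect_equal(wt$phi[i_shell], 0.3); expect_equal(wt$D[i_shell], 0.8)
  expect_equal(wt$phi[i_free], 1);    expect_equal(wt$D[i_free], 60)
  expect_true(is.infinite(wt$K[i_free]))
  expect_equal(wt$K[i_core], kozeny_carman(0.2) * 9)
  dy <- assemble_material_fields(overall, core, diyf_params())
  expect_equal(dy$phi[i_shell], 0.4); expect_equal(dy$D[i_shell], 1.0)
  expect_equal(dy$phi[i_core], 0.2);  expect_equal(dy$D[i_core], 0.5)
  # idempotent and piecewise constant per region
  wt2 <- assemble_material_fields(overall, core, wt_params())
  expect_identical(wt$phi, wt2$phi)
  expect_setequal(unique(wt$phi), c(0.2, 0.3, 1))
  # core membership is intersected with the overall membership
  stray <- fake_indicator(!overall$member)
  mixed <- assemble_material_fields(overall, stray, wt_params())
  expect_false(any(mixed$core))
  expect_error(material_params(D_core = 100), "D_core")
})
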