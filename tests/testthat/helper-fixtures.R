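# Shared fixtures: all synthetic, built in code at test time.

# Closed polyline of a circle / ellipse (n x 2, um).
circle_pts <- function(r = 20, center = c(0, 0), n = 200) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(center[1] + r * cos(th), center[2] + r * sin(th))
}

ellipse_pts <- function(a = 20, b = 10, center = c(0, 0), theta = 0, n = 200) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ex <- a * cos(th); ey <- b * sin(th)
  cbind(center[1] + ex * cos(theta) - ey * sin(theta),
        center[2] + ex * sin(theta) + ey * cos(theta))
}

# Small clot-like synthetic scene (defaults sized for fast tests).
test_scene <- function(n_frames = 3, base_axes = c(15, 10), growth_rate = 0.5,
                       shape = c(128, 128), seed = 1, center = c(32, 32),
                       intensity = list(), ...) {
  sched <- make_growth_schedule(max(2, n_frames), base_axes = base_axes,
                                growth_rate = growth_rate,
                                center = center, ...)
  synthetic_scene(
    image_shape = shape,
    schedule = sched[seq_len(n_frames), , drop = FALSE],
    core_scale = 0.5, pixel_size = 0.5, frame_interval = 0.55,
    intensity = intensity, seed = seed)
}

# Mid-size channel mesh reused across FEM tests.
test_mesh <- function(h = 2.5) build_vessel_mesh(100, 50, h = h)

# Indicator field with membership prescribed directly (bypasses the Laplace
# solve; for unit tests of downstream consumers).
fake_indicator <- function(member) {
  structure(list(I = as.numeric(member), member = member, eps = 1e-2),
            class = "indicator_field")
}

# Uniform synthetic flow state (u in um/s).
uniform_flow <- function(mesh, ux = 0, uy = 0, p = 0) {
  n <- nrow(mesh$nodes)
  structure(list(u = cbind(rep(ux, n), rep(uy, n)), p = rep(p, n), time = 0),
            class = "flow_state")
}
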