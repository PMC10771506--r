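# Stabilised finite-element Brinkman-Navier-Stokes solver on the fixed
# vessel mesh.
#
# Momentum:   rho (du/dt + u.grad u) = -grad p + mu lap u - (mu/K) u  in clot
# Continuity: div u = 0
# Equal-order P1-P1 elements with SUPG/PSPG stabilisation (tau from the
# classical inverse-estimate formula including transient, advective, viscous
# and Brinkman-reaction contributions; inside a low-permeability clot
# tau -> K/mu, which is the standard stabilised-Darcy limit). Backward Euler
# in time, convection linearised by Picard iteration. Internal unit system is
# SI; the mesh (um) is converted on entry and velocities are reported back in
# um/s, pressures in Pa.

#' Flow solver configuration
#'
#' Defaults carry the hemodynamic case-study values: blood density 1.06 g/cc,
#' dynamic viscosity 4.0 cP, and peak (centerline) inflow velocity 1300 um/s
#' imposed as a parabolic profile at the inlet.
#'
#' @param rho_g_cc fluid density, g/cc.
#' @param mu_cP dynamic viscosity, centipoise.
#' @param U_peak_um_s peak inlet velocity, um/s.
#' @param dt time step, s (frame interval / n_sub in the coupled pipeline).
#' @param picard_tol relative nonlinear convergence tolerance.
#' @param max_picard maximum Picard iterations per step.
#' @param pulsatile_amplitude optional sinusoidal inflow modulation amplitude
#'   (fraction of U_peak; 0 = steady inflow as measured).
#' @param pulsatile_period modulation period, s.
#' @export
flow_config <- function(rho_g_cc = 1.06, mu_cP = 4.0, U_peak_um_s = 1300,
                        dt = 0.05, picard_tol = 1e-6, max_picard = 25,
                        pulsatile_amplitude = 0, pulsatile_period = 0.1) {
  stopifnot(rho_g_cc > 0, mu_cP > 0, U_peak_um_s >= 0, dt > 0)
  structure(list(rho = rho_g_cc * 1000,        # kg/m^3
                 mu = mu_cP * 1e-3,            # Pa s
                 U_peak = U_peak_um_s * 1e-6,  # m/s
                 dt = dt, picard_tol = picard_tol, max_picard = max_picard,
                 pulsatile_amplitude = pulsatile_amplitude,
                 pulsatile_period = pulsatile_period),
            class = "flow_config")
}

# SI element geometry for a um mesh (cached on first use).
si_geometry <- function(mesh) {
  if (!is.null(mesh$geom_si)) return(mesh$geom_si)
  g <- mesh$geom
  list(area = g$area * 1e-12, gx = g$gx * 1e6, gy = g$gy * 1e6,
       h = g$h * 1e-6)
}

# Element-mean Brinkman drag coefficient mu/K (Pa s / m^2); 0 outside clot.
element_sigma <- function(mesh, materials, mu) {
  if (is.null(materials)) return(numeric(nrow(mesh$tri)))
  sig_nodal <- ifelse(is.finite(materials$K), mu / (materials$K * 1e-12), 0)
  if (any(materials$K <= 0 & is.finite(materials$K)))
    stop("non-positive permeability inside clot")
  (sig_nodal[mesh$tri[, 1]] + sig_nodal[mesh$tri[, 2]] +
     sig_nodal[mesh$tri[, 3]]) / 3
}

# Parabolic inlet profile (m/s) on inlet nodes; y in meters.
inlet_profile <- function(mesh, U_peak) {
  nodes <- mesh$boundary_nodes$inlet
  y <- mesh$nodes[nodes, 2] * 1e-6
  d <- mesh$diameter * 1e-6
  list(nodes = nodes, u = U_peak * (1 - (2 * y / d - 1)^2))
}

#' One implicit step (or steady solve) of Brinkman-Navier-Stokes flow
#'
#' @param mesh `vessel_mesh` (um coordinates).
#' @param materials `material_fields` or NULL (no clot anywhere).
#' @param config [flow_config()].
#' @param u_prev previous `flow_state` (NULL starts from rest).
#' @param steady if TRUE the transient term is dropped and the solve iterates
#'   straight to the steady state.
#' @param time physical time, s (used for the optional pulsatile inflow).
#' @return object of class `"flow_state"`: nodal `u` (n x 2, um/s), `p` (Pa),
#'   `time`, and the Picard residual history.
#' @export
solve_flow_step <- function(mesh, materials = NULL, config = flow_config(),
                            u_prev = NULL, steady = FALSE, time = 0) {
  n <- nrow(mesh$nodes)
  g <- si_geometry(mesh)
  tri <- mesh$tri
  m <- nrow(tri)
  rho <- config$rho; mu <- config$mu
  inv_dt <- if (steady) 0 else 1 / config$dt
  sig <- element_sigma(mesh, materials, mu)
  Upk <- config$U_peak
  if (config$pulsatile_amplitude > 0)
    Upk <- Upk * (1 + config$pulsatile_amplitude *
                    sin(2 * pi * time / config$pulsatile_period))
  u_n <- if (is.null(u_prev)) matrix(0, n, 2) else u_prev$u * 1e-6
  u_k <- u_n
  # Dirichlet sets
  inl <- inlet_profile(mesh, Upk)
  wall <- setdiff(mesh$boundary_nodes$wall,
                  c(mesh$boundary_nodes$inlet, mesh$boundary_nodes$outlet))
  fixed <- c(inl$nodes, n + inl$nodes, wall, n + wall)
  fvals <- c(inl$u, rep(0, length(inl$nodes)), rep(0, 2 * length(wall)))
  resid_hist <- numeric(0)
  for (iter in seq_len(config$max_picard)) {
    a1 <- (u_k[tri[, 1], 1] + u_k[tri[, 2], 1] + u_k[tri[, 3], 1]) / 3
    a2 <- (u_k[tri[, 1], 2] + u_k[tri[, 2], 2] + u_k[tri[, 3], 2]) / 3
    amag <- sqrt(a1^2 + a2^2)
    tau <- 1 / sqrt((2 * rho * inv_dt)^2 + (2 * rho * amag / g$h)^2 +
                      (4 * mu / g$h^2)^2 + sig^2)
    react <- sig + rho * inv_dt            # mass-type reaction coefficient
    A <- g$area
    nent <- 9 * m * 7
    ii <- jj <- integer(nent); xx <- numeric(nent)
    ptr <- 0
    add <- function(i, j, v) {
      r <- ptr + seq_len(m)
      ii[r] <<- i; jj[r] <<- j; xx[r] <<- v
      ptr <<- ptr + m
    }
    # transient RHS as an operator applied to [u1_n; u2_n; .]
    ri <- rj <- integer(9 * m * 4); rx <- numeric(9 * m * 4)
    rptr <- 0
    radd <- function(i, j, v) {
      r <- rptr + seq_len(m)
      ri[r] <<- i; rj[r] <<- j; rx[r] <<- v
      rptr <<- rptr + m
    }
    for (a in 1:3) {
      ga_x <- g$gx[, a]; ga_y <- g$gy[, a]
      adv_i <- a1 * ga_x + a2 * ga_y       # a . grad(lambda_a)
      na <- tri[, a]
      for (b in 1:3) {
        gb_x <- g$gx[, b]; gb_y <- g$gy[, b]
        adv_j <- a1 * gb_x + a2 * gb_y
        nb <- tri[, b]
        mab <- A * (if (a == b) 1 / 6 else 1 / 12)
        visc <- mu * A * (ga_x * gb_x + ga_y * gb_y)
        conv <- rho * adv_j * A / 3
        supg_uu <- tau * A * rho * adv_i * (rho * adv_j + react / 3)
        k_uu <- visc + conv + react * mab + supg_uu
        add(na, nb, k_uu)                  # u1-u1
        add(n + na, n + nb, k_uu)          # u2-u2
        # momentum-pressure: -p div v (+ SUPG pressure part)
        add(na, 2 * n + nb, -ga_x * A / 3 + tau * A * rho * adv_i * gb_x)
        add(n + na, 2 * n + nb, -ga_y * A / 3 + tau * A * rho * adv_i * gb_y)
        # continuity + PSPG
        add(2 * n + na, nb,
            gb_x * A / 3 + (tau / rho) * A * ga_x * (rho * adv_j + react / 3))
        add(2 * n + na, n + nb,
            gb_y * A / 3 + (tau / rho) * A * ga_y * (rho * adv_j + react / 3))
        add(2 * n + na, 2 * n + nb, (tau / rho) * A * (ga_x * gb_x + ga_y * gb_y))
        if (inv_dt > 0) {
          # Galerkin transient (consistent mass) + SUPG/PSPG transient parts
          tm <- rho * inv_dt * mab
          s1 <- tau * A * rho * adv_i * rho * inv_dt / 3
          radd(na, nb, tm + s1)
          radd(n + na, n + nb, tm + s1)
          radd(2 * n + na, nb, tau * A * inv_dt * ga_x / 3)
          radd(2 * n + na, n + nb, tau * A * inv_dt * ga_y / 3)
        }
      }
    }
    Amat <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(3 * n, 3 * n))
    rhs <- if (inv_dt > 0) {
      B <- Matrix::sparseMatrix(i = ri[seq_len(rptr)], j = rj[seq_len(rptr)],
                                x = rx[seq_len(rptr)], dims = c(3 * n, 3 * n))
      as.numeric(B %*% c(u_n[, 1], u_n[, 2], numeric(n)))
    } else numeric(3 * n)
    sol <- solve_with_dirichlet(Amat, rhs, fixed, fvals)
    u_new <- cbind(sol[1:n], sol[(n + 1):(2 * n)])
    p_new <- sol[(2 * n + 1):(3 * n)]
    du <- sqrt(sum((u_new - u_k)^2))
    nu <- sqrt(sum(u_new^2))
    resid <- if (nu > 0) du / nu else du
    resid_hist <- c(resid_hist, resid)
    u_k <- u_new
    if (resid < config$picard_tol) break
  }
  if (resid_hist[length(resid_hist)] > sqrt(config$picard_tol))
    if (length(resid_hist) >= config$max_picard &&
        resid_hist[length(resid_hist)] > 1e-3)
      stop("nonlinear iteration diverged; residual history: ",
           paste(signif(resid_hist, 3), collapse = " "))
  structure(list(u = u_k * 1e6, p = p_new,
                 time = if (steady) time else time + config$dt,
                 picard_residuals = resid_hist),
            class = "flow_state")
}

#' @export
print.flow_state <- function(x, ...) {
  sp <- sqrt(rowSums(x$u^2))
  cat(sprintf("Flow state at t = %.3g s: max |u| = %.4g um/s, p range [%.3g, %.3g] Pa (%d Picard its)\n",
              x$time, max(sp), min(x$p), max(x$p), length(x$picard_residuals)))
  invisible(x)
}

# Element-wise weak divergence residual (um/s per um); diagnostic.
flow_divergence <- function(mesh, flow) {
  g <- mesh$geom
  tri <- mesh$tri
  rowSums(sapply(1:3, function(a)
    g$gx[, a] * flow$u[tri[, a], 1] + g$gy[, a] * flow$u[tri[, a], 2]))
}
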