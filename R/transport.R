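# Stabilised advection-diffusion solute (caged-albumin) transport on the
# fixed mesh:  phi dc/dt + u . grad c = div( phi D grad c ),
# with porosity-weighted storage and diffusion. Streamline-upwind (SUPG)
# stabilisation plus continuous-interior-penalty (CIP) stabilisation of
# inter-element gradient jumps handles advection-dominated transport in the
# free lumen. Units: um and s throughout (no conversion needed).

#' Transport solver configuration
#'
#' @param dt time step, s.
#' @param cip_coef coefficient of the interior gradient-jump penalty.
#' @param inlet_bc `"zero"` (Dirichlet c = 0 at the inlet, advective outflow
#'   at the outlet) or `"closed"` (no Dirichlet anywhere: pure no-flux
#'   boundaries, used for conservation checks).
#' @param overshoot_tol allowed under/overshoot delta beyond [0, 1] before a
#'   cell-Peclet warning is raised.
#' @export
transport_config <- function(dt = 0.05, cip_coef = 0.01, inlet_bc = "zero",
                             overshoot_tol = 0.05, lump_mass = TRUE) {
  stopifnot(dt > 0, cip_coef >= 0)
  structure(list(dt = dt, cip_coef = cip_coef, inlet_bc = inlet_bc,
                 overshoot_tol = overshoot_tol, lump_mass = lump_mass),
            class = "transport_config")
}

# Interior edge table: nodes, adjacent triangles, length, unit normal.
interior_edges <- function(mesh) {
  if (!is.null(mesh$edges_cache)) return(mesh$edges_cache)
  tri <- mesh$tri
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(3, 1)])
  tid <- rep(seq_len(nrow(tri)), 3)
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  sp <- split(seq_along(key), key)
  int <- sp[lengths(sp) == 2]
  n1 <- integer(length(int)); n2 <- integer(length(int))
  t1 <- integer(length(int)); t2 <- integer(length(int))
  for (k in seq_along(int)) {
    r <- int[[k]]
    n1[k] <- pmin(e[r[1], 1], e[r[1], 2])
    n2[k] <- pmax(e[r[1], 1], e[r[1], 2])
    t1[k] <- tid[r[1]]; t2[k] <- tid[r[2]]
  }
  dx <- mesh$nodes[n2, 1] - mesh$nodes[n1, 1]
  dy <- mesh$nodes[n2, 2] - mesh$nodes[n1, 2]
  len <- sqrt(dx^2 + dy^2)
  list(n1 = n1, n2 = n2, t1 = t1, t2 = t2, len = len,
       nx = dy / len, ny = -dx / len)
}

# CIP penalty matrix: gamma * sum_F h_F^2 |u_F| len_F [dn c][dn v].
cip_matrix <- function(mesh, u_elem, gamma) {
  ed <- interior_edges(mesh)
  g <- mesh$geom
  tri <- mesh$tri
  nn <- nrow(mesh$nodes)
  nf <- length(ed$n1)
  umag <- sqrt(rowSums(u_elem^2))
  uf <- (umag[ed$t1] + umag[ed$t2]) / 2
  w <- gamma * ed$len^3 * uf
  # normal-gradient jump rows (nf x 6): +grad from t1, -grad from t2
  jr <- cbind(g$gx[ed$t1, ] * ed$nx + g$gy[ed$t1, ] * ed$ny,
              -(g$gx[ed$t2, ] * ed$nx + g$gy[ed$t2, ] * ed$ny))
  nodes <- cbind(tri[ed$t1, ], tri[ed$t2, ])
  ii <- jj <- integer(36 * nf); xx <- numeric(36 * nf)
  k <- 0
  for (a in 1:6) for (b in 1:6) {
    r <- k * nf + seq_len(nf)
    ii[r] <- nodes[, a]; jj[r] <- nodes[, b]
    xx[r] <- w * jr[, a] * jr[, b]
    k <- k + 1
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(nn, nn))
}

#' Initialize a solute uncaging pulse over the clot
#'
#' Sets the normalized concentration to 1 on every clot-member node and 0
#' elsewhere, emulating a light pulse that uncages the caged albumin
#' throughout the clot; call again at each subsequent pulse.
#'
#' @param mesh `vessel_mesh`.
#' @param indicator overall-clot `indicator_field`.
#' @return object of class `"transport_state"` (nodal `c`, `time`).
#' @export
init_uncaging <- function(mesh, indicator, time = 0) {
  if (!any(indicator$member)) stop("empty clot: nothing to uncage")
  structure(list(c = as.numeric(indicator$member), time = time),
            class = "transport_state")
}

#' One implicit step of stabilised solute transport
#'
#' @param mesh `vessel_mesh`.
#' @param materials `material_fields` (porosity and hindered diffusivity).
#' @param flow `flow_state` at the matching time (velocity in um/s); NULL
#'   means quiescent fluid.
#' @param c_prev `transport_state` (or numeric nodal vector).
#' @param config [transport_config()].
#' @return `transport_state` at time + dt.
#' @export
solve_transport_step <- function(mesh, materials, flow = NULL, c_prev,
                                 config = transport_config()) {
  n <- nrow(mesh$nodes)
  g <- mesh$geom
  tri <- mesh$tri
  m <- nrow(tri)
  c0 <- if (inherits(c_prev, "transport_state")) c_prev$c else as.numeric(c_prev)
  t0 <- if (inherits(c_prev, "transport_state")) c_prev$time else 0
  dt <- config$dt
  phi_e <- (materials$phi[tri[, 1]] + materials$phi[tri[, 2]] +
              materials$phi[tri[, 3]]) / 3
  phid_n <- materials$phi * materials$D
  phid_e <- (phid_n[tri[, 1]] + phid_n[tri[, 2]] + phid_n[tri[, 3]]) / 3
  u_e <- if (is.null(flow)) matrix(0, m, 2) else
    cbind((flow$u[tri[, 1], 1] + flow$u[tri[, 2], 1] + flow$u[tri[, 3], 1]) / 3,
          (flow$u[tri[, 1], 2] + flow$u[tri[, 2], 2] + flow$u[tri[, 3], 2]) / 3)
  umag <- sqrt(rowSums(u_e^2))
  tau <- 1 / sqrt((2 * phi_e / dt)^2 + (2 * umag / g$h)^2 +
                    (4 * phid_e / g$h^2)^2)
  A <- g$area
  ii <- jj <- integer(9 * m); xa <- xr <- numeric(9 * m)
  k <- 0
  for (a in 1:3) {
    adv_i <- u_e[, 1] * g$gx[, a] + u_e[, 2] * g$gy[, a]
    na <- tri[, a]
    for (b in 1:3) {
      adv_j <- u_e[, 1] * g$gx[, b] + u_e[, 2] * g$gy[, b]
      nb <- tri[, b]
      mab <- if (config$lump_mass) A * (if (a == b) 1 / 3 else 0)
             else A * (if (a == b) 1 / 6 else 1 / 12)
      r <- k * m + seq_len(m)
      ii[r] <- na; jj[r] <- nb
      # SUPG: residual has consistent (interpolated) storage regardless of
      # the lumping choice for the Galerkin storage term
      xa[r] <- (phi_e / dt) * mab +
        adv_j * A / 3 +
        phid_e * A * (g$gx[, a] * g$gx[, b] + g$gy[, a] * g$gy[, b]) +
        tau * A * adv_i * (adv_j + phi_e / (3 * dt))
      xr[r] <- (phi_e / dt) * mab + tau * A * adv_i * phi_e / (3 * dt)
      k <- k + 1
    }
  }
  Amat <- Matrix::sparseMatrix(i = ii, j = jj, x = xa, dims = c(n, n))
  rhs <- as.numeric(Matrix::sparseMatrix(i = ii, j = jj, x = xr,
                                         dims = c(n, n)) %*% c0)
  if (config$cip_coef > 0 && any(umag > 0))
    Amat <- Amat + cip_matrix(mesh, u_e, config$cip_coef)
  if (identical(config$inlet_bc, "zero")) {
    fixed <- mesh$boundary_nodes$inlet
    cnew <- solve_with_dirichlet(Amat, rhs, fixed, rep(0, length(fixed)))
  } else cnew <- as.numeric(Matrix::solve(Amat, rhs))
  del <- config$overshoot_tol
  if (min(cnew) < -del || max(cnew) > 1 + del) {
    pe <- umag * mesh$geom$h / pmax(2 * phid_e, 1e-300)
    warning(sprintf(
      "concentration overshoot beyond [%g, %g]: range [%.3g, %.3g]; max cell Peclet %.3g",
      -del, 1 + del, min(cnew), max(cnew), max(pe)))
  }
  structure(list(c = cnew, time = t0 + dt), class = "transport_state")
}

#' @export
print.transport_state <- function(x, ...) {
  cat(sprintf("Transport state at t = %.3g s: c range [%.3g, %.3g]\n",
              x$time, min(x$c), max(x$c)))
  invisible(x)
}

# Total porosity-weighted solute mass (um^2 of normalized concentration),
# using the same element-mean-porosity consistent mass functional the solver
# conserves in the closed-boundary case.
transport_mass <- function(mesh, materials, state, lump = TRUE) {
  tri <- mesh$tri
  phi_e <- (materials$phi[tri[, 1]] + materials$phi[tri[, 2]] +
              materials$phi[tri[, 3]]) / 3
  cc <- if (inherits(state, "transport_state")) state$c else as.numeric(state)
  if (lump) {
    w <- rep(phi_e * mesh$geom$area / 3, 3)
    agg <- tapply(w, as.vector(tri), sum)
    ml <- numeric(nrow(mesh$nodes))
    ml[as.integer(names(agg))] <- agg
    sum(ml * cc)
  } else sum(mass_matrix(mesh, phi_e) %*% cc)
}
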