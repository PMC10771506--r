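# Fictitious-domain marking of the moving clot on the fixed mesh: a Laplace
# indicator (point-set) solve per region per sub-step, then region-wise
# porosity, hindered diffusivity and Kozeny-Carman permeability fields.

# Assemble the P1 stiffness matrix (optionally with element-wise coefficient).
stiffness_matrix <- function(mesh, coef = 1) {
  g <- mesh$geom
  m <- nrow(mesh$tri)
  coef <- rep_len(coef, m)
  ii <- jj <- integer(9 * m); xx <- numeric(9 * m)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    r <- k * m + seq_len(m)
    ii[r] <- mesh$tri[, a]
    jj[r] <- mesh$tri[, b]
    xx[r] <- coef * g$area * (g$gx[, a] * g$gx[, b] + g$gy[, a] * g$gy[, b])
    k <- k + 1
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = rep(nrow(mesh$nodes), 2))
}

# Consistent P1 mass matrix with element-wise coefficient.
mass_matrix <- function(mesh, coef = 1) {
  g <- mesh$geom
  m <- nrow(mesh$tri)
  coef <- rep_len(coef, m)
  ii <- jj <- integer(9 * m); xx <- numeric(9 * m)
  k <- 0
  for (a in 1:3) for (b in 1:3) {
    r <- k * m + seq_len(m)
    ii[r] <- mesh$tri[, a]
    jj[r] <- mesh$tri[, b]
    xx[r] <- coef * g$area * (if (a == b) 1 / 6 else 1 / 12)
    k <- k + 1
  }
  Matrix::sparseMatrix(i = ii, j = jj, x = xx,
                       dims = rep(nrow(mesh$nodes), 2))
}

# Solve a linear system with Dirichlet constraints imposed by row replacement.
solve_with_dirichlet <- function(A, rhs, fixed_idx, fixed_val) {
  n <- nrow(A)
  if (length(fixed_idx)) {
    rhs <- rhs - A[, fixed_idx, drop = FALSE] %*% fixed_val
    free <- setdiff(seq_len(n), fixed_idx)
    x <- numeric(n)
    x[fixed_idx] <- fixed_val
    x[free] <- as.numeric(Matrix::solve(A[free, free, drop = FALSE], rhs[free]))
    x
  } else as.numeric(Matrix::solve(A, rhs))
}

#' Mark clot-interior nodes with a Laplace indicator solve
#'
#' Point-set front marking: solves the Laplace equation for an indicator I on
#' the fixed mesh with I = 1 on every node of an element that contains a point
#' of the (densely sampled) clot boundary curve, and I = 0 on the outer domain
#' boundary (which wins where the clot hugs the wall). By the discrete maximum
#' principle, nodes enclosed by the I = 1 ring take I close to 1; membership
#' is `I >= 1 - eps`.
#'
#' @param mesh `vessel_mesh`.
#' @param boundary `spline_boundary`, `angular_samples`, or an n x 2 matrix of
#'   boundary points (um).
#' @param eps threshold parameter (small positive number).
#' @return object of class `"indicator_field"`: nodal `I`, logical `member`,
#'   and `eps`.
#' @export
mark_indicator <- function(mesh, boundary, eps = 1e-2) {
  pts <- if (inherits(boundary, "spline_boundary")) {
    spline_polygon(boundary, max(720, round(4 * spline_length(boundary) / mesh$h)))
  } else if (inherits(boundary, "angular_samples")) boundary$points
  else as.matrix(boundary)
  loc <- locate_points(mesh, pts)
  miss <- is.na(loc)
  if (any(miss)) {
    # a clot reaching past the vessel wall: clamp its out-of-domain boundary
    # points onto the wall so the I = 1 ring closes along the first interior
    # element layer (the wall nodes themselves stay at the Dirichlet zero)
    clamped <- pts[miss, , drop = FALSE]
    clamped[, 1] <- pmin(pmax(clamped[, 1], 0), mesh$length)
    clamped[, 2] <- pmin(pmax(clamped[, 2], min(mesh$nodes[, 2])),
                         mesh$diameter)
    shift <- sqrt(rowSums((clamped - pts[miss, , drop = FALSE])^2))
    near <- shift <= 2 * mesh$h   # beyond that it is a unit/geometry mismatch
    if (any(near)) {
      idx <- which(miss)[near]
      loc[idx] <- locate_points(mesh, clamped[near, , drop = FALSE])
    }
  }
  inside <- !is.na(loc)
  if (!any(inside))
    stop("no element contains any boundary point; refine the mesh or check units")
  ring_nodes <- unique(as.vector(mesh$tri[loc[inside], ]))
  outer_nodes <- mesh$boundary_nodes$all
  ring_nodes <- setdiff(ring_nodes, outer_nodes)  # Dirichlet I = 0 wins
  K <- stiffness_matrix(mesh)
  fixed <- c(outer_nodes, ring_nodes)
  vals <- c(rep(0, length(outer_nodes)), rep(1, length(ring_nodes)))
  I <- solve_with_dirichlet(K, numeric(nrow(mesh$nodes)), fixed, vals)
  structure(list(I = I, member = I >= 1 - eps, eps = eps,
                 boundary_points = pts),
            class = "indicator_field")
}

#' @export
print.indicator_field <- function(x, ...) {
  cat(sprintf("Indicator field: %d member nodes of %d (eps = %g)\n",
              sum(x$member), length(x$member), x$eps))
  invisible(x)
}

#' Kozeny-Carman permeability from porosity
#'
#' The classical porosity-permeability law `K = phi^3 / (150 (1 - phi)^2)`
#' (dimensionless as written; multiply by a squared reference grain length to
#' dimensionalise, see [assemble_material_fields()]).
#'
#' @param phi porosity in `[0, 1)`; `phi = 1` is an error because the free
#'   (non-porous) domain must bypass the Brinkman drag term entirely rather
#'   than use a permeability.
#' @return permeability, dimensionless.
#' @export
kozeny_carman <- function(phi) {
  if (any(phi < 0) || any(phi >= 1))
    stop("phi must be in [0, 1); the free domain bypasses the Brinkman term")
  phi^3 / (150 * (1 - phi)^2)
}

#' Material parameter sets
#'
#' Region-wise porosity and effective (hindered) diffusivity for the clot
#' core and shell, the free-plasma diffusivity, and the reference grain length
#' that dimensionalises the Kozeny-Carman permeability. The two presets carry
#' the wild-type and diYF-knockout values used in the simulation case studies.
#'
#' @param phi_core,phi_shell porosities (dimensionless).
#' @param D_free free-plasma diffusivity, um^2/s.
#' @param D_shell,D_core hindered diffusivities, um^2/s.
#' @param L_ref reference grain (platelet) length scale, um.
#' @export
material_params <- function(phi_core = 0.2, phi_shell = 0.3, D_free = 60,
                            D_shell = 0.8, D_core = 0.4, L_ref = 3) {
  if (D_core > D_free) stop("D_core must not exceed D_free")
  if (!(D_core <= D_shell && D_shell <= D_free))
    stop("need D_core <= D_shell <= D_free")
  stopifnot(phi_core > 0, phi_core < 1, phi_shell > 0, phi_shell < 1,
            L_ref > 0)
  structure(list(phi_core = phi_core, phi_shell = phi_shell, D_free = D_free,
                 D_shell = D_shell, D_core = D_core, L_ref = L_ref),
            class = "material_params")
}

#' @rdname material_params
#' @export
wt_params <- function() material_params(phi_core = 0.2, phi_shell = 0.3,
                                        D_free = 60, D_shell = 0.8,
                                        D_core = 0.4)

#' @rdname material_params
#' @export
diyf_params <- function() material_params(phi_core = 0.2, phi_shell = 0.4,
                                          D_free = 60, D_shell = 1.0,
                                          D_core = 0.5)

#' Assemble nodal porosity, diffusivity and permeability fields
#'
#' Region precedence is core over shell over free plasma: the shell is the
#' overall clot membership minus the core membership (set difference), and
#' the core membership is intersected with the overall one. Outside the clot
#' phi = 1, D = D_free and the Brinkman drag is disabled (K = Inf).
#' Inside, K = kozeny_carman(phi) * L_ref^2 (um^2).
#'
#' @param overall,core `indicator_field`s (core may be NULL: whole clot
#'   treated as shell).
#' @param params [material_params()].
#' @return object of class `"material_fields"` with nodal vectors `phi`, `D`
#'   (um^2/s), `K` (um^2, Inf outside the clot) and logical `core`, `shell`,
#'   `clot` memberships.
#' @export
assemble_material_fields <- function(overall, core = NULL,
                                     params = material_params()) {
  clot <- overall$member
  core_m <- if (is.null(core)) rep(FALSE, length(clot)) else core$member & clot
  shell_m <- clot & !core_m
  phi <- rep(1, length(clot))
  phi[shell_m] <- params$phi_shell
  phi[core_m] <- params$phi_core
  D <- rep(params$D_free, length(clot))
  D[shell_m] <- params$D_shell
  D[core_m] <- params$D_core
  K <- rep(Inf, length(clot))
  K[clot] <- kozeny_carman(phi[clot]) * params$L_ref^2
  structure(list(phi = phi, D = D, K = K, clot = clot, core = core_m,
                 shell = shell_m, params = params),
            class = "material_fields")
}
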