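# Post-processing of the coupled simulation into the headline quantities:
# boundary traction loading, caged-albumin decay, Reynolds number, the
# force-volume phase portrait with embolization detection, and the
# Latin-hypercube sensitivity sweep of the segmentation parameters.

#' Flow-induced traction loading on the clot boundary
#'
#' Integrates the fluid stress over the (closed) clot boundary:
#' `F = integral of sigma . n ds` with `sigma = -p I + mu (grad u + grad u^T)`,
#' outward normal convention. The pressure part `-integral p n ds` and the
#' viscous (shear) part are reported separately; velocity gradients at the
#' boundary quadrature points are the constant P1 gradients of the containing
#' triangle. Forces are per unit out-of-plane depth, reported in nN/um.
#'
#' @param flow `flow_state` (u in um/s, p in Pa).
#' @param boundary `angular_samples`, `spline_boundary`, or n x 2 point matrix
#'   (um) forming a closed loop.
#' @param mesh `vessel_mesh`.
#' @param mu_cP dynamic viscosity in cP.
#' @return list with `pressure_force`, `shear_force`, `total_force` (2-vectors,
#'   nN/um), their magnitudes, and `time`.
#' @export
boundary_traction <- function(flow, boundary, mesh, mu_cP = 4.0) {
  pts <- if (inherits(boundary, "angular_samples")) boundary$points
  else if (inherits(boundary, "spline_boundary")) spline_polygon(boundary, 360)
  else as.matrix(boundary)
  mu <- mu_cP * 1e-3                       # Pa s
  nq <- nrow(pts)
  nxt <- c(2:nq, 1); prv <- c(nq, 1:(nq - 1))
  # segment midpoint quadrature: ds and outward normal per vertex (trapezoid)
  tx <- pts[nxt, 1] - pts[prv, 1]
  ty <- pts[nxt, 2] - pts[prv, 2]
  ds <- sqrt(tx^2 + ty^2) / 2              # um
  nx <- ty / (2 * ds); ny <- -tx / (2 * ds)
  ctr <- colMeans(pts)
  flip <- sum(nx * (pts[, 1] - ctr[1]) + ny * (pts[, 2] - ctr[2])) < 0
  if (flip) { nx <- -nx; ny <- -ny }
  loc <- locate_points(mesh, pts)
  if (any(is.na(loc))) stop("boundary point outside the mesh")
  lam <- bary_coords(mesh, pts, loc)
  tri <- mesh$tri[loc, , drop = FALSE]
  p_q <- rowSums(lam * cbind(flow$p[tri[, 1]], flow$p[tri[, 2]],
                             flow$p[tri[, 3]]))
  g <- mesh$geom
  dux <- duy <- dvx <- dvy <- numeric(nq)  # 1/s (um/s per um)
  for (a in 1:3) {
    dux <- dux + g$gx[loc, a] * flow$u[tri[, a], 1]
    duy <- duy + g$gy[loc, a] * flow$u[tri[, a], 1]
    dvx <- dvx + g$gx[loc, a] * flow$u[tri[, a], 2]
    dvy <- dvy + g$gy[loc, a] * flow$u[tri[, a], 2]
  }
  # viscous stress mu (grad u + grad u^T), Pa
  sxx <- 2 * mu * dux; syy <- 2 * mu * dvy; sxy <- mu * (duy + dvx)
  to_nN_um <- 1e-3                         # Pa*um -> nN/um
  fp <- c(-sum(p_q * nx * ds), -sum(p_q * ny * ds)) * to_nN_um
  fv <- c(sum((sxx * nx + sxy * ny) * ds),
          sum((sxy * nx + syy * ny) * ds)) * to_nN_um
  list(pressure_force = fp, shear_force = fv, total_force = fp + fv,
       pressure_mag = sqrt(sum(fp^2)), shear_mag = sqrt(sum(fv^2)),
       total_mag = sqrt(sum((fp + fv)^2)),
       sum_of_mags = sqrt(sum(fp^2)) + sqrt(sum(fv^2)),
       time = flow$time)
}

#' Loading time series from simulation checkpoints
#'
#' @param checkpoints list with elements `flow` and `boundary` per time.
#' @param mesh `vessel_mesh`. @param mu_cP viscosity, cP.
#' @return data.frame of class `"loading_series"`.
#' @export
loading_series <- function(checkpoints, mesh, mu_cP = 4.0) {
  rows <- lapply(checkpoints, function(ck) {
    tr <- boundary_traction(ck$flow, ck$boundary, mesh, mu_cP)
    data.frame(time = tr$time,
               Fp_x = tr$pressure_force[1], Fp_y = tr$pressure_force[2],
               Fs_x = tr$shear_force[1], Fs_y = tr$shear_force[2],
               pressure_mag = tr$pressure_mag, shear_mag = tr$shear_mag,
               total_mag = tr$total_mag, sum_of_mags = tr$sum_of_mags)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("loading_series", "data.frame")
  out
}

#' Volume-averaged solute decay curves
#'
#' Porosity-weighted (lumped-area) average of the normalized concentration
#' over the member nodes of the requested region, normalized to the value at
#' the pulse time.
#'
#' @param states list of `transport_state` covering one inter-pulse interval.
#' @param mesh `vessel_mesh`.
#' @param materials `material_fields` (or a list, one per state, for a moving
#'   clot).
#' @param region `"clot"`, `"core"` or `"shell"`.
#' @return data.frame (time, value, region) of class `"decay_curve"`.
#' @export
calb_decay_curve <- function(states, mesh, materials, region = "clot") {
  ml <- lumped_areas(mesh)
  per_state <- !inherits(materials, "material_fields")
  val <- vapply(seq_along(states), function(i) {
    mat <- if (per_state) materials[[i]] else materials
    memb <- switch(region, clot = mat$clot, core = mat$core,
                   shell = mat$shell, stop("unknown region: ", region))
    if (!any(memb)) stop("empty region: ", region)
    w <- ml[memb] * mat$phi[memb]
    sum(w * states[[i]]$c[memb]) / sum(w)
  }, numeric(1))
  times <- vapply(states, function(s) s$time, numeric(1))
  out <- data.frame(time = times - times[1], value = val / val[1],
                    region = region)
  class(out) <- c("decay_curve", "data.frame")
  out
}

#' Reynolds number of the vessel flow
#'
#' `Re = rho U_mean d / mu` with `U_mean = U_peak / 2` (the mean-to-peak
#' factor of a parabolic tube profile).
#'
#' @param config [flow_config()].
#' @param d_vessel_um vessel diameter, um.
#' @export
reynolds_number <- function(config = flow_config(), d_vessel_um = 50) {
  stopifnot(d_vessel_um > 0)
  config$rho * (config$U_peak / 2) * (d_vessel_um * 1e-6) / config$mu
}

#' Force-volume phase portrait with embolization detection
#'
#' Pairs the total flow-induced loading with the clot area at each checkpoint.
#' Embolization appears as a sharp sustained area drop after the running force
#' maximum: the detector finds the first run of `persist` consecutive
#' checkpoints with negative smoothed d(area)/dt occurring at or after the
#' running force maximum, and places the embolization index at the steepest
#' single-step area drop within that run.
#'
#' @param kin `kinematics_series`.
#' @param load `loading_series` on the same time grid.
#' @param persist consecutive negative-rate checkpoints required.
#' @param smooth_window smoothing window for the area-rate series.
#' @return object of class `"phase_portrait"`: data.frame `points` (time,
#'   force, area), `embolization_index` (NA if none), and `bounding_box`.
#' @export
build_phase_portrait <- function(kin, load, persist = 3, smooth_window = 5) {
  if (nrow(kin) != nrow(load) || max(abs(kin$time - load$time)) > 1e-9)
    stop("kinematics and loading series are not on the same time grid")
  n <- nrow(kin)
  force <- load$total_mag
  rate <- central_diff(moving_average(kin$area, smooth_window), kin$time)
  neg <- rate < 0
  runlen <- rle(neg)
  emb <- NA_integer_
  pos <- 1
  for (k in seq_along(runlen$lengths)) {
    if (runlen$values[k] && runlen$lengths[k] >= persist) {
      i0 <- pos; i1 <- pos + runlen$lengths[k] - 1
      # the drop must follow the running force maximum; rate smoothing can
      # shift the run start earlier by up to the smoothing half-width
      if (which.max(force[1:i1]) >= i0 - smooth_window) {
        darea <- c(0, diff(kin$area))
        emb <- (i0:i1)[which.min(darea[i0:i1])]
        break
      }
    }
    pos <- pos + runlen$lengths[k]
  }
  bb <- if (!is.na(emb))
    list(force = range(force[1:emb]), area = range(kin$area[1:emb]))
  else list(force = range(force), area = range(kin$area))
  structure(list(points = data.frame(time = kin$time, force = force,
                                     area = kin$area),
                 embolization_index = emb, bounding_box = bb),
            class = "phase_portrait")
}

#' @export
print.phase_portrait <- function(x, ...) {
  cat(sprintf("Phase portrait: %d checkpoints; embolization %s\n",
              nrow(x$points),
              if (is.na(x$embolization_index)) "not detected"
              else sprintf("at checkpoint %d (t = %.3g s)",
                           x$embolization_index,
                           x$points$time[x$embolization_index])))
  invisible(x)
}

#' Latin-hypercube sensitivity of the segmentation to its parameters
#'
#' Draws a Latin-hypercube sample over the key image-processing parameters
#' (binarization percentile, median kernel, Gaussian sigma, Canny thresholds),
#' segments the stack under each sample, and reports the time-averaged
#' relative spread (coefficient of variation, %) of the reconstructed clot
#' area and aspect ratio across samples.
#'
#' @param stack `image_stack` to segment.
#' @param param_ranges named list of `c(min, max)` intervals; recognised names:
#'   `percentile`, `median_kernel`, `gaussian_sigma`, `canny_low`,
#'   `canny_high`. Zero-width intervals are allowed.
#' @param n_samples number of LHS samples (>= 10).
#' @param seed RNG seed for the sample matrix.
#' @return list: `area_cv_pct`, `aspect_cv_pct`, `samples` (design matrix),
#'   `area` and `aspect` (frame x sample matrices), `failed` (logical).
#' @export
lhs_sensitivity <- function(stack,
                            param_ranges = list(percentile = c(70, 90),
                                                median_kernel = c(3, 7),
                                                gaussian_sigma = c(0.5, 2),
                                                canny_low = c(0.05, 0.15),
                                                canny_high = c(0.2, 0.4)),
                            n_samples = 30, seed = 1L) {
  if (n_samples < 10) stop("n_samples must be >= 10")
  nm <- names(param_ranges)
  X <- with_seed(seed, lhs::randomLHS(n_samples, length(param_ranges)))
  colnames(X) <- nm
  scale_par <- function(u, rng) rng[1] + u * (rng[2] - rng[1])
  n_frames <- dim(stack$data)[1]
  area <- aspect <- matrix(NA_real_, n_frames, n_samples)
  failed <- logical(n_samples)
  design <- matrix(NA_real_, n_samples, length(nm),
                   dimnames = list(NULL, nm))
  for (s in seq_len(n_samples)) {
    pv <- lapply(nm, function(p) scale_par(X[s, p], param_ranges[[p]]))
    names(pv) <- nm
    if (!is.null(pv$median_kernel)) {      # snap to odd integer >= 3
      k <- max(3, round(pv$median_kernel))
      pv$median_kernel <- if (k %% 2 == 0) k + 1 else k
    }
    design[s, ] <- unlist(pv)
    params <- segmentation_params(
      binarize = if (is.null(pv$percentile)) list(method = "otsu")
                 else list(method = "percentile", q = pv$percentile),
      median_kernel = if (is.null(pv$median_kernel)) 3 else pv$median_kernel,
      gaussian_sigma = if (is.null(pv$gaussian_sigma)) 1 else pv$gaussian_sigma,
      canny_low = if (is.null(pv$canny_low)) 0.1 else pv$canny_low,
      canny_high = if (is.null(pv$canny_high)) 0.3 else pv$canny_high)
    res <- tryCatch(segment_stack(stack, params), error = function(e) e)
    if (inherits(res, "error")) { failed[s] <- TRUE; next }
    for (f in seq_len(n_frames)) {
      b <- res[[f]]
      if (is.null(b)) next
      poly <- cbind((b$coords[, 2] - 0.5) * stack$pixel_size,
                    (b$coords[, 1] - 0.5) * stack$pixel_size)
      area[f, s] <- polygon_area(poly)
      aspect[f, s] <- polygon_aspect_ratio(poly)
    }
  }
  if (all(failed)) stop("all LHS samples failed")
  cv_t <- function(M) {
    per_frame <- apply(M[, !failed, drop = FALSE], 1, function(v) {
      v <- v[is.finite(v)]
      if (length(v) < 2) return(NA_real_)
      100 * stats::sd(v) / mean(v)
    })
    mean(per_frame, na.rm = TRUE)
  }
  list(area_cv_pct = cv_t(area), aspect_cv_pct = cv_t(aspect),
       samples = design, area = area, aspect = aspect, failed = failed)
}
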