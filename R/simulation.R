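# Coupled moving-domain simulation: at every sub-step the clot boundary is
# interpolated in time, the indicator fields are re-marked on the fixed mesh,
# material fields are re-assembled, and one flow step and one transport step
# are taken. States are checkpointed at the imaging frame times.

#' Run the coupled flow-transport simulation over a dynamic clot domain
#'
#' @param domain `clot_domain` (overall + optional core boundary series).
#' @param mesh `vessel_mesh`.
#' @param mat_params [material_params()] (e.g. [wt_params()]).
#' @param flow_cfg [flow_config()]; its `dt` is overridden by
#'   `frame_interval / n_sub` from the domain.
#' @param trans_cfg [transport_config()]; `dt` overridden likewise.
#' @param t_end end time, s (default: last frame time).
#' @param uncage_times times (s) at which the caged-albumin pulse re-initializes
#'   the concentration to 1 over the clot.
#' @param eps indicator threshold parameter.
#' @param verbose print per-step progress.
#' @return object of class `"clot_simulation"`: list `checkpoints` (one per
#'   frame time: flow, transport, materials, boundary, time), the mesh and
#'   the configurations.
#' @export
run_coupled_simulation <- function(domain, mesh, mat_params = wt_params(),
                                   flow_cfg = flow_config(),
                                   trans_cfg = transport_config(),
                                   t_end = NULL, uncage_times = 0,
                                   eps = 1e-2, verbose = FALSE) {
  stopifnot(inherits(domain, "clot_domain"), inherits(mesh, "vessel_mesh"))
  dt <- domain$frame_interval / domain$n_sub
  flow_cfg$dt <- dt; trans_cfg$dt <- dt
  if (is.null(t_end)) t_end <- domain$times[length(domain$times)]
  nsteps <- max(1L, as.integer(round(t_end / dt)))
  frame_steps <- unique(pmin(nsteps,
                             as.integer(round(domain$times / dt))))
  flow <- NULL; trans <- NULL
  checkpoints <- list()
  mark_at <- function(t) {
    ov <- mark_indicator(mesh, boundary_at(domain, t, "overall"), eps)
    co <- if (!is.null(domain$core))
      mark_indicator(mesh, boundary_at(domain, t, "core"), eps) else NULL
    assemble_material_fields(ov, co, mat_params)
  }
  for (k in 0:nsteps) {
    t <- k * dt
    step_err <- tryCatch({
      mats <- mark_at(t)
      if (any(abs(uncage_times - t) < dt / 2) || is.null(trans))
        trans <- init_uncaging(mesh, list(member = mats$clot), time = t)
      if (k > 0) {
        flow <- solve_flow_step(mesh, mats, flow_cfg, flow, time = t - dt)
        trans <- suppressWarnings(
          solve_transport_step(mesh, mats, flow, trans, trans_cfg))
      } else {
        flow <- solve_flow_step(mesh, mats, flow_cfg, NULL, steady = TRUE,
                                time = 0)
      }
      NULL
    }, error = function(e) e)
    if (!is.null(step_err))
      stop(sprintf("simulation failed at sub-step %d (t = %.3f s): %s",
                   k, t, conditionMessage(step_err)))
    if (k %in% frame_steps) {
      checkpoints[[length(checkpoints) + 1]] <-
        list(time = t, flow = flow, transport = trans, materials = mats,
             boundary = boundary_at(domain, t, "overall"))
      if (verbose)
        message(sprintf("checkpoint t = %.2f s: max |u| = %.0f um/s",
                        t, max(abs(flow$u))))
    }
  }
  structure(list(checkpoints = checkpoints, mesh = mesh,
                 mat_params = mat_params, flow_cfg = flow_cfg,
                 trans_cfg = trans_cfg, dt = dt),
            class = "clot_simulation")
}

#' @export
print.clot_simulation <- function(x, ...) {
  cat(sprintf("Coupled clot simulation: %d checkpoints, dt = %.3g s\n",
              length(x$checkpoints), x$dt))
  invisible(x)
}

#' Write simulation checkpoints as a VTK time series
#'
#' One legacy-VTK file per checkpoint (velocity, pressure, concentration,
#' porosity), plus a .series index file.
#' @export
write_simulation_vtk <- function(sim, dir, basename = "clotflow") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (i in seq_along(sim$checkpoints)) {
    ck <- sim$checkpoints[[i]]
    f <- file.path(dir, sprintf("%s_%03d.vtk", basename, i - 1))
    write_vtk(sim$mesh, f,
              point_data = list(velocity = ck$flow$u, pressure = ck$flow$p,
                                concentration = ck$transport$c,
                                porosity = ck$materials$phi))
    files <- c(files, f)
  }
  idx <- file.path(dir, paste0(basename, ".vtk.series"))
  jsonlite::write_json(
    list(`file-series-version` = "1.0",
         files = data.frame(
           name = basename(files),
           time = vapply(sim$checkpoints, `[[`, numeric(1), "time"))),
    idx, auto_unbox = TRUE, digits = NA)
  invisible(c(files, idx))
}
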