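# Pipeline orchestration: one validated configuration drives the synthetic
# imaging, segmentation, boundary tracking, coupled simulation, and
# quantification stages, with every artifact listed in a JSON manifest keyed
# by a hash of the configuration and the global seed.

#' Build and validate a pipeline configuration
#'
#' All parameters have working defaults emulating the wild-type case study at
#' desk scale; any subset can be overridden through `...` as named nested
#' lists (e.g. `mesh = list(h = 2)`).
#'
#' @param output_dir directory for all artifacts.
#' @param seed global seed.
#' @param ... overrides merged over the defaults.
#' @export
pipeline_config <- function(output_dir = "clotflow-out", seed = 1L, ...) {
  cfg <- list(
    output_dir = output_dir, seed = as.integer(seed),
    scene = list(image_shape = c(128, 128), pixel_size = 0.5,
                 frame_interval = 0.55, n_frames = 30,
                 base_axes = c(8, 6), growth_rate = c(0.22, 0.16),
                 saturation_tau = 12, core_scale = 0.5,
                 center = c(32, 30), mode = "growth",
                 embolize_frame = NULL, embolize_fraction = 0.5,
                 vessel = list(diameter = 50,
                               injury = list(center_x = 32, depth = 4,
                                             width = 16)),
                 intensity = list(fg_mean = 180, fg_sd = 30, bg_mean = 30,
                                  bg_sd = 10, salt_density = 0.02)),
    segmentation = list(median_kernel = 3, gaussian_sigma = 1,
                        canny_low = 0.1, canny_high = 0.3, connectivity = 8),
    geometry = list(degree = 3, n_rays = 180, n_sub = 11, smooth_window = 5),
    mesh = list(length = 64, diameter = 50, h = 2.5),
    flow = list(rho_g_cc = 1.06, mu_cP = 4.0, U_peak_um_s = 1300),
    materials = list(preset = "wt"),
    transport = list(cip_coef = 0.01),
    sensitivity = list(n_samples = 30,
                       ranges = list(percentile = c(70, 90),
                                     median_kernel = c(3, 7),
                                     gaussian_sigma = c(0.5, 2),
                                     canny_low = c(0.05, 0.15),
                                     canny_high = c(0.2, 0.4))))
  over <- list(...)
  for (nm in names(over))
    cfg[[nm]] <- if (is.list(cfg[[nm]]) && is.list(over[[nm]]))
      utils::modifyList(cfg[[nm]], over[[nm]]) else over[[nm]]
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  pos <- c(cfg$scene$pixel_size, cfg$scene$frame_interval,
           cfg$scene$base_axes, cfg$mesh$length, cfg$mesh$diameter,
           cfg$mesh$h, cfg$flow$rho_g_cc, cfg$flow$mu_cP,
           cfg$geometry$n_rays, cfg$geometry$n_sub)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop("invalid configuration: all physical parameters must be positive")
  if (!cfg$materials$preset %in% c("wt", "diyf"))
    stop("materials preset must be 'wt' or 'diyf'")
  invisible(cfg)
}

# Stable hash of the configuration (md5 of its canonical serialized form:
# NULL entries dropped and names sorted, so the hash is invariant under
# serialization round-trips that reorder or omit empty fields).
config_hash <- function(cfg) {
  canonical <- function(x) {
    if (is.list(x)) {
      x <- x[!vapply(x, is.null, logical(1))]
      if (!is.null(names(x))) x <- x[order(names(x))]
      lapply(x, canonical)
    } else x
  }
  tf <- tempfile()
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(canonical(unclass(cfg)), auto_unbox = TRUE,
                              digits = 10), tf)
  unname(tools::md5sum(tf))
}

#' Read a pipeline configuration from a YAML or JSON file
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
  else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, utils::modifyList(raw, list(...)))
}

#' Run the clot-flow pipeline
#'
#' Executes the requested stages in dependency order: `synth` (synthetic
#' imaging), `segment`, `track` (spline boundaries + kinematics), `simulate`
#' (coupled flow-transport), `quantify` (loading, decay, phase portrait),
#' `sensitivity` (LHS sweep). Earlier outputs are reloaded from disk where a
#' stage's inputs are file-based; a JSON manifest lists every artifact with
#' its md5 checksum, the configuration hash and the seed.
#'
#' @param config [pipeline_config()].
#' @param stages character subset of
#'   `c("synth", "segment", "track", "simulate", "quantify", "sensitivity")`.
#' @param sim_frames number of frames simulated in the `simulate` stage
#'   (coupled FEM sub-stepping is the dominant cost; the default covers the
#'   first 6 frames).
#' @return invisibly, the manifest list.
#' @export
run_pipeline <- function(config = pipeline_config(),
                         stages = c("synth", "segment", "track"),
                         sim_frames = 6) {
  valid <- c("synth", "segment", "track", "simulate", "quantify", "sensitivity")
  stages <- match.arg(stages, valid, several.ok = TRUE)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(config_hash = config_hash(config), seed = config$seed,
                   stages = stages, files = list(), timings = list())
  state <- new.env(parent = emptyenv())
  add_file <- function(path) {
    manifest$files[[basename(path)]] <<-
      list(path = path, md5 = unname(tools::md5sum(path)))
  }
  timed <- function(name, expr) {
    t0 <- Sys.time()
    force(expr)
    manifest$timings[[name]] <<- round(as.numeric(Sys.time() - t0, units = "secs"), 2)
  }
  sc <- config$scene
  scene <- synthetic_scene(
    image_shape = sc$image_shape,
    schedule = make_growth_schedule(
      sc$n_frames, mode = if (is.null(sc$embolize_frame)) "growth"
      else "growth_then_embolize",
      base_axes = sc$base_axes, growth_rate = sc$growth_rate,
      embolize_frame = sc$embolize_frame,
      embolize_fraction = sc$embolize_fraction,
      center = sc$center, saturation_tau = sc$saturation_tau),
    core_scale = sc$core_scale, pixel_size = sc$pixel_size,
    frame_interval = sc$frame_interval, vessel = sc$vessel,
    intensity = sc$intensity, seed = config$seed)

  if ("synth" %in% stages) timed("synth", {
    r <- render_stack(scene)
    for (ch in names(r$channels)) {
      p <- file.path(out, paste0(tolower(ch), ".tif"))
      write_stack_tiff(r$channels[[ch]], p)
      add_file(p)
    }
    gt_csv <- file.path(out, "ground_truth.csv")
    write_ground_truth(r$truth, gt_csv, file.path(out, "metadata.json"),
                       sc$pixel_size, sc$frame_interval)
    add_file(gt_csv); add_file(file.path(out, "metadata.json"))
    state$stacks <- r$channels; state$truth <- r$truth
  })

  need <- function(what, stage_hint) {
    if (is.null(state[[what]]))
      stop("missing upstream artifact '", what, "': run stage '",
           stage_hint, "' first")
    state[[what]]
  }

  if ("segment" %in% stages) timed("segment", {
    if (is.null(state$stacks)) {
      p <- file.path(out, "cd41.tif")
      if (!file.exists(p)) stop("missing upstream artifact: run stage 'synth' first")
      state$stacks <- list(
        CD41 = read_stack_tiff(p, sc$pixel_size, sc$frame_interval, "CD41"),
        PSelectin = read_stack_tiff(file.path(out, "pselectin.tif"),
                                    sc$pixel_size, sc$frame_interval,
                                    "PSelectin"))
    }
    params <- do.call(segmentation_params,
                      c(config$segmentation, list(seed = config$seed)))
    state$boundaries <- lapply(state$stacks[c("CD41", "PSelectin")],
                               segment_stack, params = params)
    for (ch in names(state$boundaries)) {
      p <- file.path(out, paste0("boundaries_", tolower(ch), ".csv"))
      write_boundaries_csv(state$boundaries[[ch]], p,
                           pixel_size = sc$pixel_size)
      add_file(p)
    }
    ql <- file.path(out, "overlay_frame1.png")
    quicklook_overlay(state$stacks$CD41, state$boundaries$CD41, 1, ql)
    add_file(ql)
  })

  if ("track" %in% stages) timed("track", {
    bnd <- need("boundaries", "segment")
    gp <- config$geometry
    to_splines <- function(bl) lapply(seq_along(bl), function(f) {
      if (is.null(bl[[f]])) return(NULL)
      fit_spline_boundary(bl[[f]], degree = gp$degree,
                          pixel_size = sc$pixel_size,
                          time = (f - 1) * sc$frame_interval)
    })
    state$domain <- dynamic_clot_domain(
      to_splines(bnd$CD41), to_splines(bnd$PSelectin),
      frame_interval = sc$frame_interval, n_sub = gp$n_sub,
      n_rays = gp$n_rays)
    kin <- compute_kinematics(state$domain, smooth_window = gp$smooth_window)
    state$kinematics <- kin
    p <- file.path(out, "kinematics.csv")
    write_kinematics_csv(kin, p); add_file(p)
  })

  if ("simulate" %in% stages) timed("simulate", {
    domain <- need("domain", "track")
    mesh <- build_vessel_mesh(config$mesh$length, config$mesh$diameter,
                              injury = sc$vessel$injury, h = config$mesh$h)
    mp <- if (config$materials$preset == "wt") wt_params() else diyf_params()
    t_end <- min((sim_frames - 1) * sc$frame_interval,
                 domain$times[length(domain$times)])
    state$sim <- run_coupled_simulation(
      domain, mesh, mp,
      flow_cfg = do.call(flow_config, config$flow),
      trans_cfg = do.call(transport_config, config$transport),
      t_end = t_end)
    files <- write_simulation_vtk(state$sim, file.path(out, "fields"))
    for (f in files) add_file(f)
  })

  if ("quantify" %in% stages) timed("quantify", {
    sim <- need("sim", "simulate")
    kin_full <- need("kinematics", "track")
    ld <- loading_series(sim$checkpoints, sim$mesh, config$flow$mu_cP)
    p <- file.path(out, "loading.csv")
    utils::write.csv(ld, p, row.names = FALSE); add_file(p)
    for (reg in c("clot", "core", "shell")) {
      dc <- calb_decay_curve(lapply(sim$checkpoints, `[[`, "transport"),
                             sim$mesh,
                             lapply(sim$checkpoints, `[[`, "materials"), reg)
      p <- file.path(out, paste0("decay_", reg, ".csv"))
      utils::write.csv(dc, p, row.names = FALSE); add_file(p)
    }
    kin <- kin_full[kin_full$time %in% ld$time, , drop = FALSE]
    if (nrow(kin) == nrow(ld)) {
      pp <- build_phase_portrait(kin, ld,
                                 smooth_window = config$geometry$smooth_window)
      p <- file.path(out, "phase_portrait.csv")
      utils::write.csv(pp$points, p, row.names = FALSE); add_file(p)
      png_p <- file.path(out, "phase_portrait.png")
      grDevices::png(png_p, 600, 480)
      plot(pp$points$force, pp$points$area, type = "b",
           xlab = "total loading (nN/um)", ylab = "clot area (um^2)",
           main = "Force-volume phase portrait")
      grDevices::dev.off()
      add_file(png_p)
    }
    re <- reynolds_number(do.call(flow_config, config$flow),
                          config$mesh$diameter)
    p <- file.path(out, "reynolds.json")
    jsonlite::write_json(list(reynolds = re), p, auto_unbox = TRUE,
                         digits = NA)
    add_file(p)
  })

  if ("sensitivity" %in% stages) timed("sensitivity", {
    if (is.null(state$stacks)) {
      p <- file.path(out, "cd41.tif")
      if (!file.exists(p)) stop("missing upstream artifact: run stage 'synth' first")
      state$stacks <- list(CD41 = read_stack_tiff(p, sc$pixel_size,
                                                  sc$frame_interval, "CD41"))
    }
    sens <- lhs_sensitivity(state$stacks$CD41,
                            param_ranges = config$sensitivity$ranges,
                            n_samples = config$sensitivity$n_samples,
                            seed = config$seed)
    p <- file.path(out, "sensitivity.csv")
    utils::write.csv(data.frame(sens$samples,
                                failed = sens$failed), p, row.names = FALSE)
    add_file(p)
    p2 <- file.path(out, "sensitivity_summary.json")
    jsonlite::write_json(list(area_cv_pct = sens$area_cv_pct,
                              aspect_cv_pct = sens$aspect_cv_pct),
                         p2, auto_unbox = TRUE, digits = NA)
    add_file(p2)
    state$sensitivity <- sens
  })

  mpath <- file.path(out, "manifest.json")
  jsonlite::write_json(manifest, mpath, auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}

# PNG overlay of a segmented boundary on its source frame.
quicklook_overlay <- function(stack, boundaries, frame, path) {
  grDevices::png(path, 480, 480)
  op <- graphics::par(mar = c(2, 2, 2, 1))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  img <- stack_frame(stack, frame)
  graphics::image(t(img)[, nrow(img):1], col = grDevices::gray.colors(64),
                  main = sprintf("%s frame %d", stack$channel, frame),
                  axes = FALSE)
  b <- boundaries[[frame]]
  if (!is.null(b)) {
    h <- nrow(img); w <- ncol(img)
    graphics::lines((b$coords[, 2] - 0.5) / w, 1 - (b$coords[, 1] - 0.5) / h,
                    col = "red", lwd = 2)
  }
  invisible(path)
}
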