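# Synthetic intravital imaging: ground-truth-labelled image stacks that
# emulate the statistical structure of laser-injury microscopy data, so the
# whole downstream pipeline is testable without animal data.
#
# Conventions: images are matrices indexed [row, col]; physical coordinates
# are x = (col - 0.5) * pixel_size, y = (row - 0.5) * pixel_size (micrometres,
# y increasing down the image). Channels: CD41 marks the overall clot,
# P-selectin the densely packed core, cAlb the plasma pool.

#' Per-frame ellipse growth schedule for a synthetic clot
#'
#' Builds the analytic trajectory of the (overall) clot ellipse: monotone axis
#' growth up to an optional plateau, optionally interrupted by an embolization
#' event modelled as an instantaneous area drop followed by regrowth. Axis
#' growth is linear by default; a finite `saturation_tau` bends it into a
#' smooth saturating curve `rate * tau * (1 - exp(-t/tau))`, emulating the
#' characteristic fast-growth-then-plateau kinetics of hemostatic plugs.
#'
#' @param n_frames number of frames (>= 2).
#' @param mode `"growth"` or `"growth_then_embolize"`.
#' @param base_axes numeric length 1 or 2, initial semi-axes (a, b) in um.
#' @param growth_rate axis growth rate, um/frame (length 1 or 2).
#' @param plateau_frame frame after which axes stop growing (default: none).
#' @param embolize_frame frame at which the area drops (embolize mode); must
#'   lie strictly inside `(1, n_frames]`.
#' @param embolize_fraction fraction of area retained at the drop, in (0, 1].
#' @param center ellipse center (x, y) in um.
#' @param rotation_rate rotation of the ellipse, rad/frame.
#' @param saturation_tau time constant (frames) of saturating growth;
#'   `Inf` gives linear growth.
#' @return data.frame with columns frame, cx, cy, a, b, theta (um, rad),
#'   class `"growth_schedule"`.
#' @export
make_growth_schedule <- function(n_frames,
                                 mode = c("growth", "growth_then_embolize"),
                                 base_axes = c(10, 10),
                                 growth_rate = 0.5,
                                 plateau_frame = n_frames,
                                 embolize_frame = NULL,
                                 embolize_fraction = 0.5,
                                 center = c(0, 0),
                                 rotation_rate = 0,
                                 saturation_tau = Inf) {
  mode <- match.arg(mode)
  if (n_frames < 2) stop("n_frames must be >= 2")
  if (any(base_axes <= 0)) stop("base_axes must be positive")
  base_axes <- rep_len(base_axes, 2)
  growth_rate <- rep_len(growth_rate, 2)
  if (mode == "growth_then_embolize") {
    if (is.null(embolize_frame) || embolize_frame <= 1 || embolize_frame > n_frames)
      stop("embolize_frame must lie in (1, n_frames]")
    if (embolize_fraction <= 0 || embolize_fraction > 1)
      stop("embolize_fraction must be in (0, 1]")
  }
  grow <- function(t) { # t in frames since start of a growth phase
    t <- pmin(t, plateau_frame - 1)
    if (is.finite(saturation_tau))
      outer(saturation_tau * (1 - exp(-t / saturation_tau)), growth_rate)
    else outer(t, growth_rate)
  }
  t <- seq_len(n_frames) - 1
  ax <- sweep(grow(t), 2, base_axes, "+")
  if (mode == "growth_then_embolize") {
    k <- embolize_frame
    # instantaneous area drop: both axes scaled by sqrt(fraction), then the
    # growth law restarts from the reduced axes
    ax_drop <- ax[k - 1, ] * sqrt(embolize_fraction)
    idx <- k:n_frames
    ax[idx, ] <- sweep(grow(idx - k), 2, ax_drop, "+")
  }
  out <- data.frame(frame = seq_len(n_frames),
                    cx = center[1], cy = center[2],
                    a = ax[, 1], b = ax[, 2],
                    theta = (seq_len(n_frames) - 1) * rotation_rate)
  class(out) <- c("growth_schedule", "data.frame")
  out
}

#' Describe a synthetic intravital imaging scene
#'
#' Bundles geometry, growth schedule, intensity statistics and acquisition
#' metadata for [render_stack()]. The vessel is an axis-aligned lumen with an
#' optional circular-arc indentation (the injury site) in one wall; the clot
#' is a nested pair of ellipses (overall and core) following `schedule`.
#'
#' @param image_shape c(H, W) in pixels.
#' @param schedule growth schedule for the overall ellipse
#'   (see [make_growth_schedule()]); centers in um.
#' @param core_scale core semi-axes as a fraction of the overall semi-axes
#'   (strictly inside for < 1).
#' @param pixel_size um per pixel.
#' @param frame_interval seconds per frame.
#' @param vessel list(diameter, injury = list(center_x, depth, width)) in um;
#'   diameter must lie in the 30-100 um arteriole range.
#' @param intensity list(fg_mean, fg_sd, bg_mean, bg_sd, salt_density) on the
#'   8-bit scale; salt noise density must be < 0.1.
#' @param seed integer RNG seed; rendering is bit-reproducible for fixed seed.
#' @return object of class `"synthetic_scene"`.
#' @export
synthetic_scene <- function(image_shape = c(128, 128),
                            schedule,
                            core_scale = 0.5,
                            pixel_size = 0.5,
                            frame_interval = 0.55,
                            vessel = list(diameter = 50,
                                          injury = list(center_x = NA, depth = 5, width = 12)),
                            intensity = list(fg_mean = 180, fg_sd = 30,
                                             bg_mean = 30, bg_sd = 10,
                                             salt_density = 0.02),
                            seed = 1L) {
  stopifnot(length(image_shape) == 2, image_shape > 8, pixel_size > 0,
            frame_interval > 0)
  if (!inherits(schedule, "data.frame")) stop("schedule must be a data.frame")
  if (any(schedule$a <= 0) || any(schedule$b <= 0)) stop("semi-axes must be > 0")
  if (core_scale <= 0 || core_scale >= 1)
    stop("core_scale must be in (0, 1): core ellipse strictly inside overall")
  inten <- utils::modifyList(list(fg_mean = 180, fg_sd = 30, bg_mean = 30,
                                  bg_sd = 10, salt_density = 0.02), intensity)
  if (inten$salt_density < 0 || inten$salt_density >= 0.1)
    stop("salt_density must be in [0, 0.1)")
  if (!is.null(vessel$diameter) &&
      (vessel$diameter < 30 || vessel$diameter > 100))
    stop("vessel diameter must be within 30-100 um")
  structure(list(image_shape = as.integer(image_shape),
                 schedule = schedule, core_scale = core_scale,
                 pixel_size = pixel_size, frame_interval = frame_interval,
                 n_frames = nrow(schedule), vessel = vessel,
                 intensity = inten, seed = as.integer(seed)),
            class = "synthetic_scene")
}

#' @export
print.synthetic_scene <- function(x, ...) {
  cat("Synthetic intravital scene:", x$n_frames, "frames,",
      paste(x$image_shape, collapse = "x"), "px at", x$pixel_size,
      "um/px,", x$frame_interval, "s/frame\n")
  cat("  overall semi-axes:", round(min(x$schedule$a), 2), "-",
      round(max(x$schedule$a), 2), "um; core scale", x$core_scale, "\n")
  invisible(x)
}

# Exact ellipse boundary polyline (n x 2, um) at one schedule row.
ellipse_polyline <- function(row, scale = 1, n = 256) {
  t <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  ct <- cos(row$theta); st <- sin(row$theta)
  ex <- scale * row$a * cos(t); ey <- scale * row$b * sin(t)
  cbind(row$cx + ex * ct - ey * st, row$cy + ex * st + ey * ct)
}

# Boolean raster of an ellipse over pixel centers (H x W matrix).
rasterize_ellipse <- function(row, scale, shape, pixel_size) {
  h <- shape[1]; w <- shape[2]
  xc <- (seq_len(w) - 0.5) * pixel_size
  yc <- (seq_len(h) - 0.5) * pixel_size
  ct <- cos(row$theta); st <- sin(row$theta)
  dx <- outer(yc - row$cy, xc - row$cx, function(Y, X) X) # H x W of x-offsets
  dy <- outer(yc - row$cy, xc - row$cx, function(Y, X) Y)
  u <- (dx * ct + dy * st) / (scale * row$a)
  v <- (-dx * st + dy * ct) / (scale * row$b)
  u * u + v * v <= 1
}

# Mask of the stagnation pool at the injury indentation (cAlb channel only).
injury_pool_mask <- function(vessel, shape, pixel_size) {
  inj <- vessel$injury
  if (is.null(inj) || is.null(inj$depth) || inj$depth <= 0)
    return(matrix(FALSE, shape[1], shape[2]))
  cx <- if (is.finite(inj$center_x)) inj$center_x else shape[2] * pixel_size / 2
  # half-disc hugging the bottom image edge (the injured wall)
  y0 <- shape[1] * pixel_size
  xc <- (seq_len(shape[2]) - 0.5) * pixel_size
  yc <- (seq_len(shape[1]) - 0.5) * pixel_size
  outer(yc, xc, function(Y, X) (X - cx)^2 + (Y - y0)^2 <= (inj$width / 2)^2)
}

#' Render a synthetic multi-channel intravital stack with ground truth
#'
#' Draws foreground pixels i.i.d. from the clipped-normal foreground intensity
#' model inside each channel's region, background pixels outside, then
#' superposes isolated salt-noise pixels (value 255) outside the clot.
#' Deterministic for a fixed scene seed.
#'
#' @param scene a [synthetic_scene()].
#' @return list with `channels` (named list of `image_stack` objects for
#'   CD41, PSelectin, cAlb) and `truth` (per-frame exact boundary polylines,
#'   areas pi*a*b in um^2, and aspect ratios max(a,b)/min(a,b)).
#' @export
render_stack <- function(scene) {
  stopifnot(inherits(scene, "synthetic_scene"))
  shape <- scene$image_shape; px <- scene$pixel_size
  sched <- scene$schedule
  # rendering error if any overall ellipse exceeds image bounds
  rmax <- pmax(sched$a, sched$b)
  lim_x <- shape[2] * px; lim_y <- shape[1] * px
  if (any(sched$cx - rmax < 0) || any(sched$cx + rmax > lim_x) ||
      any(sched$cy - rmax < 0) || any(sched$cy + rmax > lim_y))
    stop("ellipse exceeds image bounds")
  inten <- scene$intensity
  pool <- injury_pool_mask(scene$vessel, shape, px)
  channels <- c("CD41", "PSelectin", "cAlb")
  arrays <- lapply(channels, function(ch)
    array(0, dim = c(scene$n_frames, shape[1], shape[2])))
  names(arrays) <- channels
  truth_rows <- vector("list", scene$n_frames * length(channels))
  polylines <- list()
  with_seed(scene$seed, {
    for (f in seq_len(scene$n_frames)) {
      row <- sched[f, ]
      mask_all <- rasterize_ellipse(row, 1, shape, px)
      mask_core <- rasterize_ellipse(row, scene$core_scale, shape, px)
      masks <- list(CD41 = mask_all, PSelectin = mask_core,
                    cAlb = mask_all | pool)
      for (ch in channels) {
        m <- masks[[ch]]
        img <- matrix(pmin(255, pmax(0, stats::rnorm(prod(shape), inten$bg_mean,
                                                     inten$bg_sd))), shape[1])
        nfg <- sum(m)
        if (nfg > 0)
          img[m] <- pmin(255, pmax(0, stats::rnorm(nfg, inten$fg_mean,
                                                   inten$fg_sd)))
        if (inten$salt_density > 0) {
          salt <- matrix(stats::runif(prod(shape)) < inten$salt_density,
                         shape[1]) & !m
          img[salt] <- 255
        }
        arrays[[ch]][f, , ] <- round(img)
        scl <- switch(ch, CD41 = 1, PSelectin = scene$core_scale, cAlb = 1)
        polylines[[paste(f, ch, sep = "_")]] <- ellipse_polyline(row, scl)
        truth_rows[[(f - 1) * 3 + match(ch, channels)]] <- data.frame(
          frame = f, channel = ch,
          area = pi * (scl * row$a) * (scl * row$b),
          aspect = max(row$a, row$b) / min(row$a, row$b))
      }
    }
  })
  stacks <- lapply(channels, function(ch)
    image_stack(arrays[[ch]], pixel_size = px,
                frame_interval = scene$frame_interval, channel = ch))
  names(stacks) <- channels
  truth <- list(summary = do.call(rbind, truth_rows), polylines = polylines,
                schedule = sched, core_scale = scene$core_scale)
  class(truth) <- "ground_truth"
  list(channels = stacks, truth = truth)
}

#' Construct an image stack
#'
#' @param data numeric array `[n_frames, H, W]`, intensities >= 0.
#' @param pixel_size um/pixel. @param frame_interval s/frame.
#' @param channel one of CD41, PSelectin, cAlb (or any label).
#' @export
image_stack <- function(data, pixel_size, frame_interval, channel = "CD41") {
  stopifnot(length(dim(data)) == 3, all(data >= 0), pixel_size > 0,
            frame_interval > 0)
  structure(list(data = data, pixel_size = pixel_size,
                 frame_interval = frame_interval, channel = channel),
            class = "image_stack")
}

#' @export
print.image_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("Image stack [%s]: %d frames of %dx%d px (%.3g um/px, %.3g s/frame)\n",
              x$channel, d[1], d[2], d[3], x$pixel_size, x$frame_interval))
  invisible(x)
}

# Extract one frame as a plain H x W matrix.
stack_frame <- function(stack, i) stack$data[i, , ]

#' Write an image stack as a multi-page TIFF
#' @export
write_stack_tiff <- function(stack, path) {
  pages <- lapply(seq_len(dim(stack$data)[1]),
                  function(i) stack$data[i, , ] / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Read a multi-page TIFF as an image stack
#' @export
read_stack_tiff <- function(path, pixel_size, frame_interval, channel = "CD41") {
  pages <- tiff::readTIFF(path, all = TRUE)
  pages <- lapply(pages, function(p) if (length(dim(p)) == 3) p[, , 1] else p)
  arr <- array(0, dim = c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
  for (i in seq_along(pages)) arr[i, , ] <- round(pages[[i]] * 255)
  image_stack(arr, pixel_size, frame_interval, channel)
}

#' Write ground truth boundaries and metadata
#'
#' CSV of polyline vertices (frame, channel, vertex, x_um, y_um) plus a JSON
#' sidecar with acquisition metadata.
#' @export
write_ground_truth <- function(truth, csv_path, json_path = NULL,
                               pixel_size = NA, frame_interval = NA) {
  rows <- lapply(names(truth$polylines), function(key) {
    parts <- strsplit(key, "_")[[1]]
    p <- truth$polylines[[key]]
    data.frame(frame = as.integer(parts[1]), channel = parts[2],
               vertex = seq_len(nrow(p)), x_um = p[, 1], y_um = p[, 2])
  })
  utils::write.csv(do.call(rbind, rows), csv_path, row.names = FALSE)
  if (!is.null(json_path))
    jsonlite::write_json(list(pixel_size = pixel_size,
                              frame_interval = frame_interval),
                         json_path, auto_unbox = TRUE)
  invisible(csv_path)
}
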