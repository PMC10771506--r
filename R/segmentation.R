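# Automated per-frame clot boundary segmentation.
#
# Chain (per frame): intensity binarization -> median + Gaussian denoising of
# the binary image -> k-means (k = 2) clustering of the denoised image ->
# Canny edges -> connected components of the edge-pixel graph -> the component
# with the largest perimeter, ordered into a closed loop.

#' Segmentation parameters
#'
#' @param binarize threshold rule: `list(method = "otsu")` or
#'   `list(method = "percentile", q = 90)` (q in percent of the intensity
#'   distribution).
#' @param median_kernel odd window width (pixels, >= 3) of the median filter
#'   applied to the binarized image.
#' @param gaussian_sigma sigma (pixels) of the Gaussian smoothing that removes
#'   residual speckle and fills small holes.
#' @param canny_low,canny_high hysteresis thresholds as fractions of the
#'   maximum gradient magnitude.
#' @param connectivity pixel adjacency for the edge-pixel graph (4 or 8).
#' @param seed seed for the k-means restarts (k is fixed at 2).
#' @export
segmentation_params <- function(binarize = list(method = "otsu"),
                                median_kernel = 3, gaussian_sigma = 1,
                                canny_low = 0.1, canny_high = 0.3,
                                connectivity = 8, seed = 1L) {
  if (median_kernel < 3 || median_kernel %% 2 == 0)
    stop("median_kernel must be odd and >= 3")
  if (!connectivity %in% c(4, 8)) stop("connectivity must be 4 or 8")
  if (canny_low >= canny_high) stop("canny_low must be < canny_high")
  structure(list(binarize = binarize, median_kernel = median_kernel,
                 gaussian_sigma = gaussian_sigma, kmeans_k = 2L,
                 canny_low = canny_low, canny_high = canny_high,
                 connectivity = connectivity, seed = as.integer(seed)),
            class = "segmentation_params")
}

#' Binarize a frame from its intensity distribution
#'
#' Default rule is Otsu's threshold on the intensity histogram; a percentile
#' rule is exposed for the parameter-sensitivity sweep. Pixels at or above the
#' threshold map to 1.
#'
#' @param frame H x W intensity matrix (8-bit scale).
#' @param rule `list(method = "otsu")` or `list(method = "percentile", q)`.
#' @return binary 0/1 matrix; a constant-intensity frame yields an
#'   all-background mask with a warning (the threshold is undefined).
#' @export
binarize_frame <- function(frame, rule = list(method = "otsu")) {
  if (length(frame) == 0) stop("empty frame")
  rng <- range(frame)
  if (diff(rng) == 0) {
    warning("constant-intensity frame: threshold undefined, returning background")
    return(matrix(0, nrow(frame), ncol(frame)))
  }
  if (identical(rule$method, "otsu")) {
    # otsu() returns the largest background level: foreground is strictly above
    thr <- 255 * EBImage::otsu(EBImage::Image(frame / 255), range = c(0, 1))
    (frame > thr) * 1
  } else if (identical(rule$method, "percentile")) {
    q <- rule$q
    if (is.null(q) || q <= 0 || q >= 100) stop("percentile q must be in (0, 100)")
    thr <- as.numeric(stats::quantile(frame, q / 100))
    (frame >= thr) * 1
  } else stop("unknown binarization rule: ", rule$method)
}

#' Denoise a binary mask (median filter then Gaussian smoothing)
#'
#' The median filter removes sparsely spaced bright pixels (salt noise) that
#' survive binarization because their intensity matches the clot; the Gaussian
#' pass closes small interior holes. The smoothed image is re-binarized at
#' 0.5 and also kept (attribute `"smoothed"`) as the input for clustering.
#'
#' @param mask binary 0/1 matrix.
#' @param median_kernel odd window width in pixels.
#' @param gaussian_sigma Gaussian sigma in pixels (0 skips smoothing).
#' @export
denoise_mask <- function(mask, median_kernel = 3, gaussian_sigma = 1) {
  if (!all(mask %in% c(0, 1))) stop("mask must be binary")
  if (median_kernel %% 2 == 0 || median_kernel < 3)
    stop("median_kernel must be odd and >= 3")
  if (median_kernel > min(dim(mask)))
    stop("median kernel larger than image")
  med <- EBImage::medianFilter(mask, (median_kernel - 1) / 2)
  sm <- if (gaussian_sigma > 0)
    as.matrix(EBImage::gblur(med, sigma = gaussian_sigma,
                             boundary = "replicate"))
  else as.matrix(med)
  out <- (sm >= 0.5) * 1
  attr(out, "smoothed") <- sm
  out
}

#' Two-cluster intensity segmentation (k-means, k = 2)
#'
#' Clusters the pixels of the pre-processed frame by intensity; the cluster
#' with the higher mean is the clot label. Deterministic for fixed seed.
#'
#' @param frame_processed intensity grid (denoised frame).
#' @param seed seed for the restarts.
#' @param nstart number of k-means restarts.
#' @return binary matrix, 1 = clot cluster.
#' @export
cluster_labels <- function(frame_processed, seed = 1L, nstart = 10) {
  v <- as.numeric(frame_processed)
  if (diff(range(v)) == 0)
    stop("degenerate clustering: all pixels identical")
  km <- with_seed(seed, stats::kmeans(v, centers = 2, nstart = nstart))
  clot <- which.max(km$centers)
  matrix((km$cluster == clot) * 1, nrow(frame_processed))
}

# --- Canny edge detection -----------------------------------------------
# Sobel gradients, non-maximum suppression along the quantized gradient
# direction, and two-threshold hysteresis (thresholds as fractions of the
# maximum gradient magnitude).
canny_edges <- function(img, low = 0.1, high = 0.3) {
  img <- as.matrix(img)
  kx <- matrix(c(-1, 0, 1, -2, 0, 2, -1, 0, 1), 3, byrow = TRUE) # d/dcol
  # zero padding: the label mask background is genuinely 0, and a clot
  # touching the frame edge must still produce a closed edge ring
  gx <- as.matrix(EBImage::filter2(img, kx, boundary = 0))
  gy <- as.matrix(EBImage::filter2(img, t(kx), boundary = 0))
  mag <- sqrt(gx^2 + gy^2)
  mmax <- max(mag)
  if (mmax == 0) return(matrix(FALSE, nrow(img), ncol(img)))
  h <- nrow(img); w <- ncol(img)
  shift <- function(m, dr, dc) { # neighbor value, replicated at borders
    r <- pmin(pmax(seq_len(h) + dr, 1), h)
    c <- pmin(pmax(seq_len(w) + dc, 1), w)
    m[r, c, drop = FALSE]
  }
  ang <- atan2(gy, gx)                     # gy is d/drow
  sector <- (round(ang / (pi / 4)) %% 4)   # 0:=col, 1:=diag, 2:=row, 3:=anti-diag
  n1 <- mag; n2 <- mag
  for (s in 0:3) {
    off <- switch(as.character(s),
                  "0" = c(0, 1), "1" = c(1, 1), "2" = c(1, 0), "3" = c(1, -1))
    sel <- sector == s
    n1[sel] <- shift(mag, off[1], off[2])[sel]
    n2[sel] <- shift(mag, -off[1], -off[2])[sel]
  }
  keep <- mag >= n1 & mag >= n2
  strong <- keep & (mag >= high * mmax)
  weak <- keep & (mag >= low * mmax)
  if (!any(strong)) return(strong)
  lab <- EBImage::bwlabel(weak * 1)
  good <- unique(lab[strong])
  weak & matrix(lab %in% good[good > 0], h, w)
}

# Order edge pixels of one component into a closed outer-envelope loop.
# Canny rings on a binary mask are locally 1-2 px thick, so a plain
# nearest-neighbor walk dead-ends; instead pixels are binned by polar angle
# about the component centroid and each bin is represented by the pixel whose
# radius is closest to the bin's mean radius (centered in the ring). This
# returns the single outer envelope loop (interior pore edges are dropped).
order_loop <- function(coords, bins_per_pixel = 0.75) {
  n <- nrow(coords)
  if (n < 3) return(coords)
  ctr <- colMeans(coords)
  dy <- coords[, 1] - ctr[1]; dx <- coords[, 2] - ctr[2]
  ang <- atan2(dy, dx) %% (2 * pi)
  r <- sqrt(dx^2 + dy^2)
  nbins <- max(16, round(n * bins_per_pixel))
  bin <- pmin(floor(ang / (2 * pi) * nbins), nbins - 1)
  keep <- integer(0)
  for (b in sort(unique(bin))) {
    idx <- which(bin == b)
    keep <- c(keep, idx[which.min(abs(r[idx] - mean(r[idx])))])
  }
  ord <- keep[order(ang[keep])]
  coords[ord, , drop = FALSE]
}

#' Extract the largest-perimeter boundary loop from a label mask
#'
#' Canny edges are computed on the clot label mask, edge pixels become the
#' nodes of a graph with edges between pixels adjacent under `connectivity`,
#' and the connected component with the largest perimeter (edge-pixel count;
#' ties broken by larger enclosed area, then lowest centroid row) is returned
#' as an ordered closed loop.
#'
#' @param labels binary clot label mask.
#' @param connectivity 4 or 8.
#' @param canny_low,canny_high hysteresis thresholds (fractions of max
#'   gradient magnitude).
#' @param frame_index stored in the result for bookkeeping.
#' @return object of class `"pixel_boundary"`: ordered (row, col) loop,
#'   perimeter (pixel count) and enclosed pixel area.
#' @export
extract_boundary <- function(labels, connectivity = 8, canny_low = 0.1,
                             canny_high = 0.3, frame_index = NA_integer_) {
  if (!any(labels > 0)) stop("segmentation failure: empty clot label")
  edges <- canny_edges(labels, canny_low, canny_high)
  if (!any(edges)) stop("segmentation failure: no edge pixels")
  comp <- label_components(edges, connectivity)
  ncomp <- max(comp)
  stats_list <- lapply(seq_len(ncomp), function(k) {
    idx <- which(comp == k, arr.ind = TRUE)
    loop <- order_loop(idx)
    area <- if (nrow(loop) >= 3) polygon_area(loop) else 0
    list(coords = idx, loop = loop, perimeter = nrow(idx), area = area,
         crow = mean(idx[, 1]))
  })
  per <- vapply(stats_list, `[[`, numeric(1), "perimeter")
  best <- which(per == max(per))
  if (length(best) > 1) { # tie: larger enclosed area, then lowest centroid row
    ar <- vapply(stats_list[best], `[[`, numeric(1), "area")
    best <- best[ar == max(ar)]
    if (length(best) > 1) {
      cr <- vapply(stats_list[best], `[[`, numeric(1), "crow")
      best <- best[which.max(cr)]
    }
  }
  s <- stats_list[[best[1]]]
  structure(list(frame = frame_index, coords = s$loop,
                 perimeter = s$perimeter, area_px = s$area),
            class = "pixel_boundary")
}

# Connected components of a logical matrix under 4- or 8-connectivity.
# EBImage::bwlabel is 4-connected; for 8-connectivity, bridge diagonal
# neighbours through a one-pass union of labels.
label_components <- function(mask, connectivity = 8) {
  lab <- EBImage::bwlabel(mask * 1)
  lab <- matrix(as.integer(lab), nrow(mask))
  if (connectivity == 4 || max(lab) <= 1) return(lab)
  h <- nrow(lab); w <- ncol(lab)
  parent <- seq_len(max(lab))
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (off in list(c(1, 1), c(1, -1))) {
    a <- lab[seq_len(h - 1), if (off[2] > 0) seq_len(w - 1) else 2:w]
    b <- lab[2:h, if (off[2] > 0) 2:w else seq_len(w - 1)]
    sel <- a > 0 & b > 0 & a != b
    if (any(sel)) for (k in which(sel)) {
      ra <- find(a[k]); rb <- find(b[k])
      if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
    }
  }
  roots <- vapply(seq_along(parent), find, integer(1))
  remap <- match(roots, sort(unique(roots)))
  lab[lab > 0] <- remap[lab[lab > 0]]
  lab
}

#' @export
print.pixel_boundary <- function(x, ...) {
  cat(sprintf("Pixel boundary (frame %s): %d boundary pixels, %.1f px^2 enclosed\n",
              x$frame, x$perimeter, x$area_px))
  invisible(x)
}

# Full single-frame chain; internal worker for segment_stack().
segment_frame <- function(frame, params, frame_index = NA_integer_) {
  mask <- binarize_frame(frame, params$binarize)
  den <- denoise_mask(mask, params$median_kernel, params$gaussian_sigma)
  labels <- cluster_labels(attr(den, "smoothed"), seed = params$seed)
  extract_boundary(labels, params$connectivity, params$canny_low,
                   params$canny_high, frame_index)
}

#' Segment every frame of an image stack
#'
#' Runs the full automated chain on each frame. Frames where any stage fails
#' are flagged (attribute `"failed"`) and later bridged by temporal
#' interpolation in the geometry stage; more than 20% failures aborts.
#'
#' @param stack an `image_stack`.
#' @param params [segmentation_params()].
#' @return list of `pixel_boundary` (NULL at failed frames), with logical
#'   attribute `"failed"`.
#' @export
segment_stack <- function(stack, params = segmentation_params()) {
  stopifnot(inherits(stack, "image_stack"))
  n <- dim(stack$data)[1]
  out <- vector("list", n)
  failed <- logical(n)
  for (f in seq_len(n)) {
    res <- tryCatch(
      suppressWarnings(segment_frame(stack_frame(stack, f), params, f)),
      error = function(e) e)
    if (inherits(res, "error")) failed[f] <- TRUE else out[[f]] <- res
  }
  if (mean(failed) > 0.2)
    stop(sprintf("segmentation failed on %d/%d frames (> 20%%)",
                 sum(failed), n))
  attr(out, "failed") <- failed
  attr(out, "pixel_size") <- stack$pixel_size
  attr(out, "frame_interval") <- stack$frame_interval
  out
}

#' Write segmented boundaries to CSV (frame, vertex, x_um, y_um)
#' @export
write_boundaries_csv <- function(boundaries, path,
                                 pixel_size = attr(boundaries, "pixel_size")) {
  rows <- lapply(seq_along(boundaries), function(f) {
    b <- boundaries[[f]]
    if (is.null(b)) return(NULL)
    data.frame(frame = f, vertex = seq_len(nrow(b$coords)),
               x_um = (b$coords[, 2] - 0.5) * pixel_size,
               y_um = (b$coords[, 1] - 0.5) * pixel_size)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
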