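# Shared small utilities: polygon geometry and RNG scoping.

# Run code with a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    if (had) old <- get(".Random.seed", envir = globalenv())
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(seed)
  }
  force(code)
}

# Signed area of a closed polygon (vertices as n x 2 matrix, not repeated).
polygon_signed_area <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

polygon_area <- function(pts) abs(polygon_signed_area(pts))

# Area centroid of a closed polygon.
polygon_centroid <- function(pts) {
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.eps * 100) return(colMeans(pts))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Second central area moments of a polygon: list(Ixx, Iyy, Ixy, area, centroid).
# Ixx = integral of (y - cy)^2 dA, Iyy = integral of (x - cx)^2 dA.
polygon_moments <- function(pts) {
  if (polygon_signed_area(pts) < 0) pts <- pts[rev(seq_len(nrow(pts))), ]
  x <- pts[, 1]; y <- pts[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  cx <- sum((x + xn) * cr) / (6 * a)
  cy <- sum((y + yn) * cr) / (6 * a)
  ixx <- sum((y^2 + y * yn + yn^2) * cr) / 12
  iyy <- sum((x^2 + x * xn + xn^2) * cr) / 12
  ixy <- sum((x * yn + 2 * x * y + 2 * xn * yn + xn * y) * cr) / 24
  list(Ixx = ixx - a * cy^2, Iyy = iyy - a * cx^2, Ixy = ixy - a * cx * cy,
       area = a, centroid = c(cx, cy))
}

# Rotation-invariant aspect ratio sqrt(lambda_max / lambda_min) of the second
# central moment tensor; equals a/b for an ellipse with semi-axes a >= b.
polygon_aspect_ratio <- function(pts) {
  m <- polygon_moments(pts)
  j <- matrix(c(m$Iyy, m$Ixy, m$Ixy, m$Ixx), 2, 2)
  ev <- eigen(j, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("degenerate boundary: zero second moment")
  sqrt(max(ev) / min(ev))
}

# Centered moving average with shrinking window at the ends.
moving_average <- function(x, window) {
  if (window <= 1) return(x)
  n <- length(x)
  half <- floor(window / 2)
  vapply(seq_len(n), function(i) {
    lo <- max(1, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# Central differences with one-sided stencils at the ends.
central_diff <- function(x, t) {
  n <- length(x)
  d <- numeric(n)
  if (n < 2) return(d)
  d[1] <- (x[2] - x[1]) / (t[2] - t[1])
  d[n] <- (x[n] - x[n - 1]) / (t[n] - t[n - 1])
  if (n > 2) {
    i <- 2:(n - 1)
    d[i] <- (x[i + 1] - x[i - 1]) / (t[i + 1] - t[i - 1])
  }
  d
}
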