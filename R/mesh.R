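# Fixed background vessel mesh. The vessel is a 2D channel (length L, diameter
# d) with an optional circular-arc indentation of one wall at the injury site.
# The mesh never moves: all clot motion is carried by nodal indicator fields.

#' Build a triangulated vessel-lumen mesh
#'
#' Structured triangulation of the channel `[0, L] x [0, d]` (two triangles
#' per quad). An injury is modelled as a circular-arc bite of depth `depth`
#' and half-width `width/2` displacing the bottom wall (y = 0) outward; grid
#' columns are mapped conformingly onto the indented wall.
#'
#' @param length channel length L, um.
#' @param diameter lumen diameter d, um (30-100 um arteriole range).
#' @param injury NULL or list(center_x, depth, width) in um.
#' @param h target element size, um (must be <= d/10).
#' @return object of class `"vessel_mesh"`: nodes (n x 2 um), triangles
#'   (m x 3), boundary edge table with tags inlet/outlet/wall, and cached
#'   element geometry (areas, P1 shape-function gradients).
#' @export
build_vessel_mesh <- function(length, diameter, injury = NULL, h = diameter / 10) {
  if (diameter < 30 || diameter > 100)
    warning("vessel diameter outside the typical 30-100 um arteriole range")
  if (h > diameter / 10) stop("element size h must be <= diameter/10")
  nx <- max(2L, as.integer(round(length / h)))
  ny <- max(2L, as.integer(round(diameter / h)))
  xs <- seq(0, length, length.out = nx + 1)
  y_bot <- rep(0, nx + 1)
  if (!is.null(injury) && !is.null(injury$depth) && injury$depth > 0) {
    w <- injury$width / 2; dep <- injury$depth
    xc <- if (is.null(injury$center_x) || !is.finite(injury$center_x))
      length / 2 else injury$center_x
    R <- (w^2 + dep^2) / (2 * dep)          # circular arc through chord ends
    inside <- abs(xs - xc) <= w
    y_bot[inside] <- -(sqrt(pmax(0, R^2 - (xs[inside] - xc)^2)) - (R - dep))
  }
  nodes <- matrix(0, (nx + 1) * (ny + 1), 2)
  idx <- function(i, j) (j - 1) * (nx + 1) + i   # i along x, j along y
  for (j in seq_len(ny + 1)) {
    eta <- (j - 1) / ny
    rows <- idx(seq_len(nx + 1), j)
    nodes[rows, 1] <- xs
    nodes[rows, 2] <- y_bot + eta * (diameter - y_bot)
  }
  tri <- matrix(0L, 2 * nx * ny, 3)
  k <- 0
  for (j in seq_len(ny)) for (i in seq_len(nx)) {
    n00 <- idx(i, j); n10 <- idx(i + 1, j)
    n01 <- idx(i, j + 1); n11 <- idx(i + 1, j + 1)
    tri[k + 1, ] <- c(n00, n10, n11)
    tri[k + 2, ] <- c(n00, n11, n01)
    k <- k + 2
  }
  be <- rbind(
    data.frame(n1 = idx(1, seq_len(ny)), n2 = idx(1, seq_len(ny) + 1),
               tag = "inlet"),
    data.frame(n1 = idx(nx + 1, seq_len(ny)), n2 = idx(nx + 1, seq_len(ny) + 1),
               tag = "outlet"),
    data.frame(n1 = idx(seq_len(nx), 1), n2 = idx(seq_len(nx) + 1, 1),
               tag = "wall"),
    data.frame(n1 = idx(seq_len(nx), ny + 1), n2 = idx(seq_len(nx) + 1, ny + 1),
               tag = "wall"))
  mesh <- structure(list(nodes = nodes, tri = tri, boundary_edges = be,
                         h = h, length = length, diameter = diameter,
                         injury = injury,
                         structured = list(nx = nx, ny = ny, xs = xs,
                                           y_bot = y_bot)),
                    class = "vessel_mesh")
  mesh$geom <- tri_geometry(mesh)
  if (any(mesh$geom$area <= 0)) stop("non-manifold geometry: inverted elements")
  mesh$boundary_nodes <- boundary_node_tags(mesh)
  mesh
}

# Cache per-element geometry: area and constant P1 shape-function gradients.
tri_geometry <- function(mesh) {
  t1 <- mesh$tri[, 1]; t2 <- mesh$tri[, 2]; t3 <- mesh$tri[, 3]
  x1 <- mesh$nodes[t1, 1]; y1 <- mesh$nodes[t1, 2]
  x2 <- mesh$nodes[t2, 1]; y2 <- mesh$nodes[t2, 2]
  x3 <- mesh$nodes[t3, 1]; y3 <- mesh$nodes[t3, 2]
  det <- (x2 - x1) * (y3 - y1) - (x3 - x1) * (y2 - y1)
  area <- det / 2
  gx <- cbind(y2 - y3, y3 - y1, y1 - y2) / det   # d(lambda_i)/dx
  gy <- cbind(x3 - x2, x1 - x3, x2 - x1) / det
  hel <- sqrt(2 * abs(area))                     # characteristic element size
  list(area = area, gx = gx, gy = gy, h = hel)
}

# Named list of node index vectors per boundary tag, plus `all`.
boundary_node_tags <- function(mesh) {
  be <- mesh$boundary_edges
  tags <- unique(be$tag)
  out <- lapply(tags, function(tg) {
    sel <- be$tag == tg
    sort(unique(c(be$n1[sel], be$n2[sel])))
  })
  names(out) <- tags
  out$all <- sort(unique(c(be$n1, be$n2)))
  out
}

#' @export
print.vessel_mesh <- function(x, ...) {
  cat(sprintf("Vessel mesh: %.0f x %.0f um channel, %d nodes, %d triangles (h = %.2g um)\n",
              x$length, x$diameter, nrow(x$nodes), nrow(x$tri), x$h))
  if (!is.null(x$injury) && !is.null(x$injury$depth) && x$injury$depth > 0)
    cat(sprintf("  injury indentation: depth %.1f um, width %.1f um\n",
                x$injury$depth, x$injury$width))
  invisible(x)
}

# Locate points in the mesh: returns triangle index (NA if outside).
# Structured fast path (column lookup) with brute-force fallback.
locate_points <- function(mesh, pts) {
  pts <- matrix(pts, ncol = 2)
  np <- nrow(pts)
  out <- rep(NA_integer_, np)
  st <- mesh$structured
  bary_ok <- function(tri_id, p) {
    v <- mesh$tri[tri_id, ]
    a <- mesh$nodes[v[1], ]; b <- mesh$nodes[v[2], ]; c3 <- mesh$nodes[v[3], ]
    det <- (b[1] - a[1]) * (c3[2] - a[2]) - (c3[1] - a[1]) * (b[2] - a[2])
    l2 <- ((p[1] - a[1]) * (c3[2] - a[2]) - (c3[1] - a[1]) * (p[2] - a[2])) / det
    l3 <- ((b[1] - a[1]) * (p[2] - a[2]) - (p[1] - a[1]) * (b[2] - a[2])) / det
    l1 <- 1 - l2 - l3
    eps <- -1e-9
    l1 >= eps && l2 >= eps && l3 >= eps
  }
  if (!is.null(st)) {
    nx <- st$nx; ny <- st$ny
    hx <- mesh$length / nx
    for (q in seq_len(np)) {
      p <- pts[q, ]
      i <- min(max(1L, as.integer(floor(p[1] / hx)) + 1L), nx)
      # candidate cells: the column's cells around the estimated row
      yb <- st$y_bot[i]
      eta <- (p[2] - yb) / (mesh$diameter - yb)
      j <- min(max(1L, as.integer(floor(eta * ny)) + 1L), ny)
      cand <- c()
      for (jj in max(1, j - 1):min(ny, j + 1))
        for (ii in max(1, i - 1):min(nx, i + 1)) {
          cell <- ((jj - 1) * nx + (ii - 1)) * 2
          cand <- c(cand, cell + 1, cell + 2)
        }
      for (tr in cand) if (bary_ok(tr, p)) { out[q] <- tr; break }
    }
    return(out)
  }
  for (q in seq_len(np)) {
    for (tr in seq_len(nrow(mesh$tri))) if (bary_ok(tr, pts[q, ])) {
      out[q] <- tr; break
    }
  }
  out
}

# Barycentric coordinates of points within given triangles (n x 3).
bary_coords <- function(mesh, pts, tri_id) {
  pts <- matrix(pts, ncol = 2)
  v1 <- mesh$tri[tri_id, 1]; v2 <- mesh$tri[tri_id, 2]; v3 <- mesh$tri[tri_id, 3]
  ax <- mesh$nodes[v1, 1]; ay <- mesh$nodes[v1, 2]
  bx <- mesh$nodes[v2, 1]; by <- mesh$nodes[v2, 2]
  cx <- mesh$nodes[v3, 1]; cy <- mesh$nodes[v3, 2]
  det <- (bx - ax) * (cy - ay) - (cx - ax) * (by - ay)
  l2 <- ((pts[, 1] - ax) * (cy - ay) - (cx - ax) * (pts[, 2] - ay)) / det
  l3 <- ((bx - ax) * (pts[, 2] - ay) - (pts[, 1] - ax) * (by - ay)) / det
  cbind(1 - l2 - l3, l2, l3)
}

# Lumped nodal areas (row sums of the consistent mass matrix): each element
# contributes A/3 to its three nodes. Units: um^2.
lumped_areas <- function(mesh) {
  w <- rep(mesh$geom$area / 3, 3)
  idx <- as.vector(mesh$tri)
  out <- numeric(nrow(mesh$nodes))
  agg <- tapply(w, idx, sum)
  out[as.integer(names(agg))] <- agg
  out
}

#' Write mesh and nodal fields as a legacy VTK (ASCII) file
#'
#' @param mesh `vessel_mesh`.
#' @param path output file.
#' @param point_data named list of nodal scalar vectors or n x 2 vector fields.
#' @export
write_vtk <- function(mesh, path, point_data = list()) {
  n <- nrow(mesh$nodes); m <- nrow(mesh$tri)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "clotflow fields", "ASCII",
               "DATASET UNSTRUCTURED_GRID", sprintf("POINTS %d float", n)), con)
  writeLines(apply(cbind(mesh$nodes, 0), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELLS %d %d", m, 4 * m), con)
  writeLines(apply(cbind(3, mesh$tri - 1), 1, paste, collapse = " "), con)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(rep("5", m), con)
  if (length(point_data)) {
    writeLines(sprintf("POINT_DATA %d", n), con)
    for (nm in names(point_data)) {
      v <- point_data[[nm]]
      if (is.matrix(v)) {
        writeLines(sprintf("VECTORS %s float", nm), con)
        writeLines(apply(cbind(v, 0), 1, paste, collapse = " "), con)
      } else {
        writeLines(c(sprintf("SCALARS %s float 1", nm), "LOOKUP_TABLE default"),
                   con)
        writeLines(format(v, digits = 7), con)
      }
    }
  }
  invisible(path)
}
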