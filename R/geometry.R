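# Planar geometry helpers shared by the growth-cone, encounter and
# colocalization modules. Polygons are n x 2 matrices (x, y in um), open or
# closed; polylines are n x 2 matrices of ordered vertices.

as_poly <- function(p, name = "polygon") {
  p <- as.matrix(p)
  if (ncol(p) != 2L || nrow(p) < 3L)
    abort("%s must be an n x 2 matrix with n >= 3", name)
  storage.mode(p) <- "double"
  # drop a closing vertex; all routines treat polygons as implicitly closed
  if (nrow(p) > 3L && all(p[1L, ] == p[nrow(p), ])) p <- p[-nrow(p), , drop = FALSE]
  p
}

#' Polygon area (shoelace formula)
#'
#' @param poly n x 2 matrix of vertices in um.
#' @return area in um^2 (always >= 0).
#' @export
polygon_area <- function(poly) {
  p <- as_poly(poly)
  x <- p[, 1L]; y <- p[, 2L]
  xs <- c(x[-1L], x[1L]); ys <- c(y[-1L], y[1L])
  abs(sum(x * ys - xs * y)) / 2
}

#' Point-in-polygon test
#'
#' Wraps [mgcv::in.out()]. Points exactly on the boundary are resolved with
#' an explicit on-segment test and reported as inside, so that region
#' assignment tie-breaks are deterministic.
#'
#' @param pts n x 2 matrix of query points.
#' @param poly polygon vertex matrix.
#' @param boundary_tol distance (um) below which a point counts as on the
#'   boundary, hence inside.
#' @return logical vector of length n.
#' @export
point_in_polygon <- function(pts, poly, boundary_tol = 1e-9) {
  p <- as_poly(poly)
  pts <- matrix(as.numeric(as.matrix(pts)), ncol = 2L)
  bnd <- rbind(p, p[1L, ])
  inside <- mgcv::in.out(bnd, pts)
  onb <- dist_to_polyline(pts, bnd) <= boundary_tol
  inside | onb
}

# Reference ray-crossing implementation; kept independent of mgcv as a test
# oracle for point-in-polygon assignment.
point_in_polygon_ray <- function(pts, poly) {
  p <- as_poly(poly)
  n <- nrow(p)
  apply(matrix(as.numeric(as.matrix(pts)), ncol = 2L), 1L, function(q) {
    x <- q[1L]; y <- q[2L]; crossings <- 0L
    for (i in seq_len(n)) {
      j <- if (i == n) 1L else i + 1L
      x1 <- p[i, 1L]; y1 <- p[i, 2L]; x2 <- p[j, 1L]; y2 <- p[j, 2L]
      if ((y1 > y) != (y2 > y)) {
        xint <- x1 + (y - y1) / (y2 - y1) * (x2 - x1)
        if (x < xint) crossings <- crossings + 1L
      }
    }
    crossings %% 2L == 1L
  })
}

# Distance from each point to a polyline (min over segments). pts: n x 2,
# path: m x 2 with m >= 2.
dist_to_polyline <- function(pts, path) {
  pts <- matrix(as.numeric(as.matrix(pts)), ncol = 2L)
  path <- as.matrix(path)
  if (nrow(path) < 2L) abort("polyline needs >= 2 vertices")
  d <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(path) - 1L)) {
    a <- path[i, ]; b <- path[i + 1L, ]
    ab <- b - a
    len2 <- sum(ab^2)
    if (len2 == 0) {
      di <- sqrt((pts[, 1L] - a[1L])^2 + (pts[, 2L] - a[2L])^2)
    } else {
      t <- ((pts[, 1L] - a[1L]) * ab[1L] + (pts[, 2L] - a[2L]) * ab[2L]) / len2
      t <- pmin(1, pmax(0, t))
      px <- a[1L] + t * ab[1L]; py <- a[2L] + t * ab[2L]
      di <- sqrt((pts[, 1L] - px)^2 + (pts[, 2L] - py)^2)
    }
    d <- pmin(d, di)
  }
  d
}

polyline_length <- function(path) {
  path <- as.matrix(path)
  if (nrow(path) < 2L) return(0)
  sum(sqrt(rowSums(diff(path)^2)))
}

# Do segments (a1,a2) and (b1,b2) properly intersect (excluding collinear
# touch)? Returns TRUE/FALSE.
segments_intersect <- function(a1, a2, b1, b2) {
  cross <- function(o, p, q) (p[1] - o[1]) * (q[2] - o[2]) - (p[2] - o[2]) * (q[1] - o[1])
  d1 <- cross(b1, b2, a1); d2 <- cross(b1, b2, a2)
  d3 <- cross(a1, a2, b1); d4 <- cross(a1, a2, b2)
  ((d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0)) &&
    ((d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0))
}

# Does a polyline cross another polyline anywhere? Returns the index of the
# last trajectory segment that crosses, or 0L.
last_crossing_segment <- function(traj, path) {
  traj <- as.matrix(traj); path <- as.matrix(path)
  hit <- 0L
  for (i in seq_len(nrow(traj) - 1L)) {
    for (j in seq_len(nrow(path) - 1L)) {
      if (segments_intersect(traj[i, ], traj[i + 1L, ], path[j, ], path[j + 1L, ])) {
        hit <- i
        break
      }
    }
  }
  hit
}

# Signed angle helpers (degrees). Direction of a 2-vector.
vec_angle <- function(v) atan2(v[2L], v[1L]) * 180 / pi

# Smallest absolute angle between two directions, treating a direction and
# its opposite as distinct (range [0, 180]).
angle_between <- function(a, b) {
  d <- abs(((a - b) %% 360 + 360) %% 360)
  min(d, 360 - d)
}

# Angle between a direction and an undirected line/tangent (range [0, 90]).
angle_to_line <- function(a, tangent) {
  d <- angle_between(a, tangent)
  min(d, 180 - d)
}

# Rasterize a polygon onto a square grid of resolution `res` um/px.
# Returns list(mask, origin = c(x0, y0), res): pixel [i, j] covers
# x in origin[1] + (j-1..j)*res, y in origin[2] + (i-1..i)*res, and the mask
# tests the pixel center.
rasterize_polygon <- function(poly, res = 0.05, pad = 1) {
  p <- as_poly(poly)
  x0 <- min(p[, 1L]) - pad; y0 <- min(p[, 2L]) - pad
  nx <- ceiling((max(p[, 1L]) + pad - x0) / res)
  ny <- ceiling((max(p[, 2L]) + pad - y0) / res)
  xc <- x0 + (seq_len(nx) - 0.5) * res
  yc <- y0 + (seq_len(ny) - 0.5) * res
  pts <- cbind(rep(xc, each = ny), rep(yc, times = nx))
  m <- matrix(point_in_polygon(pts, p), nrow = ny, ncol = nx)
  list(mask = m * 1, origin = c(x0, y0), res = res)
}

# Trace the outer contour of a binary mask back to um coordinates using the
# raster geometry produced by rasterize_polygon().
mask_to_polygon <- function(mask, origin, res) {
  lbl <- EBImage::bwlabel(EBImage::Image(t(mask)))  # EBImage is x-major
  if (max(lbl) == 0) abort("mask is empty; nothing to trace")
  ct <- EBImage::ocontour(lbl)
  sizes <- vapply(ct, nrow, integer(1))
  c0 <- ct[[which.max(sizes)]]  # 0-based (x, y) pixel indices
  cbind(origin[1L] + (c0[, 1L] + 0.5) * res,
        origin[2L] + (c0[, 2L] + 0.5) * res)
}
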