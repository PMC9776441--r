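# Orthographic depth rendering and back-projection: partial views are the
# visible portion of the surface from a single viewpoint, mimicking the
# incomplete clouds produced by back-projecting depth images. Because the
# returned points sit at ray-surface intersections on pixel centers, a
# partial view is never a subset of the area-uniform complete sampling.

#' Specify a rendering viewpoint
#'
#' @param azimuth angle in radians around the z axis.
#' @param elevation angle in radians above the xy plane.
#' @param resolution depth-buffer side length in pixels (>= 32).
#' @param distance camera distance in multiples of the (normalized) shape
#'   radius; must exceed 1 so the camera sits outside the unit sphere.
#' @return a `view_spec` list.
#' @export
view_spec <- function(azimuth, elevation, resolution = 160L, distance = 2.5) {
  stopifnot(resolution >= 32L, distance > 1)
  structure(list(azimuth = azimuth, elevation = elevation,
                 resolution = as.integer(resolution), distance = distance),
            class = "view_spec")
}

#' Draw random viewpoints
#'
#' Azimuth uniform on `[0, 2*pi)`, elevation uniform on `[-pi/3, pi/3]`
#' (avoiding the degenerate poles).
#'
#' @param n number of views.
#' @param rng_seed integer seed.
#' @param resolution,distance forwarded to [view_spec()].
#' @return list of `view_spec`.
#' @export
random_views <- function(n, rng_seed = 1L, resolution = 160L, distance = 2.5) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  az <- stats::runif(n, 0, 2 * pi)
  el <- stats::runif(n, -pi / 3, pi / 3)
  lapply(seq_len(n), function(i) view_spec(az[i], el[i], resolution, distance))
}

# Orthonormal camera frame: viewing direction v (from origin toward the
# camera) plus in-plane axes e1, e2.
.camera_frame <- function(view) {
  v <- c(cos(view$elevation) * cos(view$azimuth),
         cos(view$elevation) * sin(view$azimuth),
         sin(view$elevation))
  up <- if (abs(v[3]) < 0.99) c(0, 0, 1) else c(0, 1, 0)
  e1 <- .unit(c(up[2] * v[3] - up[3] * v[2],
                up[3] * v[1] - up[1] * v[3],
                up[1] * v[2] - up[2] * v[1]))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2],
          v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  list(v = v, e1 = e1, e2 = e2)
}

# Rasterize a mesh into a depth buffer (orthographic camera at distance
# view$distance along the frame's v axis, image plane spanning
# [-extent, extent]^2). Returns the buffer plus the frame for back-projection.
.render_depth <- function(mesh, view, extent = 1.1) {
  fr <- .camera_frame(view)
  res <- view$resolution
  d <- view$distance
  verts <- mesh$vertices
  px <- verts %*% fr$e1
  py <- verts %*% fr$e2
  pz <- d - verts %*% fr$v          # depth from the camera plane
  step <- 2 * extent / res
  centers <- -extent + (seq_len(res) - 0.5) * step
  zbuf <- matrix(Inf, res, res)     # [ix, iy]
  f <- mesh$faces
  for (k in seq_len(nrow(f))) {
    i1 <- f[k, 1]; i2 <- f[k, 2]; i3 <- f[k, 3]
    x1 <- px[i1]; x2 <- px[i2]; x3 <- px[i3]
    y1 <- py[i1]; y2 <- py[i2]; y3 <- py[i3]
    det <- (y2 - y3) * (x1 - x3) + (x3 - x2) * (y1 - y3)
    if (abs(det) < 1e-14) next      # edge-on or degenerate in projection
    ix0 <- max(1L, ceiling((min(x1, x2, x3) + extent) / step + 0.5 - 1))
    ix1 <- min(res, floor((max(x1, x2, x3) + extent) / step + 0.5))
    iy0 <- max(1L, ceiling((min(y1, y2, y3) + extent) / step + 0.5 - 1))
    iy1 <- min(res, floor((max(y1, y2, y3) + extent) / step + 0.5))
    if (ix0 > ix1 || iy0 > iy1) next
    cx <- centers[ix0:ix1]; cy <- centers[iy0:iy1]
    gx <- rep(cx, times = length(cy))
    gy <- rep(cy, each = length(cx))
    w1 <- ((y2 - y3) * (gx - x3) + (x3 - x2) * (gy - y3)) / det
    w2 <- ((y3 - y1) * (gx - x3) + (x1 - x3) * (gy - y3)) / det
    w3 <- 1 - w1 - w2
    inside <- w1 >= 0 & w2 >= 0 & w3 >= 0
    if (!any(inside)) next
    depth <- w1 * pz[i1] + w2 * pz[i2] + w3 * pz[i3]
    ii <- rep(ix0:ix1, times = length(cy))[inside]
    jj <- rep(iy0:iy1, each = length(cx))[inside]
    dep <- depth[inside]
    lin <- cbind(ii, jj)
    better <- dep < zbuf[lin]
    if (any(better)) zbuf[lin[better, , drop = FALSE]] <- dep[better]
  }
  list(zbuf = zbuf, frame = fr, centers = centers, extent = extent)
}

#' Render a partial point cloud from one viewpoint
#'
#' Renders an orthographic depth image of the mesh, back-projects every pixel
#' with finite depth to its 3D hit point, and samples `n` of those points
#' (with replacement when fewer than `n` pixels are hit). All returned points
#' are visible from the camera: each lies at the first intersection of its
#' pixel's view ray with the surface.
#'
#' @param mesh a normalized `surface_mesh`.
#' @param view a `view_spec`.
#' @param n number of points to return.
#' @param rng_seed integer seed for the pixel subsample.
#' @return N x 3 matrix of visible surface points.
#' @export
render_partial <- function(mesh, view, n, rng_seed = 1L) {
  stopifnot(n >= 1L)
  r <- .render_depth(mesh, view)
  hit <- which(is.finite(r$zbuf), arr.ind = TRUE)
  if (nrow(hit) == 0L) {
    stop("view misses the object: no pixel hits the mesh", call. = FALSE)
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  pick <- sample.int(nrow(hit), n, replace = nrow(hit) < n)
  ix <- hit[pick, 1L]; iy <- hit[pick, 2L]
  dep <- r$zbuf[cbind(ix, iy)]
  fr <- r$frame
  x <- r$centers[ix]; y <- r$centers[iy]
  pts <- outer(x, fr$e1) + outer(y, fr$e2) + outer(view$distance - dep, fr$v)
  pts
}
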