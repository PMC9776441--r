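# Area-uniform surface sampling and the normalization convention shared by
# complete clouds and their partial views.

#' Sample points area-uniformly from a mesh surface
#'
#' Faces are drawn with probability proportional to their area and points are
#' placed uniformly inside each drawn triangle (square-root barycentric
#' warp). Deterministic for a fixed seed.
#'
#' @param mesh a `surface_mesh`.
#' @param n number of points (>= 1).
#' @param rng_seed integer seed.
#' @return N x 3 matrix with an integer attribute `"face"` giving the source
#'   face of each point.
#' @export
sample_complete <- function(mesh, n, rng_seed = 1L) {
  stopifnot(n >= 1L)
  if (is.null(mesh$faces) || nrow(mesh$faces) == 0L) {
    stop("cannot sample from an empty mesh", call. = FALSE)
  }
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  areas <- face_areas(mesh)
  fidx <- sample.int(length(areas), n, replace = TRUE, prob = areas)
  r1 <- sqrt(stats::runif(n))
  r2 <- stats::runif(n)
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[fidx, 1], , drop = FALSE]
  b <- v[f[fidx, 2], , drop = FALSE]
  cc <- v[f[fidx, 3], , drop = FALSE]
  pts <- (1 - r1) * a + r1 * (1 - r2) * b + r1 * r2 * cc
  attr(pts, "face") <- fidx
  pts
}

#' Normalize a point cloud to the unit sphere
#'
#' Centers the cloud at its centroid and scales so the farthest point has
#' norm 1. The returned transform is applied unchanged to the partial views
#' of the same sample so that metric values are comparable across shapes.
#'
#' @param points N x 3 matrix.
#' @param transform optional transform (list with `center`, `scale`) reused
#'   from another cloud; when `NULL` it is computed from `points`.
#' @return list with `points` (normalized), `center`, `scale`.
#' @export
normalize_cloud <- function(points, transform = NULL) {
  points <- as.matrix(points)
  if (is.null(transform)) {
    center <- colMeans(points)
    centered <- sweep(points, 2L, center)
    scale <- max(sqrt(rowSums(centered^2)))
    if (scale == 0) scale <- 1
  } else {
    center <- transform$center
    scale <- transform$scale
    centered <- sweep(points, 2L, center)
  }
  list(points = centered / scale, center = center, scale = scale)
}

#' Invert the unit-sphere normalization
#' @param points normalized N x 3 matrix.
#' @param transform list with `center` and `scale` from [normalize_cloud()].
#' @return N x 3 matrix in the original coordinates.
#' @export
denormalize_cloud <- function(points, transform) {
  sweep(points * transform$scale, 2L, transform$center, "+")
}

# Apply a cloud transform to mesh vertices.
normalize_mesh <- function(mesh, transform) {
  v <- sweep(mesh$vertices, 2L, transform$center) / transform$scale
  new_surface_mesh(v, mesh$faces)
}
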