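# Synthetic watertight tubular meshes emulating segmented intracranial
# vessel/aneurysm surface models: capped swept tubes along smooth random
# centerlines, Y-shaped bifurcations, and tubes carrying an ellipsoidal bleb.

new_surface_mesh <- function(vertices, faces) {
  storage.mode(vertices) <- "double"
  storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3L, ncol(faces) == 3L,
            min(faces) >= 1L, max(faces) <= nrow(vertices))
  m <- list(vertices = vertices, faces = faces,
            watertight = mesh_is_watertight(list(vertices = vertices, faces = faces)))
  class(m) <- "surface_mesh"
  m
}

#' Check edge-manifold closedness of a triangle mesh
#'
#' A mesh is considered watertight when every undirected edge is shared by
#' exactly two faces. Meshes assembled from several closed components (for
#' example a tube with a bleb) pass this check even though the components
#' interpenetrate.
#'
#' @param mesh a `surface_mesh` or a list with `vertices` and `faces`.
#' @return logical scalar.
#' @export
mesh_is_watertight <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  all(table(key) == 2L)
}

face_areas <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  b <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  cx <- a[, 2] * b[, 3] - a[, 3] * b[, 2]
  cy <- a[, 3] * b[, 1] - a[, 1] * b[, 3]
  cz <- a[, 1] * b[, 2] - a[, 2] * b[, 1]
  0.5 * sqrt(cx^2 + cy^2 + cz^2)
}

.unit <- function(v) v / sqrt(sum(v^2))

# Parallel-transport orthonormal frames along a polyline (n x 3).
.pt_frames <- function(cl) {
  n <- nrow(cl)
  tang <- rbind(cl[2, ] - cl[1, ],
                (cl[3:n, , drop = FALSE] - cl[1:(n - 2), , drop = FALSE]) / 2,
                cl[n, ] - cl[n - 1, ])
  tang <- tang / sqrt(rowSums(tang^2))
  nrm <- matrix(0, n, 3)
  ref <- if (abs(tang[1, 3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  nrm[1, ] <- .unit(ref - sum(ref * tang[1, ]) * tang[1, ])
  for (i in 2:n) {
    v <- nrm[i - 1, ] - sum(nrm[i - 1, ] * tang[i, ]) * tang[i, ]
    nrm[i, ] <- .unit(v)
  }
  bin <- cbind(tang[, 2] * nrm[, 3] - tang[, 3] * nrm[, 2],
               tang[, 3] * nrm[, 1] - tang[, 1] * nrm[, 3],
               tang[, 1] * nrm[, 2] - tang[, 2] * nrm[, 1])
  list(tangent = tang, normal = nrm, binormal = bin)
}

# Closed capped tube swept along a centerline. Radial noise perturbs ring
# vertices by up to noise_scale * radius.
.make_tube_mesh <- function(centerline, radius, n_circ = 16L, noise_scale = 0) {
  n_seg <- nrow(centerline)
  fr <- .pt_frames(centerline)
  theta <- seq(0, 2 * pi, length.out = n_circ + 1L)[-(n_circ + 1L)]
  verts <- matrix(0, n_seg * n_circ + 2L, 3)
  for (i in seq_len(n_seg)) {
    r <- radius
    if (noise_scale > 0) r <- radius * (1 + stats::runif(n_circ, -noise_scale, noise_scale))
    ring <- centerline[rep(i, n_circ), ] +
      r * (cos(theta) %o% c(1, 1, 1) * matrix(fr$normal[i, ], n_circ, 3, byrow = TRUE) +
           sin(theta) %o% c(1, 1, 1) * matrix(fr$binormal[i, ], n_circ, 3, byrow = TRUE))
    verts[(i - 1L) * n_circ + seq_len(n_circ), ] <- ring
  }
  c0 <- n_seg * n_circ + 1L  # start cap center
  c1 <- n_seg * n_circ + 2L  # end cap center
  verts[c0, ] <- centerline[1, ]
  verts[c1, ] <- centerline[n_seg, ]
  faces <- matrix(0L, 0L, 3L)
  quads <- vector("list", n_seg - 1L)
  for (i in seq_len(n_seg - 1L)) {
    a <- (i - 1L) * n_circ + seq_len(n_circ)
    b <- i * n_circ + seq_len(n_circ)
    an <- a[c(2:n_circ, 1L)]
    bn <- b[c(2:n_circ, 1L)]
    quads[[i]] <- rbind(cbind(a, b, bn), cbind(a, bn, an))
  }
  faces <- do.call(rbind, quads)
  ring1 <- seq_len(n_circ)
  ringN <- (n_seg - 1L) * n_circ + seq_len(n_circ)
  cap0 <- cbind(rep(c0, n_circ), ring1[c(2:n_circ, 1L)], ring1)
  cap1 <- cbind(rep(c1, n_circ), ringN, ringN[c(2:n_circ, 1L)])
  new_surface_mesh(verts, rbind(faces, cap0, cap1))
}

# Ellipsoid as a closed UV sphere scaled by semi-axes and rotated.
.make_ellipsoid_mesh <- function(center, semi_axes, rot = diag(3),
                                 n_stack = 10L, n_slice = 14L) {
  phi <- seq(0, pi, length.out = n_stack + 2L)[2:(n_stack + 1L)]
  theta <- seq(0, 2 * pi, length.out = n_slice + 1L)[-(n_slice + 1L)]
  verts <- matrix(0, n_stack * n_slice + 2L, 3)
  for (i in seq_len(n_stack)) {
    ring <- cbind(sin(phi[i]) * cos(theta), sin(phi[i]) * sin(theta),
                  rep(cos(phi[i]), n_slice))
    verts[(i - 1L) * n_slice + seq_len(n_slice), ] <- ring
  }
  npole <- n_stack * n_slice + 1L
  spole <- n_stack * n_slice + 2L
  verts[npole, ] <- c(0, 0, 1)
  verts[spole, ] <- c(0, 0, -1)
  verts <- sweep(verts, 2L, semi_axes, "*") %*% t(rot)
  verts <- sweep(verts, 2L, center, "+")
  faces <- list()
  for (i in seq_len(n_stack - 1L)) {
    a <- (i - 1L) * n_slice + seq_len(n_slice)
    b <- i * n_slice + seq_len(n_slice)
    an <- a[c(2:n_slice, 1L)]
    bn <- b[c(2:n_slice, 1L)]
    faces[[i]] <- rbind(cbind(a, b, bn), cbind(a, bn, an))
  }
  top <- seq_len(n_slice)
  bot <- (n_stack - 1L) * n_slice + seq_len(n_slice)
  faces[[n_stack]] <- rbind(
    cbind(rep(npole, n_slice), top, top[c(2:n_slice, 1L)]),
    cbind(rep(spole, n_slice), bot[c(2:n_slice, 1L)], bot))
  new_surface_mesh(verts, do.call(rbind, faces))
}

.concat_meshes <- function(...) {
  ms <- list(...)
  off <- 0L
  verts <- list(); faces <- list()
  for (m in ms) {
    verts[[length(verts) + 1L]] <- m$vertices
    faces[[length(faces) + 1L]] <- m$faces + off
    off <- off + nrow(m$vertices)
  }
  new_surface_mesh(do.call(rbind, verts), do.call(rbind, faces))
}

# Tube parameters drawn from the current RNG stream; shared between the
# plain tube and the aneurysm variant so both see the same centerline.
.draw_tube_params <- function(n_seg = 40L) {
  t <- seq(-1, 1, length.out = n_seg)
  ay <- stats::runif(1, 0.1, 0.3); wy <- stats::runif(1, 1, 2.5); py <- stats::runif(1, 0, 2 * pi)
  az <- stats::runif(1, 0.1, 0.3); wz <- stats::runif(1, 1, 2.5); pz <- stats::runif(1, 0, 2 * pi)
  radius <- stats::runif(1, 0.12, 0.2)
  centerline <- cbind(t, ay * sin(wy * pi * t + py), az * sin(wz * pi * t + pz))
  list(centerline = centerline, radius = radius)
}

#' Generate a synthetic tubular or aneurysm-bearing surface mesh
#'
#' Produces watertight triangle meshes that stand in for segmented vessel
#' surface models: `"tube"` is a capped tube swept along a smooth random
#' centerline, `"bifurcation"` adds a second tube branching off the first
#' (a Y shape), and `"aneurysm"` attaches an ellipsoidal bleb to the tube
#' wall. Output is deterministic for a fixed seed; the `"aneurysm"` variant
#' shares its centerline with the `"tube"` variant at the same seed.
#'
#' @param kind one of `"tube"`, `"bifurcation"`, `"aneurysm"`.
#' @param rng_seed integer seed.
#' @param noise_scale radial vertex jitter as a fraction of the tube radius,
#'   in `[0, 0.1]`.
#' @return a `surface_mesh` (vertices, faces, watertight flag).
#' @export
generate_toy_shape <- function(kind = c("tube", "bifurcation", "aneurysm"),
                               rng_seed = 1L, noise_scale = 0) {
  if (length(kind) != 1L || !kind %in% c("tube", "bifurcation", "aneurysm")) {
    stop("unknown shape kind: ", paste(kind, collapse = ", "), call. = FALSE)
  }
  stopifnot(noise_scale >= 0, noise_scale <= 0.1)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  p <- .draw_tube_params()
  tube <- .make_tube_mesh(p$centerline, p$radius, noise_scale = noise_scale)
  if (kind == "tube") return(tube)
  if (kind == "bifurcation") {
    # Branch starts on the trunk centerline (its start cap is buried inside
    # the trunk) and leaves at a 30-55 degree angle.
    i0 <- sample(18:28, 1L)
    start <- p$centerline[i0, ]
    ang <- stats::runif(1, pi / 6, pi * 55 / 180)
    rot <- stats::runif(1, 0, 2 * pi)
    dir0 <- .unit(p$centerline[i0 + 1L, ] - p$centerline[i0 - 1L, ])
    perp <- .unit(if (abs(dir0[3]) < 0.9) c(-dir0[2], dir0[1], 0) else c(1, 0, 0))
    perp2 <- c(dir0[2] * perp[3] - dir0[3] * perp[2],
               dir0[3] * perp[1] - dir0[1] * perp[3],
               dir0[1] * perp[2] - dir0[2] * perp[1])
    bdir <- .unit(cos(ang) * dir0 + sin(ang) * (cos(rot) * perp + sin(rot) * perp2))
    blen <- stats::runif(1, 0.6, 0.9)
    s <- seq(0, 1, length.out = 20L)
    bend <- stats::runif(3, -0.15, 0.15)
    bcl <- sweep(outer(s * blen, bdir), 2L, start, "+") +
      outer(s^2, bend)
    branch <- .make_tube_mesh(bcl, p$radius * stats::runif(1, 0.7, 0.95),
                              noise_scale = noise_scale)
    return(.concat_meshes(tube, branch))
  }
  # aneurysm: ellipsoidal bleb centered just off the tube wall
  i0 <- sample(12:28, 1L)
  fr <- .pt_frames(p$centerline)
  ang <- stats::runif(1, 0, 2 * pi)
  u <- cos(ang) * fr$normal[i0, ] + sin(ang) * fr$binormal[i0, ]
  rb <- p$radius * stats::runif(1, 1.2, 1.8)
  center <- p$centerline[i0, ] + (0.8 * p$radius + 0.4 * rb) * u
  ax <- rb * c(1, stats::runif(1, 0.75, 0.95), stats::runif(1, 0.8, 1))
  bleb <- .make_ellipsoid_mesh(center, ax)
  .concat_meshes(tube, bleb)
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
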