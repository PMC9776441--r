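# Refinement stage: a minimum-spanning-tree expansion penalty discourages
# individual decoded patches from spreading over each other, and minimum
# density sampling merges the coarse cloud (plus, optionally, the observed
# partial points) down to the final refined cloud while equalizing local
# density.

#' Euclidean minimum spanning tree of a point set
#'
#' Prim's algorithm on the complete Euclidean graph, O(M^2). Ties are broken
#' toward the smaller point index, so the edge list is deterministic.
#'
#' @param points M x 3 matrix, M >= 2.
#' @return data.frame with columns `u`, `v`, `w` (M-1 rows).
#' @export
euclidean_mst <- function(points) {
  points <- as.matrix(points)
  m <- nrow(points)
  stopifnot(m >= 2L)
  d <- .cross_dist(points, points)
  in_tree <- logical(m)
  in_tree[1L] <- TRUE
  best <- d[1L, ]
  parent <- rep(1L, m)
  edges <- matrix(0, m - 1L, 3L)
  for (e in seq_len(m - 1L)) {
    cand <- which(!in_tree)
    j <- cand[which.min(best[cand])]
    edges[e, ] <- c(parent[j], j, best[j])
    in_tree[j] <- TRUE
    upd <- !in_tree & d[j, ] < best
    parent[upd] <- j
    best[upd] <- d[j, upd]
  }
  data.frame(u = as.integer(edges[, 1]), v = as.integer(edges[, 2]),
             w = edges[, 3])
}

.as_patch_list <- function(patches) {
  if (is.list(patches) && !is.null(patches$points) && !is.null(patches$K)) {
    return(split_patches(patches$points, patches$K))
  }
  if (is.matrix(patches)) return(list(patches))
  stopifnot(is.list(patches))
  lapply(patches, as.matrix)
}

#' Expansion penalty over patch minimum spanning trees
#'
#' For each patch, builds the Euclidean MST, takes the mean edge length
#' `l_i`, and sums the lengths of edges not shorter than `lambda * l_i`; the
#' total is normalized by `K * N` (patch count times points per patch).
#' A patch whose MST edges are all equal (e.g. an equilateral triangle) is
#' never penalized for `lambda > 1`. Scaling all coordinates by `c` scales
#' the penalty by `c` (the threshold is scale-free because `l_i` scales
#' too).
#'
#' @param patches list of M x 3 matrices (equal M), a single matrix, or a
#'   list with `points` and `K` as returned by the decoder.
#' @param lambda threshold multiplier on the mean MST edge length.
#' @return non-negative scalar.
#' @export
expansion_penalty <- function(patches, lambda = 1.5) {
  pl <- .as_patch_list(patches)
  sizes <- vapply(pl, nrow, integer(1))
  if (any(sizes < 2L)) stop("each patch needs at least 2 points", call. = FALSE)
  stopifnot(length(unique(sizes)) == 1L)
  total <- 0
  for (p in pl) {
    mst <- euclidean_mst(p)
    li <- mean(mst$w)
    total <- total + sum(mst$w[mst$w >= lambda * li])
  }
  total / (length(pl) * sizes[1])
}

# Differentiable expansion penalty: the MST and the indicator are computed
# on detached values; gradients flow through the retained edge lengths
# (straight-through on the indicator).
.ag_expansion_penalty <- function(coarse, K, lambda = 1.5) {
  pts <- ag_value(coarse)
  M <- nrow(pts) / K
  retained <- list()
  for (p in seq_len(K)) {
    off <- (p - 1L) * M
    mst <- euclidean_mst(pts[off + seq_len(M), , drop = FALSE])
    keep <- mst$w >= lambda * mean(mst$w) & mst$w > 1e-12
    if (any(keep)) {
      retained[[length(retained) + 1L]] <-
        cbind(off + mst$u[keep], off + mst$v[keep])
    }
  }
  edges <- if (length(retained)) do.call(rbind, retained) else matrix(0L, 0L, 2L)
  ag_edge_length_sum(coarse, edges, norm = K * M)
}

#' Minimum density sampling
#'
#' Greedy subsampling: the first point is the one nearest the input
#' centroid; each subsequent step selects the candidate with the lowest
#' Gaussian-kernel density with respect to the already-selected points.
#' Deterministic for a fixed input order (argmin ties go to the smaller
#' index).
#'
#' @param cloud N x 3 matrix.
#' @param n_out number of points to keep (`<= N`).
#' @param sigma kernel bandwidth, in the same (normalized) units as the
#'   cloud.
#' @param rng_seed accepted for interface symmetry; the procedure is
#'   deterministic and does not consume randomness.
#' @return `n_out` x 3 matrix with integer attribute `"index"` giving the
#'   selected rows of `cloud`.
#' @export
minimum_density_sample <- function(cloud, n_out, sigma = 0.05, rng_seed = NULL) {
  cloud <- as.matrix(cloud)
  n <- nrow(cloud)
  if (n_out > n) stop("n_out exceeds the cloud size", call. = FALSE)
  centroid <- colMeans(cloud)
  first <- which.min(rowSums(sweep(cloud, 2L, centroid)^2))
  selected <- mds_select_cpp(cloud, as.integer(n_out), sigma, as.integer(first))
  out <- cloud[selected, , drop = FALSE]
  attr(out, "index") <- selected
  out
}

#' Merge and refine a coarse cloud
#'
#' Concatenates the coarse cloud with the partial input (when
#' `merge_partial`) and reduces the union to `n_out` points by minimum
#' density sampling.
#'
#' @param coarse (K*M) x 3 decoded coarse cloud.
#' @param partial partial input cloud or `NULL`.
#' @param n_out output cardinality.
#' @param merge_partial include the partial points in the merged pool.
#' @param sigma MDS kernel bandwidth.
#' @return `n_out` x 3 matrix, a subset of the merged input (attribute
#'   `"index"` indexes into the merged pool).
#' @export
refine <- function(coarse, partial = NULL, n_out, merge_partial = TRUE,
                   sigma = 0.05) {
  pool <- as.matrix(coarse)
  if (merge_partial && !is.null(partial)) pool <- rbind(pool, as.matrix(partial))
  if (nrow(pool) < n_out) {
    stop("coarse plus partial must contain at least n_out points", call. = FALSE)
  }
  minimum_density_sample(pool, n_out, sigma = sigma)
}
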