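# Independent reference implementations used as oracles: literal loops over
# the defining formulas, exhaustive search, and (for larger assignment
# problems) scipy's Hungarian solver called through the system python.

vc <- asNamespace("vesselcomplete")

rand_cloud <- function(n, scale = 1) matrix(stats::runif(n * 3, -scale, scale), n)

cross_dist_oracle <- function(a, b) {
  d <- matrix(0, nrow(a), nrow(b))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b)))
      d[i, j] <- sqrt(sum((a[i, ] - b[j, ])^2))
  d
}

chamfer_oracle <- function(a, b) {
  d <- cross_dist_oracle(a, b)
  0.5 * (mean(apply(d, 1, min)) + mean(apply(d, 2, min)))
}

fscore_oracle <- function(pred, gt, thr) {
  d <- cross_dist_oracle(pred, gt)
  p <- mean(apply(d, 1, min) <= thr)
  r <- mean(apply(d, 2, min) <= thr)
  if (p + r == 0) 0 else 2 * p * r / (p + r)
}

all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) cbind(i, p + (p >= i))))
}

emd_perm_oracle <- function(a, b) {
  d <- cross_dist_oracle(a, b)
  n <- nrow(a)
  min(apply(all_perms(n), 1, function(p) mean(d[cbind(seq_len(n), p)])))
}

# Hungarian oracle via scipy for problems too large to enumerate.
emd_scipy_oracle <- function(a, b) {
  f <- tempfile(fileext = ".csv")
  d <- cross_dist_oracle(a, b)
  utils::write.table(d, f, row.names = FALSE, col.names = FALSE, sep = ",")
  code <- paste0(
    "import numpy as np; from scipy.optimize import linear_sum_assignment as l; ",
    "d = np.loadtxt('", f, "', delimiter=','); r, c = l(d); ",
    "print(repr(float(d[r, c].mean())))")
  as.numeric(system2("python", c("-c", shQuote(code)), stdout = TRUE))
}

# Literal per-edge loop over the edge-convolution formula with an explicit
# two-layer perceptron.
edge_conv_oracle <- function(features, idx, weights, reduce = TRUE) {
  W1 <- vc$ag_value(weights$mlp[[1]]$W); b1 <- vc$ag_value(weights$mlp[[1]]$b)
  W2 <- vc$ag_value(weights$mlp[[2]]$W); b2 <- vc$ag_value(weights$mlp[[2]]$b)
  n <- nrow(features); k <- ncol(idx)
  ef <- matrix(0, n * k, ncol(W2))
  for (i in seq_len(n)) {
    for (j in seq_len(k)) {
      e <- c(features[i, ], features[idx[i, j], ] - features[i, ])
      h <- pmax(as.vector(e %*% W1 + b1), 0)
      ef[(i - 1) * k + j, ] <- as.vector(h %*% W2 + b2)
    }
  }
  if (!reduce) return(ef)
  out <- matrix(0, n, ncol(ef))
  for (i in seq_len(n)) {
    out[i, ] <- apply(ef[(i - 1) * k + seq_len(k), , drop = FALSE], 2, max)
  }
  out
}

se_gate_oracle <- function(edge_features, weights) {
  W1 <- vc$ag_value(weights$mlp[[1]]$W); b1 <- vc$ag_value(weights$mlp[[1]]$b)
  W2 <- vc$ag_value(weights$mlp[[2]]$W); b2 <- vc$ag_value(weights$mlp[[2]]$b)
  descr <- colMeans(edge_features)
  h <- pmax(as.vector(descr %*% W1 + b1), 0)
  1 / (1 + exp(-(as.vector(h %*% W2 + b2))))
}

adain_oracle <- function(x, gamma, beta, eps = 1e-5) {
  out <- x
  for (c in seq_len(ncol(x))) {
    mu <- mean(x[, c])
    sd <- sqrt(mean((x[, c] - mu)^2) + eps)
    out[, c] <- gamma[c] * (x[, c] - mu) / sd + beta[c]
  }
  out
}

# Kruskal MST with union-find; independent of the package's Prim version.
kruskal_mst_weight <- function(points) {
  n <- nrow(points)
  d <- cross_dist_oracle(points, points)
  edges <- which(upper.tri(d), arr.ind = TRUE)
  ord <- order(d[edges])
  parent <- seq_len(n)
  find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
  total <- 0; used <- 0
  for (e in ord) {
    u <- find(edges[e, 1]); v <- find(edges[e, 2])
    if (u != v) {
      parent[u] <- v
      total <- total + d[edges[e, 1], edges[e, 2]]
      used <- used + 1
      if (used == n - 1) break
    }
  }
  total
}

expansion_oracle <- function(patches, lambda) {
  total <- 0
  for (p in patches) {
    mst <- vesselcomplete::euclidean_mst(p)   # edge set checked separately
    li <- mean(mst$w)
    total <- total + sum(mst$w[mst$w >= lambda * li])
  }
  total / (length(patches) * nrow(patches[[1]]))
}

mds_oracle <- function(cloud, n_out, sigma) {
  n <- nrow(cloud)
  centroid <- colMeans(cloud)
  sel <- which.min(rowSums(sweep(cloud, 2, centroid)^2))
  for (step in seq_len(n_out - 1)) {
    dens <- rep(Inf, n)
    for (i in setdiff(seq_len(n), sel)) {
      dens[i] <- sum(exp(-rowSums(sweep(cloud[sel, , drop = FALSE], 2,
                                        cloud[i, ])^2) / (2 * sigma^2)))
    }
    sel <- c(sel, which.min(dens))
  }
  sel
}

# First-hit ray casting (Moller-Trumbore) for the visibility audit.
ray_first_hit <- function(origin, dir, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  best <- Inf
  for (k in seq_len(nrow(f))) {
    v0 <- v[f[k, 1], ]; e1 <- v[f[k, 2], ] - v0; e2 <- v[f[k, 3], ] - v0
    h <- c(dir[2] * e2[3] - dir[3] * e2[2],
           dir[3] * e2[1] - dir[1] * e2[3],
           dir[1] * e2[2] - dir[2] * e2[1])
    a <- sum(e1 * h)
    if (abs(a) < 1e-14) next
    s <- origin - v0
    u <- sum(s * h) / a
    if (u < -1e-9 || u > 1 + 1e-9) next
    q <- c(s[2] * e1[3] - s[3] * e1[2],
           s[3] * e1[1] - s[1] * e1[3],
           s[1] * e1[2] - s[2] * e1[1])
    w <- sum(dir * q) / a
    if (w < -1e-9 || u + w > 1 + 1e-9) next
    t <- sum(e2 * q) / a
    if (t > 1e-9 && t < best) best <- t
  }
  best
}

camera_frame_oracle <- function(view) {
  v <- c(cos(view$elevation) * cos(view$azimuth),
         cos(view$elevation) * sin(view$azimuth),
         sin(view$elevation))
  up <- if (abs(v[3]) < 0.99) c(0, 0, 1) else c(0, 1, 0)
  e1 <- up * 0
  cr <- c(up[2] * v[3] - up[3] * v[2], up[3] * v[1] - up[1] * v[3],
          up[1] * v[2] - up[2] * v[1])
  e1 <- cr / sqrt(sum(cr^2))
  e2 <- c(v[2] * e1[3] - v[3] * e1[2], v[3] * e1[1] - v[1] * e1[3],
          v[1] * e1[2] - v[2] * e1[1])
  list(v = v, e1 = e1, e2 = e2)
}
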