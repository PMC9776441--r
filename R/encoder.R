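# Multi-scope graph-feature encoder. A single-scope module (SSM) runs an
# edge convolution over the k-NN graph, gates channels with a
# squeeze-excitation vector computed from all N*k edge features, and
# max-reduces edges per point. The multi-scope aggregate (MSA) runs several
# SSMs at different k, fuses them with softmax attention over branches, and
# adds the lifted input back. Four stacked MSA stages feed max+average
# pooling to produce the global shape descriptor G.

#' Exact k-nearest-neighbour graph of a point cloud
#'
#' Euclidean distances in coordinate space; the point itself is excluded and
#' ties are broken toward the smaller point index. Neighbours are stored in
#' increasing distance order, so the first `k'` columns form the `k'`-NN
#' graph for any `k' <= k`.
#'
#' @param cloud N x 3 matrix.
#' @param k neighbour count, `1 <= k < N`.
#' @return a `knn_graph` list with `k` and integer `indices` (N x k).
#' @export
knn_graph <- function(cloud, k) {
  cloud <- as.matrix(cloud)
  n <- nrow(cloud)
  if (k >= n) stop("k must be smaller than the number of points", call. = FALSE)
  stopifnot(k >= 1L)
  d <- .cross_dist(cloud, cloud)
  diag(d) <- Inf
  # one global sort keyed by (row, distance, column index)
  ord <- order(rep(seq_len(n), each = n), as.vector(t(d)),
               rep(seq_len(n), times = n))
  jcol <- ((ord - 1L) %% n) + 1L
  idx <- matrix(jcol, nrow = n, byrow = TRUE)[, seq_len(k), drop = FALSE]
  structure(list(k = as.integer(k), indices = idx), class = "knn_graph")
}

.graph_slice <- function(graph, k) {
  if (k == graph$k) return(graph)
  stopifnot(k <= graph$k)
  structure(list(k = as.integer(k),
                 indices = graph$indices[, seq_len(k), drop = FALSE]),
            class = "knn_graph")
}

# --- weight constructors -----------------------------------------------------

#' Initialize weights for one edge convolution
#' @param cin,cout input/output channel counts.
#' @param hidden hidden width of the shared two-layer perceptron.
#' @return weight list usable by [edge_conv()].
#' @export
init_edge_conv_weights <- function(cin, cout, hidden = cout) {
  list(mlp = init_mlp(c(2L * cin, hidden, cout), c("relu", "linear")))
}

#' Initialize weights for a squeeze-excitation gate
#' @param channels channel count.
#' @param reduction bottleneck reduction factor.
#' @return weight list usable by [se_gate()].
#' @export
init_se_weights <- function(channels, reduction = 4L) {
  mid <- max(1L, channels %/% reduction)
  list(mlp = init_mlp(c(channels, mid, channels), c("relu", "sigmoid")))
}

init_ssm_weights <- function(cin, cout) {
  list(edge = init_edge_conv_weights(cin, cout),
       se = init_se_weights(cout))
}

# The attention head uses a bounded (sigmoid) hidden activation so the
# branch-weighting path can never die, whatever the feature scale.
init_msa_weights <- function(cin, cout, n_branch) {
  list(lift = init_mlp(c(cin, cout), "relu"),
       branches = lapply(seq_len(n_branch), function(b) init_ssm_weights(cout, cout)),
       attention = init_mlp(c(cout, max(4L, cout %/% 4L), n_branch),
                            c("sigmoid", "linear")))
}

#' Initialize the full encoder weight set
#' @param config an encoder config, see [model_config()] (`$encoder`).
#' @return nested weight list for [encode()].
#' @export
init_encoder_weights <- function(config) {
  ch <- config$channels
  kn <- length(config$k_list)
  cin <- 3L
  stages <- vector("list", length(ch))
  for (s in seq_along(ch)) {
    stages[[s]] <- init_msa_weights(cin, ch[s], kn)
    cin <- ch[s]
  }
  list(stages = stages)
}

# --- forward passes (autodiff nodes) ----------------------------------------

# Pre-reduction edge features: rows ordered point-major (point i's k edges
# are consecutive). Returns an (N*k) x Cout node.
.ag_edge_features <- function(x, graph, weights) {
  x <- as_ag(x)
  n <- nrow(x$value)
  if (nrow(graph$indices) != n) {
    stop("graph and feature row counts differ", call. = FALSE)
  }
  k <- graph$k
  idx_i <- rep(seq_len(n), each = k)
  idx_j <- as.integer(t(graph$indices))
  ei <- ag_rows(x, idx_i)
  ej <- ag_rows(x, idx_j)
  ag_mlp(ag_concat_cols(ei, ag_sub(ej, ei)), weights$mlp)
}

.ag_se_gate <- function(edge_feats, weights) {
  ag_mlp(ag_colmeans(edge_feats), weights$mlp)
}

.ag_ssm <- function(x, graph, weights) {
  n <- nrow(ag_value(x))
  ef <- .ag_edge_features(x, graph, weights$edge)
  s <- .ag_se_gate(ef, weights$se)
  gated <- ag_mul(ef, s)
  ag_group_max(gated, n, graph$k)
}

.ag_msa <- function(x, graph, k_list, weights, detail = FALSE) {
  lifted <- ag_mlp(x, weights$lift)
  branches <- lapply(seq_along(k_list), function(b) {
    .ag_ssm(lifted, .graph_slice(graph, k_list[b]), weights$branches[[b]])
  })
  merged <- branches[[1]]
  if (length(branches) > 1L) {
    merged <- ag_scale(Reduce(ag_add, branches), 1 / length(branches))
  }
  att <- ag_softmax(ag_mlp(ag_colmeans(merged), weights$attention))
  fused <- ag_weighted_sum(branches, att)
  out <- ag_add(fused, lifted)
  if (detail) list(out = out, fused = fused, attention = att,
                   branches = branches, lifted = lifted)
  else out
}

.ag_encode <- function(cloud, weights, config, graph = NULL) {
  cloud_m <- as.matrix(ag_value(cloud))
  kmax <- max(config$k_list)
  if (nrow(cloud_m) < kmax + 1L) {
    stop("need at least max(k_list) + 1 points", call. = FALSE)
  }
  if (is.null(graph)) graph <- knn_graph(cloud_m, kmax)
  x <- as_ag(cloud)
  for (s in seq_along(weights$stages)) {
    x <- .ag_msa(x, graph, config$k_list, weights$stages[[s]])
  }
  ag_concat_cols(ag_colmax(x), ag_colmeans(x))
}

# --- exported numeric surfaces ----------------------------------------------

#' Edge convolution over a neighbour graph
#'
#' For each directed edge (i, j) the concatenation `(e_i, e_ij - e_i)` of the
#' point's feature and the neighbour difference is passed through a shared
#' two-layer perceptron; the k edge responses of each point are max-reduced
#' channel-wise.
#'
#' @param features N x C feature matrix.
#' @param graph a `knn_graph` over the same N points.
#' @param weights from [init_edge_conv_weights()] (or any compatible MLP).
#' @param reduce max-reduce over edges (default); `FALSE` returns the raw
#'   (N*k) x Cout edge features, point-major.
#' @return numeric matrix.
#' @export
edge_conv <- function(features, graph, weights, reduce = TRUE) {
  ef <- .ag_edge_features(ag_node(as.matrix(features)), graph, weights)
  if (!reduce) return(ef$value)
  ag_value(ag_group_max(ef, nrow(as.matrix(features)), graph$k))
}

#' Squeeze-excitation gating vector from edge features
#'
#' Averages all N*k edge features into a channel descriptor, passes it
#' through a bottleneck perceptron and a sigmoid.
#'
#' @param edge_features (N*k) x C matrix of pre-reduction edge features.
#' @param weights from [init_se_weights()].
#' @return numeric gating vector of length C, entries in (0, 1).
#' @export
se_gate <- function(edge_features, weights) {
  as.vector(ag_value(.ag_se_gate(ag_node(as.matrix(edge_features)), weights)))
}

#' Single-scope module: edge convolution with SE gating
#'
#' `edge_conv` (pre-reduction) -> `se_gate` -> channel-wise multiply -> max
#' over the k edges. Permutation-equivariant in the point order.
#'
#' @param cloud N x 3 coordinates (used to build the k-NN graph).
#' @param features N x C input features.
#' @param k neighbour count.
#' @param weights from `init_ssm_weights()`-style list (`$edge`, `$se`).
#' @return N x Cout matrix.
#' @export
ssm <- function(cloud, features, k, weights) {
  graph <- knn_graph(cloud, k)
  ag_value(.ag_ssm(ag_node(as.matrix(features)), graph, weights))
}

#' Multi-scope aggregate module
#'
#' Lifts the input features, runs one SSM per value in `k_list`, fuses the
#' branch outputs with softmax attention computed from their average, and
#' adds the lifted input back (residual).
#'
#' @param cloud N x 3 coordinates.
#' @param features N x Cin features.
#' @param k_list integer vector of neighbourhood scopes.
#' @param weights from `init_msa_weights()`.
#' @param detail return branch outputs, attention weights, and the
#'   pre-residual fusion alongside the output.
#' @return N x Cout matrix, or a list when `detail = TRUE`.
#' @export
msa <- function(cloud, features, k_list, weights, detail = FALSE) {
  if (length(k_list) == 0L) stop("k_list must be non-empty", call. = FALSE)
  graph <- knn_graph(cloud, max(k_list))
  res <- .ag_msa(ag_node(as.matrix(features)), graph, k_list, weights,
                 detail = TRUE)
  if (!detail) return(ag_value(res$out))
  list(out = ag_value(res$out), fused = ag_value(res$fused),
       attention = as.vector(ag_value(res$attention)),
       branches = lapply(res$branches, ag_value),
       lifted = ag_value(res$lifted))
}

#' Encode a point cloud into a global shape descriptor
#'
#' Four stacked MSA stages of increasing width followed by channel-wise max
#' and average pooling, concatenated into G. Permutation-invariant in the
#' point order.
#'
#' @param cloud N x 3 matrix.
#' @param weights from [init_encoder_weights()].
#' @param config encoder config (`$k_list`, `$channels`).
#' @return numeric vector of length `2 * tail(channels, 1)`.
#' @export
encode <- function(cloud, weights, config) {
  as.vector(ag_value(.ag_encode(ag_node(as.matrix(cloud)), weights, config)))
}
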