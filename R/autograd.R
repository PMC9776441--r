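# Reverse-mode automatic differentiation on dense numeric matrices.
#
# Every tensor is a 2-D double matrix (vectors are 1 x C). A node is an
# environment holding the value, the accumulated gradient, its parents and a
# closure that maps the output gradient to a list of parent gradients. The
# graph is built eagerly during the forward pass and consumed by ag_backward().

.ag_state <- new.env(parent = emptyenv())
.ag_state$next_id <- 1L

ag_node <- function(value, parents = list(), backfn = NULL, requires_grad = FALSE) {
  stopifnot(is.numeric(value))
  if (!is.matrix(value)) value <- matrix(as.double(value), nrow = 1L)
  storage.mode(value) <- "double"
  e <- new.env(parent = emptyenv())
  e$value <- value
  e$grad <- NULL
  e$parents <- parents
  e$backfn <- backfn
  e$requires_grad <- requires_grad
  e$needs <- requires_grad || any(vapply(parents, function(p) p$needs, logical(1)))
  e$id <- .ag_state$next_id
  .ag_state$next_id <- .ag_state$next_id + 1L
  class(e) <- "ag_tensor"
  e
}

is_ag <- function(x) inherits(x, "ag_tensor")

as_ag <- function(x) if (is_ag(x)) x else ag_node(x)

#' Create a learnable tensor for the autodiff engine
#'
#' Wraps a numeric matrix as a leaf node that accumulates gradients during
#' [ag_backward()]. Used for every weight and bias in the network.
#'
#' @param value numeric matrix (a plain vector is treated as a row vector).
#' @return an `ag_tensor` leaf with `requires_grad = TRUE`.
#' @keywords internal
ag_param <- function(value) ag_node(value, requires_grad = TRUE)

ag_value <- function(x) if (is_ag(x)) x$value else x

# Topological order of the graph rooted at `root` (iterative DFS; visited
# marks are an epoch counter stamped on the nodes themselves).
.ag_topo <- function(root) {
  epoch <- (.ag_state$epoch %||% 0L) + 1L
  .ag_state$epoch <- epoch
  order <- vector("list", 64L)
  n_ord <- 0L
  stack <- list(list(node = root, i = 0L))
  root$.visited <- epoch
  while (length(stack)) {
    top <- stack[[length(stack)]]
    node <- top$node
    if (top$i < length(node$parents)) {
      stack[[length(stack)]]$i <- top$i + 1L
      p <- node$parents[[top$i + 1L]]
      if (p$needs && !identical(p$.visited, epoch)) {
        p$.visited <- epoch
        stack[[length(stack) + 1L]] <- list(node = p, i = 0L)
      }
    } else {
      n_ord <- n_ord + 1L
      if (n_ord > length(order)) order <- c(order, vector("list", length(order)))
      order[[n_ord]] <- node
      stack[[length(stack)]] <- NULL
    }
  }
  order[seq_len(n_ord)]
}

#' Backpropagate from a scalar loss node
#'
#' Accumulates gradients into `$grad` of every reachable node with
#' `requires_grad = TRUE` (and intermediates that need them).
#'
#' @param loss an `ag_tensor` holding a 1 x 1 value.
#' @keywords internal
ag_backward <- function(loss) {
  stopifnot(is_ag(loss), length(loss$value) == 1L)
  if (!loss$needs) return(invisible(NULL))
  order <- .ag_topo(loss)
  for (nd in order) nd$grad <- NULL
  loss$grad <- matrix(1, 1L, 1L)
  for (i in rev(seq_along(order))) {
    nd <- order[[i]]
    if (is.null(nd$backfn) || is.null(nd$grad)) next
    pgrads <- nd$backfn(nd$grad)
    for (j in seq_along(nd$parents)) {
      p <- nd$parents[[j]]
      g <- pgrads[[j]]
      if (is.null(g) || !p$needs) next
      p$grad <- if (is.null(p$grad)) g else p$grad + g
    }
  }
  invisible(NULL)
}

# --- elementwise / broadcast arithmetic -------------------------------------

# b may be: same shape, a 1 x C row vector broadcast over rows, or a scalar.
.bcast_back <- function(g, dims_b) {
  if (all(dim(g) == dims_b)) return(g)
  if (dims_b[1] == 1L && dims_b[2] == ncol(g)) return(matrix(colSums(g), 1L))
  if (all(dims_b == c(1L, 1L))) return(matrix(sum(g), 1L, 1L))
  stop("unsupported broadcast gradient shape")
}

.bcast_val <- function(a, b) {
  if (all(dim(b) == dim(a))) return(b)
  if (nrow(b) == 1L && ncol(b) == ncol(a)) return(matrix(b, nrow(a), ncol(a), byrow = TRUE))
  if (length(b) == 1L) return(matrix(b[1], nrow(a), ncol(a)))
  stop("incompatible shapes")
}

ag_add <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  db <- dim(b$value)
  ag_node(a$value + .bcast_val(a$value, b$value), list(a, b),
          function(g) list(g, .bcast_back(g, db)))
}

ag_sub <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  db <- dim(b$value)
  ag_node(a$value - .bcast_val(a$value, b$value), list(a, b),
          function(g) list(g, -.bcast_back(g, db)))
}

ag_mul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  db <- dim(b$value)
  bv <- .bcast_val(a$value, b$value)
  av <- a$value
  ag_node(av * bv, list(a, b),
          function(g) list(g * bv, .bcast_back(g * av, db)))
}

ag_scale <- function(a, s) {
  a <- as_ag(a)
  ag_node(a$value * s, list(a), function(g) list(g * s))
}

ag_matmul <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  av <- a$value; bv <- b$value
  ag_node(av %*% bv, list(a, b),
          function(g) list(g %*% t(bv), t(av) %*% g))
}

# --- nonlinearities ----------------------------------------------------------

ag_relu <- function(x) {
  x <- as_ag(x)
  m <- x$value > 0
  ag_node(x$value * m, list(x), function(g) list(g * m))
}

ag_sigmoid <- function(x) {
  x <- as_ag(x)
  s <- 1 / (1 + exp(-x$value))
  ag_node(s, list(x), function(g) list(g * s * (1 - s)))
}

ag_square <- function(x) {
  x <- as_ag(x)
  v <- x$value
  ag_node(v * v, list(x), function(g) list(2 * v * g))
}

ag_sqrt <- function(x) {
  x <- as_ag(x)
  s <- sqrt(x$value)
  ag_node(s, list(x), function(g) list(g / (2 * s)))
}

ag_recip <- function(x) {
  x <- as_ag(x)
  v <- x$value
  ag_node(1 / v, list(x), function(g) list(-g / (v * v)))
}

# --- reductions --------------------------------------------------------------

ag_mean <- function(x) {
  x <- as_ag(x)
  n <- length(x$value)
  dims <- dim(x$value)
  ag_node(matrix(mean(x$value), 1L, 1L), list(x),
          function(g) list(matrix(g[1] / n, dims[1], dims[2])))
}

ag_sum <- function(x) {
  x <- as_ag(x)
  dims <- dim(x$value)
  ag_node(matrix(sum(x$value), 1L, 1L), list(x),
          function(g) list(matrix(g[1], dims[1], dims[2])))
}

ag_colmeans <- function(x) {
  x <- as_ag(x)
  n <- nrow(x$value)
  ag_node(matrix(colMeans(x$value), 1L), list(x),
          function(g) list(matrix(g / n, n, ncol(g), byrow = TRUE)))
}

# Column-wise max, ties to the smaller row index.
ag_colmax <- function(x) {
  x <- as_ag(x)
  v <- x$value
  am <- max.col(t(v), ties.method = "first")
  ag_node(matrix(v[cbind(am, seq_along(am))], 1L), list(x),
          function(g) {
            pg <- matrix(0, nrow(v), ncol(v))
            pg[cbind(am, seq_along(am))] <- g[1L, ]
            list(pg)
          })
}

# Max over k consecutive rows per group: x is (n*k) x C with rows ordered
# group-major; returns n x C. Ties go to the smaller (earlier) row.
ag_group_max <- function(x, n, k) {
  x <- as_ag(x)
  v <- x$value
  stopifnot(nrow(v) == n * k)
  C <- ncol(v)
  out <- matrix(0, n, C)
  arg <- matrix(0L, n, C)   # global row index of each winner
  base <- (seq_len(n) - 1L) * k
  for (c in seq_len(C)) {
    m <- matrix(v[, c], nrow = k)       # columns are groups
    w <- max.col(t(m), ties.method = "first")
    arg[, c] <- base + w
    out[, c] <- m[cbind(w, seq_len(n))]
  }
  ag_node(out, list(x), function(g) {
    pg <- matrix(0, n * k, C)
    for (c in seq_len(C)) pg[cbind(arg[, c], c)] <- g[, c]
    list(pg)
  })
}

# --- indexing / reshaping ----------------------------------------------------

ag_rows <- function(x, idx) {
  x <- as_ag(x)
  idx <- as.integer(idx)
  nr <- nrow(x$value)
  ag_node(x$value[idx, , drop = FALSE], list(x), function(g) {
    acc <- rowsum(g, group = idx)
    pg <- matrix(0, nr, ncol(g))
    pg[as.integer(rownames(acc)), ] <- acc
    list(pg)
  })
}

ag_tile <- function(x, n) {
  x <- as_ag(x)
  stopifnot(nrow(x$value) == 1L)
  ag_node(matrix(x$value, n, ncol(x$value), byrow = TRUE), list(x),
          function(g) list(matrix(colSums(g), 1L)))
}

ag_concat_cols <- function(a, b) {
  a <- as_ag(a); b <- as_ag(b)
  ca <- ncol(a$value)
  ag_node(cbind(a$value, b$value), list(a, b),
          function(g) list(g[, seq_len(ca), drop = FALSE],
                           g[, -seq_len(ca), drop = FALSE]))
}

ag_concat_rows <- function(nodes) {
  nodes <- lapply(nodes, as_ag)
  sizes <- vapply(nodes, function(x) nrow(x$value), integer(1))
  ends <- cumsum(sizes)
  starts <- ends - sizes + 1L
  ag_node(do.call(rbind, lapply(nodes, ag_value)), nodes, function(g) {
    lapply(seq_along(nodes), function(i) g[starts[i]:ends[i], , drop = FALSE])
  })
}

# --- softmax and fusion ------------------------------------------------------

ag_softmax <- function(x) {
  x <- as_ag(x)
  stopifnot(nrow(x$value) == 1L)
  z <- x$value - max(x$value)
  s <- exp(z) / sum(exp(z))
  ag_node(s, list(x), function(g) list(s * (g - sum(g * s))))
}

# sum_b w[1, b] * mats[[b]]; w is an ag 1 x B row, mats a list of equal-shape nodes.
ag_weighted_sum <- function(mats, w) {
  mats <- lapply(mats, as_ag)
  w <- as_ag(w)
  wv <- w$value
  out <- matrix(0, nrow(mats[[1]]$value), ncol(mats[[1]]$value))
  for (b in seq_along(mats)) out <- out + wv[1L, b] * mats[[b]]$value
  ag_node(out, c(mats, list(w)), function(g) {
    gs <- lapply(seq_along(mats), function(b) g * wv[1L, b])
    gw <- matrix(vapply(mats, function(m) sum(g * m$value), numeric(1)), 1L)
    c(gs, list(gw))
  })
}

# --- domain-specific terminal ops -------------------------------------------

# Transport cost sum_ij T_ij * ||x_i - y_j|| for a FIXED plan T (detached).
# Gradient flows into the predicted cloud x only.
ag_transport_cost <- function(x, y_value, plan) {
  x <- as_ag(x)
  xv <- x$value
  d2 <- outer(rowSums(xv^2), rowSums(y_value^2), "+") - 2 * xv %*% t(y_value)
  d <- sqrt(pmax(d2, 0))
  val <- sum(plan * d)
  ag_node(matrix(val, 1L, 1L), list(x), function(g) {
    w <- plan / pmax(d, 1e-12)
    gx <- g[1] * (rowSums(w) * xv - w %*% y_value)
    list(gx)
  })
}

# Expansion penalty over FIXED retained MST edges: sum ||p_u - p_v|| / norm.
# `edges` is a 2-column integer matrix of retained (u, v) row indices into x.
ag_edge_length_sum <- function(x, edges, norm) {
  x <- as_ag(x)
  xv <- x$value
  if (nrow(edges) == 0L) {
    return(ag_node(matrix(0, 1L, 1L), list(x),
                   function(g) list(matrix(0, nrow(xv), ncol(xv)))))
  }
  du <- xv[edges[, 1L], , drop = FALSE] - xv[edges[, 2L], , drop = FALSE]
  len <- sqrt(rowSums(du^2))
  ag_node(matrix(sum(len) / norm, 1L, 1L), list(x), function(g) {
    gx <- matrix(0, nrow(xv), ncol(xv))
    unit <- du / pmax(len, 1e-12)
    contrib <- g[1] / norm * unit
    for (e in seq_len(nrow(edges))) {
      gx[edges[e, 1L], ] <- gx[edges[e, 1L], ] + contrib[e, ]
      gx[edges[e, 2L], ] <- gx[edges[e, 2L], ] - contrib[e, ]
    }
    list(gx)
  })
}

# --- layers ------------------------------------------------------------------

# A linear layer is list(W = Cin x Cout, b = 1 x Cout) of ag tensors.
init_linear <- function(cin, cout, gain = sqrt(2)) {
  list(W = ag_param(matrix(stats::rnorm(cin * cout, sd = gain / sqrt(cin)), cin, cout)),
       b = ag_param(matrix(0, 1L, cout)))
}

ag_linear <- function(x, layer) ag_add(ag_matmul(x, layer$W), layer$b)

# An MLP is a list of layers, each list(W, b, act) with act in
# c("relu", "sigmoid", "linear").
init_mlp <- function(dims, acts) {
  stopifnot(length(acts) == length(dims) - 1L)
  lapply(seq_along(acts), function(i) {
    l <- init_linear(dims[i], dims[i + 1L],
                     gain = if (acts[i] == "relu") sqrt(2) else 1)
    # small positive bias keeps rectified units initially alive
    if (acts[i] == "relu") l$b$value[] <- 0.01
    l$act <- acts[i]
    l
  })
}

ag_mlp <- function(x, layers) {
  for (l in layers) {
    x <- ag_linear(x, l)
    x <- switch(l$act,
                relu = ag_relu(x),
                sigmoid = ag_sigmoid(x),
                linear = x,
                stop("unknown activation: ", l$act))
  }
  x
}

# Collect every ag_param leaf inside a nested weight list.
collect_params <- function(w) {
  out <- list()
  rec <- function(x) {
    if (is_ag(x)) {
      if (x$requires_grad) out[[length(out) + 1L]] <<- x
    } else if (is.list(x)) {
      for (el in x) rec(el)
    }
  }
  rec(w)
  out
}

# Replace parameter values in-place from a parallel list of plain matrices
# (used when loading checkpoints).
set_param_values <- function(w, values) {
  params <- collect_params(w)
  stopifnot(length(params) == length(values))
  for (i in seq_along(params)) {
    stopifnot(all(dim(params[[i]]$value) == dim(values[[i]])))
    params[[i]]$value <- values[[i]]
  }
  invisible(w)
}

get_param_values <- function(w) lapply(collect_params(w), ag_value)
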