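# Style-modulated folding decoder: K fixed 2D lattices are deformed into 3D
# surface patches by stacked perceptrons whose activations are re-modulated
# at every depth by AdaIN style parameters learned from the global feature
# G. Injecting G at every layer (rather than concatenating it once at the
# input) keeps the global shape signal alive through the whole fold. The
# observed partial cloud can be linked in through a pooled coordinate
# embedding tiled onto every grid vertex and/or by merging its raw points
# with the decoded coarse cloud before refinement.

#' Adaptive instance normalization
#'
#' Standardizes each feature channel over the point axis (mean 0, standard
#' deviation 1, with a stabilizing epsilon), then rescales by `gamma` and
#' shifts by `beta`. For a non-degenerate channel the output mean is `beta`
#' and the output standard deviation `|gamma|`; a constant channel maps to
#' `beta`.
#'
#' @param x N x C matrix.
#' @param gamma,beta numeric vectors of length C (the style).
#' @param eps stabilizer added to the variance before the square root.
#' @return N x C matrix.
#' @export
adain <- function(x, gamma, beta, eps = 1e-5) {
  ag_value(ag_adain(ag_node(as.matrix(x)), ag_node(matrix(gamma, 1L)),
                    ag_node(matrix(beta, 1L)), eps))
}

# Fused instance-norm-with-style node (single backward closure: the
# composition of colwise standardization, scale and shift).
ag_adain <- function(x, gamma, beta, eps = 1e-5) {
  x <- as_ag(x); gamma <- as_ag(gamma); beta <- as_ag(beta)
  xv <- x$value
  n <- nrow(xv)
  mu <- colMeans(xv)
  xc <- xv - rep(mu, each = n)
  sd <- sqrt(colMeans(xc * xc) + eps)
  xn <- xc / rep(sd, each = n)
  gv <- gamma$value
  out <- xn * rep(gv[1L, ], each = n) + rep(beta$value[1L, ], each = n)
  ag_node(out, list(x, gamma, beta), function(g) {
    gxn <- g * rep(gv[1L, ], each = n)
    m1 <- colMeans(gxn)
    m2 <- colMeans(gxn * xn)
    gx <- (gxn - rep(m1, each = n) - xn * rep(m2, each = n)) /
      rep(sd, each = n)
    list(gx, matrix(colSums(g * xn), 1L), matrix(colSums(g), 1L))
  })
}

#' Initialize weights for one style block
#' @param cin,cout input/output widths.
#' @param g_len length of the global feature G.
#' @return weight list for [style_block()].
#' @export
init_style_block_weights <- function(cin, cout, g_len) {
  w <- list(linear = init_linear(cin, cout),
            style = init_mlp(c(g_len, 2L * cout), "linear"),
            se = init_se_weights(cout))
  # style MLP biased so gamma starts near 1, beta near 0
  w$style[[1]]$b$value[1, seq_len(cout)] <- 1
  w
}

.ag_style_block <- function(x, g, weights) {
  h <- ag_linear(x, weights$linear)
  cout <- ncol(ag_value(h))
  gb <- ag_mlp(g, weights$style)
  gamma <- ag_node(ag_value(gb)[, seq_len(cout), drop = FALSE],
                   parents = list(gb),
                   backfn = function(gr) list(cbind(gr, matrix(0, 1L, cout))))
  beta <- ag_node(ag_value(gb)[, cout + seq_len(cout), drop = FALSE],
                  parents = list(gb),
                  backfn = function(gr) list(cbind(matrix(0, 1L, cout), gr)))
  h <- ag_adain(h, gamma, beta)
  gate <- ag_mlp(ag_colmeans(h), weights$se$mlp)
  ag_relu(ag_mul(h, gate))
}

#' One style-modulated folding layer
#'
#' Perceptron -> AdaIN with style (gamma, beta) computed from G -> SE gate
#' -> ReLU. Output entries are non-negative.
#'
#' @param x N x Cin matrix.
#' @param g global feature vector.
#' @param weights from [init_style_block_weights()].
#' @return N x Cout matrix.
#' @export
style_block <- function(x, g, weights) {
  ag_value(.ag_style_block(ag_node(as.matrix(x)), ag_node(matrix(g, 1L)), weights))
}

#' Fixed 2D folding lattices
#'
#' @param K patch count.
#' @param grid_dims integer pair; `prod(grid_dims)` grid vertices per patch,
#'   uniformly spaced in the unit square.
#' @return `prod(grid_dims)` x 2 matrix (shared by all K patches).
#' @export
patch_grids <- function(K, grid_dims) {
  gu <- seq(0, 1, length.out = grid_dims[1])
  gv <- seq(0, 1, length.out = grid_dims[2])
  as.matrix(expand.grid(u = gu, v = gv))
}

#' Initialize the decoder weight set
#'
#' When the partial input is linked in (`partial_mode` `"embed"` or
#' `"both"`), a max-pooled embedding of its coordinates is concatenated to G
#' as the style source, so the observed structure modulates every folding
#' layer. (A tiled per-vertex copy would be inert: instance normalization
#' subtracts the per-channel mean, which erases any constant-per-channel
#' input.)
#'
#' @param config decoder config (`$K`, `$grid_dims`, `$depth`, `$width`,
#'   `$emb_dim`, `$partial_mode`) and `$g_len`.
#' @return nested weight list for [decode_coarse()].
#' @export
init_decoder_weights <- function(config) {
  use_emb <- config$partial_mode %in% c("embed", "both")
  style_len <- config$g_len + if (use_emb) config$emb_dim else 0L
  patches <- lapply(seq_len(config$K), function(p) {
    dims <- c(2L, rep(config$width, config$depth))
    blocks <- lapply(seq_len(config$depth), function(d) {
      init_style_block_weights(dims[d], dims[d + 1L], style_len)
    })
    list(blocks = blocks, head = init_linear(config$width, 3L, gain = 1))
  })
  emb <- if (use_emb) init_mlp(c(3L, config$emb_dim, config$emb_dim),
                               c("relu", "linear")) else NULL
  list(patches = patches, emb = emb)
}

.ag_decode_coarse <- function(g, partial, config, weights, detail = FALSE) {
  grid <- patch_grids(config$K, config$grid_dims)
  M <- nrow(grid)
  if (!is.null(config$coarse_size) && config$K * M != config$coarse_size) {
    stop("grid_dims and K inconsistent with the configured coarse size",
         call. = FALSE)
  }
  style_src <- g
  if (config$partial_mode %in% c("embed", "both")) {
    pe <- ag_colmax(ag_mlp(as_ag(partial), weights$emb))
    style_src <- ag_concat_cols(as_ag(g), pe)
  }
  base <- ag_node(grid)
  acts <- vector("list", config$K)
  outs <- vector("list", config$K)
  for (p in seq_len(config$K)) {
    x <- base
    pa <- vector("list", config$depth)
    for (d in seq_len(config$depth)) {
      x <- .ag_style_block(x, style_src, weights$patches[[p]]$blocks[[d]])
      pa[[d]] <- x
    }
    acts[[p]] <- pa
    outs[[p]] <- ag_linear(x, weights$patches[[p]]$head)
  }
  coarse <- ag_concat_rows(outs)
  if (detail) list(coarse = coarse, activations = acts, M = M) else coarse
}

#' Decode a coarse cloud from the global feature
#'
#' Each of the K patches maps its grid vertices through `depth` style blocks
#' (style from G) and a final linear head to 3D; the patches are
#' concatenated into one coarse cloud of exactly `K * prod(grid_dims)`
#' points. When `config$partial_mode` is `"embed"` or `"both"`, a max-pooled
#' embedding of the partial input's coordinates joins G as the style source,
#' so the observed structure modulates every folding layer.
#'
#' @param g global feature vector.
#' @param partial N x 3 partial input cloud (normalized like training data).
#' @param config decoder config, see [init_decoder_weights()].
#' @param weights from [init_decoder_weights()].
#' @param detail also return per-depth activations per patch.
#' @return (K*M) x 3 matrix, or a list when `detail = TRUE`.
#' @export
decode_coarse <- function(g, partial, config, weights, detail = FALSE) {
  res <- .ag_decode_coarse(ag_node(matrix(g, 1L)),
                           ag_node(as.matrix(partial)), config, weights,
                           detail = TRUE)
  pts <- ag_value(res$coarse)
  if (!detail) return(pts)
  list(points = pts, M = res$M,
       activations = lapply(res$activations, function(pa) lapply(pa, ag_value)))
}

#' Split a coarse cloud back into its patches
#' @param coarse (K*M) x 3 matrix.
#' @param K patch count.
#' @return list of K matrices (M x 3).
#' @export
split_patches <- function(coarse, K) {
  M <- nrow(coarse) / K
  stopifnot(M == round(M))
  lapply(seq_len(K), function(p) coarse[(p - 1L) * M + seq_len(M), , drop = FALSE])
}
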