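test_that("knn graph matches the brute-force oracle and handles forced cases", {
  pts <- matrix(c(0, 0, 0, 1, 0, 0, 3, 0, 0), 3, byrow = TRUE)
  g <- knn_graph(pts, 1)
  expect_identical(as.vector(g$indices), c(2L, 1L, 2L))
  set.seed(1)
  cl <- rand_cloud(100)
  g5 <- knn_graph(cl, 5)
  d <- cross_dist_oracle(cl, cl)
  diag(d) <- Inf
  for (i in 1:100) {
    expect_identical(g5$indices[i, ], order(d[i, ])[1:5])
  }
  gn <- knn_graph(cl[1:10, ], 9)
  for (i in 1:10) expect_setequal(gn$indices[i, ], setdiff(1:10, i))
  expect_error(knn_graph(cl[1:5, ], 5), "smaller than")
})

test_that("edge convolution reduces to its forced special cases", {
  set.seed(2)
  cl <- rand_cloud(20)
  g <- knn_graph(cl, 1)
  # identity two-layer perceptron: W1 = I (relu-safe via split +/-), use
  # linear second layer to undo; simplest: both layers linear-equivalent
  C <- 3
  id <- list(mlp = list(
    list(W = vc$ag_param(diag(2 * C)), b = vc$ag_param(matrix(0, 1, 2 * C)),
         act = "linear"),
    list(W = vc$ag_param(diag(2 * C)), b = vc$ag_param(matrix(0, 1, 2 * C)),
         act = "linear")))
  out <- edge_conv(cl, g, id)
  manual <- t(vapply(seq_len(20), function(i) {
    c(cl[i, ], cl[g$indices[i, 1], ] - cl[i, ])
  }, numeric(6)))
  expect_equal(out, manual, tolerance = 1e-12)
  # identical features at all points -> identical rows everywhere
  feats <- matrix(1, 20, 4)
  w <- init_edge_conv_weights(4, 6)
  g4 <- knn_graph(cl, 4)
  out2 <- edge_conv(feats, g4, w)
  expect_equal(out2, out2[rep(1, 20), ], tolerance = 1e-12)
})

test_that("edge convolution and SE gate match literal loop oracles", {
  set.seed(3)
  cl <- rand_cloud(30)
  feats <- matrix(rnorm(30 * 5), 30)
  g <- knn_graph(cl, 4)
  w <- init_edge_conv_weights(5, 8)
  expect_equal(edge_conv(feats, g, w), edge_conv_oracle(feats, g$indices, w),
               tolerance = 1e-5)
  ef <- edge_conv(feats, g, w, reduce = FALSE)
  expect_equal(ef, edge_conv_oracle(feats, g$indices, w, reduce = FALSE),
               tolerance = 1e-5)
  ws <- init_se_weights(8)
  s <- se_gate(ef, ws)
  expect_equal(s, se_gate_oracle(ef, ws), tolerance = 1e-5)
  expect_true(all(s > 0 & s < 1))
  # zero features with zero-bias perceptron -> sigmoid(0) = 0.5
  wz <- init_se_weights(8)
  for (l in wz$mlp) { l$W$value[] <- 0; l$b$value[] <- 0 }
  expect_equal(se_gate(matrix(0, 40, 8), wz), rep(0.5, 8))
})

test_that("the single-scope module is permutation-equivariant and composes its parts", {
  set.seed(4)
  cl <- rand_cloud(25)
  feats <- matrix(rnorm(25 * 4), 25)
  w <- vc$init_ssm_weights(4, 6)
  out <- ssm(cl, feats, 3, w)
  perm <- sample(25)
  out_p <- ssm(cl[perm, ], feats[perm, ], 3, w)
  expect_equal(out_p, out[perm, ], tolerance = 1e-6)
  # gate forced to ~1 (huge bias) -> plain reduced edge convolution
  wg <- vc$init_ssm_weights(4, 6)
  wg$se$mlp[[2]]$W$value[] <- 0
  wg$se$mlp[[2]]$b$value[] <- 100
  g <- knn_graph(cl, 3)
  expect_equal(ssm(cl, feats, 3, wg), edge_conv(feats, g, wg$edge),
               tolerance = 1e-9)
  # composition equals the two oracles chained
  ef <- edge_conv_oracle(feats, g$indices, w$edge, reduce = FALSE)
  s <- se_gate_oracle(ef, w$se)
  gated <- sweep(ef, 2, s, "*")
  manual <- t(vapply(seq_len(25), function(i) {
    apply(gated[(i - 1) * 3 + 1:3, , drop = FALSE], 2, max)
  }, numeric(6)))
  expect_equal(out, manual, tolerance = 1e-5)
})

test_that("multi-scope fusion normalizes attention and respects symmetry", {
  set.seed(5)
  cl <- rand_cloud(30)
  feats <- matrix(rnorm(30 * 4), 30)
  w <- vc$init_msa_weights(4, 8, 2)
  res <- msa(cl, feats, c(3, 6), w, detail = TRUE)
  expect_equal(sum(res$attention), 1, tolerance = 1e-12)
  expect_true(all(res$attention > 0))
  # two identical branches: tie the weights, use the same k, and make the
  # attention head symmetric (zero final layer) so only symmetry decides
  w2 <- vc$init_msa_weights(4, 8, 2)
  w2$branches[[2]] <- w2$branches[[1]]
  w2$attention[[2]]$W$value[] <- 0
  w2$attention[[2]]$b$value[] <- 0
  res2 <- msa(cl, feats, c(4, 4), w2, detail = TRUE)
  expect_equal(res2$attention, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(res2$fused, res2$branches[[1]], tolerance = 1e-9)
  # a single branch gets attention 1 and the fusion equals that SSM
  w1 <- vc$init_msa_weights(4, 8, 1)
  res1 <- msa(cl, feats, 5, w1, detail = TRUE)
  expect_equal(res1$attention, 1)
  lifted <- vc$ag_value(vc$ag_mlp(vc$ag_node(feats), w1$lift))
  expect_equal(res1$fused, ssm(cl, lifted, 5, w1$branches[[1]]),
               tolerance = 1e-9)
  expect_error(msa(cl, feats, integer(0), w1), "non-empty")
})

test_that("the encoder is permutation-invariant and pools as documented", {
  set.seed(6)
  cfg <- model_config("toy")$encoder
  w <- local({ set.seed(10); init_encoder_weights(cfg) })
  cl <- rand_cloud(40)
  g1 <- encode(cl, w, cfg)
  g2 <- encode(cl[sample(40), ], w, cfg)
  expect_equal(g1, g2, tolerance = 1e-5)
  expect_identical(length(g1), 2L * utils::tail(cfg$channels, 1L))
  expect_true(all(is.finite(g1)))
  # max half >= average half when pooling the same feature map
  C <- utils::tail(cfg$channels, 1L)
  expect_true(all(g1[1:C] >= g1[C + 1:C] - 1e-12))
  expect_error(encode(cl[1:5, ], w, cfg), "at least")
})

test_that("max pooling ignores feature multiplicity; average pooling does not", {
  # the pooling stage of G: max over a duplicated feature map is unchanged,
  # while the average half shifts whenever duplication is unbalanced
  set.seed(7)
  fm <- matrix(rnorm(30 * 8), 30)
  dup <- rbind(fm, fm[1:10, ])
  g_max <- vc$ag_value(vc$ag_colmax(vc$ag_node(dup)))
  expect_equal(as.vector(g_max), apply(fm, 2, max), tolerance = 1e-12)
  g_avg <- vc$ag_value(vc$ag_colmeans(vc$ag_node(dup)))
  expect_false(isTRUE(all.equal(as.vector(g_avg), colMeans(fm))))
})

test_that("a scalar loss on G sends gradients into every encoder weight", {
  set.seed(8)
  cfg <- model_config("toy")$encoder
  w <- init_encoder_weights(cfg)
  cl <- rand_cloud(40)
  params <- vc$collect_params(w)
  acc <- lapply(params, function(p) 0)
  for (rep in 1:3) {
    g <- vc$.ag_encode(vc$ag_node(rand_cloud(40)), w, cfg)
    loss <- vc$ag_mean(vc$ag_square(g))
    for (p in params) p$grad <- NULL
    vc$ag_backward(loss)
    for (i in seq_along(params)) {
      if (!is.null(params[[i]]$grad)) acc[[i]] <- acc[[i]] + sum(abs(params[[i]]$grad))
    }
  }
  expect_true(all(vapply(acc, function(a) a > 0, logical(1))))
})
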