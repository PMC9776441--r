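test_that("adain re-modulates channel moments as specified", {
  set.seed(1)
  x <- matrix(rnorm(200 * 4, mean = 3, sd = 2), 200)
  z <- adain(x, gamma = rep(1, 4), beta = rep(0, 4))
  expect_equal(colMeans(z), rep(0, 4), tolerance = 1e-10)
  expect_equal(apply(z, 2, function(c) sqrt(mean(c^2))), rep(1, 4),
               tolerance = 1e-3)
  z2 <- adain(x, gamma = rep(2, 4), beta = rep(-1, 4))
  expect_equal(colMeans(z2), rep(-1, 4), tolerance = 1e-4)
  expect_equal(apply(z2, 2, function(c) sqrt(mean((c - mean(c))^2))),
               rep(2, 4), tolerance = 1e-3)
  # constant channel collapses to beta
  xc <- cbind(rep(5, 50), rnorm(50))
  zc <- adain(xc, c(3, 1), c(0.7, 0))
  expect_equal(zc[, 1], rep(0.7, 50))
  expect_equal(adain(x, c(2, 2, 2, 2), c(0, 0, 0, 0)),
               adain_oracle(x, rep(2, 4), rep(0, 4)), tolerance = 1e-10)
})

test_that("a style block is non-negative, style-sensitive, and matches its composition", {
  set.seed(2)
  g_len <- 16
  w <- init_style_block_weights(5, 7, g_len)
  x <- matrix(rnorm(30 * 5), 30)
  g1 <- rnorm(g_len); g2 <- rnorm(g_len)
  y1 <- style_block(x, g1, w)
  expect_true(all(y1 >= 0))
  y2 <- style_block(x, g2, w)
  expect_gt(max(abs(y1 - y2)), 1e-6)
  # literal composition oracle
  lin <- x %*% vc$ag_value(w$linear$W) +
    matrix(vc$ag_value(w$linear$b), 30, 7, byrow = TRUE)
  gb <- matrix(g1, 1) %*% vc$ag_value(w$style[[1]]$W) +
    vc$ag_value(w$style[[1]]$b)
  ad <- adain_oracle(lin, gb[1, 1:7], gb[1, 7 + 1:7])
  gate <- se_gate_oracle(ad, w$se)
  manual <- pmax(sweep(ad, 2, gate, "*"), 0)
  expect_equal(y1, manual, tolerance = 1e-9)
})

test_that("the decoder emits exactly K*M points and wires bias through", {
  set.seed(3)
  cfg <- model_config("toy")$decoder
  w <- init_decoder_weights(cfg)
  partial <- rand_cloud(64)
  g <- rnorm(cfg$g_len)
  out <- decode_coarse(g, partial, cfg, w)
  expect_equal(nrow(out), cfg$K * prod(cfg$grid_dims))
  expect_identical(ncol(out), 3L)
  expect_true(all(is.finite(out)))
  # zero final layers with a coordinate bias collapse each patch to its bias
  wz <- init_decoder_weights(cfg)
  for (p in seq_len(cfg$K)) {
    wz$patches[[p]]$head$W$value[] <- 0
    wz$patches[[p]]$head$b$value[] <- c(p, -p, 0.5)
  }
  outz <- decode_coarse(g, partial, cfg, wz)
  pl <- split_patches(outz, cfg$K)
  for (p in seq_len(cfg$K)) {
    expect_equal(pl[[p]], matrix(c(p, -p, 0.5), prod(cfg$grid_dims), 3,
                                 byrow = TRUE), tolerance = 1e-12,
                 ignore_attr = TRUE)
  }
  # inconsistent configured coarse size is rejected
  bad <- cfg; bad$coarse_size <- 999L
  expect_error(decode_coarse(g, partial, bad, w), "inconsistent")
})

test_that("partial-input linking is live when enabled", {
  set.seed(4)
  cfg <- model_config("toy")$decoder
  w <- init_decoder_weights(cfg)
  g <- rnorm(cfg$g_len)
  p1 <- rand_cloud(64); p2 <- rand_cloud(64)
  o1 <- decode_coarse(g, p1, cfg, w)
  o2 <- decode_coarse(g, p2, cfg, w)
  expect_gt(max(abs(o1 - o2)), 1e-8)
  # with linking disabled the partial cannot influence the fold
  cfg_off <- model_config("toy", partial_input = FALSE)$decoder
  w_off <- init_decoder_weights(cfg_off)
  expect_equal(decode_coarse(g, p1, cfg_off, w_off),
               decode_coarse(g, p2, cfg_off, w_off))
})

test_that("perturbing G changes activations at every styled depth", {
  set.seed(5)
  cfg <- model_config("toy")$decoder
  w <- init_decoder_weights(cfg)
  partial <- rand_cloud(64)
  g <- rnorm(cfg$g_len)
  g_pert <- g + rnorm(cfg$g_len, sd = 0.1)
  a1 <- decode_coarse(g, partial, cfg, w, detail = TRUE)$activations
  a2 <- decode_coarse(g_pert, partial, cfg, w, detail = TRUE)$activations
  for (p in seq_along(a1)) {
    for (d in seq_along(a1[[p]])) {
      expect_gt(max(abs(a1[[p]][[d]] - a2[[p]][[d]])), 1e-8)
    }
  }
})

test_that("decoded outputs stay finite across many weight draws", {
  cfg <- model_config("toy", K = 2L, width = 16L, emb_dim = 8L)$decoder
  partial <- rand_cloud(64)
  for (seed in 1:100) {
    set.seed(seed)
    w <- init_decoder_weights(cfg)
    out <- decode_coarse(rnorm(cfg$g_len), partial, cfg, w)
    expect_true(all(is.finite(out)))
  }
})
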