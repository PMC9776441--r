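test_that("the Euclidean MST is a spanning tree of minimal total weight", {
  set.seed(1)
  for (m in c(5L, 20L, 50L)) {
    pts <- rand_cloud(m)
    mst <- euclidean_mst(pts)
    expect_identical(nrow(mst), m - 1L)
    # connectivity: union-find over the returned edges reaches one component
    parent <- seq_len(m)
    find <- function(x) { while (parent[x] != x) x <- parent[x]; x }
    for (e in seq_len(nrow(mst))) parent[find(mst$u[e])] <- find(mst$v[e])
    expect_identical(length(unique(vapply(seq_len(m), find, integer(1)))), 1L)
    expect_equal(sum(mst$w), kruskal_mst_weight(pts), tolerance = 1e-10)
  }
})

test_that("expansion penalty evaluates its forced geometric cases", {
  # equilateral triangle: all MST edges equal, lambda > 1 filters everything
  tri <- matrix(c(0, 0, 0, 1, 0, 0, 0.5, sqrt(3) / 2, 0), 3, byrow = TRUE)
  expect_equal(expansion_penalty(list(tri), lambda = 1.5), 0)
  # collinear 0, 1, 10: MST edges {1, 9}, mean 5, only 9 >= 7.5 passes
  col3 <- matrix(c(0, 0, 0, 1, 0, 0, 10, 0, 0), 3, byrow = TRUE)
  expect_equal(expansion_penalty(list(col3), lambda = 1.5), 3)
  expect_error(expansion_penalty(list(matrix(0, 1, 3))), "at least 2")
})

test_that("expansion penalty is scale-covariant and matches its oracle", {
  set.seed(2)
  patches <- lapply(1:4, function(i) rand_cloud(20))
  pen <- expansion_penalty(patches, 1.2)
  expect_equal(expansion_penalty(lapply(patches, function(p) 3 * p), 1.2),
               3 * pen, tolerance = 1e-10)
  expect_equal(pen, expansion_oracle(patches, 1.2), tolerance = 1e-12)
  expect_gte(pen, 0)
})

test_that("the differentiable penalty agrees with the plain evaluation and its gradient", {
  set.seed(3)
  pts <- rand_cloud(24)
  node <- vc$ag_param(pts)
  pen <- vc$.ag_expansion_penalty(node, K = 3L, lambda = 1.2)
  expect_equal(vc$ag_value(pen)[1],
               expansion_penalty(split_patches(pts, 3), 1.2), tolerance = 1e-12)
  vc$ag_backward(pen)
  # finite differences along the retained-edge subgradient (fixed edge set)
  g <- node$grad
  expect_true(any(g != 0))
  h <- 1e-7
  for (probe in sample(length(pts), 5)) {
    pp <- pts; pp[probe] <- pp[probe] + h
    pm <- pts; pm[probe] <- pm[probe] - h
    num <- (expansion_penalty(split_patches(pp, 3), 1.2) -
              expansion_penalty(split_patches(pm, 3), 1.2)) / (2 * h)
    expect_equal(g[probe], num, tolerance = 1e-4)
  }
})

test_that("minimum density sampling follows the greedy density rule", {
  # forced case: after picking x = 0 (nearest the centroid is 0.1 though)
  pts <- matrix(c(0, 0, 0, 0.1, 0, 0, 5, 0, 0), 3, byrow = TRUE)
  out <- minimum_density_sample(pts, 2, sigma = 0.5)
  idx <- attr(out, "index")
  # first pick: nearest the centroid (1.7, 0, 0) is the point at x = 0.1
  expect_identical(idx[1], 2L)
  # second pick: the far point has much lower density than the near one
  expect_identical(idx[2], 3L)
  # n_out = n returns every point
  all3 <- minimum_density_sample(pts, 3, sigma = 0.5)
  expect_setequal(attr(all3, "index"), 1:3)
  expect_error(minimum_density_sample(pts, 4, 0.5), "exceeds")
})

test_that("greedy selection matches the brute-force density loop", {
  set.seed(4)
  cl <- rand_cloud(100)
  out <- minimum_density_sample(cl, 30, sigma = 0.2)
  expect_identical(attr(out, "index"), as.integer(mds_oracle(cl, 30, 0.2)))
  expect_identical(out, minimum_density_sample(cl, 30, sigma = 0.2))
})

test_that("refine merges, subsamples to the exact cardinality, and equalizes density", {
  set.seed(5)
  coarse <- rand_cloud(200)
  partial <- rand_cloud(50)
  out <- refine(coarse, partial, n_out = 120, merge_partial = TRUE, sigma = 0.1)
  expect_identical(nrow(out), 120L)
  pool_keys <- paste(rbind(coarse, partial)[, 1], rbind(coarse, partial)[, 2])
  expect_true(all(paste(out[, 1], out[, 2]) %in% pool_keys))
  expect_identical(anyDuplicated(attr(out, "index")), 0L)
  out2 <- refine(coarse, partial, n_out = 120, merge_partial = FALSE)
  key_c <- paste(coarse[, 1], coarse[, 2], coarse[, 3])
  expect_true(all(paste(out2[, 1], out2[, 2], out2[, 3]) %in% key_c))
  expect_error(refine(coarse[1:10, ], NULL, n_out = 50), "at least n_out")

  # clustered coarse + sparse partial: MDS flattens the density landscape
  # relative to a uniform random subsample, over repeated draws
  kd_max <- function(sel, sigma = 0.1) {
    d <- cross_dist_oracle(sel, sel)
    max(rowSums(exp(-d^2 / (2 * sigma^2))))
  }
  wins <- 0L
  for (s in 1:20) {
    set.seed(100 + s)
    clustered <- rbind(matrix(rnorm(150 * 3, sd = 0.05), 150),
                       rand_cloud(50))
    sparse <- rand_cloud(30)
    mds_sel <- refine(clustered, sparse, n_out = 60, sigma = 0.1)
    rnd_sel <- rbind(clustered, sparse)[sample.int(230, 60), ]
    if (kd_max(mds_sel) < kd_max(rnd_sel)) wins <- wins + 1L
  }
  expect_gte(wins, 16L)
})
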