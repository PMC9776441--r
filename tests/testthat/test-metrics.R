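test_that("Chamfer distance handles forced cases and matches the loop oracle", {
  set.seed(1)
  cl <- rand_cloud(40)
  expect_equal(chamfer_distance(cl, cl), 0)
  expect_equal(chamfer_distance(matrix(0, 1, 3), matrix(c(1, 0, 0), 1, 3)), 1)
  for (i in 1:10) {
    a <- rand_cloud(50); b <- rand_cloud(70)
    expect_equal(chamfer_distance(a, b), chamfer_oracle(a, b), tolerance = 1e-9)
    expect_equal(chamfer_distance(a, b), chamfer_distance(b, a))
  }
  expect_error(chamfer_distance(matrix(0, 0, 3), cl), "empty")
})

test_that("exact EMD solves tiny problems to the permutation optimum", {
  a <- matrix(c(0, 0, 0, 1, 0, 0), 2, byrow = TRUE)
  b <- a[2:1, ]
  expect_equal(emd(a, b, "exact"), 0)
  expect_equal(emd(a, a, "exact"), 0)
  set.seed(2)
  for (i in 1:20) {
    n <- sample(2:8, 1)
    x <- rand_cloud(n); y <- rand_cloud(n)
    expect_equal(emd(x, y, "exact"), emd_perm_oracle(x, y), tolerance = 1e-9)
  }
  expect_error(emd(rand_cloud(4), rand_cloud(5)), "equal cardinalities")
})

test_that("approximate EMD stays within its documented tolerance of exact", {
  set.seed(3)
  for (i in 1:100) {
    x <- rand_cloud(64); y <- rand_cloud(64)
    ex <- emd(x, y, "exact")
    ap <- emd(x, y, "approximate")
    expect_lt(abs(ap - ex), 0.10 * ex + 0.02)
  }
})

test_that("F-score covers saturation, separation, and the loop oracle", {
  set.seed(4)
  cl <- rand_cloud(30)
  expect_equal(f_score(cl, cl, 1e-6), 1)
  expect_equal(f_score(cl, cl + 10, 0.05), 0)
  for (i in 1:10) {
    a <- rand_cloud(30); b <- rand_cloud(40)
    expect_equal(f_score(a, b, 0.05), fscore_oracle(a, b, 0.05))
  }
  expect_error(f_score(cl, cl, 0), "positive")
})

test_that("F-score is non-decreasing in the threshold", {
  set.seed(5)
  a <- rand_cloud(40); b <- rand_cloud(40)
  ths <- seq(0.01, 1, length.out = 20)
  vals <- vapply(ths, function(t) f_score(a, b, t), numeric(1))
  expect_true(all(diff(vals) >= 0))
})

test_that("metrics are invariant to point order and rigid motions", {
  set.seed(6)
  a <- rand_cloud(40); b <- rand_cloud(40)
  pa <- a[sample(40), ]; pb <- b[sample(40), ]
  expect_equal(chamfer_distance(pa, pb), chamfer_distance(a, b), tolerance = 1e-12)
  expect_equal(emd(pa, pb, "exact"), emd(a, b, "exact"), tolerance = 1e-12)
  expect_equal(f_score(pa, pb, 0.1), f_score(a, b, 0.1))
  # random rotation (QR of a Gaussian matrix) plus translation
  qr_R <- qr.Q(qr(matrix(rnorm(9), 3)))
  if (det(qr_R) < 0) qr_R[, 1] <- -qr_R[, 1]
  shift <- c(0.3, -1, 2)
  ra <- sweep(a %*% qr_R, 2, shift, "+")
  rb <- sweep(b %*% qr_R, 2, shift, "+")
  expect_equal(chamfer_distance(ra, rb), chamfer_distance(a, b), tolerance = 1e-6)
  expect_equal(emd(ra, rb, "exact"), emd(a, b, "exact"), tolerance = 1e-6)
  expect_equal(f_score(ra, rb, 0.1), f_score(a, b, 0.1), tolerance = 1e-6)
})

test_that("the joint loss bundle honours its arithmetic identity", {
  set.seed(7)
  gt_c <- rand_cloud(32); gt_r <- rand_cloud(48)
  b0 <- joint_loss(gt_c, gt_r, gt_c, gt_r, l_expansion = 0, mode = "exact")
  expect_lt(b0$l_joint, 1e-6)  # zero up to distance-matrix round-off
  # the training-time approximate solver gets within its entropic tolerance
  b0a <- joint_loss(gt_c, gt_r, gt_c, gt_r, l_expansion = 0)
  expect_lt(b0a$l_joint, 0.01)
  b1 <- joint_loss(rand_cloud(32), rand_cloud(48), gt_c, gt_r,
                   l_expansion = 5, alpha = 0)
  expect_identical(b1$l_joint, b1$l_coarse_emd + b1$l_refine_emd)
  b2 <- joint_loss(gt_c, gt_r, gt_c, gt_r, l_expansion = 2, alpha = 0.1,
                   mode = "exact")
  expect_equal(b2$l_joint, 0.2, tolerance = 1e-6)
})
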