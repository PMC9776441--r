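test_that("training is deterministic for a fixed seed", {
  man <- toy_manifest()
  cfg <- model_config("toy", rng_seed = 42L)
  r1 <- train_model(man, cfg, n_steps = 4L, sinkhorn_iters = 10L)
  r2 <- train_model(man, cfg, n_steps = 4L, sinkhorn_iters = 10L)
  expect_identical(r1$history$l_joint, r2$history$l_joint)
  v1 <- vc$get_param_values(r1$model$weights)
  v2 <- vc$get_param_values(r2$model$weights)
  expect_identical(v1, v2)
})

test_that("the single-scope ablation collapses the encoder to k = 5", {
  cfg <- model_config("toy", multi_scope = FALSE)
  expect_identical(cfg$encoder$k_list, 5L)
  m <- init_model(cfg)
  expect_identical(length(m$weights$encoder$stages[[1]]$branches), 1L)
  cfg2 <- model_config("toy", multi_scope = TRUE)
  expect_gt(length(cfg2$encoder$k_list), 1L)
})

test_that("every registered parameter receives gradient within a few steps", {
  man <- toy_manifest()
  cfg <- model_config("toy")
  model <- init_model(cfg)
  params <- vc$collect_params(model$weights)
  acc <- rep(0, length(params))
  samples <- vc$.load_samples(man, "train")
  set.seed(1)
  for (step in 1:6) {
    smp <- samples[[(step %% length(samples)) + 1L]]
    partial <- smp$partials[[(step %% length(smp$partials)) + 1L]]
    fw <- vc$.ag_forward(model, partial)
    jl <- vc$.ag_joint_loss(fw, smp$complete,
                            vc$.sample_gt(smp$complete, cfg$refine$n_out),
                            alpha = cfg$train$alpha, sinkhorn_iters = 10L)
    for (p in params) p$grad <- NULL
    vc$ag_backward(jl$joint)
    for (i in seq_along(params)) {
      if (!is.null(params[[i]]$grad)) acc[i] <- acc[i] + sum(abs(params[[i]]$grad))
    }
  }
  expect_true(all(acc > 0))
})

test_that("evaluation scores perfect predictions as perfect", {
  man <- toy_manifest()
  report <- evaluate_model(man, toy_model(), split = "train",
                           predict_fn = function(partial, complete) complete)
  overall <- report[report$category == "overall", ]
  expect_equal(overall$cd_x1000, 0, tolerance = 1e-5)
  expect_equal(overall$emd_x1000, 0, tolerance = 1e-5)
  expect_equal(overall$fscore, 1)
})

test_that("the overall row is the sample-weighted mean and reports round-trip", {
  man <- toy_manifest()
  # jittered ground truth gives nontrivial, category-dependent scores
  report <- evaluate_model(man, toy_model(), split = "train",
                           predict_fn = function(partial, complete) {
    complete + matrix(stats::rnorm(length(complete), sd = 0.02),
                      nrow(complete))
  })
  cats <- report[report$category != "overall", ]
  overall <- report[report$category == "overall", ]
  expect_equal(overall$cd_x1000, sum(cats$cd_x1000 * cats$n) / sum(cats$n))
  expect_equal(overall$n, sum(cats$n))
  f <- tempfile(fileext = ".tsv")
  utils::write.table(report, f, sep = "\t", row.names = FALSE, quote = FALSE)
  back <- utils::read.table(f, sep = "\t", header = TRUE)
  expect_equal(back$cd_x1000, report$cd_x1000, tolerance = 1e-9)
})

test_that("file-level completion honours its contracts and is idempotent", {
  man <- toy_manifest()
  model <- toy_model()
  partial_path <- vc$manifest_partials(man, 1)[1]
  out1 <- tempfile(fileext = ".ply"); out2 <- tempfile(fileext = ".ply")
  pts <- complete_cloud(partial_path, model, out1)
  expect_identical(nrow(read_ply(out1)$points), model$config$refine$n_out)
  expect_true(all(is.finite(pts)))
  complete_cloud(partial_path, model, out2)
  expect_identical(readLines(out1), readLines(out2))
  # too-small input is rejected
  tiny <- tempfile(fileext = ".ply")
  write_ply_cloud(rand_cloud(4), tiny)
  expect_error(complete_cloud(tiny, model, tempfile()), "too few points")
})

test_that("checkpoints round-trip and reject mismatched configurations", {
  model <- toy_model()
  f <- tempfile(fileext = ".rds")
  save_checkpoint(model, f)
  back <- load_checkpoint(f)
  expect_equal(vc$get_param_values(back$weights),
               vc$get_param_values(model$weights))
  other <- model_config("toy", K = 4L)
  expect_error(load_checkpoint(f, config = other), "does not match")
  expect_silent(load_checkpoint(f, config = model$config))
})

test_that("training configurations survive a YAML round-trip", {
  cfg <- model_config("toy", multi_scope = FALSE, learning_rate = 5e-4)
  f <- tempfile(fileext = ".yaml")
  write_train_config(cfg, f)
  back <- read_train_config(f)
  expect_identical(back$encoder$k_list, cfg$encoder$k_list)
  expect_equal(back$train$learning_rate, 5e-4)
  expect_false(back$multi_scope)
})
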