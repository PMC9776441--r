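# Training loop (Adam on the joint loss), evaluation over a manifest split,
# and single-file inference.

.load_samples <- function(manifest, split) {
  idx <- which(manifest$split == split)
  lapply(idx, function(i) {
    partials <- lapply(manifest_partials(manifest, i),
                       function(p) read_ply(p)$points)
    list(sample_id = manifest$sample_id[i],
         category = manifest$category[i],
         complete = read_ply(manifest$complete_path[i])$points,
         partials = partials,
         graphs = vector("list", length(partials)))
  })
}

.adam_step <- function(params, lr, beta1, beta2, t, eps = 1e-8) {
  for (p in params) {
    g <- p$grad
    if (is.null(g)) next
    if (is.null(p$adam_m)) { p$adam_m <- g * 0; p$adam_v <- g * 0 }
    p$adam_m <- beta1 * p$adam_m + (1 - beta1) * g
    p$adam_v <- beta2 * p$adam_v + (1 - beta2) * g^2
    mhat <- p$adam_m / (1 - beta1^t)
    vhat <- p$adam_v / (1 - beta2^t)
    p$value <- p$value - lr * mhat / (sqrt(vhat) + eps)
  }
}

# Differentiable joint loss for one sample; gt clouds are plain matrices.
.ag_joint_loss <- function(fw, gt_coarse, gt_refine, alpha, sinkhorn_iters = 50L) {
  cv <- ag_value(fw$coarse)
  plan_c <- .sinkhorn_plan(.cross_dist(cv, gt_coarse), sinkhorn_iters)
  lc <- ag_transport_cost(fw$coarse, gt_coarse, plan_c)
  rv <- ag_value(fw$refined)
  plan_r <- .sinkhorn_plan(.cross_dist(rv, gt_refine), sinkhorn_iters)
  lr <- ag_transport_cost(fw$refined, gt_refine, plan_r)
  joint <- ag_add(ag_add(lc, lr), ag_scale(fw$expansion, alpha))
  list(joint = joint, l_coarse = ag_value(lc)[1], l_refine = ag_value(lr)[1],
       l_expansion = ag_value(fw$expansion)[1])
}

.sample_gt <- function(complete, n) {
  if (nrow(complete) == n) return(complete)
  complete[sample.int(nrow(complete), n, replace = nrow(complete) < n), ,
           drop = FALSE]
}

#' Train the completion network
#'
#' Every step draws a batch of training samples, picks one of the rendered
#' view angles per sample at random, runs encode -> decode -> refine,
#' computes the joint loss (approximate EMD on the coarse and refined
#' clouds plus the weighted expansion penalty) against ground-truth clouds
#' sampled from the complete cloud at matching cardinalities, and applies
#' one Adam update. Fully deterministic for a fixed config seed on CPU.
#'
#' @param manifest a `dataset_manifest` with a non-empty train split.
#' @param config a `model_config`.
#' @param n_steps optional step cap overriding `epochs` (used by the
#'   toy-scale experiments).
#' @param sinkhorn_iters iterations for the approximate EMD inside the loss.
#' @param verbose print the per-epoch mean loss.
#' @return list with `model` (trained), `history` (per-step data.frame with
#'   loss components).
#' @export
train_model <- function(manifest, config, n_steps = NULL, sinkhorn_iters = 30L,
                        verbose = FALSE) {
  samples <- .load_samples(manifest, "train")
  if (length(samples) == 0L) stop("train split is empty", call. = FALSE)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(config$train$rng_seed))
  model <- init_model(config, rng_seed = config$train$rng_seed + 1L)
  params <- collect_params(model$weights)
  tr <- config$train
  steps_per_epoch <- max(1L, ceiling(length(samples) / tr$batch_size))
  total_steps <- if (is.null(n_steps)) tr$epochs * steps_per_epoch else n_steps
  hist <- vector("list", total_steps)
  for (step in seq_len(total_steps)) {
    batch_idx <- sample.int(length(samples), tr$batch_size,
                            replace = length(samples) < tr$batch_size)
    batch_terms <- vector("list", length(batch_idx))
    comp <- numeric(3)
    for (b in seq_along(batch_idx)) {
      si <- batch_idx[b]
      smp <- samples[[si]]
      vi <- sample.int(length(smp$partials), 1L)
      partial <- smp$partials[[vi]]
      # the k-NN graph of a stored view never changes; cache it
      if (is.null(samples[[si]]$graphs[[vi]])) {
        samples[[si]]$graphs[[vi]] <-
          knn_graph(partial, max(config$encoder$k_list))
      }
      fw <- .ag_forward(model, partial, graph = samples[[si]]$graphs[[vi]])
      gt_coarse <- .sample_gt(smp$complete, model$config$decoder$coarse_size)
      gt_refine <- .sample_gt(smp$complete, model$config$refine$n_out)
      jl <- .ag_joint_loss(fw, gt_coarse, gt_refine, tr$alpha, sinkhorn_iters)
      batch_terms[[b]] <- jl$joint
      comp <- comp + c(jl$l_coarse, jl$l_refine, jl$l_expansion)
    }
    loss <- ag_scale(Reduce(ag_add, batch_terms), 1 / length(batch_idx))
    lval <- ag_value(loss)[1]
    if (!is.finite(lval)) {
      stop("non-finite joint loss at step ", step,
           " (components: ", paste(signif(comp / length(batch_idx), 4),
                                   collapse = ", "), ")", call. = FALSE)
    }
    for (p in params) p$grad <- NULL
    ag_backward(loss)
    .adam_step(params, tr$learning_rate, tr$adam_beta1, tr$adam_beta2, step)
    comp <- comp / length(batch_idx)
    epoch <- ceiling(step / steps_per_epoch)
    hist[[step]] <- data.frame(step = step, epoch = epoch,
                               l_coarse = comp[1], l_refine = comp[2],
                               l_expansion = comp[3], l_joint = lval)
    if (verbose && step %% steps_per_epoch == 0L) {
      message(sprintf("epoch %d  joint loss %.4f", epoch, lval))
    }
  }
  history <- do.call(rbind, hist)
  list(model = model, history = history)
}

#' Evaluate a model over a manifest split
#'
#' Runs the network on every partial view of every sample in the split and
#' scores the refined output against the complete cloud with Chamfer
#' distance, EMD (exact when the cardinality permits, otherwise the
#' approximate solver), and the F-score at 1% of the ground-truth
#' bounding-box diagonal. Metrics are aggregated per category and overall
#' (sample-weighted mean).
#'
#' @param manifest a `dataset_manifest`.
#' @param model a `completion_model` (or a checkpoint path).
#' @param split which split to evaluate (default `"test"`).
#' @param predict_fn optional override `function(partial, complete)` that
#'   returns the predicted cloud; used to audit the metric plumbing.
#' @return an `eval_report` data.frame with one row per category plus
#'   `"overall"`, columns `n`, `cd_x1000`, `emd_x1000`, `fscore`.
#' @export
evaluate_model <- function(manifest, model, split = "test", predict_fn = NULL) {
  if (is.character(model)) model <- load_checkpoint(model)
  samples <- .load_samples(manifest, split)
  if (length(samples) == 0L) stop("split '", split, "' is empty", call. = FALSE)
  rows <- list()
  for (smp in samples) {
    for (partial in smp$partials) {
      pred <- if (is.null(predict_fn)) {
        complete_partial(model, partial)$refined
      } else {
        predict_fn(partial, smp$complete)
      }
      emd_mode <- if (nrow(pred) <= 1024L && nrow(pred) == nrow(smp$complete)) {
        "exact"
      } else "approximate"
      gt <- if (nrow(pred) == nrow(smp$complete)) smp$complete else
        .sample_gt(smp$complete, nrow(pred))
      rows[[length(rows) + 1L]] <- data.frame(
        category = smp$category,
        cd = chamfer_distance(pred, smp$complete),
        emd = emd(pred, gt, mode = emd_mode),
        fscore = f_score(pred, smp$complete, fscore_threshold(smp$complete)))
    }
  }
  per <- do.call(rbind, rows)
  agg <- do.call(rbind, lapply(split(per, per$category), function(d) {
    data.frame(category = d$category[1], n = nrow(d),
               cd_x1000 = 1000 * mean(d$cd), emd_x1000 = 1000 * mean(d$emd),
               fscore = mean(d$fscore))
  }))
  overall <- data.frame(category = "overall", n = nrow(per),
                        cd_x1000 = 1000 * mean(per$cd),
                        emd_x1000 = 1000 * mean(per$emd),
                        fscore = mean(per$fscore))
  report <- rbind(agg, overall)
  rownames(report) <- NULL
  class(report) <- c("eval_report", "data.frame")
  report
}

#' Complete a partial point cloud from a PLY file
#'
#' Reads the partial cloud, normalizes it to the unit sphere by its own
#' centroid and radius, runs the network, inverts the normalization, and
#' writes the refined cloud as ascii PLY. Deterministic: the same input and
#' checkpoint produce a byte-identical output file.
#'
#' @param input_path PLY file with at least `max(k_list) + 1` points.
#' @param model a `completion_model` or checkpoint path.
#' @param output_path output PLY path.
#' @return the refined cloud (invisibly), denormalized.
#' @export
complete_cloud <- function(input_path, model, output_path) {
  if (is.character(model)) model <- load_checkpoint(model)
  pts <- read_ply(input_path)$points
  kmax <- max(model$config$encoder$k_list)
  if (nrow(pts) < kmax + 1L) {
    stop("input cloud has too few points (need > max k)", call. = FALSE)
  }
  tr <- normalize_cloud(pts)
  out <- complete_partial(model, tr$points)$refined
  out <- denormalize_cloud(out, tr)
  write_ply_cloud(out, output_path)
  invisible(out)
}

#' Write / read a training configuration as YAML
#' @param config a `model_config`.
#' @param path YAML file path.
#' @export
write_train_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_train_config
#' @return `read_train_config`: a `model_config`.
#' @export
read_train_config <- function(path) {
  raw <- yaml::read_yaml(path)
  do.call(model_config, c(list(preset = raw$preset %||% "paper",
                               multi_scope = raw$multi_scope %||% TRUE,
                               partial_input = raw$partial_input %||% TRUE),
                          raw$encoder, raw$decoder, raw$refine, raw$train))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
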