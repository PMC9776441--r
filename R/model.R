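# Model configuration, weight initialization, the full forward pass, and
# checkpointing.

#' Build a model/training configuration
#'
#' The `"paper"` preset follows the published recipe: 512-point partial
#' input, 2048-point complete clouds, K = 32 patches of 8 x 8 grids (2048
#' coarse points), Adam with beta1 = 0, beta2 = 0.9, learning rate 1e-4,
#' batch 32, 150 epochs, loss weight alpha = 0.1. The `"toy"` preset is a
#' small CPU-friendly variant of the same architecture (64-point partial,
#' 256-point complete, K = 8 patches of 32 points) used by the test-scale
#' experiments.
#'
#' Two ablation switches mirror the studied variants: `multi_scope = FALSE`
#' collapses the encoder to a single scope with k = 5, and
#' `partial_input = FALSE` removes both the partial-coordinate embedding in
#' the decoder and the merge of partial points before refinement.
#'
#' @param preset `"paper"` or `"toy"`.
#' @param multi_scope use multiple neighbourhood scopes in the encoder.
#' @param partial_input link the partial input into decoding/refinement.
#' @param ... named overrides of any top-level or nested field, e.g.
#'   `learning_rate`, `k_list`, `epochs`, `K`.
#' @return a nested `model_config` list with `$encoder`, `$decoder`,
#'   `$refine`, `$train` blocks.
#' @export
model_config <- function(preset = c("paper", "toy"), multi_scope = TRUE,
                         partial_input = TRUE, ...) {
  preset <- match.arg(preset)
  cfg <- if (preset == "paper") {
    list(
      encoder = list(k_list = c(5L, 10L, 20L), channels = c(64L, 128L, 256L, 512L)),
      decoder = list(K = 32L, grid_dims = c(8L, 8L), depth = 3L, width = 256L,
                     emb_dim = 64L),
      refine = list(lambda = 1.5, sigma = 0.05, n_out = 2048L),
      train = list(n_partial = 512L, n_complete = 2048L, batch_size = 32L,
                   learning_rate = 1e-4, adam_beta1 = 0, adam_beta2 = 0.9,
                   epochs = 150L, alpha = 0.1, rng_seed = 1L)
    )
  } else {
    list(
      encoder = list(k_list = c(4L, 8L), channels = c(8L, 16L, 16L, 32L)),
      decoder = list(K = 8L, grid_dims = c(8L, 4L), depth = 2L, width = 32L,
                     emb_dim = 16L),
      refine = list(lambda = 1.5, sigma = 0.05, n_out = 256L),
      train = list(n_partial = 64L, n_complete = 256L, batch_size = 4L,
                   learning_rate = 1e-3, adam_beta1 = 0, adam_beta2 = 0.9,
                   epochs = 10L, alpha = 0.1, rng_seed = 1L)
    )
  }
  cfg$preset <- preset
  cfg$multi_scope <- isTRUE(multi_scope)
  cfg$partial_input <- isTRUE(partial_input)
  dots <- list(...)
  for (nm in names(dots)) {
    hit <- FALSE
    for (blk in c("encoder", "decoder", "refine", "train")) {
      if (nm %in% names(cfg[[blk]])) { cfg[[blk]][[nm]] <- dots[[nm]]; hit <- TRUE }
    }
    if (!hit) cfg[[nm]] <- dots[[nm]]
  }
  if (!cfg$multi_scope) cfg$encoder$k_list <- 5L
  cfg$decoder$partial_mode <- if (cfg$partial_input) "embed" else "none"
  cfg$refine$merge_partial <- cfg$partial_input
  cfg$decoder$g_len <- 2L * utils::tail(cfg$encoder$channels, 1L)
  cfg$decoder$coarse_size <- cfg$decoder$K * prod(cfg$decoder$grid_dims)
  class(cfg) <- "model_config"
  cfg
}

#' Initialize a model (weights + config)
#'
#' @param config a `model_config`.
#' @param rng_seed seed for the weight draw (defaults to the config's
#'   training seed).
#' @return a `completion_model` list with `$config` and `$weights`.
#' @export
init_model <- function(config, rng_seed = config$train$rng_seed) {
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(rng_seed))
  weights <- list(encoder = init_encoder_weights(config$encoder),
                  decoder = init_decoder_weights(config$decoder))
  structure(list(config = config, weights = weights), class = "completion_model")
}

# Full differentiable forward pass on one sample. Returns ag nodes for the
# coarse cloud, the refined cloud (row-gathered from the merged pool at
# indices chosen by MDS on detached values), and the expansion penalty.
.ag_forward <- function(model, partial, graph = NULL) {
  cfg <- model$config
  pnode <- ag_node(as.matrix(partial))
  g <- .ag_encode(pnode, model$weights$encoder, cfg$encoder, graph = graph)
  coarse <- .ag_decode_coarse(g, pnode, cfg$decoder, model$weights$decoder)
  lexp <- .ag_expansion_penalty(coarse, cfg$decoder$K, cfg$refine$lambda)
  merged <- if (cfg$refine$merge_partial) {
    ag_concat_rows(list(coarse, pnode))
  } else coarse
  sel <- minimum_density_sample(ag_value(merged), cfg$refine$n_out,
                                sigma = cfg$refine$sigma)
  refined <- ag_rows(merged, attr(sel, "index"))
  list(g = g, coarse = coarse, refined = refined, expansion = lexp)
}

#' Run the completion network on a partial cloud
#'
#' @param model a `completion_model`.
#' @param partial N x 3 normalized partial cloud.
#' @return list with `coarse`, `refined` (matrices), `g` (vector), and the
#'   scalar `expansion` penalty.
#' @export
complete_partial <- function(model, partial) {
  fw <- .ag_forward(model, partial)
  list(coarse = ag_value(fw$coarse), refined = ag_value(fw$refined),
       g = as.vector(ag_value(fw$g)), expansion = ag_value(fw$expansion)[1])
}

.config_fingerprint <- function(config) {
  txt <- paste(deparse(unclass(config)), collapse = "")
  sprintf("%08x", sum(utf8ToInt(txt) * (seq_along(utf8ToInt(txt)) %% 97 + 1)) %% 4294967291)
}

#' Save / load a model checkpoint
#'
#' A checkpoint stores the configuration, every weight matrix, and a
#' fingerprint of the configuration used to detect mismatched loads.
#'
#' @param model a `completion_model`.
#' @param path file path (`.rds`).
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(list(config = model$config,
               values = get_param_values(model$weights),
               fingerprint = .config_fingerprint(model$config)), path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @param config optional `model_config` that the checkpoint must match;
#'   a mismatch is an error.
#' @return `load_checkpoint`: a `completion_model`.
#' @export
load_checkpoint <- function(path, config = NULL) {
  ck <- readRDS(path)
  if (!is.null(config) &&
      .config_fingerprint(config) != ck$fingerprint) {
    stop("checkpoint does not match the requested configuration", call. = FALSE)
  }
  model <- init_model(ck$config)
  set_param_values(model$weights, ck$values)
  model
}
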