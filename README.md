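# vesselcomplete

Point-cloud completion for 3D surface models of intracranial vessels and
aneurysms. Surface models segmented from clinical angiography are often
incomplete: a single viewpoint (or a failed reconstruction region) leaves
only part of the tubular geometry. `vesselcomplete` predicts the complete
shape from a partial observation.

The package is aimed at researchers working with vascular surface models
(or other tubular shapes) who want a fully CPU-reproducible, dependency-light
implementation of an encoder–decoder completion network together with the
standard evaluation metrics of the field.

## What is inside

**Model.** A partial cloud `P_in` (N×3) is encoded by four stacked
multi-scope aggregate (MSA) stages. Each stage runs several single-scope
modules (SSM) at different neighbourhood sizes *k*; an SSM computes an edge
convolution over the k-NN graph,

    e'_ij = max_{j:(i,j) in E} MLP(e_i, e_ij − e_i),

gates channels with a squeeze-excitation vector
`s = sigmoid(MLP(mean over all N·k edge features))`, and max-reduces the
edges per point. Branch outputs are fused by softmax attention and a
residual lift. Max- plus average-pooling of the last stage gives the global
feature `G`.

A style-based folding decoder deforms K fixed 2D lattices into 3D patches.
Every folding layer is re-modulated by adaptive instance normalization,

    AdaIN(x) = gamma_g * (x − mu(x)) / sigma(x) + beta_g,

with `(gamma_g, beta_g)` learned from `G` (and, when partial linking is
enabled, from a pooled embedding of the observed coordinates). The
concatenated patches form the coarse cloud. A refinement stage penalizes
patch spreading with an expansion penalty over per-patch Euclidean minimum
spanning trees,

    L_exp = 1/(K·N) * sum_i sum_{(u,v) in T_i} 1{dis(u,v) >= lambda·l_i} dis(u,v),

and merges/subsamples coarse (plus partial) points with minimum density
sampling. Training minimizes the joint loss

    L = EMD(P_coarse, P_gt_coarse) + EMD(P_refine, P_gt_refine) + alpha·L_exp,

with `alpha = 0.1`, using Adam (beta1 = 0, beta2 = 0.9, lr = 1e-4) — all on
a small reverse-mode autodiff engine included in the package, so no deep
learning framework is required.

**Metrics.** Chamfer distance (unsquared L2, symmetric mean
nearest-neighbour), Earth Mover's distance (exact linear assignment in
compiled code up to 1024 points, entropic Sinkhorn approximation for
training), and the F-score at 1% of the ground-truth bounding-box diagonal.

**Data.** A synthetic generator for watertight tubes, Y-bifurcations and
aneurysm-bearing tubes; area-uniform surface sampling; orthographic
depth-image rendering that back-projects visible pixels into partial
clouds; and a dataset builder that writes PLY pairs with a stratified
8:1:1 train/val/test manifest.

## Worked example

```r
library(vesselcomplete)

# synthetic dataset: 2 vessels, complete 256 / partial 64 points, 4 views
meshes <- list(generate_toy_shape("tube", 1), generate_toy_shape("tube", 2))
man <- build_dataset(meshes, c("vessel", "vessel"), "toy_data",
                     n_complete = 256, n_partial = 64, n_views = 4,
                     rng_seed = 3, resolution = 96)

cfg <- model_config("toy")           # CPU-sized preset of the architecture
run <- train_model(man, cfg, n_steps = 50, sinkhorn_iters = 10)
head(run$history$l_joint, 1); tail(run$history$l_joint, 1)
#> [1] 2.22847
#> [1] 0.2277229
```

The joint loss falls from 2.228 to 0.228 in 50 steps on this two-shape
overfit task — the sanity check that gradients reach every part of the
network. Scoring a completion against its ground truth:

```r
out <- complete_partial(run$model, read_ply(manifest_partials(man, 1)[1])$points)
gt  <- read_ply(man$complete_path[1])$points
1000 * chamfer_distance(out$refined, gt)   # CD x 10^3
1000 * emd(out$refined, gt, "exact")       # EMD x 10^3
f_score(out$refined, gt, fscore_threshold(gt))  # F-score @1%
```

A command-line wrapper (`inst/cli/vesselcomplete`) exposes the same
pipeline as subcommands `generate-data`, `train`, `evaluate`, `complete`
and `score`; `score` prints CD and EMD multiplied by 10^3, the convention
used in completion benchmarks.

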