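---
title: "Completing partial vascular point clouds: model, data and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Completing partial vascular point clouds: model, data and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Surface models of intracranial vessels and aneurysms reconstructed from
angiographic imaging are frequently incomplete: occlusion, a limited view,
or a failed segmentation region removes part of the tubular geometry.
`vesselcomplete` treats this as point-cloud completion: given a partial
cloud `P_in` sampled from the visible surface, predict a complete cloud of
the whole shape. Everything here runs on one CPU with reproducible seeds;
the network and its training loop are implemented on a small reverse-mode
autodiff engine over dense matrices (`R/autograd.R`), with the two hot
numeric kernels (linear assignment, Sinkhorn, density sampling) in
compiled code.

## Model

**Encoder.** Point clouds carry no connectivity, so local structure is
recovered from k-nearest-neighbour graphs in coordinate space. A
single-scope module (SSM) computes, for every directed edge, an edge
convolution `MLP(e_i, e_ij − e_i)` — the point's own feature plus its
neighbourhood offset — then gates channels with a squeeze-excitation
vector obtained by averaging all `N*k` edge features through a bottleneck
perceptron and a sigmoid, and finally max-reduces each point's k edges.
A fixed k under-represents shapes with uneven sampling density, which
tubular models have (thin branches vs. aneurysm sacs), so a multi-scope
aggregate (MSA) stage runs one SSM per value in `k_list`, averages the
branch maps into a descriptor, derives per-branch softmax attention
weights from it, rescales each branch's output, sums them, and adds the
lifted input back. Four MSA stages of increasing width feed channel-wise
max- and average-pooling whose concatenation is the global feature `G`.

Choices a reader should know about:

* `k_list = c(5, 10, 20)` (full preset). Only the single-scope ablation
  value k = 5 is fixed by the study design; the multi-scope set brackets
  it at doublings, a common multi-scale choice. Configurable.
* Channel widths 64/128/256/512 with `G` of length 1024 (512 max + 512
  average): a standard encoder ladder for 512-point inputs. Configurable.
* The k-NN graph is built once per forward pass in coordinate space and
  shared by all stages. Neighbourhoods are defined by Euclidean distance
  between points, not re-derived in feature space; this keeps the graph
  semantics fixed and saves three graph builds.
* Attention rescales branch *outputs* before summation, with a residual
  add of the lifted input. The alternative (weighting branch inputs) is
  equivalent up to where the nonlinearity sits; the output-side wiring is
  the one that is unambiguous and differentiable end to end.
* The attention head's hidden layer uses a bounded (sigmoid) activation.
  With the tiny hidden widths involved, a rectified hidden layer can be
  born dead, silencing the branch-weighting path permanently.
* Ties in k-NN and in max-pooling go to the smaller index, making every
  forward pass deterministic.

**Decoder.** K = 32 fixed 8×8 lattices in the unit square (64 vertices
each, 2048 coarse points) are each deformed by a stack of style blocks:
linear map, adaptive instance normalization, squeeze-excitation gate,
ReLU, and a final linear head to 3D. AdaIN standardizes each channel over
the patch's vertices (epsilon 1e-5 inside the square root, so a constant
channel maps to its shift parameter) and re-modulates it with a scale and
shift computed per layer from the style source. Injecting the style at
*every* depth keeps the global shape signal from washing out down the
stack — the failure mode of concatenate-once folding — and the tests
verify that perturbing `G` changes activations at every styled depth.

Partial-input linking: the observed coordinates should steer the fold. A
pooled embedding of the partial cloud (pointwise MLP, channel-wise max) is
concatenated to `G` as the style source. We first implemented the more
literal reading — tiling the embedding onto every grid vertex — and found
it provably inert: a tiled vector is constant per channel, and instance
normalization subtracts the per-channel mean, so the decoder output did
not depend on the partial input at all. Routing the embedding through the
style shift `beta_g` (which is applied *after* normalization) makes the
linking live, which a regression test now guards. The second linking
mechanism is merging the raw partial points into the refinement pool
(below); both are controlled by the `partial_input` flag that mirrors the
ablation switch.

**Refinement.** The K patches are decoded independently and tend to
overlap. Two remedies: (1) an expansion penalty — per patch, build the
Euclidean minimum spanning tree, take its mean edge length `l_i`, and sum
the lengths of edges ≥ `lambda * l_i`, normalized by `K*N`. The penalty is
scale-covariant because the threshold scales with `l_i`. Gradients flow
through the retained edge lengths only (straight-through on the indicator
and on the tree structure), the standard subgradient treatment. (2)
minimum density sampling — greedily pick the candidate with the lowest
Gaussian-kernel density relative to already-selected points — reduces the
merged coarse ∪ partial pool to the output size while equalizing density.
The first MDS pick is the point nearest the centroid: the defining rule is
degenerate at step one (the empty sum ties all candidates), and this
tie-break is deterministic. `lambda = 1.5` and `sigma = 0.05` (in
normalized units) follow the published defaults of the expansion-penalty
refinement this stage adopts. MDS selection is not differentiated through;
during training the refined cloud is the gather of selected rows, so
gradients reach the selected coordinates but the selection indices are
treated as constants.

**Loss and optimization.** Training minimizes
`EMD(coarse, gt_coarse) + EMD(refine, gt_refine) + 0.1 * L_exp`, with both
ground-truth clouds sampled from the complete cloud at the matching
cardinality (EMD requires equal sizes; the coarse output is `K*M` by
construction, so `gt_coarse` is sampled at `K*M`). Adam uses beta1 = 0,
beta2 = 0.9, learning rate 1e-4, batch 32, 150 epochs in the full preset;
no schedule, weight decay or clipping (none are part of the recipe).
Every step draws one of the eight stored view angles per sample.

## Metrics

* **Chamfer distance**: symmetric mean nearest-neighbour distance with
  *unsquared* L2 norms, matching the evaluation formula as printed;
  squared distances are available as an option.
* **EMD**: mean per-point cost of the optimal bijection. Exact mode solves
  the linear assignment problem by shortest augmenting paths (O(n³),
  limited to 1024 points); requests with unequal cardinalities are an
  error rather than silently resampled, so pipeline bugs surface.
  Approximate mode is a 50-iteration log-domain Sinkhorn solver whose
  entropic temperature anneals geometrically from 0.5× to 0.02× the mean
  pairwise cost; the returned plan's rows are exactly uniform. On uniform
  random clouds the approximate value stays within 10% relative + 0.02
  absolute of the exact optimum (measured once during development and
  frozen as the documented tolerance; the suite asserts it on 100
  64-point pairs). Training uses a shorter 10–30 iteration anneal — the
  gradient only needs a reasonable plan, not a converged one.
* **F-score @1%**: harmonic mean of precision and recall at a match
  radius of 1% of the ground-truth bounding-box diagonal — the common
  completion-benchmark convention; the percentage is configurable since
  the radius base is a convention, not a law.

## Synthetic data

Real vascular datasets cannot be redistributed here, so the generator
emulates their geometry: capped tubes swept along smooth random
centerlines (parallel-transport frames avoid twist), Y-bifurcations
(a second tube rooted on the trunk centerline), and aneurysm stand-ins
(an ellipsoidal bleb attached to the tube wall). Components are
individually closed meshes; a compound shape is their concatenation, so
every edge is shared by exactly two faces (the watertightness sense used
throughout) even though components interpenetrate. Consequences: a small
fraction of `sample_complete` points lies on buried internal surface, as
happens with imperfect real segmentations; no boolean surface union is
performed.

Complete clouds are sampled area-uniformly (face probabilities
proportional to area, square-root barycentric warp). Each sample is
normalized to the unit sphere — centroid at the origin, maximum radius 1 —
and the *same* transform is applied to its partial views, so metric values
are comparable across shapes. Partial views are rendered with an
orthographic camera (160×160 depth buffer, camera at 2.5× the shape
radius; azimuth uniform on [0, 2π), elevation uniform on [−π/3, π/3] to
avoid degenerate poles) and back-projected from pixels with finite depth.
Orthographic back-projection is exact and keeps the visibility audit
simple: every returned point is the first hit of its pixel's view ray,
which the tests verify with an independent ray caster. Because partial
points sit at pixel-ray intersections, a partial view is never a subset of
the complete sampling. The perspective-vs-orthographic question and the
image resolution are stand-in choices; real depth sensors differ.

Split rule: validation and test sizes are `floor(ratio * n)` per category,
remainder to train. On a 1694-vessel / 215-aneurysm census at 8:1:1 this
reproduces 1356:169:169 and 173:21:21 exactly (largest-remainder
allocation does not: it yields 1355:170:169 for the vessel class).

What passing tests on this generator do **not** show: robustness to
scanner noise, to segmentation artifacts, to real vessel-tree topology
beyond one bifurcation, or to the category imbalance of clinical data.
They do validate every computational contract: formula-level correctness
against literal-loop oracles, visibility, determinism, split arithmetic,
and end-to-end trainability.

## Problem sizes used by the suite

The full preset (512-point partials, 2048-point completes, K = 32,
150 epochs) is the configuration a GPU port would train; the shipped
experiments use the toy preset — 64-point partials, 256-point completes,
K = 8 patches of 32 points, batch 4, learning rate 1e-3 (a standard Adam
scale for very small networks; the full preset keeps 1e-4) — which
overfits a two-shape dataset to ~10–15% of its initial joint loss within
200 CPU steps under all four ablation-flag combinations. These sizes are
the package's chosen study conditions for CPU-scale verification.

## Known limitations

* O(N²) distance matrices throughout: fine to ~4096 points, not beyond.
* The exact-EMD solver is dense O(n³); 1024 points is the enforced limit.
* Inference normalizes a lone partial cloud by its own centroid/radius,
  which only approximates the training-time normalization (there the
  transform comes from the complete cloud). Completions of very
  asymmetric partials inherit that offset.
* Batches are accumulated sample-by-sample (no batched tensor dimension);
  throughput, not correctness, is the cost.
* MDS selection indices are non-differentiable and detached; the training
  signal for refinement flows only through selected coordinates.
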