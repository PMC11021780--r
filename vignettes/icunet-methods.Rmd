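---
title: "Methods: a cascaded 3D segmentation network with EM attention and dynamic convolutions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a cascaded 3D segmentation network with EM attention and dynamic convolutions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem and the model

Gliomas are segmented from four co-registered MRI contrasts (FLAIR, T1,
T1ce, T2) into four voxel classes — healthy (0), necrotic (1), edema (2)
and enhancing (4) — and evaluated over three nested regions: whole tumor
(labels 1∪2∪4), tumor core (1∪4) and enhancing tumor (4). `icunet`
implements a coarse-to-fine cascade of two 3D encoder–decoder networks:

1. **Stage 1** segments the 4-channel input with standard 3×3×3
   convolutions.
2. Its channelwise-softmax probabilities are concatenated with the input
   (8 channels) and passed to **stage 2**, which refines the result.

Each stage has four resolution levels (two convolutions per block, group
normalization, ReLU), 2× max pooling between levels, a bottleneck, and a
decoder with trilinear upsampling, pointwise channel reduction, lateral
(skip) concatenation and two further convolutions per level. Channel
width doubles per level from `base_width`; with `base_width = 16` and a
128-voxel input side the deepest lateral tensor is 128 channels × 16³,
and the output matches the input grid (4 × 128³).

Stage 2 differs from stage 1 in two ways:

* **Dynamic convolutions** replace every 3×3×3 convolution. A layer keeps
  K parallel kernels; per input sample, a squeeze-and-excitation head
  (global average pool → bottleneck affine + ReLU → affine to K →
  softmax) produces weights π with Σπ = 1, and the layer convolves with
  the aggregated kernel Σₖ πₖWₖ. Because convolution is linear in the
  kernel this equals the π-weighted sum of the K convolutions — the
  identity our test oracle exploits — while costing one convolution. The
  aggregation is linear in the kernels; the nonlinearity enters through
  π's dependence on the input.
* **EM attention** on the fourth (deepest) lateral connection. A
  pointwise convolution adapts channels, then t = 3 alternations of an
  E step (responsibilities Aₙₖ = softmaxₖ⟨Xₙ, μₖ⟩) and an M step
  (μₖ = Σₙ AₙₖXₙ / (Σₙ Aₙₖ + ε), columns renormalized to unit length)
  iterate K compact bases; the feature map is reconstructed as the
  low-rank product μAᵀ, passed through a second pointwise convolution and
  added residually. This aggregates long-range context at cost linear in
  the voxel count.

## Objective

The composite objective is
`0.5·CE(stage1) + 0.5·CE(stage2) + Dice(stage2)`. Cross-entropy is the
voxel-mean of −Σᵢ xᵢ log x̂ᵢ over softmax probabilities; the mean (rather
than the sum) makes the value independent of crop size. The Dice term is
soft (probabilities, not argmax), computed per foreground class with
ε = 1e-5 smoothing in numerator and denominator, and averaged over the
three foreground classes only: with background included, empty space
would dominate exactly the imbalance the Dice term exists to counter.
There is deliberately no stage-1 Dice term. Supervising stage 1 through
both its own cross-entropy and the fused softmax keeps the cascade
differentiable end to end, so both stages train jointly from scratch.

## Differentiation strategy

The package implements its own reverse-mode gradients layer by layer
(verified against central finite differences in the test suite). Two
paths are intentionally approximate:

* The EM inner loop is treated as a fixed solver: gradients flow through
  the final responsibilities and reconstruction (with the converged bases
  held constant) and through both pointwise convolutions, but not through
  the t basis updates. This is the standard stabilization for an
  iterative inner loop inside a learned model.
* The persistent global bases that seed the EM iteration are maintained
  by momentum (0.9) from each batch's converged bases, not by gradient
  descent, and are renormalized to unit columns after every update.

## Preprocessing and sampling

Intensities are z-score standardized per modality and per case over
**nonzero voxels only** — skull-stripped volumes are mostly zero
background, which would otherwise dominate the statistics — with the
population (1/N) standard deviation; zero voxels stay exactly zero, and a
channel with spread below 1e-8 is zeroed with a warning rather than
divided by ~0. Whether the statistics should be per case or dataset-wide
is an open choice; per-case is used, being robust to scanner-level
intensity shifts.

Training samples are random cubic crops (default 128³, any multiple of
16). With probability 0.5 the crop centers on a uniformly drawn tumor
voxel when one exists; purely uniform crops of brain volumes are mostly
background. Augmentation is restricted to label-safe transforms —
per-axis flips (p = 0.5 each), rotations by multiples of 90° in the
axial plane, and an intensity affine map with scale ~ U(0.9, 1.1) and
shift ~ U(−0.1, 0.1) on normalized intensities. The magnitudes are
package choices; only the categories (rotation, flipping, intensity) are
given by the protocol the package follows.

## Optimization

Adam with first-moment decay 0.95 (the protocol's "momentum"),
second-moment decay at its conventional 0.999, constant learning rate
0.001, decoupled weight decay 1e-5 (applied to weight tensors, not biases
or normalization parameters), batch size 3, 550 steps for the full-scale
configuration. "Iterations" is read as optimizer steps. The
dynamic-convolution softmax temperature is annealed linearly from 30 to 1
over the first 30% of steps, then held at 1 — without this, one kernel
tends to win all attention before the bank has differentiated.

## Inference

Full volumes are covered by sliding windows of the training crop size at
50% overlap; stage-2 softmax probabilities are averaged over overlaps
before the voxelwise argmax, and class 3 is mapped back to raw label 4.
Volumes smaller than the window are zero-padded and un-padded. The
window protocol is a package choice (the training protocol does not
specify one); probability averaging at 50% overlap is the common
volumetric default.

Two postprocessing steps, both standard for this domain and both
optional flags of `predict_case()`, clean the argmax map: voxels with
zero intensity in every modality are fixed to healthy (in skull-stripped
data, zero background *is* the healthy-label convention, and
tumor-biased training crops underrepresent pure background, which makes
background windows out-of-distribution); and only the largest
6-connected component of the predicted whole-tumor mask is kept, since
the tumors modeled here — like the phantom generator, which explicitly
excludes multi-focal disease — are single-focal, so detached satellite
predictions are spurious by assumption. In our held-out phantom
experiments the satellites removed by the second step appear near the
brain boundary, the region training crops sample least.

## Evaluation

Dice is 2TP/(FP + 2TP + FN) per region. HD95 is the 95th percentile of
the pooled symmetric surface distances (prediction surface → reference
surface and vice versa), with surfaces defined by 6-connectivity and
distances from an exact Euclidean distance transform honouring voxel
spacing; the implementation is validated against an exhaustive
pairwise-distance oracle. A "95% of the maximum" reading of HD95 exists
in parts of the literature but is not the benchmark definition; the
percentile form is used. Conventions for degenerate cases are explicit:
both masks empty → Dice 1 and HD95 0; exactly one empty → Dice 0 and
HD95 undefined (`NA`), excluded from means and counted separately. This
matters for low-grade gliomas that lack enhancing tumor entirely.

## The phantom generator

`generate_phantom()` emulates the *layout* of the target data so the
whole pipeline runs without any download: four co-registered volumes
with modality-dependent contrast over concentric tumor ellipsoids (edema
shell ⊃ necrotic rim ⊃ enhancing nucleus) inside a spherical brain
mask, additive Gaussian noise (default sd 10 against compartment
contrasts of roughly 30–110), zero outside the brain, written as NIfTI
with the `<case>_<modality>.nii.gz` naming scheme. Defaults make edema
brightest on FLAIR/T2 and the enhancing nucleus brightest on T1ce,
mirroring the qualitative contrast of real glioma MRI. Concentric
ellipsoids guarantee the region nesting ET ⊆ TC ⊆ WT by construction.

What phantoms do **not** model: MRI physics (bias fields, partial
volume, anisotropic resolution), multi-focal or irregularly shaped
tumors, inter-case intensity distribution shifts. A network that
segments phantoms has demonstrated that the architecture, losses,
gradients, training loop and inference plumbing work together — not that
it would reach competitive accuracy on real brain MRI, which requires
the real datasets and GPU-scale training.

## Numerical choices

* M-step stabilizer ε = 1e-6; an attention column with (numerically)
  zero mass keeps its previous basis.
* Dice smoothing ε = 1e-5; log-sum-exp stabilization in every softmax
  and cross-entropy.
* Group normalization uses 8 groups (clipped to the channel count),
  variance floor 1e-5 — chosen over batch normalization because the
  reference batch size of 3 is too small for stable batch statistics.
* Max-pool ties resolve to the first maximum in memory order;
  trilinear upsampling uses half-voxel alignment with edge clamping.
* Default K = 64 EM bases and K = 4 dynamic kernels with reduction
  r = 4; neither is fixed by the protocol, and both follow the values
  common in the respective literatures. Both are configurable.
* Weight initialization is He-scaled Gaussian, seeded; every random
  choice in the package draws from an explicitly seeded stream, so a
  configuration plus seed fully determines phantoms, weights, sampling
  and the training trajectory.

## Desk-scale problem sizes

The tests and the acceptance script exercise a scaled-down configuration:
64³ phantoms, 32³ crops, `base_width` 8, 2 dynamic kernels, 8 EM bases,
300 optimizer steps with batches of 2, training on 4 phantoms and
evaluating on 2 held-out phantoms. These sizes keep a full
train-and-evaluate cycle in the minutes range on one CPU core while
leaving every architectural element (cascade, EM attention, dynamic
convolutions, composite loss, sliding-window inference) in play. The
full-scale defaults (128³ crops, `base_width` 16, batch 3, 550 steps)
are the package defaults in `train_config()` but need GPU-class
throughput and the real datasets to be meaningful.

## Known limitations

* Training throughput is CPU-bound R + BLAS; the implementation is for
  correctness, method study and desk-scale experiments, not competitive
  training runs.
* The EM gradient approximation (above) means stage-1 gradients that
  flow through the stage-2 attention module are approximate; the test
  suite checks the exactly-differentiated paths against finite
  differences and tolerates this approximation where it applies.
* Checkpoints are R serializations of the full parameter tree; they are
  versioned by the package version string but no cross-version migration
  is attempted.
* No test-time augmentation, ensembling, or more than two cascade
  stages.
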