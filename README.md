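# icunet

A self-contained R implementation of a **two-stage cascaded 3D
encoder–decoder network** for multi-modal brain-tumor segmentation, with
an **expectation–maximization (EM) attention** module on the deepest
lateral connection of the refinement stage and **dynamic
(attention-aggregated) 3D convolutions** throughout that stage — plus
everything around it: NIfTI I/O in the BraTS layout, z-score
preprocessing, tumor-biased patch sampling and label-safe augmentation,
the compound cross-entropy + Dice objective, Adam training,
sliding-window inference, Dice / 95th-percentile-Hausdorff evaluation
over the whole-tumor (WT), tumor-core (TC) and enhancing-tumor (ET)
regions, and a synthetic nested-ellipsoid phantom generator so the whole
pipeline runs with no dataset download.

It is written for method study and desk-scale experiments: the network
engine (3D convolutions, pooling, trilinear upsampling, group
normalization, and all reverse-mode gradients) is implemented in the
package itself in R and C++ (BLAS-backed), verified against
finite-difference and brute-force oracles in the test suite.

## The model in brief

Stage 1 is a 3D U-Net (4 levels, two 3×3×3 convolutions + group norm +
ReLU per block, 2× max pooling, trilinear upsampling, lateral skips)
that maps the 4-modality input (FLAIR, T1, T1ce, T2) to 4 class scores.
Its softmax probabilities are concatenated with the input (8 channels)
and refined by stage 2, where

- every 3×3×3 convolution keeps K parallel kernels and convolves with
  the per-sample softmax-weighted aggregate `Σₖ πₖ Wₖ` (`Σₖ πₖ = 1`,
  π from a squeeze-and-excitation head on the input), and
- the fourth lateral tensor passes through EM attention: t = 3
  alternations of responsibilities `Aₙₖ = softmaxₖ⟨Xₙ, μₖ⟩` and basis
  updates `μₖ = Σₙ Aₙₖ Xₙ / (Σₙ Aₙₖ + ε)`, then the low-rank
  reconstruction `μAᵀ` is added residually.

Both stages are supervised jointly by
`0.5·CE₁ + 0.5·CE₂ + Dice₂` (soft Dice over the three foreground
classes). Labels follow the BraTS vocabulary 0/1/2/4 and the evaluation
regions are WT = {1,2,4}, TC = {1,4}, ET = {4}.

See `vignettes/icunet-methods.Rmd` for the full methods account.

## Worked example

```r
library(icunet)

# 6 phantom cases: 64^3, four modalities, nested tumor compartments
cohort <- generate_cohort(6, base_seed = 101, grid_shape = c(64, 64, 64))

# a small configuration that trains in minutes on one CPU core
cfg <- train_config(iterations = 300, batch_size = 2, crop_size = 32,
                    base_width = 8, dyconv_kernels = 2, ema_bases = 8,
                    seed = 202)
ck <- train(cfg, cohort[1:4], verbose = TRUE)
#> step    1  total 2.2581 (ce1 1.3764 ce2 1.2643 dc2 0.9378)
#> step  100  total 1.0135 (ce1 0.4068 ce2 0.2333 dc2 0.6935)
#> step  300  total 0.3149 (ce1 0.0940 ce2 0.0302 dc2 0.2528)

# sliding-window inference on a held-out phantom, then region metrics
pred <- predict_case(ck, cohort[[5]]$stack)
evaluate_case(pred, cohort[[5]]$label, case_id = "held-out")
#> # A tibble: 1 × 7
#>   case_id  dice_wt dice_tc dice_et hd95_wt hd95_tc hd95_et
#>   <chr>      <dbl>   <dbl>   <dbl>   <dbl>   <dbl>   <dbl>
#> 1 held-out   0.979   0.979   0.997       1       1       0
```

The composite loss falls by roughly an order of magnitude over 300
steps, and the refined prediction overlaps the held-out phantom's
whole-tumor region with Dice ≈ 0.98; `dice_*` are overlap scores in
[0, 1] (1 = perfect), `hd95_*` are 95th-percentile surface distances in
voxel units (0 = surfaces coincide, `NA` = undefined because exactly one
mask is empty).

There is also a command-line interface (`inst/cli/icunet`) with
`simulate`, `train`, `predict` and `evaluate` subcommands over NIfTI
directories and CSV reports.

## Scope

Phantoms validate the machinery, not clinical accuracy: reaching the
accuracy that a network of this design attains on real brain MRI
requires the actual BraTS datasets and GPU-scale training, which are
outside this package's scope.
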