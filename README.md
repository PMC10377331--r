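# cesynth

Synthesis of portal-venous-phase contrast-enhanced liver MR (T1ce) from two
pre-contrast inputs — T1-weighted (T1pre) and T2-weighted — with a
conditional GAN, for settings (e.g. adaptive radiotherapy monitoring) where
repeated gadolinium injections are undesirable. The package is aimed at
medical-image-synthesis researchers who want an inspectable, fully-tested
reference implementation of the model, its training recipe, and its entire
evaluation suite, exercisable end-to-end on a seeded synthetic phantom.

## The model

The generator `G` encodes T1pre and T2 with separate convolutional encoders
and fuses them at every level by **sparse channel attention**: learned
nonnegative weights `c` are soft-thresholded,

    c* = S_lambda(c) = max(c - lambda, 0),

so weakly-informative fused channels contribute exactly zero. Training
combines three mechanisms around a pix2pix-style conditional GAN:

    min_G max_{D1,D2,D3}  sum_k L_cGAN(G, D_k)  +  lambda1 * L_GR(G)  +  lambda2 * L_L1(G)

* `L_GR = || g (x) (G(x1,x2) - y) ||^2` with `g` the Sobel operator —
  penalizes edge/texture discrepancies (vessels, tumor rims).
* `D1..D3` score the candidate at full/half/quarter resolution,
  conditioned on the inputs, and additionally see a Gaussian-blurred copy of
  the synthetic image as a negative — an explicit penalty on over-smoothing
  (multi-scale multi-smoothness discrimination).
* `lambda2 = 100`; `lambda1` ramps 0→50 over the first 50 epochs then
  freezes; Adam (batch 16) with learning rate 2e-4 for 50 epochs then linear
  decay to 0 at epoch 150.

The convolutional engine (forward passes and hand-derived backward passes,
im2col + BLAS) is implemented inside the package; gradients are verified
against finite differences in the test suite. Evaluation covers MSE, PSNR,
global SSIM, tumor CNR, Dice, Hausdorff distance, tumor center-of-mass
shift, and a Turing-test scoring harness.

Because clinical paired studies cannot be shipped, a seeded abdominal
phantom generator provides studies with a *known* deterministic enhancement
rule (`T1ce = T1pre + gain` on vessel and tumor-rim pixels), per-study
heterogeneity, optional noise and breathing-motion-style mis-registration —
so the learning task has a certifiable zero-MSE floor.

## Worked example

```r
library(cesynth)

# 30 noise-free phantom studies: 20 train / 5 val / 5 test, 64x64
params <- phantom_params(image_size = 64, noise_sd = 0, seed = 1)
make_dataset(20, 5, 5, params, "phantoms")
manifest <- load_manifest("phantoms/manifest.csv")

# the task is well-posed: the latent-class oracle reaches the floor
st <- load_study(manifest, "study021")
mse(st$t1ce$intensities,
    enhancement_oracle(st$t1pre$intensities, st$t2$intensities, params))
#> [1] 0

# 5-epoch smoke training of the full model, then the L1-only ablation
fit  <- train(manifest, smoke_config(seed = 1, ablation = "full"))
abl  <- train(manifest, smoke_config(seed = 1, ablation = "no_gr_no_mmd"))
fit$history$val_mse[c(1, 6)]   # untrained -> epoch 5
#> [1] 5463.188 2072.289
tail(abl$history$val_mse, 1)
#> [1] 2119.012

summarise_metrics(synthesize_split(fit, manifest, "test"))
#> # A tibble: 3 x 3
#>   metric     mean       sd
#>   <chr>     <dbl>    <dbl>
#> 1 mse    1964.    127.
#> 2 psnr     15.2     0.279
#> 3 ssim      0.122   0.0233
```

Five epochs at smoke scale cut the validation MSE to under half the
untrained network's and, under this paired seed, keep the full model at or
below its no-GR-no-MMD ablation — the direction expected of the two removed
mechanisms. (Converged quality requires the full 150-epoch recipe.)

The Turing-test harness aggregates per-rater correct counts; on the bundled
six-rater example counts it prints:

```r
turing_score(readr::read_csv(system.file("extdata", "turing_counts.csv",
                                         package = "cesynth")))
#> Turing test: 52.33% +/- 6.06 correct across 6 raters
```

A score near 50% means raters cannot tell synthetic from real slices.

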