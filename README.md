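# neurorecon

Reconstruction of structural brain MRI volumes with a fully-connected
bottleneck autoencoder, and discrimination of two diagnostic groups (the
motivating application is autism spectrum disorder, ASD, versus typical
controls) with a 3D convolutional neural network — implemented end to end in
R, with a synthetic brain-phantom generator so the whole pipeline runs at
desk scale without any clinical data.

It is aimed at methods researchers who want a small, fully seeded, fully
tested reference implementation of this two-stage design: every stage — from
NIfTI ingestion to the ROC report — is a plain R function with deterministic
behaviour under a seed.

## The model

**Stage 1 — reconstruction.** A volume is flattened (last-axis-fastest; a
128³ volume becomes a vector of length 2,097,152) and passed through a
symmetric dense autoencoder with layer sizes `[D, 4, 2, H, 2, 4, D]`:

- encode: `h = σ_e(W₁x + b₁)` applied layerwise, `σ_e` the rectifier,
  giving a 2-unit bottleneck code;
- decode: `y = σ_d(W₂h + b₂)` with rectifier interior layers and a final
  tanh, so `y ∈ (−1, 1)ᴰ`.

Training minimizes squared reconstruction error
`J(W,b) = Σ‖y − x‖₂²` (per-element mean by default) by backpropagation,
streaming one volume at a time (batch size 1) with Adam
(learning rate 0.001, ε = 1e−08); momentum SGD, RMSprop and Adagrad are
available for comparison. Model complexity is the exact scalar count
`U = Σ_α (n_{α−1}·n_α + n_α)`.

**Stage 2 — discrimination.** A 3D CNN (3×3×3 kernels: 2 then 8 filters at
stride 2, average pooling 2³, then 16/32/64/128 filters at stride 1 with
batch normalization; dense 128-relu and 64-tanh layers with dropout 0.5; a
2-unit softmax head) maps a volume to `(p_healthy, p_diseased)`, trained
with Adam (lr 1e−05) on binary cross-entropy under a reduce-on-plateau
schedule. Evaluation: SSIM/PSNR/MAE/MSE for reconstructions; ROC, AUC and
per-class accuracy for the classifier.

Since no clinical cohort ships with the package, a phantom module generates
labeled brain-like volumes: an ellipsoidal brain containing ellipsoidal
interior regions, a subset of which gain a mean-intensity offset
(`effect_size`) in the diseased class, plus Gaussian voxel noise — the known
ground truth the pipeline is tested against.

## Worked example

```r
library(neurorecon)

spec <- phantom_spec(shape = c(16, 16, 16), noise_sd = 0.02, seed = 7)
vol  <- normalize_volume(generate_phantom(spec, label = 0), c(-1, 1))
vol
#> <mri_volume> 16 x 16 x 16 voxels, spacing 1 x 1 x 1 mm
#>   intensities in [-1, 1], normalized to [-1, 1]

ae <- ae_init(input_dim = prod(dim(vol)), seed = 3)
parameter_count(ae)
#> <complexity_estimate> layers 4096-4-2-2-2-4-4096: 36,902 trainable parameters

fit <- ae_train(ae, list(vol), train_config(epochs = 6000, seed = 3))
fit
#> <ae_fit> 6000 epochs (adam), final loss 3.38493e-05

recon <- reconstruct_volume(fit$params, vol)
reconstruction_report(vol, recon, group = "HC")
#> # A tibble: 1 × 6
#>    ssim  psnr     mae       mse group shape
#>   <dbl> <dbl>   <dbl>     <dbl> <chr> <chr>
#> 1 1.000  50.7 0.00260 0.0000338 HC    16x16x16
```

The report reads as: after overfitting one 16³ phantom, the reconstruction
is structurally indistinguishable from the input (SSIM ≈ 1), with a peak
signal-to-noise ratio of 50.7 dB and mean absolute error of 0.0026 on the
(−1, 1) intensity scale. The classification stage follows the same pattern:

```r
cohort <- generate_cohort(phantom_spec(seed = 11), n_per_class = 20) |>
  cohort_map(\(v) normalize_volume(v, c(-1, 1)))
cnn  <- build_cnn(cnn_config(input_shape = c(32, 32, 32), seed = 5))
cfit <- train_cnn(cnn, cohort, epochs = 30)
holdout_eval(cfit, cohort)   # ROC/AUC/accuracy on the stratified 20% split
```

A command-line driver wrapping these functions (subcommands `simulate`,
`train-ae`, `reconstruct`, `eval-recon`, `train-cnn`, `eval-clf`,
`visualize`, `compare-optimizers`, each writing a JSON run manifest) is
installed at `system.file("cli", "neurorecon", package = "neurorecon")`.

See `vignettes/neurorecon-methods.Rmd` for the full account of the model,
the phantom design, and every numerical convention.

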