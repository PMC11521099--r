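---
title: "Methods: dense-autoencoder MRI reconstruction and 3D CNN discrimination"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dense-autoencoder MRI reconstruction and 3D CNN discrimination}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The pipeline

`neurorecon` implements a two-stage analysis of structural brain MRI:

1. **Reconstruction.** A volume is flattened to a vector and passed through a
   fully-connected symmetric autoencoder. The encoder applies two
   rectifier-activated dense layers of 4 and 2 units; an intermediate
   fully-connected layer of width $H$ sits between encoder and decoder; the
   decoder mirrors the encoder (2 then 4 rectifier units) and ends in a tanh
   output layer of the input dimension $D$, so layer sizes are
   $[D, 4, 2, H, 2, 4, D]$. Encoding is $h = \sigma_e(W_1 x + b_1)$ applied
   layerwise with $\sigma_e$ the rectifier; decoding is
   $y = \sigma_d(W_2 h + b_2)$ with interior rectifiers and a final tanh, so
   reconstructions live in $(-1, 1)$.
2. **Discrimination.** The (reconstructed) volume feeds a 3D convolutional
   network that outputs a two-class softmax — probability of the diseased
   class (label 1) versus the healthy class (label 0).

Reconstruction quality is scored with SSIM, PSNR, MAE and MSE; the
classifier with ROC curves, AUC and per-class accuracies.

# The autoencoder and its training

The training loss is squared reconstruction error,
$J(W, b) = \sum_x \lVert y(x) - x \rVert_2^2$. Two conventions of the same
quantity are exposed: the default `loss = "mean"` divides by $D$ so the loss
scale is independent of volume size, and `loss = "sum"` is the raw squared
norm. `sgd_step()` implements the plain gradient-descent update
$W \leftarrow W - v\,\partial J/\partial W$,
$b \leftarrow b - v\,\partial J/\partial b$ exactly and is kept separate so
its arithmetic is directly testable; the training default is Adam (learning
rate $v = 0.001$, $\varepsilon = 10^{-8}$), which handles the noisy
batch-size-1 regime far better. Momentum SGD, RMSprop and Adagrad are
provided for the optimizer comparison harness.

Design choices that the underlying description left open, and how this
package resolves them:

* **Mean vs. sum loss.** The loss is described both as a sum of squared
  norms and as mean squared error; we default to the per-element mean (scale
  independence) and expose the sum as an option.
* **Decoder activation.** The decoder is described both as using "the same"
  nonlinearity as the encoder and as ending in tanh; we use rectifiers on
  interior decoder layers and tanh on the output layer, matching the
  architecture description.
* **Interior width $H$.** No value is fixed by the architecture description;
  the default is 2 (a continuation of the bottleneck) and it is configurable.
  A 2-unit bottleneck for volumes with millions of voxels is an extreme
  compression; it is implemented as specified rather than silently widened.
  With a single training volume the network can still memorize its target
  through the output biases ($y = \tanh(b)$ reaches any interior point), which
  is exactly the overfit regime the single-phantom training test exercises.
* **Weight initialization.** Seeded uniform fan-in draws,
  $U(-1/\sqrt{n_\text{in}}, 1/\sqrt{n_\text{in}})$, biases zero. Every run is
  reproducible from its seed.
* **Epoch semantics.** One epoch is one pass over the (possibly single-item)
  dataset with batch size 1 streaming, mirroring generator-style training of
  large volumes; the epoch budget is always a config value.
* **2D mode.** Slice experiments use the same architecture with $D$ the
  pixel count; only $D$ and $H$ vary between modes.

Model complexity is reported as the exact count of trainable scalars,
$U = \sum_{\alpha=1}^{d} (n_{\alpha-1} n_\alpha + n_\alpha)$ — connection
weights plus biases — and is printed whenever a model is built.

# The 3D CNN discriminator

The layer stack is: conv $3^3{\times}2$ stride 2 → conv $3^3{\times}8$
stride 2 → batch norm → average pool $2^3$ stride 2 → conv $3^3$ with 16,
32, 64, 128 filters at stride 1 (same-padding, preserving spatial
resolution), each rectifier-activated and batch-normalized → flatten →
dense 128 (rectifier) → dropout 0.5 → dense 64 (tanh) → dropout 0.5 →
dense 2 softmax. Training minimizes binary cross-entropy with Adam at
learning rate $10^{-5}$ under a reduce-on-plateau schedule (factor 0.5,
patience 5 epochs, floor $10^{-7}$ — the callback is named in the source
description, the values are this package's choices). The exact ordering of
the deep layers is not fully pinned down by the description (one 8-filter
layer is assumed before the 16–128 progression); the whole plan lives in
`cnn_config()` so alternatives are one argument away.

Implementation notes: convolutions are evaluated by an im2col lowering
(compiled C++) followed by a BLAS matrix product; batch normalization with
batch size 1 normalizes each channel over its spatial positions during
training and uses running statistics (momentum 0.9) at inference; dropout
is inverted and disabled at inference, so prediction is deterministic.
Same-padding is used everywhere. The positive class for ROC scoring is the
diseased label (1), the conventional choice; accuracy uses a 0.5 cut on
that probability. The train/validation split is stratified 80/20 with a
seeded shuffle.

# The phantom generator

Real cohorts of T1-weighted volumes (the motivating application is
autism-spectrum versus typical-control discrimination) are replaced by
synthetic phantoms so every stage runs on a desk in minutes:

* an ellipsoidal "brain" (semi-axes 0.9 of the half-extent) of tissue
  intensity $0.5\,b$ on a zero background, where $b$ is `base_intensity`;
* `n_regions` interior ellipsoidal regions at intensity $b$, placed by a
  deterministic function of the spec seed so every subject shares one
  layout — mirroring the idea that fixed cortical areas carry the
  diagnostic signal;
* the first half of the regions ("designated") gain `effect_size` for
  class-1 subjects;
* i.i.d. additive Gaussian voxel noise with `noise_sd`.

Defaults are a $32^3$ grid, 5 regions, $b = 1$, effect 0.5 and noise 0.05
— an effect-to-noise ratio of 10 chosen so the two classes are clearly
separable by design, which is what an end-to-end discrimination check needs;
the null behaviour is obtained by setting `effect_size = 0` or shuffling
labels. With `noise_sd = 0` generation is a deterministic function of
`(spec, label, draw_index)`; all randomness flows from the single spec seed
through private RNG streams, leaving the caller's RNG state untouched.

What the phantoms deliberately do **not** model: anatomy (tissue classes,
cortex/white-matter geometry), MR physics (Rician noise, bias fields,
partial-volume effects), motion artifacts, or inter-site heterogeneity.
Passing tests therefore demonstrate that the algorithms are implemented
correctly and can detect a regional intensity effect of known location and
size under Gaussian noise — not that they reach any particular performance
on real clinical data.

# Metrics

* **MSE / MAE**: plain element means of squared / absolute differences.
* **PSNR**: $10 \log_{10}(R^2 / \mathrm{MSE})$ dB with $R$ the data range
  (2 for $(-1,1)$-normalized intensities); infinite for identical inputs.
* **SSIM**: mean over sliding windows of
  $\frac{(2\mu_x\mu_y + C_1)(2\sigma_{xy} + C_2)}
        {(\mu_x^2 + \mu_y^2 + C_1)(\sigma_x^2 + \sigma_y^2 + C_2)}$
  with $C_1 = (0.01 R)^2$, $C_2 = (0.03 R)^2$. 2D inputs use an 11×11
  Gaussian window ($\sigma = 1.5$); 3D inputs a uniform $7^3$ window; both
  are evaluated only where the full window fits (no padding) and use
  population (weighted-mean) moments. Whether to score volumes
  volumetrically or slice-by-slice is left to the caller — both are single
  calls. All constants are arguments.
* **ROC/AUC**: threshold sweep over unique scores with ties grouped;
  trapezoidal area, identical to the normalized Mann–Whitney statistic with
  half credit for ties.

Numerical conventions worth noting: min–max normalization maps constant
volumes to the interval midpoint (avoiding 0/0); flattening is
last-axis-fastest over the (x, y, z) axes and is documented and constant —
any fixed order works because the autoencoder is fully connected; slice
indices are 1-based, following R convention; NIfTI volumes are reoriented
to a RAS-like layout on read so slice axes mean the same thing for every
input.

# Problem sizes and reproducibility

The test-suite and acceptance-script runs use the package's desk-scale
study conditions: single-phantom autoencoder overfit at $16^3$ (6000 Adam
epochs), optimizer comparison at $16^3$ (300 epochs), and end-to-end
classification on a 20+20 cohort at $32^3$ trained for 30 epochs with
held-out evaluation on the stratified 20% split, plus label-shuffled
controls. The published-scale configuration ($128^3$ volumes, 2,097,152-long
flattened inputs) is fully supported by the same code paths; only the
phantom sizes differ. Every stochastic step — weight initialization, sample
order, dropout, splits, phantom noise — derives from explicit integer seeds,
and repeated runs with one seed are bit-identical.

# Known limitations

* The CNN trains sample-by-sample (batch size 1); there is no mini-batch
  batch-norm, GPU path or parallelism — $128^3$ training is possible but
  slow.
* SSIM windows are hypercubic; anisotropic voxel spacing is carried as
  metadata but not used to shape windows.
* The classifier evaluation is a single stratified split, not
  cross-validation (out of scope by design).
* Phantom realism is intentionally minimal (see above).
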