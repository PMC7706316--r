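---
title: "Synthesizing field-style maize tassel images: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing field-style maize tassel images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tasselsynth)
```

## The problem

Machine-learning models for field phenotyping of maize need training images
of tassels — the male inflorescence, a central spike with lateral branches —
photographed against natural backgrounds. Such data are scarce: most
available tassel imagery is lab-based, captured against uniform backdrops.
`tasselsynth` addresses the gap generatively: two separate deep
convolutional generative adversarial networks (DC-GANs) learn the
distribution of (a) segmented tassel patches on black backgrounds and (b)
sky patches, and their outputs are composited through a binary mask into
labelled field-style images. Synthesizing foreground and background
separately keeps each generation problem simple; the compositing stage
supplies the ground-truth segmentation mask for free.

## The adversarial model

The networks follow the DC-GAN template: the generator maps a latent vector
$z \sim \mathcal{N}(0, I_{100})$ through a stack of 4x4 transposed
convolutions (stride 2, padding 1), each doubling the spatial resolution
from 4x4 up to the output size, with ReLU activations and a final tanh so
outputs live in $[-1, 1]$; the discriminator mirrors this with strided
convolutions, leaky-ReLU (slope 0.2) and a sigmoid output. A model for
$R \times R$ output has $\log_2(R/4) + 1$ stages, so 6 stages at 128 and 5
at 64. Channel widths double toward the coarse end
(1024, 512, 256, 128, 64, 3 for the 128 model with the default
`base_channels = 64`).

Training alternates one discriminator update with one generator update per
mini-batch (configurable via `g_steps_per_d_step`), using the
cross-entropy losses

$$\mathcal{L}_D = -\mathbb{E}[\log D(x)] - \mathbb{E}[\log(1 - D(G(z)))],
\qquad \mathcal{L}_G = -\mathbb{E}[\log D(G(z))],$$

the non-saturating generator form standard for DC-GANs. Probabilities are
clamped to $[10^{-7}, 1 - 10^{-7}]$ before the logarithms, so a saturated
discriminator yields large finite losses rather than infinities. The
optimizer is Adam with $\beta_1 = 0.5$, $\beta_2 = 0.999$.

### Two deviations from the DC-GAN template

**Batch normalization is removed** from both networks. With batch norm in
place the discriminator converges within a few epochs — its loss collapses
toward zero — after which the generator receives no usable gradient and
never learns. Removing normalization delays discriminator convergence and
keeps the adversarial game alive. This is viable here because the tassel
patches are mostly black background with limited color variation, so the
stabilizing effect of batch norm is not needed. `run_ablation()` reproduces
the contrast: at desk scale, the with-batch-norm discriminator drives its
loss far lower, far earlier, than the without-batch-norm variant (see
"Desk-scale study conditions" below).

**Residual additions in the generator.** Going from 5 stages (64x64) to 6
stages (128x128) triggers the classic degradation problem: the deeper
network trains worse than the shallower one and fails to learn the colors
of the foreground. The remedy is a ResNet-style skip: the feature maps of
stage $i$ are upscaled by 2 (nearest-neighbour by default, bilinear
optionally) and passed through a learned 1x1 convolution that matches the
channel count of stage $i+1$; the result is added to stage $i+1$'s
pre-activation output. Residuals attach to the 16, 32, 64 and 128
resolution stages (`residual_stages`). Kept on for the whole run they
eventually inject noise into the generations, so the schedule
`residual_schedule(epoch, disable_epoch)` switches them off after the
first 40% of training (1000 of 2500 epochs in the full-scale recipe);
epoch indices are 0-based, so epochs $0 \ldots d-1$ run with residuals.

The 1x1 projection weights are learned parameters, initialized like every
other kernel from $\mathcal{N}(0, 0.02^2)$. The sky model needs no
residuals (sky patches show no degradation at 128), so its generator is
the plain no-batch-norm variant.

### Full-scale training recipes

The reference recipes are 2500 epochs at learning rate $1.5 \times 10^{-5}$
for the tassel model and 600 epochs at $2 \times 10^{-5}$ for the sky
model, both at 128x128. Batch size is not part of the published recipes;
the default is 64. These runs take GPU-hours; the package supports them,
but everything in the test suite and the acceptance script runs at desk
scale (below).

## Dataset preparation

Lab captures are center-cropped (`crop_center`, window offset
$\lfloor (H-h)/2 \rfloor$), converted to YCbCr (ITU-R BT.601 full-range —
the common still-image convention; nothing in the method depends on the
variant, but fixing one makes the Otsu contracts exact), and segmented by
Otsu-thresholding the Cb chroma channel, which separates the brownish
tassel from a bluish backdrop. The tassel-side class is the one whose mean
Cb lies farther from the backdrop mode; when that ties, the smaller class
wins, since the tassel occupies a minority of the frame. Background pixels
are forced to exact black. Patches are resized bicubically (Catmull-Rom,
$a = -0.5$) to the model resolution and mapped to $[-1, 1]$ via
$x/127.5 - 1$.

`otsu_threshold` maximizes between-class variance over the 256-bin
histogram and breaks ties toward the smallest threshold; a single-level
channel is a degenerate input and raises an error rather than returning an
arbitrary value.

Sky training sets are augmented by scaling HSV saturation by 0.6 and, for
some images, value by 1.3 (the published factors). Dark sky patches are
removed because the tassels were captured under bright light and would
composite implausibly; the darkness criterion is unspecified in the source
method, so the package uses a documented heuristic: drop an image when its
mean HSV value falls below a configurable fraction (default 0.35) of the
maximum. Images exactly at the threshold are kept.

## Compositing

`compose_field_image` turns a tassel patch and a sky patch into a labelled
field image:

1. **Luminance correction.** GAN-generated tassels come out brighter than
   the training data (the generator's learned RGB mapping differs from a
   camera's spectral response), so the Y channel is scaled down. The
   magnitude is not stated in the source method; the default
   `luminance_factor` is 0.85, configurable.
2. **Masking.** Otsu on the Y channel — the luma separation between bright
   tassel and black background is maximal there — with the brighter class
   as foreground.
3. **Upscale by 2** (bicubic) of tassel, sky and mask; the mask is
   re-binarized at 0.5.
4. **Seeded shift** of tassel and mask, uniform integer in
   $[-\text{shift\_range}, +\text{shift\_range}]$ per axis, clipped so the
   tassel bounding box stays in frame (with a warning).
5. **Mask merge:** $I_m = m \cdot I_f + (1 - m) \cdot I_b$ — a pure
   selection, no new colors.
6. **Edge blending.** For each row, the first and last foreground pixels of
   every maximal mask run are edge pixels. With $L$ and $R$ the pre-blend
   values of the edge pixel's left and right row neighbours, the three
   pixels are reassigned simultaneously: edge $\leftarrow 0.5L + 0.5R$,
   left $\leftarrow 0.75L + 0.25R$, right $\leftarrow 0.25L + 0.75R$. All
   three weights sum to 1, so constant neighbourhoods are fixed points.
   The source method leaves the edge-pixel definition, the update order and
   the treatment of vertical transitions open; this package blends a single
   pass, horizontally only (matching the "in a row" construction), computes
   all updates from pre-blend values (sequential evaluation would be
   order-dependent), and skips transitions at image borders where a
   neighbour is missing.
7. **Downscale by 2** back to the input resolution; the mask is again
   re-binarized at 0.5 and returned alongside the image.

## Evaluation suite

* **SSIM** (`ssim`): single-scale structural similarity on the 8-bit luma
  channel; 11x11 Gaussian window with $\sigma = 1.5$, $K_1 = 0.01$,
  $K_2 = 0.03$, dynamic range 255 — the defaults of the metric's defining
  implementation (the source method names the metric without parameters).
  The map is averaged over the fully-windowed (valid) region.
  `paired_ssim_score` pairs every member of one set with a random partner
  from the other and averages over 3 repeats; `intraclass_ssim` does the
  same within a set, excluding self-pairings (an ambiguity in the protocol,
  resolved and documented here — including self-pairs would inflate the
  score toward 1).
* **Bounding-box morphometrics** (`bounding_box`, `morph_stats`): tassels
  are Y-channel Otsu-thresholded, the tight box is computed, and widths and
  heights are summarized with **population** (divide-by-$N$) standard
  deviations — the convention is unstated in the source, and the population
  form makes the fixture oracles exact. The fraction of tassels wider than
  a cutoff uses a strict inequality.
* **Inter-annotator error bound** (`interannotator_error`): for $K$
  annotators and $N$ items,
  $e = \frac{1}{KN}\sum_i \min_j (K - X_{ij})$ with $X_{ij}$ the number of
  annotators labelling item $i$ with label $j$; 0 means unanimity, and for
  binary labels $e \le 0.5$.
* **KNN augmentation experiment** (`knn_augmentation_experiment`): real
  width/height features are split 50/50 (stratified — the fixture-scale
  sets are small enough that an unstratified split can lose a class from
  one half), generated samples are appended at fractions of the training
  half, and a $k = 5$ nearest-neighbour classifier (Euclidean distance on
  the raw pixel-unit features; both features share units, so no scaling)
  is scored on the held-out half.
* **Perception-deck utilities** (`build_perception_deck`,
  `confusion_table`): seeded shuffling of real and generated images with an
  answer key, and 2x2 column-percentage confusion summaries of responses.
  Running human studies is out of scope; the utilities prepare and score
  the materials.

## Procedural fixtures

The original training corpora (a lab tassel dataset and two sky/cloud
databases) are not redistributable, so the package generates its own test
inputs with the statistical structure each stage assumes:

* `make_tassel_image` draws a central vertical spike plus angled branch
  strokes in brownish tones on an **exact-black** background, without
  anti-aliasing, so the ground-truth mask (`make_tassel_mask`, same
  parameters and seed) is exactly the set of painted pixels. Painted
  pixels are clamped away from pure black to keep the mask/complement
  identity exact.
* `make_sky_image` builds a vertical blue gradient plus 3 octaves of
  bicubically upsampled uniform noise pulling pixels toward white; with
  default (blue-dominant) gradient colors, no pixel ends up with red
  exceeding blue.
* `make_lab_scene` places a rendered tassel over a uniform bluish (high-Cb)
  backdrop, the input the chroma segmentation stage assumes.
* `make_annotation_matrix` simulates $N \times K$ categorical labels with a
  per-annotator flip probability.

All fixture generators are deterministic under a fixed seed. The fixtures
deliberately do **not** model photorealistic botany, illumination
gradients, camera noise, or the long-tailed shape variation of real
tassels; tests passing on fixtures demonstrate the pipeline's mechanics
and contracts, not field-readiness of models trained on real data.

## Desk-scale study conditions

The published headline numbers (SSIM of 0.84-0.85 against 1224 training
tassels, perceptual confusion percentages, morphometric standard
deviations) depend on proprietary training corpora, GPU-scale training and
human participants, and are not reproducible on a single CPU. The test
suite and `scripts/acceptance.R` therefore run the full pipeline at a
deliberately reduced scale, fixed once as the package's desk conditions:

* 200 procedural tassel fixtures at 32x32 resolution;
* quarter-width networks (`base_channels = 16`);
* 100 training epochs, batch size 32, learning rate $2 \times 10^{-4}$
  (the DC-GAN default — the published rates pair with thousand-epoch
  GPU runs), residuals disabled after epoch 40 (the same 40% point as the
  full recipe);
* the batch-norm ablation uses 100 fixtures, 40 epochs, and compares
  variants by (a) the minimum epoch-mean discriminator loss and (b) the
  epoch at which each variant first reaches the other's minimum. The
  40-epoch horizon matters: the contrast between the variants is an
  early-training phenomenon, and with enough epochs on such simple
  fixtures the no-batch-norm discriminator eventually converges too.

At this scale a seeded training run is bit-reproducible on one machine and
completes in about a minute; the discriminator loss stays well away from
the collapse detector's threshold (`tol = 0.01` over a 10-epoch window).

## Numerical conventions and degenerate inputs

* Images are H x W x 3 arrays of 8-bit values (0..255) throughout; the
  normalized $[-1,1]$ representation exists only inside the training loop.
  `denormalize_image(normalize_image(x))` is exact on all 256 levels.
* Coordinates are R-native 1-based inclusive; the center-crop offset and
  all width/height formulas match the usual 0-based half-open statements
  of the same windows.
* Otsu ties break toward the smallest threshold; single-level channels,
  empty masks, and all-black images raise degenerate-input errors.
* Bicubic resampling uses the Catmull-Rom kernel ($a = -0.5$) with
  clamped borders and renormalized edge weights; resampled masks are
  re-binarized at 0.5.
* Seeded operations save and restore the caller's RNG state, so library
  calls do not perturb user scripts.

## Known limitations

* The GAN engine is CPU-bound R/C++ with BLAS; full-scale 128x128,
  2500-epoch runs are supported but slow compared to GPU frameworks.
* Batch-norm models sample with batch statistics (no running-moment
  tracking); this only affects ablation sample grids, not the recommended
  no-batch-norm models.
* Edge blending is horizontal and single-pass by design; vertical
  transitions are left to the final downscale to soften.
* The dark-sky filter and the luminance-correction factor are documented
  heuristics where the source method states an operation but not its
  magnitude.
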