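---
title: "Methods: automatic sFAZ segmentation and quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: automatic sFAZ segmentation and quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

The superficial foveal avascular zone (sFAZ) is the capillary-free region
at the centre of the macula in en-face OCTA angiograms of the superficial
retinal plexus. Its area is a clinically used biomarker (diabetic
retinopathy, retinal vein occlusion), but manual delineation is slow and —
worse — sensitive to the brightness/contrast (B/C) settings under which the
viewer renders the exported image: the same eye exported at nine different
B/C settings can yield visibly different vessel maps. `fazseg` implements a
segmentation-by-classification pipeline designed to be robust to these
rendering changes: every pixel is classified sFAZ / non-sFAZ by an
encoder–decoder network, the resulting probability map is binarised and
morphologically cleaned, and the physical area is computed from the pixel
count and the scan's physical width.

## Pipeline

1. **Simulation** (`generate_cohort()`). Clinical OCTA exports of this kind
   are not freely redistributable, so the package ships a seeded synthetic
   cohort generator used by every example and test (see below).
2. **Preprocessing** (`resize_to_standard()`, `normalize_minmax()`,
   `augment_rigid()`). Images are resized bilinearly to the square network
   input (704 px at full scale), min-max normalised per image to [0, 1]
   (`(X - X_min) / (X_max - X_min)`; a constant image maps to zeros), and
   augmented on the fly with the six rigid transforms {identity, three
   quarter-turn rotations, horizontal flip, vertical flip}, applied
   identically to image and mask. The six-element group is what turns 405
   source images into 2430 training pairs. Min-max normalisation is also
   the first line of B/C robustness: any affine rendering change that does
   not clip is removed exactly by it.
3. **Segmentation network** (`network_config()`, `train_model()`,
   `predict_probmap()`).
4. **Post-processing** (`refine()` = binarise, keep the largest
   8-connected component, fill 4-connected interior holes).
5. **Quantification** (`compute_area()`:
   `area = N · scan_mm² / (H · W)`).
6. **Evaluation** (`confusion_counts()`, `dsc()`, `sensitivity()`,
   `specificity()`, `pearson_r()`, `threshold_sweep()`, `group_report()`),
   under participant-based stratified cross-validation
   (`make_cv_splits()`) so that all nine renderings of an eye stay on one
   side of every split.

## The network

The architecture is a U-Net-style encoder–decoder with
squeeze-and-excitation (SE) channel attention:

* a stem of two Conv-BN-ReLU blocks (each block = two [3×3 conv →
  batch-norm → ReLU] stages, same-size padding);
* five pooling blocks (Conv-BN-ReLU block → SE block → 2×2 stride-2 max
  pool), halving the grid from 704 to 22 px;
* five upsampling blocks (bilinear 2× upsample → concatenation with the
  same-resolution encoder skip → Conv-BN-ReLU block → SE block);
* a 1×1 convolution + sigmoid head emitting a per-pixel probability.

The SE block global-average-pools each channel, passes the channel vector
through a bottleneck pair of dense layers (ReLU then sigmoid) and rescales
each channel by the resulting weight in (0, 1); it reduces exactly to
per-channel multiplication, which the tests exploit (zeroing its dense
weights must halve every activation).

Choices this architecture family leaves open, fixed here as
configuration defaults: 3×3 kernels (the standard choice for this family),
channel schedule `c(32, 64, 128, 256, 512, 512)` at full scale (standard
doubling, capped), SE reduction 16 (the SE literature default), average
pooling inside SE, He-uniform initialisation with unit-scale/zero-shift
batch norm, everything seeded. All of these are `network_config()`
arguments rather than constants.

The training engine is part of the package (no external deep-learning
framework is involved): exact backpropagation through every layer
(verified against central finite differences to ~1e-8 relative error),
Adam (β₁ = 0.9, β₂ = 0.999, ε = 1e-8), pixelwise binary cross-entropy or
soft Dice loss, a plateau schedule that halves the learning rate when the
minimum training loss of the trailing 30-epoch window fails to beat the
best loss before that window (after a reduction the window must refill
before the rule can fire again — this is what makes two consecutive
plateaus yield ×0.25 rather than a halving per epoch), and best-on-test
checkpointing: the model is persisted exactly when the test-set *correct
rate* strictly improves. "Correct rate" is read as mean pixel accuracy,
the most literal interpretation; per-image DSC is logged alongside it.

## The synthetic cohort

The generator emulates the acquisition protocol of the emulated study: 45
eyes (12 high-myopic, 33 low-myopic), one 3 mm × 3 mm macular scan each,
exported under nine B/C settings — the default 130/20 plus 90/20, 110/20,
150/20, 170/20, 130/0, 130/10, 130/30, 130/40 — giving 405 images; the
ground-truth mask is drawn once per eye and shared by its nine renderings.

* **FAZ geometry**: a star-convex region whose boundary radius is a circle
  (radius drawn uniformly in 0.18–0.44 mm, covering the typical adult
  sFAZ range) modulated by two or three low-order angular harmonics with
  amplitudes up to 0.07 and a centre jitter of ±3% of the field. The
  construction is hole-free and single-component by design, which the
  flood-fill oracles confirm.
* **Vasculature**: seeded biased random walks with persistent direction
  stamp capillary strokes onto the field, a 3×3 binomial blur gives them a
  soft profile, and strokes terminate at the FAZ rim (the eroded interior
  is kept clean). Background sits at ~20 gray levels with Gaussian noise
  (sd 6) and vessels at ~200, so the FAZ interior is darker than its
  surroundings by well over 30 levels.
* **B/C remap**: the vendor viewer's mapping is proprietary; only its
  direction of effect is documented (higher brightness or contrast ⇒
  darker image; lowering contrast makes faint capillaries visible). The
  package uses `out = clip(gain(contrast) · (x − pivot(brightness)))` with
  `gain(c) = (148 − c)/128` and `pivot(b) = 0.5·(b − 130)`, which makes
  the default 130/20 the exact identity and satisfies every documented
  monotonicity.

What the generator does **not** model: OCT speckle statistics and
flow-decorrelation noise, the deep plexus, projection artifacts,
pathological FAZ shapes, or motion artifacts. Consequently, passing the
scaled-down learning tests shows that the pipeline's machinery — data
handling, optimisation, refinement, evaluation — is correct and that the
network can learn B/C-invariant FAZ delineation on plausible geometry; it
does not certify clinical-grade accuracy on real OCTA exports.

## Scaled-down validation profile

The full protocol (45 subjects, 704 × 704 inputs, 5-fold cross-validation,
300 epochs) is GPU-scale. The package's validation surface therefore runs
a reduced but structurally identical experiment, `scaled_config()`:
12 subjects at 128 × 128 (scan width still 3 mm, so ~23 µm/pixel), channel
schedule `c(8, 16, 32, 32, 32, 32)` with SE reduction 4, one of four
participant-based folds held out (9 training subjects = 81 images, 3 test
subjects = 27 images), Dice loss, Adam at 3e-3 with batch size 1, at most
20 epochs with early stop once held-out mean DSC reaches 0.97. The higher
learning rate, small batch and Dice objective are deliberate departures
from the full-scale defaults (1e-4, batch 4, BCE): with a FAZ occupying
only 1–7% of pixels, cross-entropy at a small step size spends many epochs
reproducing the background class, while the Dice objective with more
optimiser steps per epoch converges an order of magnitude faster on the
thin network. The full-scale defaults retain the protocol values.

## Numerical choices and edge cases

* Binarisation uses `>=`, so threshold 0 marks everything foreground and
  the sweep curve is defined at 0. The default threshold 0.44 is the
  reference optimum; the sweep (0 to 1, step 0.01 — a grid that contains
  0.44 exactly) reports the smallest grid point attaining the maximal mean
  DSC.
* Foreground connectivity is 8, hole connectivity 4 (the standard dual
  pairing); ties for the largest component go to the component containing
  the smallest pixel in row-major order, making refinement deterministic.
* Metric conventions with empty denominators (e.g. both masks empty) return
  1 when the masks agree on the undefined class and are flagged with a
  `degenerate` attribute.
* Min-max normalisation of a constant image returns zeros rather than NaN.
* Bilinear operations use the half-pixel-centre convention with clamped
  borders, so constants are preserved exactly and a same-size resize is the
  identity.
* Batch norm uses per-batch moments at training time (ε = 1e-5); with
  batch size 1 this normalises each image by its own moments. Inference
  therefore defaults to the same per-image statistics
  (`predict_probmap(bn = "batch")`) — the function evaluated at test time
  is then exactly the one optimised — while conventional running
  statistics (momentum 0.1) are accumulated and available via
  `bn = "running"`. On desk-scale runs the per-image mode is markedly more
  accurate and stable, as the running averages blur image-to-image
  contrast differences that the nine B/C renderings deliberately induce.
* The Pearson p-value uses the two-sided t transform with n − 2 degrees of
  freedom; groups with fewer than 3 images report an undefined R rather
  than failing.
* Probability maps are stored as 16-bit grayscale TIFF (1/65535
  resolution) so on-disk rounding cannot move a pixel across the 0.44
  threshold; images and masks are 8-bit PNG with masks 0/255 on disk and
  0/1 in memory.

## Known limitations

* The synthetic renderer is a geometric emulation, not a physical model of
  OCTA contrast; absolute DSC values on it are optimistic relative to
  clinical data.
* At desk scale the per-group Pearson R is computed from 3 held-out
  subjects per group and is accordingly unstable; the pooled R over all
  27 held-out images is the meaningful figure.
* The engine is CPU-bound and single-threaded beyond BLAS; full-scale
  704 × 704 training is out of reach without substituting a GPU framework
  behind the same interfaces.
* Only the superficial FAZ is addressed; the deep plexus poses a harder
  boundary-contrast problem and is out of scope.
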