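# fazseg

Automatic segmentation and quantification of the **superficial foveal
avascular zone (sFAZ)** in en-face OCTA angiograms, robust to the
brightness/contrast (B/C) settings of the exporting viewer.

The sFAZ — the capillary-free region at the centre of the macula — is a
biomarker for diabetic retinopathy, retinal vein occlusion and other
retinal disease. Manual delineation is slow and changes with the B/C
rendering of the export. `fazseg` segments it automatically: an
encoder–decoder network with squeeze-and-excitation (SE) channel attention
classifies every pixel as sFAZ / non-sFAZ, the probability map is
binarised and morphologically cleaned (largest 8-connected component +
hole filling), and the physical area follows from the pixel count:

```
DSC  = 2·TP / (FP + 2·TP + FN)
area = N · scan_mm² / (H · W)        # N = foreground pixels
```

The package is self-contained for R: it includes a seeded synthetic OCTA
cohort simulator (45 eyes × 9 B/C renderings emulating the acquisition
protocol), the full training engine (exact backprop, Adam,
plateau-halving learning rate, best-on-test checkpointing,
participant-based stratified cross-validation), and the complete
evaluation harness (DSC/sensitivity/specificity, threshold sweep,
per-B/C-group report, predicted-vs-true area correlation). No external
deep-learning framework is required; the pixel-level primitives are
compiled C++ and the convolutions run through BLAS.

## Worked example

The package's desk-scale profile (12 synthetic subjects at 128×128, 3
held-out subjects × 9 renderings, a thin network — roughly 15 minutes on
one CPU):

```r
library(fazseg)

res <- run_pipeline(scaled_config())   # seed 1 by default
res
#> <faz_run> 27 held-out images over 1 fold(s); pooled DSC 0.940 +/- 0.017, area R 0.999

pooled <- res$report[res$report$group == "all", ]
round(c(dsc = pooled$dsc_mean, sens = pooled$sensitivity_mean,
        spec = pooled$specificity_mean, R = pooled$area_r), 3)
#>   dsc  sens  spec     R
#> 0.940 0.948 0.999 0.999

res$sweep$argmax_threshold
#> [1] 0.35

autoplot(res$sweep)        # mean-DSC-vs-threshold curve, ±1 SD ribbon
autoplot(res$fits[[1]])    # training loss and held-out DSC per epoch
```

`res$report` is the per-B/C-group table: each of the nine groups'
held-out mean ± SD DSC, sensitivity and specificity at the default
threshold 0.44, plus the Pearson R between predicted and reference sFAZ
areas, with a pooled all-groups row. `res$sweep` holds the mean-DSC curve
over thresholds 0–1 (step 0.01) with its flat central plateau; its argmax
is the reported operating threshold. For a faster (but much less
accurate) smoke run, shrink the configuration, e.g.
`scaled_config(list(synthetic = list(n_subjects = 4L, size = 64L), ...))`
as the pipeline tests do.

Individual stages compose just as well:

```r
coh  <- generate_cohort(12, 3, seed = 1, size = c(128, 128))
mask <- refine(probmap, threshold = 0.44)       # binarise + morphology
compute_area(mask, scan_mm = 3)                 # tibble: n_pixels, area_mm2, ...
```

A thin CLI over the same functions lives at `inst/cli/faz-seg.R`
(`simulate | train | segment | postprocess | quantify | run-all`).

## Package layout

- `R/synthetic.R` — cohort simulator (FAZ geometry, vessel walks, B/C remap)
- `R/preprocess.R` — resize, min-max normalisation, rigid augmentation
- `R/layers.R`, `R/network.R`, `src/ops.cpp` — SE encoder–decoder + backprop
- `R/train.R` — Adam loop, LR schedule, checkpointing, CV splits
- `R/postprocess.R` — binarise, largest component, hole filling
- `R/quantify.R` — physical area
- `R/evaluate.R` — metrics, threshold sweep, group report
- `R/io.R`, `R/pipeline.R` — manifests, PNG/TIFF I/O, end-to-end runner
- `vignettes/fazseg-methods.Rmd` — model, assumptions, design rationale
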