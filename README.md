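# renalseg

Automatic whole-kidney and renal compartment (medulla/cortex) segmentation
for 4D dynamic contrast-enhanced (DCE) MRI, in R.

DCE-MRI acquires a 3D abdominal volume every few seconds while a gadolinium
tracer transits the kidneys; the signal dynamics of the renal cortex (early
enhancement) and medulla (delayed enhancement) carry clinically decisive
information — per-kidney time–intensity curves, filtration markers, evidence
of urinary-tract obstruction. Extracting them requires segmenting the whole
kidney and then its compartments across the entire time series, which is
impractical to do by hand and hard to automate in paediatric cohorts with
congenital abnormalities, streak artefacts and motion blur. `renalseg` is
aimed at researchers building such quantitative renal MRI pipelines.

## What it implements

**Stage 1 — learning-based whole-kidney segmentation.**
A 3D residual U-Net (four encoder scales with additive identity shortcuts,
five decoder blocks, three output classes: background / right / left kidney)
localises each kidney on a compact spatio-temporal encoding of the scan:
per-voxel time courses resampled to a uniform grid, reduced to 5 channels by
per-scan PCA, downsampled to 64³. The minimum bounding box of each coarse
class crops the kidney; a missing kidney is encoded as a single-voxel box.
Each crop is then segmented voxel-wise by a 3D fully convolutional DenseNet
(dense blocks of 4, 5, 7, 10, 12, 15 layers down and 12, 10, 7, 5, 4 layers
up, growth rate 12, transition-down compression 0.8). Both networks minimise
a class-balanced cross-entropy

    L = -(1/N) * sum_i w_i [ y_i log p_i + (1 - y_i) log(1 - p_i) ]

summed over voxels and output channels, with `w_i` inversely proportional to
the prior of voxel i's true class, trained with Adam. The 3D convolution,
transpose-convolution and pooling kernels, and the backpropagation engine,
are implemented in the package (Rcpp/RcppArmadillo, im2col + BLAS); training
is bit-deterministic under a fixed seed.

**Stage 2 — rule-based compartment separation.**
Within the whole-kidney mask, every coronal slice of every frame passes a
contrast-maximisation cascade: intensity shifting on central slices
(`s <- s - a_min` for strictly interior intensities), gamma correction on
peripheral slices (`s <- (s/255)^γ · 255`), sigmoidal enhancement
`E(s) = 1/(1 + exp(δ(μ - s)))`, and exact Otsu thresholding (between-class
variance maximised over the unique values of the in-mask histogram). Dark
pixels inside the mask become medulla, bright ones cortex. A temporal fusion
then takes the labelling at a reference frame `t_x = round(x·T)` and promotes
cortex to medulla wherever other frames agree — gated by the slice's medulla
percentage lying in (α, β) = (30, 60) — before a cortex refinement restores
the kidney rim and contrast-free slices. Defaults: δ = 2, μ = 1.5, γ = 1.5,
depth range fractions 0.3–0.7, x = 0.375.

**Synthetic phantoms.** Because the clinical data such pipelines are built on
are not redistributable, `generate_phantom()` produces seeded 4D phantoms
with exact ground truth: ellipsoidal kidneys with a bright cortical shell
around darker medullary lobes, compartment-specific enhancement kinetics
(cortex peaking before medulla), optional Gaussian/Rician noise, radial
streaking and motion blur, plus abnormal variants (missing kidney, dilated
collecting system). The whole test suite runs on these phantoms.

## Worked example

```r
library(renalseg)

# a small noise-free two-kidney phantom with exact ground truth
ph <- generate_phantom(phantom_config(shape = c(24, 64, 64), n_frames = 12,
                                      noise_sigma = 0, seed = 1))
ph$series
#> <dce_series> T=12 frames, D=24 x H=64 x W=64 voxels
#>   times: 25.0 .. 300.0 s; spacing 3.00 x 1.25 x 1.25 mm

# rule-based cortex/medulla segmentation from the whole-kidney masks
labels <- segment_compartments(ph$series,
                               list(right = ph$right_mask,
                                    left  = ph$left_mask))

round(c(medulla = dsc(ph$labels$data == 1, labels$data == 1),
        cortex  = dsc(ph$labels$data == 2, labels$data == 2)), 3)
#> medulla  cortex
#>   1.000   0.871

# relative contrast-enhancement time-intensity curves
cv <- extract_curves(ph$series, labels, sides = list(right = ph$right_mask))
subset(cv, compartment != "whole" & time_s %in% c(25, 100, 300))
#>    compartment time_s      value
#>        medulla     25  0.0000000
#>        medulla    100  0.7780662
#>        medulla    300  0.4201134
#>         cortex     25  0.0000000
#>         cortex    100  0.1869069
#>         cortex    300 -0.1480835
```

The Dice scores compare the recovered compartments with the phantom's exact
truth (the cortex score is bounded by the deliberate one-pixel rim the
refinement adds around the kidney). The curves show the expected physiology
the phantom encodes: the cortex has already peaked and is washing out by
100 s while the medulla is still rising.

To train the networks instead of using ground-truth masks, see
`train_localizer()` / `train_segmenter()` (phantom-based helpers:
`make_localizer_dataset()`, `make_segmenter_dataset()`), then
`predict_boxes()` and `predict_kidney_mask()`, or drive everything through
`run_pipeline()`. A thin command-line front end with `phantom`, `run` and
`evaluate` subcommands is installed at `inst/cli/renalseg.R`.

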