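---
title: "Restoration methods for FIB-SEM volumes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restoration methods for FIB-SEM volumes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(semrestore)
```

FIB-SEM acquisition alternates SEM imaging with ion-beam milling, and each
step leaves its signature on the stack: smooth intensity gradients where the
sample charges, vertical "curtaining" stripes from uneven milling, in-plane
drift between consecutive slices, occasional defocused or destroyed planes.
This vignette walks through how each `semrestore` stage works and why it is
built the way it is. Everything below runs on synthetic data generated by
the package itself.

## Quality metrics

### LoG sharpness

`sharpness()` scores a slice by the standard deviation of its
Laplacian-of-Gaussian response. The LoG is a band-pass filter: defocus
suppresses exactly the band it responds to, so blurred slices score low.
Implementation details that matter:

- the slice is mean-centred first, so the metric is exactly 0 for constants
  and invariant to intensity offsets;
- boundaries are mirror-padded, so edge response does not dominate small
  images.

```{r}
ph <- make_phantom(shape = c(8, 64, 64), seed = 1)
s <- get_slice(ph, 3)
c(sharp = sharpness(s), blurred = sharpness(semrestore:::gaussian_blur(s, 3)))
```

### Fourier ring correlation

`frc()` measures the coherence of two images over rings of spatial
frequency: per ring, `Re(sum(F1 * Conj(F2))) / sqrt(sum|F1|^2 * sum|F2|^2)`,
which Cauchy–Schwarz confines to `[-1, 1]`. The DC sample is excluded
(offset invariance), frequencies are normalised per axis so Nyquist is 0.5
for both axes of non-square images, and the global score — the package's
acceptance criterion for restored slices — is the unweighted mean over
rings. Self-correlation is exactly 1; independent noise scores about 0.

### Artifactual-slice detection

`detect_artifactual_slices()` applies the sharpness metric to every slice
and flags outliers. The robust rule works on the *log* of the sharpness:
sharpness is a positive scale variable whose legitimate slice-to-slice
variation is multiplicative, so on the log scale a `median - 3 * MAD`
threshold tracks relative drops, a zero-sharpness (dropped) slice is `-Inf`
and always flagged, and the spread is floored so perfectly uniform stacks do
not flag normal variation.

## Corrections

### Charge gradients: rolling ball

`rolling_ball()` estimates the background as the grayscale morphological
opening of the slice with a ball-shaped (ellipsoid-cap) structuring element:
the surface the ball traces as it rolls underneath the intensity landscape.
Features narrower than the ball survive subtraction; broad gradients do not.
The vertical semi-axis of the ball defaults to the image's intensity range —
a ball "round" in mixed pixel/intensity units would be locally flat on
normalised images and would swallow every object.

### Stripes: wedge filtering plus compressed sensing

Curtaining stripes are constant along one image axis, so their energy
concentrates in a narrow angular wedge around the orthogonal frequency axis.
`remove_stripes()` zeroes that wedge (default half-width 2 degrees, with a
notch below 0.1 cycles/pixel so genuine low-frequency object structure is
spared, and DC always kept), then treats the zeroed coefficients as missing
measurements: it alternates total-variation denoising with re-injection of
the kept coefficients, so the suppressed region is re-estimated from the
TV prior rather than simply left empty. With `cs_iterations = 0` you get
the plain wedge filter.

### Drift: multi-scale phase correlation

`estimate_drift()` registers two slices by phase correlation (normalised
cross-power spectrum) on a factor-2 image pyramid, with a Gaussian low-pass
that discounts the high frequencies where genuine slice-to-slice content
change decorrelates the phases, and a local matrix-DFT upsampling of the
correlation peak for 1/16-pixel precision. `align_stack()` estimates
pairwise shifts at lags 1 and 2 and solves for the absolute trajectory by
least squares — pure accumulation of lag-1 estimates would random-walk away
from the truth, while the lag-2 observations pin the accumulation down.

```{r}
deg <- degrade(ph, degradation_spec(drift_step_std = 1, seed = 1))
res <- align_stack(deg$degraded)
max(abs(res$trajectory$shifts - deg$truth$drift))
```

### Defocus: PSF estimation and Richardson–Lucy

A Gaussian blur of width `sigma` multiplies the power spectrum by
`exp(-4 pi^2 sigma^2 f^2)`. `estimate_psf()` therefore fits a straight line
in `f^2` to the log of the radially averaged power spectrum (Hann-windowed
against leakage; rings near the noise floor excluded) over a grid of
candidate widths with parabolic refinement. The estimate includes the
sample's intrinsic texture width, a small positive bias that is immaterial
for detecting and correcting *relative* focus drift.

`richardson_lucy()` then deconvolves with the classic multiplicative
maximum-likelihood update for Poisson noise, optionally damped by a
total-variation factor. Convolution is periodic via FFT, so flux is
conserved exactly for a normalised PSF.

## Structural inpainting

Slices too damaged to correct are rebuilt from their 3D neighbourhood.
All four methods operate natively in 3D, so a missing plane is constrained
by both of its z-neighbours, and all return known voxels bit-identical:

- **harmonic** — solves the Laplace equation on the masked set with
  Dirichlet data from known voxels (red-black Gauss–Seidel). The filled
  values obey the maximum principle and reproduce discrete-harmonic fields
  exactly.
- **dct** — Garcia-style penalised least squares in the DCT basis:
  `(W + s L^2) u = W y`, diagonal in the DCT domain, annealed from heavy to
  light smoothing. Best all-round choice for textured content.
- **tv** — alternates Chambolle TV denoising with exact re-injection of
  known voxels; preserves edges the harmonic solution would smear.
- **multiscale** — known-voxel average pyramid, filled coarse-to-fine by
  trilinear upsampling; fast and robust, close to linear interpolation.

```{r}
vol <- make_phantom(shape = c(16, 64, 64), bead_fraction = 0, seed = 2)
m <- mask_from_slices(dim(vol), 8)
filled <- inpaint_dct(vol, m)
frc(get_slice(filled, 8), get_slice(vol, 8))$global_score
```

## The pipeline

`run_restoration()` applies the enabled stages in a fixed order — charge,
destripe, align, deconvolve, detect, inpaint, validate — because each stage
assumes the artifacts the earlier ones remove: registration fails on
gradient-dominated slices, PSF estimation is biased by stripes, and the
sharpness screen must run on *corrected* slices so that correctable blur is
not needlessly inpainted. Flagged slices that survive correction are
replaced by structural inpainting, and each replacement is accepted only if
its global FRC against a reference slice `plane_range` planes away (clear of
any artifactual run) does not decrease.

Plans serialise to YAML (`plan_to_yaml()` / `plan_from_yaml()`) and reports
to JSON (`report_to_json()`), so a run is reproducible from its artefacts.
Per-slice stages parallelise over `n_workers` with results identical to the
serial execution.

```{r}
plan <- restoration_plan(
  detect = list(enabled = TRUE, log_sigma = 2, rule = "robust_z", k = 3,
                cutoff = NULL),
  inpaint = list(enabled = TRUE, params = inpaint_params("dct")),
  validate = list(enabled = TRUE, plane_range = 3))
deg2 <- degrade(vol, degradation_spec(blur_slices = c("8" = 4),
                                      noise = c(0.01, 0), seed = 3))
out <- run_restoration(deg2$degraded, plan)
out$report$frc_validation
```
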