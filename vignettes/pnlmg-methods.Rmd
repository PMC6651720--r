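---
title: "Gray-value restoration of speckled microarray images: models and methods"
author: "pnlmg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gray-value restoration of speckled microarray images: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pnlmg)
```

## The measurement problem

Porous-silicon (PSi) microcavity microarrays are label-free biosensors: a
biological binding event inside a unit changes the local refractive index,
which shifts the unit's optical response, which in turn changes the mean
gray level of the unit in a CCD image of the chip.  The *average gray level*
(AGL) of each circular unit is therefore the detection signal, and the
calibration between gray-level change and refractive-index change is linear
over the working range.  Laser illumination of the rough PSi surface,
however, produces speckle — granular multiplicative interference — and the
speckle intensity differs between units because the bound reactants change
the surface morphology.  Uncorrected, speckle biases each unit's AGL by a
different amount and corrupts the calibration.

This package implements the full apparatus needed to study and solve that
problem on synthetic data: the multiplicative noise model, the restoration
pipeline (PNLM-G), classical comparison filters, the evaluation metrics,
microarray-unit quantification, and a scripted Monte-Carlo harness.

## The noise model

A corrupted pixel is modeled as \(I(i,j) = M(i,j)\,(1 + n(i,j))\) with
\(n\) zero-mean of variance \(v\).  The reference dialect (the convention of
the `speckle` routine in common numerical toolboxes) draws
\(n \sim U[-\sqrt{3v}, \sqrt{3v}]\), clips the product to \([0,255]\) and
rounds to integer gray levels, emulating an 8-bit camera.  `speckle_spec()`
exposes the variance, the family (`uniform`, plus `gaussian` and
`exponential` for robustness checks), the clip/quantize flags and a seed;
`add_speckle()` applies it.  All study conditions use 256 × 256 frames —
a typical working crop of a CCD acquisition; the sources never state a
frame size, and every statistical property below scales with the pixel
count in the standard way.

Two consequences of this dialect drive everything else:

* **Censoring.** For \(v > 1/3\) the multiplier support crosses zero, and
  negative products are clipped to 0.  The clipped mass inflates the
  ensemble mean: analytically \(E[\mathrm{AGL}]\) for clean gray 40 is
  40.41 at \(v = 0.5\) and 43.09 at \(v = 1.0\), an upward bias that grows
  with variance.  Singular pixels — values at least twice the clean gray,
  possible once \(v > 1/3\) — add the bright tail; pre-quantization their
  fraction at \(v = 1\) is \((\sqrt3 - 1)/(2\sqrt3) \approx 0.2113\).
* **A pivotal symmetry.** The *median* of the noisy distribution equals the
  clean gray at every variance: the multiplier is symmetric about 1, and
  clipping only relocates mass below the median (at most 21 % at
  \(v = 1\)).  The mean is biased; the median is not.  The restoration
  design leans on this.

The analytic intensity densities of fully developed speckle are also
provided: one pattern is exponential (`intensity_pdf_single()`), the sum of
\(N\) independent patterns is the gamma density with shape \(N\)
(`intensity_pdf_sum()`, implemented with `stats::dgamma`), which moves from
the negative exponential at \(N = 1\) toward a Gaussian as \(N\) grows
(skewness \(2/\sqrt N\)).

## The restoration pipeline

`pnlm_g()` cycles four stages and stops when the fraction of marked
residual pixels falls below `tol_fraction` (default \(10^{-4}\)) or after
`max_passes` (default 3) passes:

1. **Selective median repair.**  Marked pixels are replaced by the median of
   their 9 × 9 window (`median_repair()`; odd window, mirror padding, exact
   median).  On the first pass *every* pixel is treated as a
   singular-pixel candidate: a raw speckle frame is singular everywhere,
   and — by the pivotal symmetry above — the window median is an unbiased
   estimate of the clean gray at every variance, so this sweep anchors the
   restoration at the right level before any averaging is done.  Patch
   averaging first would instead lock in the censoring bias, which no later
   selective repair can remove (the bias is diffuse, not localized).
2. **PNLM filtering** (`pnlm_denoise()`).  The probability-based non-local
   means restoration
   \(\hat u_i = \sum_j w_{ij} p_j u_j / \sum_j w_{ij} p_j\) over the search
   window, with \(w_{ij} = \exp(-d^2_{ij}/h^2)\),
   \(p_j = \exp(-0.01\,\mathrm{ROAD}(u_j))\) the undamaged probability from
   the rank-ordered absolute differences statistic, and \(d^2_{ij}\) the
   probability-damped squared patch distance in which each pixelwise
   difference is scaled by the smaller of the two pixels' probabilities.
   Damaged pixels lose weight twice: in the distance and in the average.
   With all \(p_j = 1\) the filter is exactly classical NLM.
3. **Quantization** to the 8-bit gray grid.  Restored frames live on the
   same grid as acquired frames; this step is also what turns a nearly
   flat field into an exactly flat one, removing residual sampling
   fluctuation below half a gray level.
4. **Gradient marking** (`smooth_image()`, `gradient_field()`,
   `mark_residual()`).  A 9 × 9 Gaussian template (σ = 2) smooths the
   frame; four central-difference derivatives (horizontal, vertical, both
   diagonals) are combined into the Euclidean gradient magnitude; pixels
   with \(G > \max(\mu_G + k\,\sigma_G,\ \texttt{min\_grad})\) are marked
   for the next pass.  The gradient direction is computed and reported but
   not used in marking.

On a *globally homogeneous* scene — relative spread of the repaired field
below 20 % — the averaging stage of the later passes uses the whole-image
search window of the non-local means formulation (`search_radius = Inf`).
In that limit the patch kernel is flat and every pixel's restoration is the
same probability-weighted global mean, computed exactly in \(O(n)\); the
closing quantization then collapses the frame to a single gray level.  This
is what makes exact AGL recovery possible at all: any estimator of the
clean gray from one \(256\times256\) frame at \(v = 1\) carries a sampling
standard error of roughly 0.24 gray levels, far above the 0.05 recovery
tolerance, so only consolidation to the nearest integer level can absorb
it.  Structured scenes (a microarray frame) skip the global pass; there the
windowed filter plus mark/repair erosion preserves region boundaries.

### Parameter choices

| parameter | default | meaning and rationale |
|---|---|---|
| `search_radius` r | 5 | 11 × 11 search window.  On piecewise-constant targets nothing changes beyond r ≈ 5 while cost grows as \((2r+1)^2\); `Inf` = whole-image window (consolidation passes). |
| `patch_radius` f | 2 | 5 × 5 similarity patches, the common NLM choice. |
| `road_radius`, `road_L` | 1, 4 | ROAD over the 8-neighborhood, summing the 4 smallest deviations — the classic configuration of the statistic. |
| `alpha` | 0.01 | the fixed decay scale of the undamaged probability. |
| `h` | `10 * sigma_hat` | weight-kernel bandwidth.  `sigma_hat` is the median absolute Laplacian residual scaled for consistency (`estimate_noise_sd()`); the factor 10 makes the kernel nearly flat at the noise scale, appropriate for homogeneous regions.  `pnlm_g()` estimates h **once from the input** and holds it fixed: re-estimating on the partially restored field would shrink the bandwidth toward zero and stall the iteration. |
| `window` | 9 | median-repair window.  It must exceed the residual-structure scale to repair it; the 9 × 9 choice pairs with the 11 × 11 search window. |
| `k`, `min_grad` | 2, 1 | marking threshold \(\mu_G + k\sigma_G\) with an absolute floor of one gray level.  A purely adaptive threshold always marks the upper tail of *any* field, so the convergence criterion could never be met; the floor declares sub-quantization gradients clean. |
| `homogeneity` | 0.2 | relative-spread threshold for engaging whole-image consolidation.  Constant scenes at the highest variance measure ≈ 0.12 after repair; a two-level array frame measures ≈ 0.35. |

The iteration-order choice deserves emphasis because the pipeline is a
cycle: repair → filter → quantize → mark → repair → …  Entering at the
repair stage (rather than the filter stage) is a phase choice within the
same cycle, and the unbiasedness argument above decides it.

## Evaluation metrics

`average_gray()` is the pixel mean; `speckle_index()` is the global
standard deviation over the mean, which for un-censored multiplicative
noise on a constant image converges to \(\sqrt v\) — this is the reading
under which the unprocessed low-variance table entries reproduce
(\(\sqrt{0.1} = 0.316\) against a printed 0.3236).  A window-averaged local
variant is available but is not the default.  PSNR (peak 255) and ENL
(mean²/variance, with \(\mathrm{ENL} = 1/\mathrm{SI}^2\)) round out the
report; identical images and constant images give `Inf` sentinels.
Reported AGLs are conventionally printed to two decimals and SIs to four.

## Baseline filters

The Lee filter (`lee_filter()`) is the classical local-statistics
despeckler \(\hat u = \mu_w + \sigma_w^2/(\sigma_w^2 + \sigma_n^2)(u -
\mu_w)\) with the global noise variance estimated as the median of local
window variances (7 × 7 default).  The adaptive median (`adaptive_median()`)
is the standard two-stage algorithm with growing window.  Both are written
here because no installed package provides them; both are verified against
literal step-by-step oracles.  The comparison harness (`run_table1()`)
accepts arbitrary plug-in denoisers as named functions, so externally
implemented methods (block matching, wavelet shrinkage, anisotropic
diffusion) can join the table without being reimplemented here.

## Microarray quantification

`array_grid_spec()` describes the unit layout explicitly (rows, columns,
disk radius, pitch or explicit centers) — segmentation is configuration,
not inference.  `synth_array_image()` paints unit disks on a background and
speckles the frame; `measure_units()` reports per-unit AGLs plus the
overall AGL and SI pooled over the union of unit pixels (the pooled reading
of "SI of all array units"; a per-unit reading is recoverable from the
per-unit table).  `restore_units()` follows the acquisition workflow in
which the chip image is segmented before quantification: each unit's
inscribed square is restored with `pnlm_g()` (a homogeneous crop, so the
consolidation applies per unit) and the restored level is assigned to the
disk.  `fit_line()` / `gray_to_index()` provide the linear calibration
machinery; with no public optical data it is validated on synthetic
parameter-recovery cases only.

## The synthetic generator as study design

The generator emulates exactly the published study conditions: constant
images of gray 20–50, variances 0.1–1.0, uniform zero-mean multiplicative
noise, clipping, quantization, 256 × 256 frames, with 100 replicates per
cell in the desk-scale harness (the full-scale design of 2500 replicates is
a flag away, `reps`).  What it does **not** emulate: spatially correlated
speckle grains (real speckle has a grain size set by the optics; here
pixels are independent), illumination gradients, unit-edge diffraction,
chip tilt, or camera read noise.  Passing the synthetic suite therefore
demonstrates correctness of the statistical machinery under the stated
model, not robustness to those physical effects.

## Numerical choices and degenerate inputs

Mirror (half-sample symmetric) padding is used everywhere, which together
with symmetric normalized kernels preserves the global mean exactly.  All
internal arithmetic is double precision; quantization happens only in the
noise dialect, in pipeline stage 3, and at image write time.  The weight
kernel is evaluated with a table-driven `exp(-x)` accurate to ~1e-15
relative, indistinguishable from libm at all tolerances used.  Degenerate
cases: zero-variance specs are rejected; constant images short-circuit to
fixed points (zero ROAD, all-ones probabilities, zero gradients, empty
masks); an all-zero weight sum would fall back to the center pixel with a
warning (unreachable with positive probabilities, kept as a guard); even
median windows are rejected so the median is always an order statistic.

## Known limitations

* Exact AGL recovery relies on quantization collapse, so it degrades
  near cell corners where the per-frame sampling error approaches half a
  gray level: at gray 50 and variance 1.0 about 9 % of frames consolidate
  to a neighboring integer level (an error of one gray level).  Across the
  full sweep this leaves roughly 98–99 % of frames within ±0.05, slightly
  below the full-scale published rate.
* The unprocessed-ensemble AGL at high variance is dialect-sensitive: the
  analytic value under this generator (43.09 at \(v = 1\)) sits about 0.9
  gray levels below the published 44.00, inside the stated comparison band
  but near its edge.
* Whole-image consolidation presumes a single-region scene; the
  auto-detection threshold is a heuristic, and callers with structured
  scenes of unusually low contrast should pass `consolidate = "none"`.
* Per-unit restoration accuracy is sample-size limited: a unit of radius
  \(\rho\) pixels carries a location standard error
  \(\approx 1.25\,\sigma/\sqrt{\pi\rho^2}\), so reliable exact quantification
  at variance 0.25 needs \(\rho \gtrsim 40\) pixels.
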