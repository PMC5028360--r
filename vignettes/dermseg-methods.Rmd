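---
title: "Methods: wavelet-based lesion segmentation in dermoscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: wavelet-based lesion segmentation in dermoscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the model behind `dermseg`, the choices made where
the method left latitude, and what the synthetic-phantom validation does
and does not establish.

## The segmentation model

A dermoscopic image is modeled as a darker pigmented lesion on lighter
skin, corrupted by three artifact classes: dark curvilinear hairs, bright
gel/water bubbles, and dark rounded lens corners. The pipeline removes the
two dark artifact classes explicitly and relies on heavy low-pass
filtering to suppress the bright ones.

Segmentation proper happens in the wavelet domain. The cleaned blue
channel is decomposed by a 2-level separable DWT and the level-2
approximation band A2 — a smoothed, 4-fold-downsampled version of the
image in which bubbles, residual hair fragments and pigment texture are
largely averaged away — is thresholded by Otsu's criterion with dark
pixels as foreground. The choice of the biorthogonal `bior6.8` as default
mother wavelet follows its symmetric linear-phase filters (no boundary
drift of the mask) and long smoothing support; `haar`, `db4`, `sym4` and
the JPEG2000 `cdf97` pair are provided for comparison via
`compare_wavelets()`.

Two numerical details matter for reproducibility:

* **Fixed quantization range.** A2 is quantized for Otsu over
  `input range × low-pass DC gain` rather than its observed min/max, so
  the threshold grid is independent of boundary content. Together with
  half-up rounding in the coefficient-to-pixel map, this makes the raw
  mask exactly shift-covariant at the level-2 stride in the image
  interior.
* **Group-delay alignment.** A level-L coefficient `i` maps to pixel
  `2^L i − d(2^L − 1)`, with `d` the energy centroid of the analysis
  low-pass filter. For symmetric banks this equals `(flen−1)/2`; for
  asymmetric ones (db4) the centroid corrects an otherwise visible mask
  offset.

The DWT uses half-sample symmetric extension with
`floor((n + flen − 1)/2)` coefficients per level, a mildly expansive
convention that reconstructs perfectly for arbitrary input sizes (round
trips are checked to 1e-8 in the tests against an independently computed
coefficient reference).

## Hair removal

Hairs are enhanced by a bank of anisotropic difference-of-Gaussians
matched filters: first Gaussian narrow across the line (σ across 1.5 px,
along 6 px), second broader (3 and 9 px) as local background estimate,
gains k₁ = 1, k₂ = 0.4, mean-subtracted so constant regions respond
exactly zero, rotated to 12 orientations at 15° steps (bicubic
resampling). Because hairs are dark, the per-orientation response is the
negated matched-filter output; the detection keeps the pixelwise maximum
and its orientation.

The method description leaves the hair threshold open. Otsu on
the response map was tried first and rejected on measurement: a response
map without hairs is unimodal, and Otsu then splits the noise mid-way
(about a quarter of a hairless frame gets flagged), while on hairy frames
it under-covers the low-contrast hair segments crossing the lesion. The
default is instead an absolute calibrated floor: the response that a
nominal 3-px dark line of 20 gray levels contrast would produce (the
matched-filter gain times 20). Twenty gray levels is below any plausible
lesion/skin contrast and an order of magnitude above the noise floor at
the filter scale. Otsu, fixed, quantile, and literal raw-intensity
(`raw_dark`) strategies remain available.

Thresholded components pass a shape filter — major axis ≥ 15 px and
either elongation ≥ 3 or everywhere thin (maximal inscribed radius
≤ 12 px). The thinness alternative is essential: crossing hairs merge
into webs whose global elongation is only ≈ 2 although every strand is
thin. Surviving regions are halos at the filter scale, so they are
trimmed to pixels at least 10 gray levels darker than their local 15×15
median background, closed by 1 px and dilated by 1 px.

Inpainting dilates the mask by 2 px (hair halos), initializes the hole
harmonically, then transports the Laplacian along isophotes (the
direction perpendicular to the gradient) with light interleaved
diffusion — 50 iterations by default. Median smoothing (3×3) is applied
only under the dilated hair mask, so pixels away from detected hairs are
returned bit-exact; on paired phantoms this restores the hair-free twin
inside the hair region to within ~8% of the uncorrected error.

## Corner handling

Dark lens corners are detected by Otsu thresholding of the luminance with
dark-is-foreground, keeping components that touch an image corner pixel,
clipped to the near-corner zone (within half the shorter image side of a
corner). The clip guards against a failure mode found during development:
a residual dark hair can bridge the lesion to a corner component, and
without the geometric bound the lesion would be absorbed into the corner
mask. For the same reason corner detection runs after hair removal.
Before decomposition, corner pixels are filled with the median
non-corner intensity so they cannot dominate the A2 histogram; they are
also subtracted from the final mask.

## Post-processing

The raw mask is cleaned in a fixed order: subtract corners, fill enclosed
holes (4-connectivity flood from the border), keep the largest component,
retain and bridge satellites within 20 px (closing with a
`merge_distance/2` disc), drop the rest, open with 3-px radii, and smooth
the boundary. Smoothing operates on the ordered boundary coordinate
sequence (8-connected trace, circular moving average of window W = 15
applied to row and column sequences independently) and re-rasterizes the
polygon with a half-pixel band that compensates the half-pixel erosion a
strict center-inside fill would apply — a rasterized circle is a fixed
point of the operation to within Dice 0.98. `min_island_area = 100` px is
the smallest dominant component accepted as a lesion; below it the result
is "no lesion found" (a warning and an empty mask, not an error). None of
these constants are given by the method's description; the defaults are
set relative to the 256×192 working canvas and all are exposed in
`morphology_config()`.

## Evaluation metrics

`evaluate_masks()` implements the literature's conventions, with two
deliberate readings. The printed FPR formula divides by the ground-truth
area (not the background area); it is implemented as printed, and the
standard fall-out `fp/(fp+tn)` is reported separately. The printed TNR
and TPR formulas are typesetting slips (one duplicates TDR, the other
uses complements); the standard confusion-matrix forms are used, which
also make the error probability a proper rate in [0, 1]. Reports are in
percent; EP is averaged and reported ×100, matching the scale on which
such tables are usually printed.

## The phantom generator

`generate_phantom()` renders the study conditions: a 256×192 canvas
(the 768×560 dermoscope frame scaled; full size available), skin RGB
(224, 172, 150), an alpha-blended elliptical lesion (122, 84, 66) whose
soft edge is a 4-px Gaussian blur of the alpha map (ground truth =
alpha ≥ 0.5), quadratic-Bézier hair strokes of thickness 3 in RGB
(52, 42, 36) crossing lesion and skin, bright bubbles with darker rims,
quarter-disc-complement dark corners, and additive Gaussian noise with
σ = 5, clipped to [0, 255]. Each artifact class draws from its own seeded
RNG substream, so switching one class off leaves the others bit-identical
— which is what makes the paired inpainting measurement possible.
`generate_suite()` jitters lesion position (±8% of the frame), axes
(±20%) and lesion color (±15 levels) reproducibly.

The phantoms deliberately omit pigment networks, skin texture, vessels,
uneven illumination and camera vignetting beyond the corner model.
Passing the phantom suites therefore demonstrates internal correctness
and artifact robustness of the pipeline, not clinical-grade performance
on real dermoscopy; on real data the lesion/skin contrast is lower and
more variable, and the reported suite numbers (Dice ≈ 0.97–0.99) should
be read as upper bounds of the mechanism, not expected field accuracy.

## Problem sizes and defaults

The test and acceptance suites use 20-case suites at 256×192, 10 paired
phantoms for the hair stage, 20 random 64×64 images for wavelet round
trips, 50 random images for the Otsu oracle and 100 random mask pairs for
the metric oracle. Degenerate inputs are defined throughout: constant
images raise "degenerate histogram" (Otsu) or yield "no lesion" (full
pipeline); empty masks evaluate with a warning and are excluded from
batch averages; an all-true inpainting mask is an error since there is
nothing to propagate from.
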