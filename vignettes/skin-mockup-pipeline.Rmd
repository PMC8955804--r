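---
title: "From RGB skin images to multilayer print jobs: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From RGB skin images to multilayer print jobs: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(skinfab)
```

## The optical model

Human skin color is dominated by two chromophores: melanin in the epidermis
and hemoglobin in the dermis. Working in optical density $d = -\log \rho$
(with $\rho$ the linear reflectance in each of R, G, B), skinfab assumes the
modified Lambert–Beer model

$$
d_c \;=\; c_m\, w_{m,c} \;+\; c_h\, w_{h,c} \;+\; b_c \;-\; s\, \ell_c,
\qquad c \in \{R, G, B\},
$$

where $c_m, c_h$ are the per-pixel (relative, unitless) melanin and
hemoglobin concentrations, $w_m, w_h$ are the pigments' density vectors per
unit concentration, $b$ is a stationary baseline density, $s$ is a signed
log-intensity shading offset, and $\ell = (1,1,1)/\sqrt 3$ is the
illumination direction (shading scales intensity identically on all
channels, hence a gray-axis offset in log space). Mixing is linear in
density space; that linearity is what every stage of the package exploits.

`render_skin()` is this model run forward; `separate()` is its inverse,
estimated blindly from an image.

## Pigment component separation

`separate()` composes four steps, each exposed on its own:

1. **Color plane (`estimate_color_plane`).** In a region little affected by
   illumination changes, shading is nearly constant, so densities lie on the
   2-D plane spanned by $w_m$ and $w_h$. PCA over the region's densities
   gives the plane (first two principal directions). The default region is
   a centered window covering a quarter of the image; callers with a
   non-skin background should pass an explicit mask.
2. **Shading removal (`remove_shading`).** Every density is decomposed
   *exactly* as $d = \text{origin} + u\,e_u + v\,e_v + s\,\ell$ by a 3×3
   solve. This is an *oblique* projection along $\ell$ onto the plane —
   orthogonal projection would be wrong unless $\ell$ happened to be the
   plane normal. The decomposition is exact to machine precision, which the
   tests assert; consequently any shading field whatsoever, as long as it
   acts along $\ell$, lands entirely in $s$.
3. **Pigment axes (`estimate_pigment_vectors`).** Within the plane there
   are exactly two sources, so ICA runs in the 2-D plane coordinates:
   center, whiten, fixed-point iteration with the $\log\cosh$ (tanh)
   contrast. Two choices matter and were genuinely open:
   * *Initialization.* Rather than a random start, the rotation angle is
     scanned (180 steps) for maximal contrast deviation from Gaussianity
     and the fixed point is refined from there. Random starts occasionally
     sit near the contrast saddle and converge to heavily biased
     directions; the scan is deterministic and costs a few milliseconds.
     The `seed` argument is accepted for interface stability but has no
     effect.
   * *Ambiguity resolution.* ICA leaves order, sign and scale free. Signs
     are fixed by orienting each lifted density vector toward absorption
     (positive component sum — pigments absorb); labels by the
     green-to-red density ratio (hemoglobin absorbs green strongly, so the
     axis with the larger ratio is hemoglobin); scale by normalizing the
     lifted vectors to unit norm, which makes concentrations relative —
     recovery is therefore assessed after affine alignment.
4. **Projection (`project_concentrations`).** A per-pixel 2×2 solve
   expresses the bias-subtracted plane coordinate in the pigment axes. The
   bias point is placed at the per-axis minimum concentration (percentile
   configurable), so each pigment's floor touches zero. Negative
   concentrations are kept in the map as diagnostics and clamped to zero
   only at the calibration boundary.

A practical conditioning note: the three directions $w_m$, $w_h$, $\ell$
form the unmixing system, and noise amplification is governed by its
inverse. A melanin vector close to the gray axis makes melanin and shading
nearly indistinguishable; the bundled default basis was chosen chromatic
enough to keep row norms of the inverse near 2.

## Concentration → CMYK calibration

The calibration grid (`build_patch_set`) crosses `n_mel` × `n_hem` equally
spaced concentrations (default 30 × 30 = 900 patches over [0, 1]; the level
count follows the printed-patch protocol, the spacing and range are package
choices). Each patch carries the RGB encodings of its two concentrations,
$\text{rgb} = \exp(-(c\,w + b))$, and CMYK targets from a pluggable color
transform. The default transform is naive under-color removal
($K = 1 - \max(R,G,B)$, remainder scaled by $1-K$); a profile-derived
transform can be substituted since press ICC profiles are proprietary.

Three estimators share one interface (`fit_* ` / `predict`):

* **LUT** — stores all patches; queries return the stored CMYK pair of the
  patch nearest in root-mean-square distance over the 6-vector of both RGB
  encodings, ties to the lowest index. Tested against an exhaustive scan.
* **Regression** — per layer and channel,
  $D_i = a_R \log R + a_G \log G + a_B \log B + b$, by least squares. Note
  that single-pigment encodings make $(\log R, \log G, \log B)$ exactly
  collinear (all affine in one scalar), so the design is rank-2 by
  construction; aliased coefficients are dropped via pivoted QR exactly as
  `lm()` does, and fitted values remain unique on the spanned subspace.
  With targets in this model class, leave-one-out error is numerically
  zero — the calibration pipeline's parameter-recovery surface.
* **MLP** — per layer, a 3→20→30→20→4 fully connected network (ReLU hidden
  units, linear output; 1414 parameters per network), trained with Adam on
  mean-squared error. Step size 1e-3, batch 32, 30 epochs and He-normal
  initialization are package choices; training is bit-reproducible given a
  seed and the per-epoch loss curve is recorded. Inputs are the raw RGB
  encodings (the regression uses logs; the network does not need them).

`loocv()` refits on each leave-one-out fold and scores the held-out 8
CMYK components; `compare_methods()` runs a two-sided *paired* t-test on
the matched per-patch errors (paired because LOOCV yields matched folds).
Zero-variance differences are flagged degenerate: identical error vectors
give $p = 1$; an exactly constant shift is reported as the infinite-t
limit, $p = 0$.

## Halftoning and the layer stack

Colored layers are binarized per channel by Floyd–Steinberg error
diffusion: plain raster scan, threshold 0.5 with ties firing a dot, error
weights 7/16 (right), 3/16 (below-left), 5/16 (below), 1/16 (below-right),
out-of-image targets dropped, accumulated values never clamped. No
serpentine scan and no dot-size modulation: stacking uniformity favors a
single, largest dot. The C++ kernel is checked bit-for-bit against an
independent double-loop reference implementation.

Before halftoning, rasters are resampled to the printer grid by
nearest-neighbour scaling with independent horizontal and vertical factors
(UV flatbeds commonly print 720 × 1200 dpi); nearest-neighbour preserves
concentration boundaries, and halftoning afterwards puts the dot
statistics on the device grid.

The print job is the fixed top-to-bottom stack *clear / melanin / clear /
hemoglobin / clear / white*: a protective clear layer, the epidermis-like
melanin layer, a clear spacer, the dermis-like hemoglobin layer, a clear
spacer, and an opaque white reflector playing the role of paper. Colored
layers are always one sublayer (concentration is expressed in area
gradation); clear layers may be several sublayers thick, and
`enumerate_samples()` produces the standard 3 × 3 thickness grid
({2,4,6} × {2,4,6}). The pipeline default (1, 2, 4) is the configuration
that scored best in subjective evaluation of printed samples. Jobs are
written as 1-bit-content PNGs plus a JSON manifest with a content hash;
`read_job()` round-trips losslessly.

## The synthetic data generator

Everything above is testable without a printer or camera because the
`synth_skin` module provides the forward direction:

* `render_skin()` renders the optical model exactly, flagging clamped
  pixels so round-trip tests can exclude them (reflectance is clamped to
  $[2^{-16}, 1]$ before any log).
* `virtual_print_capture()` stands in for printing a two-layer patch and
  photographing it: per-layer transmittance $\exp(-\sum_i D_i\,
  \delta_i)$ with fixed per-ink density vectors, squared for the down-and-
  back light path over a white reflector. It is smooth, monotone (more ink
  never brightens any channel) and injective over the patch grid.
* `make_phantom()` builds three families of concentration maps. The
  `palm_like` phantom is the main test subject: melanin as a low-frequency
  field plus skewed fine-grain mottle, hemoglobin as vessel-like ridges
  plus skewed fine-grain perfusion texture, and a smooth shading field
  that is flat in the central region (where the color-plane window sits)
  and darkens toward the edges.

Two generator choices deserve explanation. First, both pigment fields
carry a pixel-scale, strongly non-Gaussian texture component. ICA's
identifiability rests on source independence and non-Gaussianity; fields
with *only* low-frequency structure have so few effective degrees of
freedom at 128×128 that accidental sample correlation between the two
pigments (easily |r| ≈ 0.1) tilts any whitening-based estimator by
several degrees. The fine-grain component is the realistic cure — real
skin is mottled at pixel scale — and it restores identifiability. Second,
the generator explicitly removes the residual sample correlation between
the two finished fields, because the separation model *assumes*
independent sources; the adjustment is a few percent of one field's shape.

What passing tests therefore demonstrate: the separation machinery is
exact where its assumptions hold, degrades gracefully under sensor noise
(σ = 0.005 in reflectance), and is insensitive to shading. What they do
not demonstrate: performance on real skin, where surface reflections,
camera spectral response, pigment spectra that vary between individuals,
and spatially dependent pigment fields all violate the model to unknown
degrees. The printed-patch loop is likewise idealized by
`virtual_print_capture()`; physical ink scattering, dot gain and
inter-layer mixing are out of scope.

## Numerical choices and degenerate inputs

* Reflectance clamped to $[2^{-16}, 1]$ before logs; log features guarded
  by the same floor.
* PCA plane estimation rejects regions whose second principal variance is
  below 1e-12; shading removal rejects an illumination direction within
  1e-6 of the plane; projection rejects pigment axes with in-plane
  condition number above 1e8.
* ICA: 180-step angle scan, then fixed-point iteration, tolerance 1e-8 on
  the direction change, at most 500 iterations; non-convergence is an
  error carrying the iteration diagnostics, near-Gaussian data a warning.
* Floyd–Steinberg threshold is exactly 0.5 and a tie fires a dot; the
  error budget is per channel and never clamped.
* All stochastic stages draw from seeds passed explicitly; global RNG
  state is saved and restored, so library calls never perturb a caller's
  stream.

## Problem sizes

The shipped tests and the acceptance script use a 128×128 palm phantom for
separation experiments (plus 20 noisy replicates), the full 30×30 = 900
patch grid for calibration (LOOCV refits all 900 folds for LUT and
regression; the MLP's LOOCV smoke test runs on a reduced grid), 100 random
instances up to 64×64 for halftone oracle equivalence, and 64×64 jobs for
end-to-end determinism. These sizes were chosen so the whole suite runs in
well under a minute of compute per module while leaving the statistics
(correlation thresholds, tone-error bounds) far from their acceptance
margins.

## Known limitations

* Planar targets only: no 3-D geometry, no ink-limit or adhesion modeling,
  no vendor driver output — the job directory is the interface.
* Two pigments and three channels: no oxy/deoxy-hemoglobin distinction,
  no spectral (beyond-RGB) rendering, no surface-reflection removal
  (physically done with polarizers at capture time).
* The default CMYK transform is a crude stand-in for a press profile;
  calibration quality against a real device depends entirely on
  substituting a measured transform.
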