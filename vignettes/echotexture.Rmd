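---
title: "GLCM echotexture analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{GLCM echotexture analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(echotex)
```

## The model

`echotex` characterizes B-mode ultrasound echotexture through the
second-order statistics of gray-level pairs. Fix a displacement: a paired
distance `d` in pixels and an angle θ. Every pixel whose displaced
neighbor falls inside the image contributes one (reference, neighbor)
gray-level pair; tallying all pairs into an `L × L` matrix gives the
gray-level co-occurrence matrix (GLCM). With `symmetric = TRUE` each pair
is also counted in the reversed order, so the matrix equals its transpose
and the analysis is insensitive to the direction (as opposed to the
orientation) of the displacement. With `normalized = TRUE` the counts are
divided by their total, turning the GLCM into the joint probability
distribution `p(i, j)` of gray-level pairs — the object all features are
defined on. Pairs are only counted when both pixels are inside the image;
there is no padding, so an ROI must be larger than the displacement or
`compute_glcm()` refuses it.

Seven scalar features summarize `p`. Contrast (`Σ p (i−j)²`) and
dissimilarity (`Σ p |i−j|`) weight off-diagonal mass by squared and
absolute gray-level difference and respond to edges and coarse granularity;
homogeneity (`Σ p / (1+(i−j)²)`) is their inverse-weighted counterpart.
ASM (`Σ p²`) measures orderliness — a few heavily used pair values give a
high ASM — and energy is its square root, so the two are monotone images
of each other. Entropy (`−Σ p ln p`) measures spread of the pair
distribution. Correlation is the Pearson correlation of the two marginal
gray levels under `p`.

These definitions imply structural relationships the test suite asserts as
properties: `energy² = ASM` by construction; `dissimilarity ≤ √contrast`
(Cauchy–Schwarz applied to `|i−j|` under `p`); `contrast = 0`,
`homogeneity = 1` and all mass on the diagonal are equivalent; entropy
lies in `[0, 2 ln L]` with the maximum attained by the uniform GLCM; and
all seven features are invariant to adding a constant to every pixel,
because the whole matrix just translates along its diagonal. They also
explain the empirical regularities seen in feature tables: entropy and ASM
are strongly negatively correlated (spread vs. concentration of the same
distribution), while dissimilarity and contrast are strongly positively
correlated (the same off-diagonal mass under two weightings).

## Parameters that matter

* `distance` (pixels, default 5): the spatial scale probed. At 1 the GLCM
  sees speckle-grain transitions; at 5 it compares pixels across roughly a
  speckle cell, which is the convention this package follows for
  ultrasound parenchyma.
* `angle` (degrees, default 0): 0° pairs each pixel with the one
  `distance` to its right; 45°, 90°, 135° rotate counter-clockwise. Which
  orientation is "right" for a given transducer geometry is genuinely
  open; the package defaults to 0° and offers
  `image_features(average_angles = TRUE)` to average the features over all
  four orientations when rotational invariance is wanted.
* `levels` (default 256): gray-level resolution of the matrix. 8-bit input
  with `levels = 256` gives the full 256 × 256 matrix; coarser
  quantization trades gray-level detail for denser cell occupancy.
* `symmetric`, `normalized` (defaults `TRUE`): the feature formulas
  require a normalized matrix, and symmetry removes direction dependence;
  both can be disabled for inspection of raw counts.

"Normalization" here always means matrix normalization (entries sum
to 1), not intensity normalization of the image; gray-level translation
invariance of the features makes per-image brightness offsets immaterial
anyway.

## Quantization and image loading

`quantize_image()` maps `[min, max]` linearly onto `[0, levels−1]`,
rounding half toward zero; a constant image maps to all zeros, and inputs
already in range pass through unchanged. Rounding direction only matters
for values exactly halfway between levels; it is fixed, documented and
tested rather than left to the platform.

PNG input must be 8-bit (the bit depth is read from the file header and
anything else is an explicit error — no silent truncation). Grayscale or
channel-equal RGB is used directly; true-color RGB collapses by Rec. 709
luminance (`0.2126 R + 0.7152 G + 0.0722 B`). TIFF may be 8- or 16-bit;
16-bit values rescale by the fixed-range map `v · 255/65535`, independent
of image content, so identical tissue recorded at different bit depths
lands on comparable gray levels. DICOM is deliberately out of scope: the
supported workflow exports to a lossless 8-bit format first.

ROIs are axis-aligned rectangles in 0-based, half-open coordinates
(`x` = column, `y` = row); the convention is part of the CSV contract so
that ROI tables are portable. ROI selection is file-driven rather than
interactive — reproducibility over interactivity.

## PCA choices

Features are standardized (correlation-matrix PCA). Their natural scales
differ by orders of magnitude — contrast of speckle at 256 levels runs in
the hundreds while ASM lives near 1e-4 — so covariance PCA would simply
rank features by numeric range. Standardization also buys affine
invariance: rescaling any feature leaves scores and loadings unchanged,
which the test suite asserts.

Principal component signs are arbitrary, so a deterministic convention is
applied: within each loading column the entry of largest magnitude is made
positive (first index wins ties). Reported variance fractions are
eigenvalues over their total, hence non-increasing and summing to 1 when
all components are kept. A zero-variance feature cannot be standardized
and is reported by name as an error rather than dropped silently. Biplot
arrows are loadings scaled by the component standard deviation (the usual
display scaling); the raw unit-norm loadings stay available in the
returned structure.

## What the phantom generator emulates — and what it does not

The generator produces images that *behave like* ultrasound parenchyma
under GLCM analysis; it is not an acoustic simulation. The background is
an independent Rayleigh-distributed envelope per pixel — the classical
amplitude model for fully developed speckle — smoothed with a Gaussian of
`smoothing_radius` 1.2 px to give the speckle a finite correlation length,
then rescaled so the background mean lands at gray level 120 of the 8-bit
range, comfortably inside it. Log-compression, beam geometry, attenuation,
shadowing and the point-spread function's anisotropy are all omitted: the
texture features care about relative gray-level structure, and adding
unvalidated physics would only add unverifiable parameters.

Three lesion classes are drawn on top, each a pure function of its
parameters and seed:

* **Microliths**: `count` bright disks (default radius drawn from 1–3 px,
  gain +120 gray levels, clipped at 255) at non-overlapping random
  positions, echoing pinpoint hyperechoic foci; deliberately *without* an
  acoustic shadow, matching how such foci present. Ground-truth centers
  are returned.
* **Septated cyst**: an ellipse whose interior is replaced by a fresh
  low-mean Rayleigh noise floor (default mean 18 — near-anechoic but not
  flat, since anechoic regions in real scans still carry a noise floor),
  crossed by thin bright septa with per-pixel intensity jitter. The
  noise-floor interior is a deliberate design choice: a flat dark fill
  concentrates the pair distribution and *lowers* GLCM entropy, the
  opposite of what heterogeneous lesions do to real images.
* **Heterogeneous parenchyma**: a smooth multiplicative gain field
  (blurred uniform noise mapped into 0.55–1.45), emulating patchy
  echogenicity.

Default cohort composition is 245 normal / 16 microlith / 19 other
(cysts and heterogeneous parenchyma alternating), a study-scale 280-image
cohort with a realistic 12.5% lesion prevalence; all sizes are parameters.
Phantom shape defaults to 128 × 128 px, a typical cropped-ROI size; the
test suite uses 64 × 64 phantoms (48 per group for cohort-level checks,
above the 40-per-group floor needed for stable group means) and the
acceptance script uses 96 × 96 at the full 280-image composition — sizes
chosen as the package's own balance between statistical stability and a
fast default run.

Because phantoms are generated, passing tests demonstrate internal
consistency of the pipeline and the *direction* of lesion effects
(entropy, dissimilarity, contrast up; ASM, energy down; lesion group
displaced along PC1 toward the entropy/contrast loadings) — not that the
generator reproduces any particular scanner's texture statistics, for
which no quantitative per-group reference values exist. Magnitudes of
group differences on phantoms should not be read as clinical effect
sizes.

## Numerical choices and degenerate inputs

* Entropy uses the natural logarithm with `0 · ln 0 = 0`; base choice
  rescales entropy by a constant and cannot change standardized-PCA
  structure.
* Correlation of a GLCM with a zero marginal standard deviation (constant
  image) is defined as 1 — a constant image is perfectly self-similar;
  the guard triggers below 1e-14.
* Normalization is checked to 1e-8 before features are computed;
  normalized matrices sum to 1 within 1e-9 by construction.
* Feature CSVs are written with full double precision and round-trip
  losslessly; the schema (column order included) is validated on read,
  with duplicate `(image_id, ROI)` keys reported by row.
* Per-image seeds derive from the master seed by a fixed affine map modulo
  2³¹−1, keeping every seed in integer range and every artifact
  bit-reproducible; reruns of the pipeline with one config are
  byte-identical on all CSV outputs.
* The pipeline's resolved configuration is recorded as flat JSON next to
  its outputs (one machine-readable key-value document; flags mirror the
  keys), and the record alone suffices to reproduce the run.

## Known limitations

Only the four canonical GLCM orientations and a single distance per run
are supported; higher-order texture families (run-length, wavelet, local
binary patterns) are out of scope, as are supervised classifiers over the
feature table — the PCA exploration is intentionally unsupervised. The
phantom generator's realism bounds what synthetic validation can show, as
discussed above. Multi-frame or DICOM input is not read directly.
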