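---
title: "Quantifying leaf color from raw imagery: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying leaf color from raw imagery: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`ryecolor` quantifies the leaf color of harvested perennial ryegrass
(*Lolium perenne*) from raw camera imagery and relates a single
color-intensity score to phenotypic, environmental, genetic and temporal
covariates. This vignette is the package's own account of the method: the
processing model stage by stage, the tunable parameters and why their
defaults are what they are, what the synthetic-data generator does and does
not emulate, and the numerical choices made where the design was open.
Every number quoted here is computed by the test suite, the `analysis/`
drivers or `scripts/acceptance.R`; the vignette adds no empirical claims of
its own.

## The measurement model

A harvested plant is photographed on a white board next to a 24-patch
reference chart. The camera stores a color-filter-array (CFA) frame: one
sensor count per pixel, laid out on a Bayer mosaic. Development into a
color-corrected RGB image proceeds in nine steps:

1. subtract the sensor's black level from every count;
2. floor negative values at zero;
3. normalize by the white-minus-black range;
4. white balance by scaling red and blue photosites relative to green;
5. quantize to the unsigned 16-bit grid, then demosaic with
   gradient-corrected linear interpolation (bilinear estimate of each
   missing channel plus a scaled Laplacian correction from the measured
   channel, the standard 5 x 5 kernel set);
6. map from the camera's color space to RGB with the metadata matrix;
7. locate the 24 chart patches and measure each as the per-channel median
   over the central 50% of its area;
8. fit the affine color correction `c -> M c + b` by ordinary least
   squares of the reference patch colors on the measured ones;
9. apply the fitted map and clip to [0, 1].

Leaf pixels are then extracted: crop to the white board (bounding box of
the largest near-white connected region, leaves included as interior
holes), convert to HSV, keep pixels with hue in [0, 0.4] or [0.875, 1]
(yellow-green plus the red wraparound), saturation in [0.2, 1] and value in
[0, 0.9], remove connected components under 100 pixels, refine with 50
sweeps of region-based active contours, and re-gate saturation at
[0.25, 1]. Each plant is reduced to its per-channel median RGB; medians
are used throughout for their robustness to outliers and skew.

The per-plant median-RGB matrix is decomposed by an **uncentered, unscaled
principal component analysis** — a singular value decomposition of the raw
n x 3 matrix. Centering is deliberately omitted to preserve the channels'
relative values; because median RGB is non-negative, the first axis is a
size (lightness) axis with all-positive loadings. Its score is the plant's
*color intensity*: larger is lighter, smaller is darker. The share of
variation per axis is the squared singular value over their sum, which is
invariant to the n-versus-(n-1) divisor convention.

The statistical layer screens each PC axis with Shapiro-Wilk, compares
paired groups (harvests within a water status; water statuses within a
harvest) with Kendall's tau-b rank correlation and Wilcoxon's signed-rank
test, and fits an ordinary least-squares model of PC1 on dried biomass
(g), maximum height (cm), SPAD (chlorophyll index), soil moisture (%),
climate treatment (2 levels), variety (4 levels) and harvest month (2
levels). Each term is then assessed by single-term deletion: a Type II F
test against the full model plus the AIC change on removal.

## Tunable parameters

| Parameter | Default | Units | Rationale |
|---|---|---|---|
| hue gate | [0, 0.4] and [0.875, 1] | hue fraction | yellow-green-red leaf hues incl. red wraparound |
| saturation gate | [0.2, 1] | fraction | excludes the near-achromatic white board |
| value gate | [0, 0.9] | fraction | excludes bright board pixels |
| component filter | 100 | pixels | strict "fewer than" semantics; debris removal |
| active contours | 50 | sweeps | boundary refinement; 0 disables |
| saturation re-gate | [0.25, 1] | fraction | removes desaturated rim pixels after growth |
| connectivity | 8 | — | avoids fragmenting thin blades; configurable to 4 |
| quantization | on | — | 16-bit snap between linearization and demosaic |

All interval bounds are inclusive: the gates are written as closed ranges,
and the tests pin the boundary semantics (a component of exactly 100
pixels survives; saturation exactly 0.25 is retained).

## What the synthetic generator emulates

Every stage is exercised on rendered scenes with known ground truth, so
the package needs no external downloads to be tested end to end.

* **Scenes.** A dark surround, the 24-patch chart in a strip, and a white
  board carrying elongated blades. The board is near-white with slight
  texture (channels 0.92-1.0) so the saturation gate does real work; a
  perfectly white background would make several filters vacuous. Blades
  are parametric (random orientation, length 36-56 px, width 10-18 px,
  taper, curvature) and cluster around a pile centre, overlapping as
  harvested material does. One plant's leaves share pigmentation: a
  per-plant base hue with ±0.025 between-leaf jitter, per-leaf HSV draws,
  and ±7% multiplicative within-leaf shading. Blade widths are set
  against the 5 x 5 demosaic kernel scale: at this rendering resolution a
  blade is many kernel-widths across, as real blades are at the
  photographed resolution.
* **Camera.** The exact forward inverse of development steps 1-6 plus a
  configured affine color cast, Gaussian read noise and integer
  quantization. The default cast and camera matrix are mild and keep the
  whole scene gamut inside the sensor range after inversion — a camera
  whose calibration destroyed in-gamut colors by clipping would be a
  broken instrument, not a test condition. With zero noise the full
  develop-and-segment chain must reproduce each plant's true median RGB
  within 2% per channel for at least 95% of plants; this is checked, and
  the residual error is demosaic edge error at leaf boundaries.
* **Phenotypes.** The full factorial design — 4 varieties x 2 water
  statuses x 2 climate treatments, each plant measured at 2 harvests —
  with `n_per_cell = 20` reproducing the study scale of 320 plants and
  640 records (630 residual degrees of freedom under the 10-parameter
  model). The response is a known linear predictor plus Gaussian noise
  (residual sd 11 on a PC1-like scale of roughly 100-400); coefficient
  signs follow the biology: heavier, taller, chlorophyll-rich plants are
  darker, wetter soil and the warm high-CO2 treatment lighten leaves, the
  diploid reference variety is lightest, and the second harvest is
  darker. Covariates are drawn uniformly over realistic ranges (biomass
  0.5-6 g, height 15-60 cm, SPAD 8-45, moisture 15-60%).

What the generator does **not** emulate: real leaf morphology (folding,
specular highlights, shadows), lens effects, chart placement error, and
correlation between covariates and the imaging scene beyond lightness.
Passing tests therefore demonstrate that the algorithms are implemented
correctly and are mutually consistent — not that the segmentation
thresholds are optimal for any particular real camera or lighting.

## Numerical choices and open-design decisions

* **Normalization constant.** "Divide by the maximum pixel value" is read
  as the metadata white level (after black subtraction), not the per-image
  observed maximum, which would make calibration exposure-dependent.
* **Quantize-then-demosaic.** The 16-bit conversion and demosaicing share
  a step in the published pipeline order; the package quantizes first
  (switchable with `quantize = FALSE`); the effect is below 1/65535 per
  channel.
* **White balance** uses metadata gains, not chart-derived gains; the
  chart already absorbs residual casts through the affine fit.
* **Demosaic borders** use reflective padding, avoiding zero-border
  fringes; patch measurement avoids borders anyway. Interior pixels agree
  exactly with a direct-convolution oracle, and constants and planar ramps
  are reproduced exactly (the Laplacian correction vanishes on affine
  images).
* **Chart localization is not automated.** Patch positions come from
  recorded corner coordinates (the simulator always records them; real
  use supplies them via config). The patch statistic is the median of the
  central 50% area, robust to edge bleed.
* **Active-contour variant.** Region-based Chan-Vese evolution on the
  value channel with zero smoothing weight: each sweep recomputes the
  inside/outside means and flips boundary pixels to the closer region, so
  the contour can grow and shrink one ring per sweep and stops at a fixed
  point. The channel and iteration count are configurable and logged; a
  mask that already separates a two-level image is provably unchanged.
* **Empty masks** yield a flagged missing-median record, never an
  exception, so batch runs survive failed plants; such records are
  excluded from the PCA with a logged count.
* **PCA sign convention.** SVD signs are arbitrary; PC1 is fixed
  all-positive (so positive means lighter), PC2/PC3 by making the
  largest-magnitude loading positive.
* **Pairing is explicit.** Between-harvest comparisons pair on
  `plant_id`; between-water-status comparisons pair on the design stratum
  (variety x treatment x replicate). No positional pairing is ever
  inferred.
* **Rank-test conventions.** Kendall: tau-b with the tie-adjusted normal
  z (a z statistic is reported even with ties). Wilcoxon: zero
  differences dropped, ties mid-ranked, exact null distribution for 25 or
  fewer untied differences, otherwise the normal approximation with tie
  and continuity correction.
* **AIC** on the `n log(RSS/n) + 2p` scale; only differences are
  reported, so the constant is irrelevant. The deletion table's AIC
  change is full minus reduced: negative when removing the term worsens
  the model.
* **No multiplicity correction** is applied; raw p values carry
  significance stars at 0.05 / 0.01 / 0.001.
* **Monte-Carlo sizes.** The size of the rank tests is estimated on 3000
  null replicates of 40 pairs, putting the binomial standard error near
  0.4 percentage points — small against the 4-6% acceptance band; both
  tests sit near 4.8%. Chart-recovery checks add per-patch noise of sd
  0.002, reflecting that a measured patch color is a median over hundreds
  of pixels and so carries far less noise than a single photosite.
  Synthetic study runs use 200 x 288 scenes and 32-64 records; these sizes
  are the package's reference conditions and are stated wherever results
  from them are reported.

## Limitations

* The color model is affine; strong nonlinear casts (tone curves applied
  in-camera) are out of scope, as is vendor RAW decoding — the CFA
  container is a 16-bit TIFF plus JSON sidecar, with a declared adapter
  hook for real RAW sources.
* Segmentation separates leaf from background, not leaf from leaf; no
  per-leaf morphology is measured.
* Mixed-effects alternatives to the fixed-effects model are deliberately
  not fitted: with few levels per grouping factor, random-effect variance
  estimates can collapse to zero and worsen the fit.
* The published study-scale benchmark values (PC axis shares, adjusted
  R-squared, deletion-table F statistics) can only be recomputed from the
  study's deposited data, which is not shipped with the package; the
  corresponding check reports itself as unmet when the deposit is absent.
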