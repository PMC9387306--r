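# ryecolor

Quantifies leaf color of harvested perennial ryegrass (*Lolium perenne*)
from raw camera imagery, and relates the resulting **color intensity** of
each plant to its phenotype. Waterlogging stress changes leaf pigmentation
— stressed plants turn lighter, young stressed plants purplish — so a
calibrated, scalar color measure is a cheap whole-plant health readout for
stress experiments and breeding trials. The package targets plant
scientists running such experiments: it turns a folder of raw frames (or
fully synthetic, ground-truthed stand-ins) into a scored plant table and
the statistics to interpret it.

## What it computes

1. **Raw development.** Each color-filter-array (Bayer) frame is
   developed into a color-corrected RGB image: black-level subtraction,
   normalization, white balance, 16-bit quantization, demosaicing by
   gradient-corrected linear interpolation (5 x 5 kernels), camera-to-RGB
   matrix, then an affine color correction `c -> M c + b` fitted by least
   squares on the 24 patches of an in-frame reference chart.
2. **Leaf segmentation.** Crop to the white background board, HSV gates
   (hue in [0, 0.4] or [0.875, 1], saturation in [0.2, 1], value in
   [0, 0.9]), removal of connected components under 100 pixels, 50 sweeps
   of region-based active contours, and a saturation re-gate at
   [0.25, 1].
3. **Color intensity.** Per-plant median RGB, then an *uncentered,
   unscaled* PCA of the n x 3 median matrix (SVD of the raw matrix). PC1
   has all-positive loadings — a lightness axis; its score is the plant's
   color intensity (higher = lighter).
4. **Statistics.** Shapiro-Wilk screening; paired Kendall tau-b and
   Wilcoxon signed-rank comparisons between harvests and between water
   statuses; ordinary least squares of PC1 on biomass, height, SPAD, soil
   moisture, climate treatment, variety and harvest month; single-term
   deletion Type II ANOVA with AIC deltas and adjusted R².

A synthetic-data module renders ground-truthed scenes (leaves + chart +
known camera distortion, mosaicked to a CFA) and factorial phenotype
tables with known effect structure, so the whole chain is testable without
any downloads.

## Worked example

The `analysis/` drivers run the full synthetic study (16 plants, 2
harvests) end to end:

```sh
Rscript analysis/01_simulate.R   # factorial design + raw frames
Rscript analysis/02_develop.R    # develop + chart calibration
Rscript analysis/03_segment.R    # leaf masks + funnel audit
Rscript analysis/04_quantify.R   # median RGB + uncentered PCA
Rscript analysis/05_stats.R      # rank tests + linear model
```

Output of stages 3-5 on the default seed:

```
Segmented 32 images; 0 empty masks.
Mask IoU vs rendered truth: median 0.975, min 0.955

Uncentered PCA of 32 median-RGB records.
Variance explained: PC1 98.9%, PC2 1.0%, PC3 0.1%
PC1 loadings (all positive -> a lightness axis): 0.497, 0.808, 0.317

Color-intensity model: 32 records, 22 residual df, adjusted R^2 87.2%
Single-term deletions (Type II ANOVA + AIC):
               term df   sum_sq     rss    aic    d_aic      F         p stars
1            <none> NA       NA 0.04143 -192.8       NA     NA        NA
4              spad  1 0.129893 0.17132 -149.4 -43.4258 68.976 3.153e-08   ***
```

Reading it: the masks recover the rendered ground truth almost exactly
(IoU 0.975); virtually all color variation collapses onto the single
lightness axis (PC1 98.9%, all-positive loadings); and deleting SPAD — the
chlorophyll proxy — costs the model most (largest F, most negative AIC
change), exactly the structure the simulator planted. Equivalent
programmatic access:

```r
library(ryecolor)
res <- run_pipeline(default_config(seed = 1, n_per_cell = 1))
res$pca                 # variance shares and loadings
res$model               # color-intensity linear model
res$drop1               # single-term deletion table
```

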