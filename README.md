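# wpbquant

Quantification of secretory-vesicle trafficking in multi-channel
fluorescence microscopy images of endothelial cells.

Weibel–Palade bodies (WPBs) — the cigar-shaped, von-Willebrand-factor-storing
granules of endothelial cells — redistribute between the cell periphery and
a perinuclear region (the microtubule organizing centre) in response to
inflammatory agonists. The package implements the image-quantification
battery used to measure that redistribution, plus a synthetic image
generator with full ground truth so that every stage can be validated
without access to original microscopy data.

## What it computes

**Radial zone distribution** (the core statistic). With particles $p$
segmented from a background-subtracted vesicle channel, each with minimum
nucleus distance $d_p$ (from an exact Euclidean distance map) and
integrated intensity $I_p$, the per-image zone fractions are

$$F_z = \frac{\sum_{p:\,d_p \in z} I_p}{\sum_x I(x)},\qquad
  z \in \{\text{perinuclear} < 2\ \mu m,\ \text{intermediate } 2\text{–}5\ \mu m,\ \text{periphery} > 5\ \mu m\},$$

averaged image → biological repeat → group and reported as mean ± SEM.
The pipeline chain is: isodata ("Default") threshold on the nucleus
channel → median filter → watershed → distance map → Max Entropy (Kapur)
segmentation of each vesicle channel → per-particle Distance (Min) and
IntDen → zone binning → normalization by total image fluorescence.

Also provided:

* **`count_wpbs()`** — vesicles per nucleus via Bernsen local thresholding
  (15-px radius) with size filtering; `count_positive_cells()` scores
  vesicle-positive cells by nearest-nucleus assignment.
* **`detect_spots()` / `colocalize()`** — scale-matched spot detection and
  object-based colocalization against a driver channel (percentage of
  secondary spots on driver structures).
* **`fit_nucleus_oval()` / `radial_sum_profile()` /
  `classify_clustering()`** — 20%-enlarged nucleus oval, 360-ray radial-sum
  intensity profile, and peak/mean classification of perinuclear
  clustering versus cytosolic distribution.
* **`paired_t_test()` / `anova_bonferroni()`** — the study's statistics:
  paired t, one-/two-way ANOVA with Bonferroni post hoc tests and
  ns / \* / \*\* / \*\*\* tiers.
* **`synth_config()` / `generate_image()` / `generate_group()`** —
  synthetic 16-bit multi-channel images (elliptical nuclei, rod- or
  spot-shaped vesicles, configurable zone intensity fractions,
  colocalization fractions, noise) with exact ground truth.

## Worked example

```r
library(wpbquant)

# a synthetic histamine-like condition: 80% of vesicle signal perinuclear
cfg <- scenario_distribution("clustered", seed = 1)
out <- generate_image(cfg)

run_distribution_pipeline(out$image)
#>   channel perinuclear intermediate  periphery n_perinuclear n_intermediate n_periphery n_particles
#> 1     red    0.784718   0.08901792 0.07469675            25              9          30          64

out$truth$zone_fractions$fraction    # generator ground truth
#> [1] 0.79212017 0.09505442 0.06336961
```

The pipeline attributes 78.5% of the image's fluorescence to segmented
perinuclear structures against a ground truth of 79.2%; the intermediate
and periphery zones agree similarly. Counting works the same way (here on
an image of dense rods, where touching rods merge into single particles —
counting is defined for the well-separated regime, see the vignette):

```r
cnt <- count_wpbs(out$image$channels$red, out$image$channels$dapi)
cnt
#> <count_result> 56 particles / 3 nuclei = 18.67 per nucleus
```

The `analysis/` scripts chain the full simulated experiment (two groups ×
3 biological repeats × 5 images) and write the result tables under
`results/`; step 2 prints, for example:

```
Zone distribution, mean +/- SEM over biological repeats:
  clustered perinuclear 0.784+/-0.003  intermediate 0.092+/-0.001  periphery 0.076+/-0.001
  uniform   perinuclear 0.225+/-0.003  intermediate 0.324+/-0.004  periphery 0.427+/-0.002
```

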