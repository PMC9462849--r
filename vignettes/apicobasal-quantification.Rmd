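---
title: "Quantifying apico-basal receptor distribution in a columnar epithelium"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying apico-basal receptor distribution in a columnar epithelium}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(apbaquant)
```

## The measurement problem

Epithelial cells are polarized along their apico-basal (Ap-Ba) axis, and
where a signalling receptor sits along that axis can matter as much as how
much of it there is. The motivating case is the Hedgehog (HH) transducer
Smoothened (SMO) in the *Drosophila* wing imaginal disc: surface-labelled
SMO is unevenly distributed along the Ap-Ba axis of the columnar
epithelium, and high HH doses shift it toward the basal membrane. The
readout is image-based: antero-posterior XZ confocal stacks, one channel
carrying the surface-labelled receptor and one carrying a Cubitus
interruptus (CI) immunostain that reports the position-dependent HH
response.

`apbaquant` re-implements that quantification as a tested pipeline:

1. **Projection** — average-intensity projection of 8 consecutive XZ
   sections (`average_projection()`).
2. **Disc detection** — the tissue footprint on the projection
   (`detect_disc()`).
3. **Column tiling** — fixed-width rectangles from the apical to the basal
   surface, anchored at the user-supplied A/P boundary
   (`make_columns()`).
4. **Partition and measurement** — each column is split into
   apical/subapical, lateral, and basal bands (15% / 75% / 10% of the
   local thickness) and each band's pixel count, integrated density
   (sum of pixel values), and mean intensity (sum over count) are
   measured (`partition_column()`, `measure_roi()`).
5. **AP classification** — pixel columns are classified, from the CI
   channel, into the four regions of the HH gradient: the posterior
   compartment P (no CI), and anterior CI-A (low CI, high HH), CI-F
   (high CI), and CI-R (no detectable CI, no HH)
   (`classify_regions()`).
6. **Statistics** — relative intensities (band integrated density over
   column integrated density), fold changes, pulse-chase percent
   reductions, and paired t / exact Wilcoxon signed-rank / exact
   Mann-Whitney tests (`fold_change()`, `percent_reduction()`,
   `paired_t()`, `wilcoxon_signed_rank()`, `mann_whitney()`).

Because no raw imaging data are publicly available for this assay, the
package ships a synthetic stack generator (`make_disc()`,
`make_pulse_chase()`) whose ground truth makes every stage testable by
parameter recovery.

## The synthetic generator and its defaults

The generator renders XZ stacks directly (the analysis only ever consumes
XZ data) of the columnar epithelium only; the overlying peripodial layer,
optical PSF blur, and cell-scale texture are deliberately not modelled.
A stack is `channel x section x z x x`, row 1 apical, anterior at low x.
Tissue pixels carry an expected intensity; everything else is background.
Each AP region `r` has an expected column-summed intensity `L_r` (photon
units) apportioned over the three depth bands by fractions
`(f_ap, f_lat, f_ba)`; band pixels share the band's expectation
uniformly. Noise follows the usual photon-counting model:

```
value = Poisson(E * poisson_scale) / poisson_scale
        + Normal(0, read_noise_sd) + background
```

clamped at zero, and `expectation_mode = TRUE` bypasses sampling entirely
for exact checks. The generator apportions intensity using the same
15/75/10 partition rule as the analysis, which makes fraction recovery a
well-posed identity test.

Defaults encode the study conditions the pipeline is meant to detect:

* geometry: 200 x 80 px, 8 sections at 1 µm, constant thickness 60 px
  (a parabolic `bow_amplitude` is available and exercised in tests);
* A/P boundary at x = 141; CI-A 12 px wide (one pixel column per cell
  row of the roughly 12-cell HH gradient), CI-F 20 px;
* receptor levels 2000 / 2600 / 3100 / 3400 for CI-R / CI-F / CI-A / P —
  a 1.7-fold posterior-over-far-anterior increase;
* Ap-Ba fractions rising basally along the gradient, from
  (0.25, 0.65, 0.10) in CI-R to (0.15, 0.60, 0.25) in P
  (`default_smo_fractions()`);
* CI levels: background in P and CI-R, high (3000) in CI-F, low (1200)
  in CI-A;
* pulse-chase retention factors per region and band
  (`default_retention()`): (0.53, 0.56, 0.72) far anterior and
  (0.62, 0.72, 0.96) posterior — i.e. subregion reductions of 47/44/28%
  without HH and 38/28/4% with HH — with the two intermediate regions
  interpolated, since only the extremes are constrained by measurement;
* noise: `poisson_scale = 1`, `read_noise_sd = 1`, `background = 0`.
  Acquisition bit depth and offsets are free parameters of the original
  assay, so these are chosen for a realistic ~6:1 per-pixel SNR rather
  than calibrated to an instrument.

What passing recovery tests on these data do show: the pipeline's
geometry, partition, classification, and estimators are unbiased and
consistent under photon-counting noise. What they cannot show: robustness
to out-of-focus light, peripodial contamination, mounting artefacts, or
segmentation of touching tissues — real-data concerns outside the
generator's vocabulary.

## Design choices in the open

**Coordinates.** All pixel ranges are 1-based and inclusive
(`x_start..x_end`, `z_top..z_bottom`), the idiomatic convention for R
matrices; row 1 is apical.

**Disc detection.** The original macro's algorithm is not published, so
detection is the package's own: Gaussian smoothing (sigma 2 px), Otsu
thresholding on the log-compressed image, largest 4-connected component,
hole filling, then per-column half-maximum edge refinement on the raw
projection. Two details matter. Otsu is applied in log space because the
several-fold regional intensity differences of a morphogen gradient
otherwise pull the global threshold between tissue modes instead of
between background and tissue. And the half-maximum refinement exists
because a thin, bright basal band blurs outward under smoothing: a global
threshold then systematically overestimates the tissue extent by a pixel
or more, which alone is enough to corrupt a 10%-of-thickness basal band.
Half-maximum localization of a step edge is exact for noiseless steps and
pixel-accurate at the default SNR.

**Local thickness.** Each column's thickness is taken from the mask at
that column (the union extent over its member pixel columns), not from a
global disc thickness: epithelium height varies along the AP axis, and a
global value would misassign bands in bowed discs.

**Partition rounding.** Band heights are `round(f * h)` half-away-from-
zero with a floor of one row; the lateral band takes the remainder. This
reproduces 15/75/10 exactly at h = 100 and keeps the three bands a
disjoint exact cover for every h >= 3. Columns thinner than 3 px are
excluded with a warning.

**Column width.** The default is 4 px so that the default column grid
divides both default region widths (CI-A 12, CI-F 20): region boundaries
then align with column boundaries and no column straddles two regions.
Any width >= 1 is accepted; straddling columns are assigned by their
midpoint pixel.

**Aggregation pools pixels.** Region-level statistics pool member-column
pixels (sums of densities and counts) rather than averaging per-column
ratios; this matches region-level integrated-density measurement and is
robust to thickness variation. The two differ in general, which the test
suite asserts.

**AP classification.** The original regions were called by eye from CI
staining; the classifier makes that reproducible. Background is the
median of the posterior profile (CI is absent in P), the anterior maximum
is the 98th percentile, and the low/high thresholds sit at 20% and 60% of
that span, so classification is invariant to positive affine rescaling of
the CI channel. Walking anterior from the boundary: the dip (CI-A), a
hysteresis-held plateau (CI-F), then background (CI-R). Regions narrower
than 3 columns merge into their anterior neighbour; profiles with no
plateau fall back to configured fixed widths; a plateau abutting the
boundary yields a zero-width CI-A ("no-dip" mode, the expected pattern
when HH signalling is inactivated). The user-supplied boundary always
wins over the built-in estimator.

**Statistics.** The signed-rank and Mann-Whitney tests take an exact path
(full randomization distribution, computed by integer generating-function
convolution and cross-checked against literal enumeration in the tests)
up to n = 25 pairs and n1 + n2 = 14 untied observations respectively,
and a tie- and continuity-corrected normal approximation beyond. Zero
differences are dropped and logged, two-sided p-values double the smaller
tail (capped at 1), and no multiple-testing correction is applied —
matching the conventions of the original analysis. Cohort-level fold
changes and percent reductions use means of per-disc means, matching a
disc-level experimental design.

## What the recovery suite runs

`cmd_recover()` generates a 20-disc time-0 cohort and a 23-disc chase
cohort at the defaults, quantifies every disc end to end, and compares
recovered fractions (within ±0.03), the P/CI-R fold change (within ±5%),
and retention-derived percent reductions (within ±3 points) against
ground truth; a 3-level noise ladder (8 discs per level) checks that the
fraction error shrinks monotonically from heavy noise
(`poisson_scale = 0.05`, `read_noise_sd = 8`) through the default to
expectation mode. Problem sizes were chosen to mirror the original
cohorts (N = 20/23) while keeping the suite fast; the type-I calibration
of the three tests uses 10,000 null simulations at n = 10 (paired t),
n = 14 (signed-rank), and 8 + 8 (Mann-Whitney), sizes at which the
attainable exact significance level is close to the nominal 0.05 so that
discreteness does not mask miscalibration.

```{r, eval = FALSE}
rec <- cmd_recover(read_run_config(NULL, overrides = list(seed = 1L)))
head(rec$report)
```

## Known limitations

* Detection assumes a single connected tissue with background darker than
  every tissue band; it has no model of the peripodial layer.
* The column is the unit of quantification; there is no per-cell
  segmentation.
* The CI classifier assumes the canonical dip–plateau–background anterior
  profile; unusual CI patterns land in the fixed-width fallback, which is
  flagged in the region map's provenance column.
* Stack I/O uses 32-bit float TIFF with a YAML sidecar; round trips are
  lossless only at float32 precision.
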