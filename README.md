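# apbaquant

Quantification of cell-surface receptor distribution along the apico-basal
(Ap-Ba) axis of a columnar epithelium, for image-based studies of polarized
signalling — the motivating case being surface-labelled Smoothened (SMO) in
antero-posterior XZ confocal stacks of the *Drosophila* wing imaginal disc,
where Hedgehog (HH) dose shifts SMO toward the basal membrane.

## What it computes

From a multi-channel XZ stack (channel 1: surface-labelled receptor,
channel 2: a Cubitus interruptus-like regional marker) the pipeline:

1. builds the average-intensity projection of 8 consecutive sections;
2. detects the tissue footprint and its per-column apical/basal limits;
3. tiles fixed-width apical-to-basal columns outward from the A/P
   boundary;
4. splits each column of thickness *h* into apical/subapical, lateral,
   and basal bands of `round(0.15 h)`, remainder, and `round(0.10 h)`
   rows, and measures for each region of interest
   - integrated density `ID = Σ pixel values`,
   - mean intensity `ID / n_pixels`,
   - relative intensity `ID_band / ID_column`;
5. classifies AP positions into the four HH-gradient regions — CI-R,
   CI-F, CI-A (anterior) and P (posterior) — from the marker profile;
6. reports disc-level statistics: fold changes of mean intensity,
   pulse-chase percent reductions `100 (1 − mean_chase / mean_t0)`, and
   paired t, exact Wilcoxon signed-rank, and exact Mann-Whitney tests
   (full enumeration of the randomization distribution at small n).

A synthetic disc generator (`make_disc`, `make_pulse_chase`) renders
stacks with known regional levels, Ap-Ba fractions, and retention
factors plus machine-readable ground truth, so the entire pipeline is
testable by parameter recovery without any raw imaging data.

## Worked example

```r
library(apbaquant)
cfg <- disc_config()            # default synthetic study conditions
d   <- make_disc(cfg, seed = 1)
q   <- quantify_stack(d$stack)  # projection -> mask -> columns -> regions
r   <- q$records[!is.na(q$records$n_pixels), ]
r[r$region %in% c("CI-R", "P"), c("region", "subregion", "n_pixels",
                                  "mean_intensity", "relative_intensity")]
#>  region subregion n_pixels mean_intensity relative_intensity
#>    CI-R    apical      972           55.5               0.25
#>    CI-R   lateral     4860           28.9               0.65
#>    CI-R     basal      648           33.4               0.10
#>    CI-R    column     6480           33.3               1.00
#>       P    apical      540           56.5               0.15
#>       P   lateral     2700           45.3               0.60
#>       P     basal      360          141.6               0.25
#>       P    column     3600           56.6               1.00
```

Read: in the far-anterior CI-R region (no HH) only 10% of the column's
integrated receptor signal sits in the basal band, against 25% in the
posterior compartment (high HH) — the basal enrichment the pipeline is
built to detect. The whole-column mean intensity rises 1.7-fold from
CI-R (33.3) to P (56.6).

A thin CLI over the same functions ships in `inst/scripts/apbaquant`
(`simulate | quantify | compare | recover`, each with `--config`,
`--seed`, `--out`); run configurations are YAML (`read_run_config()`).

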