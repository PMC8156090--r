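# lesioncog

Lesion-network overlap mapping of cognitive deficits after glioma therapy.

Patients treated for WHO Grade III/IV glioma carry several kinds of brain
damage at once — the resection cavity, contrast-enhancing (T1-CE) tumor,
T2/FLAIR hyperintense tissue (edema, gliosis, radiation-induced
white-matter injury), and amino-acid-PET-positive recurrent tumor. This
package is for imaging/outcomes researchers who want to ask, at the level
of atlas-defined functional network nodes and white-matter tracts, *which*
of these lesion types, *where*, degrades *which* cognitive functions, and
whether the affection of a single representative region improves the
prediction of clinically relevant impairment.

## What it computes

Given co-registered binary lesion masks, label atlases (e.g. a
Schaefer-style functional parcellation and a JHU-style tract atlas on a
common grid) and a cohort table:

* **PET segmentation** by tumor-to-brain-ratio thresholding: voxel is
  tumor iff `I(v) / I_ref >= 1.6` (threshold and reference statistic
  configurable), with optional small-component removal.
* **Partial volumetric overlap**: per subject, lesion type and region,
  `overlap_ml = #{v : mask(v) = 1, label(v) = r} * |det A_3x3| / 1000` and
  `overlap_fraction = overlap_ml / region_volume_ml`.
* **Normative deficit thresholds** from matched healthy controls:
  `cutoff = mean ∓ 1.5 * sd` (mirrored for timed tests where higher is
  worse); group comparisons by two-sided Mann–Whitney U.
* **Mass-univariate screen**: Kendall
  `tau_b = (C − D) / sqrt((n0 − n1)(n0 − n2))` per (lesion type, region,
  test) cell, two-sided p from the tie-corrected, continuity-corrected
  normal approximation of `S = C − D`, Bonferroni control with an explicit
  family (per lesion type and atlas by default, global optional).
* **Deficit prediction**: logistic models of impairment on age, education
  and total lesion volumes, with and without one representative region's
  T2/FLAIR overlap fraction; sensitivity/specificity/PPV/NPV/accuracy at a
  0.5 cutoff, AUC via the Mann–Whitney identity `U / (n1 n0)`, and a
  two-sided p for AUC = 0.5.

Because the motivating clinical data cannot be redistributed, the package
includes a first-class synthetic-cohort generator (ellipsoidal
two-compartment brain, Voronoi parcellation into 2 × 50 nodes in 7
resting-state networks plus 2 × 24 tracts, contiguous sphere-union lesions
with lognormal T2/FLAIR volumes of median 53.4 mL, two-level-plus-noise
PET, linear-Gaussian cognition with planted lesion effects calibrated on
the tau-b scale, propensity-matched controls) so the entire pipeline runs
and is verifiable without patient data. See the methods vignette
(`vignettes/lesion-cognition-mapping.Rmd`) for the model and every
numerical choice.

## Worked example

```r
library(lesioncog)

cfg <- synthetic_config(n_patients = 60, n_controls = 60, seed = 7)
img <- simulate_imaging(cfg)                 # atlas, lesions, PET, overlaps
cfg <- plant_effect(cfg, img$overlaps,       # plant ground truth: one node
                    test_name = "wordlist_immediate",
                    tau_target = 0.5, atlas = img$atlas)
res <- run_pipeline(cfg, verbose = TRUE)

subset(as.data.frame(res$screen), significant,
       select = c(lesion_type, region_name, test_name, tau_b, p_bonferroni))
res$table2[, c("outcome", "model", "sensitivity", "specificity", "auc")]
res$recovery$recall
```

```
imaging: 148 regions, 60 patients, 27 PET-positive, median flair 44.2 mL
cohort: 60 patients, 60 matched controls (pool 240)
screen: 6512 cells, 4477 computable, 3 significant
  lesion_type region_name          test_name      tau_b p_bonferroni
1       flair    node_L47 wordlist_immediate -0.4797336  0.002027220
2       flair    node_L27 wordlist_immediate -0.4648514  0.004951400
3       flair    node_L07 wordlist_immediate -0.4635776  0.005421249
             outcome     model sensitivity specificity       auc
1 wordlist_immediate      base   0.5000000   0.9347826 0.7965839
2 wordlist_immediate augmented   0.7142857   0.9782609 0.9099379
[1] 1
```

Reading this: the screen flags only T2/FLAIR cells, all left-hemisphere
nodes neighbouring the planted one (their overlap fractions are strongly
collinear — the reason the prediction stage augments with a *single*
representative region), the planted (region, test) pair is recovered
(recall 1), and adding that region's overlap fraction raises the deficit
model's sensitivity from 0.50 to 0.71 and its AUC from 0.80 to 0.91 at
essentially unchanged specificity.

## The analysis workflow

The numbered scripts under `analysis/` run the full study-scale analysis
(121 patients, 121 matched controls) and write their tables under
`results/`:

```sh
Rscript analysis/01_simulate.R        # atlas, lesions, volumes, ground truth
Rscript analysis/02_segment_overlap.R # TBR segmentation + overlap table
Rscript analysis/03_assessment.R      # cohort, matching, thresholds, table 1
Rscript analysis/04_screen.R          # tau-b screen, heat-maps, recovery
Rscript analysis/05_predict.R         # collinearity + base/augmented models
```

Each stage is deterministic given `results/config.json` and narrates what
it found (e.g. T2/FLAIR median 51.2 mL against the 53.4 mL calibration
target; segmentation Dice 1.000; all Bonferroni-significant cells
T2/FLAIR-related and left-hemispheric; 6/6 significant-region overlap
pairs collinear at p < 0.001; augmentation raising sensitivity by 39
points).

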