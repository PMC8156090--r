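---
title: "Methods: lesion-network overlap mapping of cognitive deficits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: lesion-network overlap mapping of cognitive deficits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## Scope

After multimodality therapy for high-grade glioma, several kinds of brain
damage coexist: the resection cavity, contrast-enhancing (T1-CE) tumor
tissue, T2/FLAIR hyperintense tissue (edema, gliosis, radiation-induced
white-matter damage, non-enhancing tumor), and metabolically active tumor
visible on amino-acid PET. `lesioncog` quantifies how each of these lesion
types overlaps atlas-defined functional cortical nodes and white-matter
tracts, screens those overlaps against a battery of cognitive test scores,
and asks whether adding a single representative region's affection improves
the prediction of clinically relevant impairment over global covariates.

The package assumes all volumes are already co-registered to a common grid;
registration itself (rigid or elastic) is out of scope, and only
nearest-neighbour grid resampling is provided. Because the clinical data
that motivate this design are not publicly distributable, the package ships
a synthetic-cohort generator that emulates the statistical structure of
such a study, with known ground truth, so every stage is verifiable.

## The pipeline

1. **PET segmentation** (`segment_tbr`): tumor-to-brain-ratio thresholding.
   A voxel is tumor-positive when its intensity divided by a reference
   healthy-brain uptake is at least the threshold (default 1.6, the
   empirically tumor-predictive value for amino-acid PET). The comparison
   is inclusive (`>=`): the threshold is read as the lowest
   tumor-predictive ratio. The reference region is user-supplied (mean
   uptake by default; median available); anatomy is not hard-coded.
   Optional removal of small 26-connected components is off by default,
   since in practice segmentations are visually corrected instead.
2. **Overlap quantification** (`compute_overlap`): for every atlas region,
   the lesion-region overlap in mL (voxel count times `|det|` of the
   affine's spatial part / 1000) and as the fraction of the region
   affected. Both are kept; the screen and the models use the fraction by
   default because region-relative affection is what "partial volumetric
   affection of a node" means, while absolute mL is retained for
   sensitivity analyses. Nodes and tracts are treated as separate atlases
   (in real data the two source atlases overlap spatially).
3. **Cognitive assessment** (`deficit_threshold`, `compare_groups`):
   normative cutoffs from the healthy controls at mean − 1.5 SD; for
   timed tests (TMT-A/B), where higher is worse, the rule mirrors to
   mean + 1.5 SD. The boundary is strict: a score exactly at the cutoff is
   unimpaired. Group comparisons use the two-sided Mann–Whitney U test
   (exact enumeration when both groups have ≤ 8 observations, midranks and
   the tie-corrected normal approximation otherwise).
4. **Mass-univariate screen** (`correlation_screen`): Kendall tau-b between
   overlap and score for every (lesion type, region, test) cell, with
   Bonferroni control. Subjects with zero overlap are retained — they
   anchor the unaffected end of the ranking, consistent with unaffected
   patients scoring like controls.
5. **Deficit prediction** (`fit_deficit_model`, `compare_models`): logistic
   models of the deficit label on age, education and the four total lesion
   volumes, optionally augmented with one representative region's T2/FLAIR
   overlap fraction. Apparent (in-sample) classification performance is
   reported from the 2×2 table at a probability cutoff of 0.5, plus AUC
   via the Mann–Whitney identity and a p-value for AUC = 0.5. No
   cross-validation is attempted — the numbers are apparent performance,
   and are labelled as such.

## The tau-b statistic

For paired vectors with ties,

tau_b = (C − D) / sqrt((n0 − n1)(n0 − n2)),

with `n0 = n(n−1)/2` and tie terms `n1 = Σ t(t−1)/2`, `n2 = Σ u(u−1)/2`
over the tie groups of each variable. The two-sided p-value uses the normal
approximation of `S = C − D` with the standard three-term tie-corrected
variance and a continuity correction (S is discrete; without the
correction the approximation misses the exact permutation p by up to ~0.15
at n = 6–8, with it the gap stays below 0.02). Ties are the normal case
here: most lesion-region overlaps are exactly zero. Cells where one
variable is entirely tied (e.g. a region no lesion touches) are undefined
and reported as not computable rather than dropped silently. The kernel is
implemented in C++ (the screen evaluates ~6,000 cells per cohort and the
validation harness runs hundreds of cohort replicates) and is
cross-checked in the tests against an O(n²) pair-counting oracle and
against `stats::cor.test`.

### The Bonferroni family

"Corrected for the total number of tests" is ambiguous, so the family is
explicit and configurable. The default (`family = "per_atlas"`) corrects
each lesion type within each atlas separately — m = (regions of that kind)
× (number of test scores) — matching a per-heat-map reading. A single
global family over all cells (`family = "global"`) is available; it is
what the familywise-error validation uses, since it makes "any significant
cell anywhere" a nominal-level event.

## The synthetic generator

The generator's job is to emulate the *statistical structure* of a
lesion-cognition study — not anatomy. Its defaults are the study
conditions used throughout the validation.

**Geometry.** The brain is an ellipsoid (semi-axes 0.45 of the grid extent;
at the default 32³ grid of 5 mm voxels, ~1.5 L) split at the mid-sagittal
plane. A configurable normalised radius (0.7) separates a deep core
(white-matter compartment) from a cortical shell. Each hemisphere's shell
is partitioned into 50 functional nodes by nearest-seed Voronoi assignment
from random in-compartment seeds, the core likewise into 24 tracts; nodes
are assigned round-robin to the seven canonical resting-state networks.
Degenerate partitions (an empty region) trigger seed resampling up to a
retry cap. Voronoi ties are broken by first minimum, which cannot empty a
region because every seed is nearest to itself.

**Lesions.** A T2/FLAIR lesion is the union of random-radius spheres
(1–2.5 voxels) whose centers random-walk over the already-grown blob —
contiguous, irregular shapes that exercise the overlap code. Growth stops
when the voxel count reaches a target drawn from a lognormal with median
53.4 mL and log-SD 0.74 (chosen so median, mean and range match the
reported T2/FLAIR volume distribution of treated WHO III/IV cohorts);
targets exceeding the brain are truncated with a log message. Cavity and
T1-CE lesions are grown *inside* the T2/FLAIR mask (fractions ~U(0.15,
0.5) and U(0.05, 0.3) of its volume, present with probability 0.87 and
0.8), and the PET-positive tumor inside the T1-CE mask for the ~48% of
patients flagged recurrent — so the subset chain cavity ⊆ flair,
pet ⊆ t1ce ⊆ flair holds by construction and is asserted exhaustively in
the tests.

**Lesion topography clusters across patients.** The T2/FLAIR seed voxel is
drawn from a mixture: with weight 0.7 from a Gaussian predilection site
(SD 15 mm, centered left-anterior, mirroring the fronto-temporal
predominance of gliomas and the radiotherapy fields around them), else
uniformly in the brain. This matters: with purely uniform seeding every
region is affected in only ~10–20% of patients, and no region-level
association can reach a Bonferroni-corrected threshold at realistic effect
sizes — which would contradict the very association structure (dozens of
co-affected, mutually correlated regions; strong pairwise collinearity of
their overlaps) that the generator exists to emulate. The clustering
weight, spread and center are configuration fields.

**PET volumes.** Healthy brain 1.0, tumor voxels at the true
tumor-to-brain ratio (default 2.0), additive Gaussian noise (SD 0.1),
zero outside the brain. In the pipeline the *segmented* PET mask — TBR
thresholding at 1.6 against mean uptake of brain outside the T2/FLAIR
lesion — is what enters the overlap table, so segmentation is exercised
end to end and its Dice agreement with the generative truth is recorded.

**Cognition.** Scores follow a linear-Gaussian model per test k:

score_ik = mu_k + beta_age,k (age_i − 50) + beta_edu,k (edu_i − 7)
           ± Σ_r gamma_kr f_ir + eps_ik,   eps ~ N(0, sigma_k²),

where `f_ir` is patient i's T2/FLAIR overlap fraction with planted region
r. The lesion term is subtracted for higher-is-better tests and added for
timed tests, so positive gamma always worsens performance; controls get a
zero lesion term. Baselines and noise SDs are typical healthy-adult values
for this battery (e.g. TMT-A 30.9 (12.1) s; word-list immediate recall
14.1 (2.6) items). Age slopes are 0.04·sigma per year toward worse
performance (an age-score rank correlation around 0.4, the moderate
dependence such batteries show) and education slopes 0.10·sigma per
ISCED-like step toward better performance. The TMT-B/TMT-A ratio is
derived downstream, with nonpositive TMT-A values yielding missing ratios.
Note two deliberate simplifications: scores are continuous (real battery
scores are partly discrete), and the Gaussian tails allow occasional
nonpositive times.

**Planted effects** are calibrated, not guessed: given the fixed overlap
fractions of the planted region, `calibrate_planted_gamma` bisects over
quick Monte-Carlo estimates until the expected tau-b between fraction and
*raw score* equals the target, inflating the noise SD by the age and
education contributions so the calibration refers to the marginal
association the screen actually sees.

**Matching.** Controls are selected from an oversampled healthy pool
(4 × the control count by default) by a logistic propensity score on age,
gender and education, with greedy 1:1 nearest-neighbour matching on the
logit scale, without replacement, patients processed in decreasing
propensity order. Greedy (not optimal) assignment and no caliper: the
method name, not a specific variant, is what the design pins down.

## Validation design and what it shows

All generators are bit-reproducible given (config, seed); every stochastic
stage derives its own seed from the master seed and a stage label, so
stages are independently reproducible and replicate harnesses can resample
exactly the component they study.

The operating characteristics are validated by replicate simulation at the
study scale — 121 patients, 148 regions, ten tests, 200 cohort replicates
spread over 10 independent imaging sets (atlas + lesions fixed per set,
covariates and score noise fresh per replicate; the error rates under
study concern the score noise, and conditioning on imaging keeps the
harness inside its runtime budget):

* with no planted effects the familywise probability of any
  Bonferroni-significant cell in the global family stays at or below its
  nominal 5%;
* a single planted node effect sized for tau-b = 0.3 is scored for
  recovery (the planted cell Bonferroni-significant) and the recovery
  rate reported. This operating point is intrinsically hard: the normal
  approximation puts the detection z for tau = 0.3 at n = 121 near
  4.9 against a Bonferroni threshold near 4.1, so even with no ties the
  recovery probability sits in the low 0.8s, and zero-inflated overlap
  fractions (a region affected in only part of the cohort) reduce the
  information per unit tau-b further. Recovery therefore depends
  sensitively on how often the planted region is affected — the clustered
  seeding above is what makes region-level recovery possible at all;
* the same planted cohorts drive the model-augmentation check: adding the
  planted region's overlap fraction to the base logistic model should not
  reduce (and typically raises) in-sample sensitivity;
* the deficit rule at null reproduces the Φ(−1.5) ≈ 6.7% prevalence;
* kernel-level checks (overlap counting, TBR thresholding, tau-b, AUC)
  are exact against brute-force oracles.

Because the generator is a deliberately simple model — geometric brain,
linear-Gaussian scores, a single planted effect, no global patient
impairment beyond the lesion term, no registration error, no score
discreteness — passing these checks demonstrates algorithmic correctness
and calibrated error control *under the stated model*, not clinical
validity on real cohorts.

## Numerical choices and degenerate inputs

* TBR comparison inclusive; segmentation scale-invariant by construction.
* Deficit boundary strict ("below" the cutoff).
* Nearest-neighbour resampling for binary masks and labels (preserves
  binarity and label identity); voxel indices 0-based under the NIfTI
  affine convention.
* Sample SD everywhere with the n − 1 denominator; missing scores
  excluded pairwise per test.
* Logistic fits by IRLS (`stats::glm`); complete separation detected via
  the fitted-probability warning and exploding coefficients, flagged, and
  optionally refit with a ridge of 1e−6 on the slopes; rank-deficient
  designs fail naming the aliased column.
* Classification cutoff 0.5 on predicted probability (exposed); predictive
  values with empty denominators reported missing, not zero.
* Undefined statistics (all-tied tau, zero-variance Spearman, constant
  covariates) surface as not-computable rows, never silent zeros.

## Limitations

Real anatomy, registration, MR contrast, diffusion tractography and
test-administration details are out of scope. The screen reports marginal
associations; strongly collinear region overlaps (the rule, not the
exception, since one lesion covers many neighbouring regions) are exactly
why the prediction stage augments with a single representative region
rather than attempting multivariable region models. All model metrics are
apparent performance without a train/test split.
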