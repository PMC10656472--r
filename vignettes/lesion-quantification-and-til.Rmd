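---
title: "Regional lesion quantification and therapeutic-intensity prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional lesion quantification and therapeutic-intensity prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tbiquant)
```

This vignette is the package's own account of its methods: the models and
rules it implements, the synthetic data it runs on, the numerical choices
made where the design was genuinely open, and what the passing tests do and
do not establish about real data.

## Label schemes and quantification

Lesion label volumes are 3D integer grids under one of two schemes. The
7-class scheme distinguishes intraparenchymal hematoma (IPH), subdural
(SDH), epidural (EDH) and subarachnoid (SAH) hemorrhage, petechiae (Pe),
perilesional oedema (Od) and intraventricular hemorrhage (IVH). The 4-class
scheme collapses SDH/EDH/SAH into extra-axial hematoma (EAH) and petechiae
into IPH. Code 0 is background everywhere, and the integer conventions are
fixed (4-class: 1 IPH, 2 EAH, 3 Od, 4 IVH; 7-class: 1 IPH, 2 SDH, 3 EDH,
4 SAH, 5 Pe, 6 Od, 7 IVH) and carried in a JSON sidecar next to every NIfTI
file, so other tools' conventions can be mapped in without code changes.
A third, single-class "All" scheme represents lesional tissue of any type
and is the basis of the overall Dice.

Quantification ascribes every lesion voxel to one of 11 atlas regions (four
lobes, caudate, cerebellum, insula, putamen, thalamus, rest-of-brain —
mainly the ventricles — and the extra-cerebral space), giving a class ×
region volume table in mm³ (voxel count × voxel volume). Two choices here
were open:

* **The extra-cerebral space counts as one of the 11 regions.** The atlas
  covers the whole head, so the 4 × 11 and 7 × 11 tables have 44 and 77
  cells. Lesion voxels falling outside the head entirely (atlas code 0) are
  *not* one of those cells: they are reported in an "(unassigned)" spill
  column, excluded from the feature sets, and flagged with a warning when
  they exceed 1% of the lesion volume. Silently losing or silently counting
  them would both corrupt downstream features.
* **Registration is out of scope.** Segmentation and atlas must already
  share a grid; a mismatch is an error, never a silent resample. Alignment
  of real data belongs to dedicated registration tools upstream.

Feature vectors are named `"class:region"` in class-major order, fixed so
that feature importances and model inputs are stable across runs. The seven
experiment feature sets (clinical 5; clinical + Marshall + Rotterdam 7;
total volume 1; per type 4/7; per region 11; type ⧺ region 15/18; type ×
region 44/77) are marginals and flattenings of the same table, which gives
useful invariants: Exp4 and Exp5 both sum to Exp3, and quantifying a merged
volume equals merging a quantification.

## Clinical scores

The daily TILsum adds point weights over categories of ICP-directed therapy.
The exact published item weighting was not available to this package, so the
shipped table (`inst/extdata/til_items.yaml`) follows the published
summary-scale category structure — positioning, sedation up to barbiturate
coma, neuromuscular blockade, CSF drainage, CPP management, ventilation,
hyperosmolar therapy, temperature control, surgery — with maxima summing to
exactly 38, and the loader rejects any table whose maximum achievable daily
sum differs from 38. The table is versioned and swappable; the scorer itself
is correct by construction against whatever valid table is loaded. The
outcome rule is inclusive: a patient is `TILsum_High` when any of the first
8 daily values reaches 11 or more ("reaches 11" is implemented as ≥ 11).

Marshall classification follows the published mass-lesion precedence: any
surgically evacuated lesion is V and a non-evacuated high/mixed-density
lesion over 25 cm³ is VI, before the diffuse-injury grades II–IV are
considered (shift > 5 mm → IV; abnormal cisterns → III; visible pathology →
II; none → I). The Rotterdam score is the additive
1 + cisterns(0/1/2) + shift(0/1) + epidural-absent(0/1) + IVH/tSAH(0/1).
Both are exhaustively enumerated in the tests: every class is attainable,
ranges hold, and Rotterdam is monotone in each finding.

## Segmentation evaluation

Dice is `2|A∩B|/(|A|+|B|)` per class and on the merged "All" masks. When a
class is absent from both masks the score is undefined and reported as `NA`
with a `defined` flag — treating it as 1 would inflate, as 0 would deflate,
per-class means, and the count of exclusions is kept visible so aggregate
tables stay interpretable. Summaries report mean and standard error over
scans (averaging over scans, not pooling voxels, matches per-scan
barplot-with-error-bar reporting; pooling would weight large lesions more).
Variant comparisons use two-sided paired Wilcoxon signed-rank tests, exact
for ≤ 25 effective pairs without ties, tie-corrected normal approximation
otherwise, and explicitly "degenerate" when all differences are zero.

## The classifier and its evaluation

The classifier pipeline is median imputation → standardisation → random
minority oversampling → univariate feature selection → probability random
forest. Three choices deserve a note:

* **Oversampling lives inside training folds only.** Balancing before
  splitting would leak duplicated patients across the split — the classic
  error this structure is designed to exclude. A leakage assertion on
  patient ids runs on every outer fold.
* **The univariate filter ranks features by |per-feature AUC − 0.5|**, a
  rank-based two-sample separation measure equivalent to the Mann–Whitney
  statistic, keeping the filter consistent with the evaluation metric.
* **The ensemble is a random forest** because the reported importance
  measure, Mean Decrease Impurity, presupposes trees. The randomized search
  covers tree count (100–500), mtry fraction (0.1–0.9), minimum node size
  (1–10) and the number of selected features (2 up to all), with 8 draws
  per outer split by default. Importances are averaged over outer folds on
  the full feature space (unselected features get 0) and normalised to sum
  to 1.

Nested cross-validation uses stratified outer folds repeated with
reshuffling: 6 folds × 10 repeats = 60 outer AUC values by default, with 6
chosen as the largest stratifiable fold count for a cohort of a few dozen
patients. AUC is the rank-based (tie-aware) pair probability. Outer folds
whose test (or training) side contains a single class are skipped and
counted. Mann–Whitney comparisons between AUC distributions treat outer
folds as independent samples — a conventional but optimistic assumption,
documented rather than corrected. The BCa bootstrap interval (default 99%,
B = 2000) takes its bias correction from the bootstrap distribution's
position relative to the point estimate and its acceleration from jackknife
skewness; degenerate samples yield a point interval.

The final model after nested CV refits the modal hyperparameters on all
training patients; `apply_model()` then reports accuracy as the raw
fraction (e.g. 5/6) with sensitivity and specificity, refusing feature
tables whose columns do not match the training manifest.

## The synthetic data generator

The generator defines the study conditions under which the package's claims
are tested; it emulates structure, not radiology.

* **Atlas**: an ellipsoidal head with an extra-cerebral shell, a central
  ventricular compartment, and the remaining brain partitioned by Voronoi
  tessellation around anatomically placed, seed-jittered generator points.
  All 11 regions are guaranteed nonempty (grids of 32³ and up).
* **Lesions**: per class, presence is Bernoulli (defaults: IPH 0.6, SDH 0.5,
  EDH 0.15, SAH 0.5, Pe 0.3, Od 0.6, IVH 0.3), total volume is log-normal
  (medians 2000/1500/600/800/150/2500/400 mm³, log-sd 0.5–0.6), and
  placement weights favour the lobes for parenchymal classes, the convexity
  for extra-axial blood, and the ventricular compartment for IVH. These are
  order-of-magnitude choices scaled to the small synthetic head (the
  default 48³ brain holds ~28 000 voxels) — the per-class volume
  distributions of real cohorts are not published, so the defaults are
  deliberately configurable and fixed once here. Components are grown by
  seeded breadth-first region growing inside their target region: connected,
  approximately isotropic blobs that cannot cross region boundaries. This
  replaces a deformed-sphere construction: shape realism is a non-goal, and
  region confinement is a stated postcondition that growth-within-mask
  satisfies by construction. When a drawn volume exceeds the region's free
  capacity the region is redrawn (up to 5 tries) before the component is
  truncated with a warning.
* **Degrader**: the automatic-segmentation stand-in erodes the truth from
  the boundary inward, optionally drops whole components, adds a dilated
  false-positive shell (default 15% × (1 − target) of the lesion volume)
  and applies class confusion. Kept and false-positive counts are solved in
  closed form so the overall Dice lands on target, then a bounded bisection
  (≤ 20 steps) verifies to the contractual ± 0.05. Class confusion changes
  per-class Dice but provably not the "All" Dice.
* **Cohort**: clinical covariates are drawn in severe-TBI admission ranges
  (age 18–80, GCS 3–15, MAP ~N(88, 16), Hb ~N(125, 25), antiaggregants
  15%). The outcome is logistic in log1p lesion volumes;
  `P(High) = plogis(intercept + Σ coef · log1p(volume))`. TIL series are
  sampled consistently with the drawn outcome (High patients get 1–3 days
  at 11–28 within the window; Low patients are capped at 10). Midline shift
  and cistern status are *generated* attributes driven by total lesion
  volume — they are not derivable from label maps — whereas the epidural
  and IVH/tSAH flags are read off the segmentation. For recovery tests the
  planted condition uses intercept −3 with coefficient 2.0 on
  `SDH:Parietal Lobe`: the intercept keeps unaffected patients at ~5%
  baseline risk so the planted signal, present in roughly a sixth of
  patients, carries the outcome.
* **Split**: patient-level, stratified by outcome, largest-remainder
  allocation per stratum; 30 patients at 60/20/20 give exactly 18/6/6.

## Problem sizes and numerical notes

The shipped tests run at deliberate desk scale: 32³–48³ grids, cohorts of
10–500 patients (500 only for a prevalence check without volumes kept),
nested CV at full default structure (60 outer folds) on n = 200 for the
null-calibration and recovery checks, B = 1000–5000 bootstrap replicates,
and 500 simulations for BCa coverage. Exact rank-test paths are
cross-checked against exhaustive enumeration up to n = 8, the regime where
enumeration is instant.

Degenerate inputs are handled explicitly rather than coerced: both-empty
masks give undefined Dice; all-zero difference vectors give a degenerate
Wilcoxon; fully tied AUC samples give p = 1; constant bootstrap samples give
point intervals; single-class folds are skipped and counted; zero-variance
features standardise with scale 1.

## What passing tests do and do not show

The synthetic generator exercises every contract of the pipeline —
topology-aware quantification, merge/quantify commutativity, Dice
bookkeeping, score rules, leakage-free nested CV that is calibrated at the
null and recovers a strong planted regional effect. It does not emulate CT
intensities, hemorrhage physics, registration error, rater variability or
longitudinal lesion evolution; a pipeline that passes here can still be
limited on real data by exactly those factors, and results on real cohorts
must be established on real cohorts. The package's role is to make the
analysis machinery itself trustworthy and reusable.
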