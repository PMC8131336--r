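---
title: "Methods: CT liver fibrosis scores and their diagnostic evaluation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: CT liver fibrosis scores and their diagnostic evaluation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsvar)
```

## The scores

Chronic liver fibrosis remodels the organ and perturbs its perfusion, and
both effects are visible on a routine portal venous CT. The package
computes three per-patient scores from segmental volumetry and two small
attenuation ROIs:

* **LSVR**, the liver segmental volume ratio
  $\mathrm{LSVR} = V_{I\text{--}III} / V_{IV\text{--}VIII}$, the volume of
  Couinaud segments I–III over segments IV–VIII. Left-lobe/caudate
  hypertrophy with right-lobe atrophy drives it up; values around 0.27 are
  typical of non-fibrotic livers, cirrhotic livers reach 0.5 and beyond.
* **LVCA**, the liver vein to cava attenuation score, ordinal on
  $\{1,2,3,4\}$. The mean density of up to three hepatic veins (measured
  1 cm proximal to the confluence) is compared with the IVC density (1 cm
  below the confluence). With difference $d$ and tolerance $t$ (default
  $t = 20$ HU): $|d| \le t$ is isoattenuating (2), $d > t$
  hyperattenuating (1), $d < -t$ hypoattenuating (3). Veins with no
  visible contrast at all are category 4, a visual call supplied to the
  classifier as a boolean flag.
* **LSVAR** $= \mathrm{LSVR} \times \mathrm{LVCA}$, the composite. Since
  LVCA $\in \{1,\dots,4\}$, LSVAR always lies in
  $[\mathrm{LSVR},\, 4\,\mathrm{LSVR}]$.

Three choices here were genuinely open and are fixed as follows.
The tolerance boundary is **inclusive**: $|d|$ exactly 20 HU counts as
isoattenuating, reading "within ± 20 HU" in its plain sense. Category 4 is
driven by an explicit `veins_contrasted` flag rather than an HU heuristic,
because "not contrasted at all" is a visual judgement with no published
numeric threshold; the synthetic generators set the flag deliberately.
When fewer than three hepatic veins are measurable (anatomy varies), the
mean is taken over the available veins and a warning is logged, rather
than excluding the patient. Scores are held at full floating precision
throughout; the two-decimal ratios and integer percentages seen in
reports are applied only at the reporting layer.

## Phantom volumetry

A `labeled_volume` pairs an HU grid with an integer label map (codes:
1–8 Couinaud segments I–VIII, 10 spleen, 20 hepatic veins, 21 IVC, 0
background) and per-axis voxel spacing in mm. Volumetry is voxel counting
(`region_volume_ml()` = count × voxel volume / 1000) and ROI attenuation
is the mean HU over the labeled voxels — the phantom analogue of the
semi-automated segmental volumetry and hand-drawn vein/IVC ROIs of a
reading workstation. Real segmentation is out of scope; the label map is
an input.

`generate_phantom()` places one ellipsoidal blob per region in its own
cell of a 3×2×2 grid partition. The blob with target volume $V$ gets
semi-axes $r \cdot (1/1.08, 1.08, 1)$ with $r = (3V/4\pi)^{1/3}$, and is
voxelized by selecting **exactly** $\mathrm{round}(V/v_{\mathrm{voxel}})$
voxels in increasing ellipsoidal-norm order (stable tie-break by linear
index). This keeps every region connected and non-overlapping and makes
the voxel-count volume exact to one voxel, so the round trip
phantom → measurement → scores reproduces the implied LSVR to well within
1%. Targets whose ellipsoid would overrun the cell raise a capacity error.
HU values are the spec levels plus seeded zero-mean Gaussian noise
(default σ = 3 HU, far below the 20 HU tolerance), clipped to the valid
HU range [−1024, 3071]; with `noise_sd = 0` the ROI means equal the spec
levels exactly. Phantoms serialize as paired gzipped NIfTI volumes with a
JSON sidecar carrying the code table; the reader validates that the pair
agrees in shape and spacing.

Two simplifications to keep in mind: the phantom has no confluence
geometry, so the vein ROI is the whole labeled vein region (one pooled
value rather than three veins), and no attempt is made at realistic
anatomy, contrast kinetics, or texture.

## The synthetic cohort

`cohort_config()` defaults encode the study conditions the package
targets: 141 patients stratified over six stiffness bands
(< 2.5 / 2.5–2.9 / 2.9–3.5 / 3.5–4 / 4–5 / ≥ 5 kPa) with counts
90/20/12/5/4/10, which the 3.5 kPa threshold splits 122 vs 19. Stiffness
is uniform within each closed band; the open top band uses
$5 + \mathrm{Exp}(\text{mean } 1.2)$ kPa capped at 8 kPa, a realistic
right tail for an MRE population. Group membership is never stored — it
is always re-derived from stiffness, so the threshold is an analysis
parameter, not a generator parameter.

Volumes are **log-normal** around the group medians (negative group
333/1237/229 ml for segments I–III, IV–VIII and spleen; positive group
449/1160/442 ml): log-normality is the natural choice for strictly
positive, right-skewed anatomical volumes. The log-scale spreads are
derived once from the reference interquartile ranges via
$\sigma_{\log} = \log(q_{75}/q_{25}) / (2 \times 0.6745)$, giving
0.31/0.20/0.42 (negative) and 0.43/0.33/0.52 (positive), so generated
IQRs bracket the reference IQRs by construction.

The LVCA is **not sampled directly**. A per-group category distribution —
(0.60, 0.25, 0.10, 0.05) below threshold, (0.05, 0.10, 0.25, 0.60) at or
above — chosen so the induced ordinal medians and IQRs match the
reference (1 [1–2] vs 4 [3–4]), drives latent vein/IVC attenuations: IVC
$\sim \mathcal{N}(110, 10)$ HU, a vein–IVC difference drawn uniformly
from the band that realises the category (±15 HU iso, +25..+60 hyper,
−60..−25 hypo), plus 3 HU per-vein jitter; category 4 sets the
uncontrasted flag and records no vein HU. Downstream scoring therefore
exercises `classify_lvca()` itself.

Stiffness–score dependence is induced only through group membership —
there is no within-group correlation between stiffness and volumes or
attenuation. That is the weakest structure consistent with the per-group
summary statistics being emulated; real cohorts likely carry gradual
within-group trends, so passing tests show the pipeline recovers
group-level structure, not that the generator is a realistic patient
model. Covariates (age, sex, liver enzymes, APRI, BMI), when enabled, are
group-shifted pass-through fields for the generic comparison tests and
carry no acceptance role. One unit oddity in the reference material —
shear modulus printed on an apparent kPa × 100 scale in its
characteristics table — is noted and left alone; the generator works in
kPa throughout.

## Diagnostic evaluation

`empirical_roc()` uses the unique observed scores plus a sentinel above
the maximum as thresholds, with positivity `score >= cutoff` (cutoffs are
reported as "this value or higher"). The AUC is computed **twice** — by
trapezoidal integration in count space and as the Mann–Whitney pair
statistic with ties counted ½ — and the run aborts if the two disagree
beyond 1e-12; this dual route guards the implementation against the
classic off-by-one-threshold and tie-handling mistakes. The Youden cutoff
maximises $J = \text{sens} + \text{spec} - 1$; ties (including
float-level ties between mathematically equal $J$) resolve to the
smallest threshold, favouring sensitivity, which matches the screening
intent of a fibrosis marker.

The 95% CI uses the DeLong placement-variance estimator by default
(deterministic, the de-facto standard), normal-theory interval clipped to
[0, 1]; a seedable stratified percentile bootstrap (2000 replicates) is
available behind `ci_method = "bootstrap"` since the CI method of the
reference analysis is not stated.

`mann_whitney_u()` and `fisher_exact()` delegate to `stats::wilcox.test`
and `stats::fisher.test`, with the branch policy made explicit: exact
Mann–Whitney enumeration when the pooled sample is ≤ 12 without ties,
otherwise the normal approximation with tie and continuity corrections;
Fisher's two-sided p is the probability-mass convention (sum of
hypergeometric probabilities ≤ the observed table's), with zero-margin
tables returning p = 1. Interrater reliability is **ICC(1)**, the one-way
random-effects coefficient
$(\mathrm{MSB} - \mathrm{MSW}) / (\mathrm{MSB} + (k-1)\mathrm{MSW})$; the
label "one-way consistency ICC" found in the field is internally
contradictory (a one-way model has no separate consistency form), and
ICC(1) is the coherent reading. Bands follow the conventional
0.4/0.6/0.75 cuts (fair/good/excellent).

`run_study()` assembles the blocks. Patients missing a splenic volume are
excluded from the splenic-volume evaluation only, never from the score
evaluations. Reports retain full precision in JSON and print ratios to 2
decimals and percentages rounded half-up to integers; every printed
percentage is recomputable from its printed confusion counts. The
provenance block echoes the full configuration, the seed and the applied
defaults (tolerance, positivity rule, tie rule, CI method), so a report
is reproducible from its own metadata; the timestamp is the only
non-deterministic field.

## Problem sizes and numerical notes

The package's own test simulations use sizes chosen to make the
statistical checks sharp without being wasteful: 200 simulated
141-patient cohorts for the stochastic ordering check of AUC(LSVAR) vs
AUC(LSVR), 100 random tied instances with up to 50 observations for the
brute-force AUC/Youden oracle comparisons, 20 phantoms spanning LSVR
0.15–0.60 on 96×64×64 grids at 2 mm spacing for the round-trip check, and
full hypergeometric enumeration of every 2×2 table up to N = 12 for
Fisher. Degenerate inputs are typed errors, not NaNs: one-class ROC
input, empty ROIs, zero-variance ratings, non-positive volumes and
oversized phantom targets all raise classed conditions
(`lsvar_degenerate_roc`, `lsvar_empty_roi`, `lsvar_undefined_icc`,
`lsvar_invalid_volume`, `lsvar_capacity_error`, ...).

## Known limitations

* The generator emulates summary statistics, not joint distributions;
  correlations between volumes, attenuation and stiffness within groups
  are absent by design.
* The phantom is geometric, not anatomical: no segmentation algorithm can
  be validated against it, only the measurement arithmetic downstream of
  segmentation.
* LVCA category 4 depends on a supplied flag; the package deliberately
  offers no HU heuristic for "not contrasted at all".
* No multi-reader ROC, partial AUC, or correlated-AUC comparison tests;
  AUCs of different scores are compared descriptively, not inferentially.
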