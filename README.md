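# lsvar

CT-derived liver fibrosis scoring and diagnostic evaluation in R.

Clinically significant liver fibrosis (MR-elastography stiffness ≥ 3.5 kPa,
roughly histologic stage ≥ F2) leaves two footprints on a routine portal
venous abdominal CT scan: the liver remodels (the left and caudate lobes,
Couinaud segments I–III, hypertrophy while the right lobe, segments
IV–VIII, atrophies) and hepatic venous enhancement lags behind systemic
enhancement. `lsvar` implements the two scores that quantify these
footprints and their composite:

- **LSVR** (liver segmental volume ratio):
  `LSVR = V(I–III) / V(IV–VIII)`, rising with cirrhotic remodeling;
- **LVCA** (liver vein to cava attenuation): an ordinal score 1–4 comparing
  hepatic-vein density to IVC density — 1 hyperattenuating, 2
  isoattenuating (mean vein HU within ± 20 HU of the IVC), 3
  hypoattenuating, 4 veins not contrasted at all;
- **LSVAR** = `LSVR × LVCA`, the composite fibrosis marker.

Around the scores the package provides the full evaluation chain a
diagnostic-accuracy study needs: empirical ROC curves with AUC computed two
ways (trapezoidal and Mann–Whitney pair counting, asserted to agree),
DeLong or bootstrap 95% confidence intervals, Youden-index cutoffs,
confusion matrices with sensitivity/specificity, Mann–Whitney U and
Fisher's exact group comparisons, and one-way intraclass correlation for
interrater reliability. Because no patient data ship with the package, a
seeded synthetic cohort generator and a labeled CT-phantom generator
reproduce the structure of a 141-patient study population so every stage —
voxel volumetry, ROI attenuation, scoring, evaluation — is testable end to
end.

## Worked example

Score a single patient — a cirrhotic liver with marked left-lobe
hypertrophy (400 ml vs 2000 ml) and veins with no visible contrast:

```r
library(lsvar)
panel <- score_patient(list(
  id = "example-cirrhotic", vol_I_III_ml = 400, vol_IV_VIII_ml = 2000,
  ivc_hu = 115, veins_contrasted = FALSE, splenic_volume_ml = 520))
print(panel)
#> LVCA 4 | LSVR 0.20 | LSVAR 0.80 | splenic volume 520 ml
```

The volume ratio alone (0.20) sits in the normal range; the uncontrasted
veins (LVCA 4) quadruple it into an LSVAR of 0.80, above the 0.67 decision
cutoff.

Run a whole synthetic study — 141 patients, 122 below and 19 at or above
the 3.5 kPa stiffness threshold — and compare the discrimination of the
composite against the plain volume ratio:

```r
cohort <- generate_cohort(cohort_config(seed = 1))
report <- run_study(cohort, seed = 1)
d <- report$diagnostic$lsvar
cat(sprintf("LSVAR: AUC %.2f (95%% CI %.2f-%.2f), Youden cutoff %.2f\n",
    d$auc, d$auc_ci95[1], d$auc_ci95[2], d$youden_cutoff))
#> LSVAR: AUC 0.89 (95% CI 0.81-0.97), Youden cutoff 0.60
d2 <- report$diagnostic$lsvr
cat(sprintf("LSVR:  AUC %.2f (95%% CI %.2f-%.2f), Youden cutoff %.2f\n",
    d2$auc, d2$auc_ci95[1], d2$auc_ci95[2], d2$youden_cutoff))
#> LSVR:  AUC 0.66 (95% CI 0.50-0.82), Youden cutoff 0.50
```

The attenuation term carries most of the discrimination: adding the LVCA
lifts the AUC of the volume ratio by ~0.2 on this cohort. `print(report)`
renders the descriptive (median [IQR] + Mann–Whitney p) and diagnostic
(AUC/CI, cutoffs, confusion counts, integer percentages) tables;
`write_report(report, dir)` serialises them as JSON, text and per-score
ROC-coordinate CSVs.

Phantoms make the measurement chain itself testable:

```r
spec <- phantom_spec(vol_I_III_ml = 333, vol_IV_VIII_ml = 1237,
                     splenic_volume_ml = 229, seed = 11)
m <- measure_patient(generate_phantom(spec))
m$volumes$vol_I_III_ml       # 333 ml to within one voxel
```

A thin command-line front end over the same functions lives at
`inst/cli/lsvar.R` (subcommands `simulate`, `score`, `evaluate`, `report`,
`all`; exit codes 0/2/3 for success / schema error / degenerate study).

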