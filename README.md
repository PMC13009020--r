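# bpequant

Automated quantification of background parenchymal enhancement (BPE) from
breast DCE-MRI, and its use as an imaging biomarker.

BPE — the contrast uptake of normal fibroglandular tissue (FGT) on dynamic
contrast-enhanced MRI — is graded visually by radiologists on the four-level
BI-RADS scale (minimal / mild / moderate / marked), with known interobserver
variability. This package implements an objective alternative for
researchers working with breast DCE-MRI and associated clinical outcomes:
it computes a volume-based quantitative BPE from co-registered phase volumes
and tissue masks, calibrates the enhancement threshold against radiologist
grades, tracks BPE change across neoadjuvant chemotherapy (NAC), and relates
quantitative BPE to overall survival (OS), recurrence-free survival (RFS)
and pathological complete response (pCR).

## The statistic

With `S_0j` the pre-contrast and `S_ij` the i-th post-contrast signal of
voxel `j`, the relative enhancement is

    E_ij = (S_ij − S_0j) / S_0j × 100%

and the volume-based BPE at enhancement threshold `k` is the enhancing-FGT
volume fraction of the analysis-side breast:

    BPE_ik = |{ j ∈ FGT : E_ij ≥ k% }| · V_voxel / V_breast

Tumor voxels are removed from the FGT mask first, and BPE is measured on the
contralateral breast (the side with no — or the smaller — tumor). The
threshold `k` is calibrated by maximizing the Spearman correlation between
`BPE_ik` and the ordinal radiologist grade over a threshold grid, with
grade-separation ROC AUCs (grade 1 vs 2–4, 1–2 vs 3–4, 1–3 vs 4) reported
alongside. Monotone cutpoints on the calibrated BPE (Youden-optimal, with
isotonic repair for the four-level model) map the continuous measurement
back to grades; the dichotomized grade (3/4 vs 1/2) enters proportional-
hazards models for OS/RFS, and a drop in quantitative grade after NAC enters
logistic models for pCR.

Because patient imaging of this kind is access-restricted, the package ships
a synthetic module: a 3-D two-breast phantom with exact ground-truth masks
and designed BPE, and a cohort simulator whose grades derive from BPE at a
known generative threshold and whose outcomes carry stated effect sizes.
All tests run against these generators.

## Worked example

```r
library(bpequant)

## a digital phantom: 50% of breast voxels are FGT, 40% of FGT enhances at
## 80%, with a 150%-enhancing tumor in the right breast and mild noise
spec <- phantom_spec(fgt_fraction = 0.5, enhancing_fraction = 0.4,
                     enhancement_amplitude = 80, noise_sd = 4, seed = 42,
                     tumor_spec = list(side = "right", center = c(24, 12, 8),
                                       radius = 2.5, amplitude = 150))
ph    <- generate_phantom(spec)
masks <- refine_fgt(ph$masks)                      # subtract tumor from FGT
lat   <- select_analysis_side(split_laterality(masks), mode = "contralateral")
lat$analysis_side
#> [1] "left"

enh <- enhancement_map(ph$study, phase_index = 1)  # peak contrast
sm  <- analysis_side_mask(lat)
bpe_volume(enh, masks$refined_fgt * sm, masks$breast * sm, threshold_k = 55)
#> <bpe_measurement> volume BPE = 0.2000 (phase 1, k = 55%)
```

The tumor is on the right, so the left breast is analysed, and the measured
BPE equals the designed `0.4 × 0.5 = 0.20` enhancing-volume fraction.

```r
## threshold calibration on a simulated 300-patient cohort whose grades
## were generated from BPE at a 55% threshold
co <- generate_cohort(cohort_spec(n = 300, k_star = 55, seed = 1))
optimize_threshold(cohort_sweep_table(co),
                   co[, c("patient_id", "radiologist_grade")])
#> <threshold_curve> 41 thresholds; optimal k = 55% (rho = 0.899)
#>   AUC at optimum: 1 vs 2-4 = 0.973, 1-2 vs 3-4 = 0.985, 1-3 vs 4 = 0.983

## survival: hazard ratio of high (grade 3/4) vs low quantitative BPE
fit_cox(co, "OS", "bpe_high")
#> <effect_estimate> HR[bpe_high] = 0.75 [0.49, 1.14], p = 0.175 (n = 300)
```

The calibration recovers the generative threshold exactly, and the Cox model
returns the protective direction simulated for high BPE (at n = 300 the
interval is wide; the recovery tests use larger cohorts).

`run_pipeline()` (or `inst/cli/bpe.R`) chains the stages —
simulate → quantify → calibrate → grade → outcomes — writing every
intermediate table plus a resolved-config record to an output directory.

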