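---
title: "Quantitative BPE from DCE-MRI: model, calibration and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantitative BPE from DCE-MRI: model, calibration and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bpequant)
```

## The measurement model

Background parenchymal enhancement (BPE) is the contrast uptake of normal
fibroglandular tissue (FGT) on dynamic contrast-enhanced breast MRI. A DCE
study here is an ordered list of co-registered 3-D volumes — one
pre-contrast phase followed by post-contrast phases — plus voxel spacing.
For post-contrast phase $i$ and voxel $j$, the relative enhancement is

$$E_{ij} = \frac{S_{ij} - S_{0j}}{S_{0j}} \times 100\%,$$

and the volume-based BPE at enhancement threshold $k$ is the enhancing
fraction of the analysis-side breast volume,

$$\mathrm{BPE}_{ik} = \frac{1}{V_\mathrm{breast}}
  \sum_{j \in \mathrm{FGT}} V_\mathrm{voxel}\,
  \mathbf{1}\!\left[E_{ij} \ge k\right].$$

Assumptions worth making explicit:

* **Ratio image.** $E_{ij}$ is a ratio, so BPE is invariant to any global
  intensity scaling of the acquisition — a property the test suite checks
  to floating-point tolerance. It is *not* invariant to spatially varying
  intensity fields; bias-field correction is out of scope and masks are
  assumed to come from an upstream segmentation.
* **Undefined voxels.** The ratio is undefined when $S_{0j} = 0$. Voxels
  whose pre-contrast signal is at or below a configurable positivity floor
  (default $10^{-6}$ signal units — effectively "exactly zero" for typical
  magnitudes, adjustable for data with an additive offset) are excluded
  from the enhancing-voxel count but kept in $V_\mathrm{breast}$, so the
  printed normalizer is preserved.
* **Closed threshold.** The comparison is $E_{ij} \ge k$; a voxel exactly
  at the threshold enhances. Negative enhancement is allowed — such voxels
  simply never pass a positive threshold.
* **Single-side normalization.** $V_\mathrm{breast}$ is the breast volume
  of the analysis side only. The equation's scope is ambiguous in the
  abstract, but BPE is measured per breast (the contralateral one), so the
  single-side convention is adopted and stated on every measurement record.

## Laterality and tumor exclusion

Breast voxels are assigned to a side by comparing their coordinate along a
configurable laterality axis (default: first array axis) with the midpoint
of the breast mask's bounding box; midpoint voxels go to the lower-index
side. A bounding-box rule was chosen over connected components because FGT
can bridge the midline and components are then unstable; the rule is
deterministic and cheap. No reorientation to anatomical axes is attempted —
"left" and "right" are array-order labels, and phantoms define their own
convention.

The analysis side is the contralateral breast: the side with zero tumor
voxels, or with the smaller tumor volume in bilateral disease (exact ties
go to the lower-index side with a warning). Studies without a tumor mask
are treated as tumor-free and the larger-FGT side is used, which permits
healthy-control phantoms. An ipsilateral mode returns the complementary
side for sub-analyses.

Tumor voxels are subtracted from the FGT mask before any statistic is
computed. The subtraction margin defaults to 0 mm (strict voxel-wise
removal, since only tumor voxels themselves are known to confound); a
positive margin dilates the tumor with spacing-aware Euclidean offsets
first.

## Threshold calibration and grade models

The enhancement threshold is the main tunable parameter (percent units,
default grid 0–200% in steps of 5, bracketing the clinically useful 20–80%
band). For each grid value the per-patient BPE is correlated with the
ordinal radiologist grade by Spearman rank correlation (average ranks for
ties); the optimal threshold maximizes the correlation, with ties broken to
the smallest threshold and the full curve reported so the flatness of the
optimum is visible. Grade-separation AUCs (1 vs 2–4, 1–2 vs 3–4, 1–3 vs 4)
are computed as rank-sum (Mann–Whitney) concordance with ties counted one
half — equivalent to the AUC of a single-covariate logistic model, since
AUC is invariant to monotone transforms of the score, and well defined even
under complete separation.

Grade cutpoints on the calibrated BPE use Youden's $J$ on the empirical ROC
rather than a logistic probability crossing: for a single covariate both
derive from the same ordering, and $J$ remains defined where a logistic fit
diverges under separation. Candidate cutpoints are midpoints between
consecutive distinct observed values; ties in $J$ break to the smallest
cutpoint. The four-level model stacks the Youden cutpoints of the three
cumulative dichotomies (grade $\ge 2$, $\ge 3$, $= 4$) and applies an
isotonic repair (logged) if the raw cutpoints are not increasing, since the
cumulative fits are independent and can cross in small samples. Grade
assignment is closed on the right: a BPE value exactly at a cutpoint takes
the higher grade. Longitudinal change is summarized as the sign of the
grade difference (drop / stable / increase), and pre- vs post-treatment BPE
is compared by a paired $t$ test on differences, optionally stratified by
baseline grade; all-zero differences return $t = 0$, $p = 1$, while
constant nonzero differences are signalled as degenerate.

## Outcome models

Survival models are Cox proportional-hazards fits (via the survival
package) with Efron tie handling — the lower-bias default when event times
are recorded coarsely. pCR models are maximum-likelihood logistic fits.
Hazard and odds ratios are reported with Wald 95% intervals computed on the
log scale and exponentiated, matching the bracketed-interval convention of
clinical tables; the test suite checks the interval transformation exactly
and cross-checks both fitters against independently maximized, hand-written
likelihoods.

Candidate covariates pass a univariate screen (one-covariate fit, Wald
$p < 0.05$) before entering a multivariate model; the primary BPE predictor
is exempt and always retained, because the biomarker term should be
reported even when nonsignificant. Stratified analyses refit within each
stratum, drop the stratifying covariate from that stratum's model, and
re-run the univariate screen per stratum (the screening log records the
decisions); strata too small to fit are marked not-estimable rather than
failing the analysis. "Unknown" menopausal status is kept as its own
category in summaries and excluded from menopause-stratified models. The
molecular subtype is derived from HR/HER2 fields, and a conflicting
pre-existing subtype column is a validation error, never silently
overwritten.

## The synthetic generators

**Phantom.** Two disjoint ellipsoids along the laterality axis form the
breasts; a seeded uniform sample of breast voxels (without replacement, so
the FGT fraction is exact by construction) forms FGT, and a seeded
subsample of FGT enhances by a designed amplitude, scaled per phase by a
kinetics vector (default `c(1, 0.9, 0.75)`: peak at the first post-contrast
phase, washout later). Noise is additive Gaussian on signal intensities,
applied before the ratio, as the simplest defensible acquisition-noise
model. Because fractions of an arbitrary ellipsoid voxel count are rarely
integers, the generator by default trims each side's breast mask — dropping
the voxels farthest from the ellipsoid centre, deterministically — to the
largest count for which both the FGT and enhancing-voxel counts are exact
integers; the designed BPE $f \cdot r$ (enhancing fraction times FGT
fraction) is then attained *exactly* at any threshold below the amplitude,
which the tests assert with `identical()`. With noise, voxels near the
threshold flip and recovery is asserted within three binomial standard
deviations. An optional ellipsoidal tumor (with its own, higher amplitude)
exercises contralateral selection and FGT refinement.

What the phantom does **not** emulate: coil inhomogeneity, motion, fat
suppression, spatially clustered FGT texture (a uniform sample has no
spatial correlation), or scanner-specific kinetics. Passing tests therefore
demonstrate correctness of the arithmetic and the mask logic, not
robustness to real acquisition artifacts.

**Cohort.** Each simulated patient carries a latent enhancement model: an
FGT volume fraction $r \sim \mathrm{Beta}(2, 8)$ (right-skewed, mean 0.2 —
typical of volumetric FGT fractions), and a Gaussian amplitude distribution
with mean $\mu \sim N(60, 25)$ percent and spread
$\sigma \sim U(15, 40)$, so the BPE-vs-threshold curve is
$\mathrm{bpe}(k) = r\,\Phi((\mu - k)/\sigma)$. The spread across patients
in both $r$ and $\mu$ is what makes the generative threshold identifiable:
at low thresholds patient ranking is dominated by $r$, at high thresholds
by $\mu$, so the correlation with grades peaks at the threshold that
generated them. Grades bin $\mathrm{bpe}(k^\*)$ at prevalence-based
cutpoints defaulting to the 471/299/205/99 per-grade split of a
1074-patient reference cohort, then flip to an adjacent grade with
probability 0.1 (a round figure for the reported interobserver variability
of visual BPE grading). Ages trend younger with higher grade; menopausal
status is logistic in age; race/ethnicity and molecular subtype follow the
reference cohort's marginal proportions.

Outcomes: survival times are exponential with a proportional-hazards
log-HR on the dichotomized (grade 3/4 vs 1/2) indicator — defaults
$\log 0.58$ for OS and $\log 0.85$ for RFS, the effect sizes the models are
meant to detect — censored administratively at the time solving for the
target event rate (0.35 OS, 0.45 RFS). Post-NAC BPE is a multiplicative
shrink, stronger for higher baseline grades (mean factor 0.9 down to 0.6
across grades 1–4), and pCR is Bernoulli with a logistic model on the
resulting grade drop (default log-OR $\log 6$, matching the magnitude of
the association the pCR models target, on a 20% base rate). Because
survival depends on the grade indicator only through the modelled term,
unadjusted fits are unbiased for the generative effect — which is what the
recovery tests exploit.

## Numerical choices and degenerate inputs

* Grid equality: shapes must match exactly; spacing within $10^{-3}$ mm
  (header rounding across NIfTI writers).
* Masks with values other than 0/1 are coerced to binary with a warning;
  FGT leaking outside the breast is clipped with a message and count.
* An empty refined-FGT mask yields BPE 0 with a warning; an empty breast
  mask is an error (the normalizer vanishes).
* Spearman correlation of a constant vector, an all-censored Cox fit, a
  single-level predictor, and a missing grade class are all signalled as
  errors rather than returning a number.
* Logistic coefficients above 15 in absolute value trigger a
  quasi-separation warning.

## Problem sizes

The test suite and the acceptance script run entirely on generated data at
sizes chosen to make the Monte-Carlo assertions sharp while keeping the
default run lightweight: 100 random volumes up to $8^3$ for the brute-force
BPE oracle; 200 random instances at $n \le 12$ for the AUC oracle; 20 seeds
per generative threshold at $n = 300$ for threshold recovery; 200 seeds at
$n = 900$ (35% event rate) for hazard-ratio recovery and interval coverage;
100 seeds at $n = 60$ per stratum for odds-ratio recovery; 500 draws at
$n = 1000$ for screening calibration; and $n = 10^4$ for the generator
self-consistency checks.

## Known limitations

Masks are inputs: no segmentation, registration across timepoints, DICOM
assembly or bias-field correction is provided. The intensity-based BPE
variant shipped here is the mean relative enhancement over valid FGT voxels
— a thresholdless summary provided for comparison and clearly labelled
non-canonical, as intensity-based definitions vary across the literature.
Pharmacokinetic modelling and kinetic-curve typing are out of scope. The
cohort simulator reproduces the statistical structure the analysis assumes
(monotone grade–BPE link, proportional hazards, logistic pCR); it cannot
certify the method against violations of those assumptions in real data.
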