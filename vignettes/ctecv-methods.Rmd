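---
title: "Quantifying myocardial extracellular volume from cardiac CT: methods and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying myocardial extracellular volume from cardiac CT: methods and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctecv)
```

## The measurement

Diffuse interstitial myocardial fibrosis expands the extracellular space.
With an extracellular iodinated contrast agent at equilibrium, the
attenuation change between a pre-contrast and a delayed-phase cardiac CT is
proportional to the contrast concentration, so the myocardial extracellular
volume fraction follows from the ratio of tissue to blood enhancement,
rescaled from plasma to whole blood by the hematocrit:

$$\mathrm{ECV} = \frac{\Delta HU_m}{\Delta HU_b}\,(1 - \mathrm{Hct})$$

where $\Delta HU_m$ is the segment-mean myocardial enhancement on the
subtraction image, $\Delta HU_b$ the blood-pool enhancement in a cavity
region of interest, and Hct the hematocrit fraction. Normal myocardium sits
near 0.25–0.28; diffuse fibrosis (as in long-term hemodialysis patients)
pushes the value above 0.30.

The pipeline mirrors the clinical workflow: (1) register the delayed phase
onto the pre-contrast volume and subtract; (2) delineate the left
ventricle, fix the long axis, and parcellate the wall into the AHA
16 segments; (3) measure $\Delta HU_m$ per segment and $\Delta HU_b$ in
the eroded cavity, apply the ECV relation, classify delayed-enhancement
patterns, and report the per-patient mean over non-ischemic segments on a
polar map. Companion modules cover dynamic-perfusion scoring, Agatston
calcium scoring, CAD-RADS banding, chamber volumetry and the cohort
statistics used in a two-group reproducibility study.

## The digital phantom

No patient data ship with the package; every claim is validated on a
seeded digital left ventricle with known ground truth. The LV is a
truncated half-ellipsoid shell — apex closed, base open — which is the
simplest smooth geometry with an unambiguous AHA-16 parcellation. The
generator *inverts* the ECV equation: each segment receives
$\Delta HU_m = \mathrm{ECV}\,\Delta HU_b/(1-\mathrm{Hct})$, so a correct
analysis recovers the encoded truth exactly on clean images.

Defaults describe a realistic adult study at 1 mm isotropic resolution on
a 96^3 grid: endo/epicardial radii 15/25 mm, 60 mm long axis, pre-contrast
blood/myocardium 45/35 HU over a −20 HU soft-tissue/fat background, blood
enhancement 100 HU (typical for a delayed acquisition some minutes after
contrast), hematocrit 0.40, per-segment ECV spanning 0.23–0.31 (the
normal-to-mildly-elevated range), 10 HU Gaussian noise, and an inter-phase
misalignment of a 3/−2/1 mm translation, small rotations and a 2 mm
sinusoidal deformation of 40 mm wavelength. Noise is added independently
to *both* volumes — subtraction noise in practice comes from both
acquisitions. Ground truth is stored alongside: masks, labels, per-segment
enhancement, the applied transform, lesion masks and the analytic
transmural-depth map.

What the phantom does **not** emulate: partial-volume blur at tissue
interfaces (edges are crisp), spatially correlated CT noise, beam
hardening, papillary muscles and trabeculation, and intra-segment ECV
heterogeneity (per-segment truth is piecewise constant). Passing the
recovery tests therefore demonstrates correctness of the measurement
chain, not robustness to every clinical artifact.

## Registration

The registrar is intentionally plain: a 3-level multi-resolution pyramid,
mean-squared-difference metric, Nelder–Mead at the coarsest level followed
by BFGS refinement for the six rigid parameters, then a fluid-style demons
stage at half resolution (100 iterations, update field smoothed with a
3-voxel Gaussian, i.e. ~6 mm regularisation) for the deformable residual.
Linear interpolation is used throughout; provenance records the transform
and interpolation. Out-of-field voxels become `NA` sentinels and are
excluded — never zero-filled — downstream.

Three numerical details matter:

* **Intensity normalisation.** The two phases differ by *regional*
  enhancement (blood +100 HU, myocardium +40–50 HU), which a plain MSD
  metric misreads as misalignment. The moving image is therefore mapped
  onto the fixed intensity distribution by monotone quantile matching
  (histogram matching) before optimisation; a mean-shift and a raw option
  exist. The registration remains invariant to global HU offsets.
* **Interpolation scalloping.** Trilinear interpolation makes an MSD
  metric locally non-smooth with period one voxel, which traps optimisers
  at grid-aligned offsets. The metric is evaluated at sample points with a
  fixed sub-voxel jitter so the artifact phases average out; both images
  are also pre-smoothed (1 voxel Gaussian) per level.
* **Fluid rather than diffusion demons.** Smoothing the *accumulated*
  field shrinks the recovered deformation toward zero at equilibrium;
  smoothing only the per-iteration *update* preserves it.

**The aperture problem.** On a piecewise-constant phantom the wall
interior and the tangential direction along the (axially symmetric)
surfaces carry no intensity gradient, so no intensity-driven registration
can observe those displacement components; for an isotropic 2 mm
sinusoidal deformation the unobservable tangential part alone averages
about 1.9 mm. The deformable stage is therefore validated on the
*boundary-normal* residual at the endocardial surface (< 0.5 mm), which is
exactly the component that creates partial-volume bias in segment means.
Rigid transforms, which are fully observable once the image carries any
azimuthal feature, are recovered to better than 0.1 mm.

With the full default conditions — noise, misalignment, deformable
registration — the mean absolute per-segment ECV error is ≤ 0.02, with
residual boundary partial volume (not noise) the dominant term.

## Segmentation and parcellation

Manual contours (per-slice JSON polygons, or ready-made masks) are taken
verbatim, mirroring the clinical reading where borders are traced by an
observer. The automatic fallback — 3-class k-means intensity clustering
with connected-component cleanup — is adequate for phantom work (Dice
≥ 0.95) and is not a clinical segmenter. The long axis is the cavity's
principal axis; the apex is the end where the epicardium overhangs the
cavity.

The axis from mitral base plane to apex is divided, after removing the
most apical 10 % (the apex cap, absent from the 16-segment model), into
basal/mid/apical thirds of equal length; basal and mid rings get six
60° sectors, the apical ring four 90° sectors, counted counterclockwise
(viewed from the apex) from a caller-supplied reference angle standing in
for the anterior right-ventricular insertion — the phantom declares that
angle explicitly since a rotationally symmetric shell cannot define it.
Sector 1 is basal anterior. The blood-pool ROI is the cavity eroded by a
3 mm default margin to stay clear of endocardial partial volume; erosion
to emptiness is an error suggesting a smaller margin.

## Pattern classification and exclusion

Delayed-enhancement reading distinguishes an ischemic pattern
(subendocardial or transmural, in a coronary distribution) from a
non-ischemic one (midwall/subepicardial with subendocardial sparing). The
operational surrogate, with no coronary-territory atlas in scope: voxels
above a threshold (default: myocardial mean + 3 SD of the subtraction
values; lesions under 0.1 mL are ignored as noise specks) are grouped into
3-D connected lesions; a lesion whose minimum transmural depth is below
0.25 — touching the subendocardial band — marks every segment it occupies
ischemic, otherwise non-ischemic. Transmural depth is computed from the
masks as $d_{endo}/(d_{endo}+d_{epi})$ using breadth-first distances.
Ischemic segments are excluded from the per-patient ECV, which is the
unweighted mean of the remaining segment values (segment weighting is the
natural reading of a polar-map mean; voxel weighting would differ only
through segment-size variation).

## Perfusion scoring

The proprietary deconvolution behind clinical MBF maps is replaced by the
declared maximum-slope stand-in: segment MBF = (max upslope of the 3-point
moving-average-smoothed tissue curve) / (arterial peak) × 6000, in
mL/100 mL/min. The phantom generates tissue curves as flow-scaled running
integrals of a gamma-variate arterial input, so the encoded MBF is exact
before smoothing; the 3-point average biases the recovered value by under
2 % at 1 s sampling, which the tests assert. Everything downstream is
estimator-agnostic: normalised MBF (per-segment value over the 16-segment
maximum), the four printed score bands (0: > 0.75; 1: ≤ 0.75, > 0.675;
2: ≤ 0.675, > 0.60; 3: ≤ 0.60 — boundaries inclusive on the low side, and
implemented exactly as the four printed categories even though the source
calls it a "5-point scale"), and SSS as the plain sum (0–48). Global MBF
is the mean of the 16 segment values.

## Calcium, CAD-RADS, chambers, dose

Agatston details absent from modern papers are taken from the classic
method: per-slice 4-connected components of voxels ≥ 130 HU, minimum
lesion area 1 mm², density weight 1/2/3/4 for peak HU in
[130,200)/[200,300)/[300,400)/≥400, lesion score = area × weight ×
(slice thickness / 3 mm). The implementation is checked against an
independent per-pixel flood-fill oracle on random plaque phantoms.

CAD-RADS is maximum-severity banding with the tie-breaks: total occlusion
(category 5) takes precedence over 4B; the left-main ≥ 50 % rule is
checked before the count of 70–99 % vessels; obstructive disease is
category ≥ 3. Chamber volumes use the modified Simpson biplane
method-of-discs and the biplane area–length left-atrial volume; LV mass is
myocardial volume × 1.05 g/mL. BSA uses Du Bois (the formula is site
convention; it reproduces the published LVM/LVMI pair to rounding) and is
configurable. Effective dose is DLP × k with the chest coefficient
k = 0.014 mSv·mGy⁻¹·cm⁻¹, a value chosen because it reproduces the
published 11.3 mSv from the published mean DLP of 806.7 mGy·cm (printed
there as "Gy cm", clearly mGy·cm).

## Cohort statistics

The workflow concretises "as appropriate" as: Shapiro–Wilk at p ≥ 0.05
routes continuous summaries (mean ± SD vs median (IQR)), two-group tests
(pooled-variance Student t vs Mann–Whitney U; Welch by flag) and
correlation (Pearson vs Spearman). Binary comparisons use the
*uncorrected* Pearson chi-square unless an expected cell is below 5 (then
Fisher's exact): the uncorrected form reproduces the published
drug-history p values, the Yates-corrected one does not. Constant vectors
route to median (IQR) with a warning.

Propensity matching fits a logistic model, then greedily pairs treated
subjects — processed in descending score, the common greedy convention —
with the nearest unmatched control by absolute difference on the *logit*
scale, caliper 0.05 read as absolute logit units (it is stated immediately
after "logit-transformed"), without replacement; equidistant controls are
broken by the session RNG so runs are seedable.

Reproducibility: Bland–Altman bias ± 1.96 SD of differences; the
within-subject CV uses the √2-difference convention for duplicate
readings; the ICC is ICC(2,1) — two-way random effects, absolute
agreement, single measures, reading the printed "interclass" as the usual
intraclass coefficient — with the McGraw–Wong F-based confidence interval,
and ICC(3,1) available. The sample-size solver searches the noncentral-t
power function for the smallest per-group n, because the normal
approximation returns 16 where the exact calculation (and the published
design) gives 17 per group.

The cohort generator draws continuous covariates at the published group
means/SDs, ECV and LAVI jointly at the published within-group correlation
(0.54), and binaries at the published prevalences; smoking and
prior-PCI prevalences are not printed and are fixed once at plausible
values (0.25/0.25 and 0.35/0.40).

## Problem sizes and determinism

Tests validate geometry-heavy properties on compact phantoms (48³, wall
radii 8/14 mm) and run the full default 96³ study once for end-to-end
recovery; simulation-based statistical checks use 200–2000 replicates at
n = 20–2000. These sizes make the whole suite a desk-scale run while
keeping every assertion a real computation. All generators are pure
functions of their specification and seed: the RNG state is saved and
restored around each, so identical seeds give bit-identical phantoms and
cohorts without disturbing the session.

## Known limitations

* The automatic LV segmenter is phantom-grade; clinical use assumes
  supplied contours.
* The ischemic/non-ischemic surrogate uses endocardial contact, not
  coronary territories; patchy multi-lesion patterns crossing segment
  borders inherit the most severe lesion class per segment.
* The maximum-slope MBF stand-in underestimates true flow relative to
  model-based deconvolution; only *relative* quantities (normalised MBF,
  SSS) should be compared across estimators.
* Registration quality is demonstrated on synthetic misalignments up to
  ~3 mm plus smooth deformation; gross motion or through-plane gaps are
  out of scope.
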