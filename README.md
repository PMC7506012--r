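# ctecv

Myocardial extracellular volume (ECV) quantification from contrast-enhanced
cardiac CT, with the surrounding comprehensive-exam toolkit: subtraction
imaging with rigid + deformable registration, AHA 16-segment analysis,
stress-perfusion scoring, Agatston calcium scoring, CAD-RADS banding,
chamber volumetry, and the two-group cohort statistics used in
reproducibility studies. A seeded digital left-ventricle phantom with known
ground truth validates the whole chain without any patient data.

## Who this is for

Imaging scientists who want a transparent, tested reference implementation
of the CT-ECV measurement chain — e.g. to prototype analyses of diffuse
myocardial fibrosis (the motivating application is hemodialysis patients,
where gadolinium is contraindicated and CT-ECV is an attractive biomarker),
or to study how registration error, noise and segmentation choices
propagate into ECV.

## The core quantity

With an extracellular contrast agent at equilibrium,

```
ECV = (ΔHUm / ΔHUb) · (1 − Hct)
```

where ΔHUm is the segment-mean myocardial attenuation change between
pre-contrast and delayed-phase CT (measured on the registered subtraction
image), ΔHUb the blood-pool change in an eroded LV-cavity ROI, and Hct the
hematocrit. Segments showing an ischemic delayed-enhancement pattern
(subendocardial/transmural lesions) are excluded; the patient value is the
unweighted mean of the remaining AHA-16 segments.

## Worked example

```r
library(ctecv)

# a clean digital LV: known per-segment ECV, no noise, aligned phases
spec <- phantom_spec(noise_sd = 0, misalignment = NULL)
ph   <- generate_paired_ct(spec)

tab <- ecv_pipeline(ph$pre, ph$delayed, hct = spec$hematocrit,
                    geometry = ph$truth$geometry, mode = "none")
head(tab, 4)
#>   segment delta_hu_m       ecv class excluded
#> 1       1   38.33333 0.2300000  none    FALSE
#> 2       2   39.22222 0.2353333  none    FALSE
#> 3       3   40.11111 0.2406667  none    FALSE
#> 4       4   41.00000 0.2460000  none    FALSE
attr(tab, "patient_ecv")
#> [1] 0.27
max(abs(tab$ecv - spec$true_ecv))
#> [1] 5.551115e-17
```

Segment 1 was generated at ECV 0.23 with blood enhancement 100 HU and
hematocrit 0.40, so its enhancement is 0.23·100/0.60 = 38.3 HU and the
pipeline returns exactly 0.23; the patient value 0.27 is the mean of the
16 encoded segment values. On the realistic default phantom (10 HU noise,
misaligned phases, `mode = "deformable"`) the same pipeline recovers the
per-segment truth with a mean absolute error ≤ 0.02 ECV.

Other modules in one line each:

```r
sample_size_ttest(5, 5, 0.80, 0.05)          # 17 per group
effective_dose(806.7, 0.014)                 # 11.294 mSv
cad_rads(c(LAD = 80, LCX = 20, RCA = 10))    # $category "4A", obstructive
sss(segment_score(normalized_mbf(mbf16)))    # summed stress score
ecv_polar_map(tab, file = "polar.png")       # AHA bullseye rendering
```

## Layout

- `R/phantom*.R` — seeded generators: paired CT volumes, perfusion curves,
  calcium volumes, two-group cohorts (all truth-carrying)
- `R/register.R` — rigid + fluid-demons registration, resampling, subtraction
- `R/lv_model.R` — LV masks, long axis, AHA-16 parcellation, blood-pool ROI
- `R/ecv_core.R` — enhancements, ECV, pattern classification, polar map
- `R/perfusion.R` — maximum-slope MBF, normalisation, SSS
- `R/morphometry.R` — Agatston, CAD-RADS, chamber volumes, BSA, dose
- `R/cohort_stats.R` — descriptives, tests, matching, Bland–Altman, CV,
  ICC, sample size
- `vignettes/ctecv-methods.Rmd` — model assumptions, parameter defaults,
  numerical choices, limitations
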