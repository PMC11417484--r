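# cardiomass

Regional left-ventricular (LV) mass from short-axis cardiac MRI
segmentation masks, and the downstream epidemiology it feeds: sex-specific
hypertrophy classification, Cox proportional-hazards association with
incident cardiovascular disease, and a desk-scale genetic pipeline
(per-variant association scan, LD clumping, polygenic scoring).

## The problem

Total LV mass (LVM) is a classic risk factor, but hypertrophy is often
*focal* — confined to the apex or the interventricular septum — and focal
hypertrophy can carry risk that total LVM misses. Given a labelled 3-D
short-axis stack (labels: 0 background, 1 LV cavity, 2 LV myocardium, 3 RV
cavity) with pixel spacing, slice thickness and inter-slice gap, the
package computes, in grams:

- **total LVM** — all myocardial pixels:
  `mass = Σ pixels × pixel_area × (thickness + gap) × 1.055 g/cm³`;
- **apical mass** — the same sum over the four most apex-ward slices that
  contain myocardium;
- **septal mass** — per slice, the myocardial segment bounded by the two
  **RV insertion points**: the endpoints of the smallest circular angular
  interval (about the LV centroid) containing every myocardial pixel that
  touches the RV cavity.

Cohorts are then classified by the sex-specific 90th percentile of each
mass (global / isolated apical / isolated septal / combined hypertrophy),
prevalent cases are removed per outcome, and hazard ratios are estimated
with Cox models adjusted for sex, age, pulse rate and hypertension:
categorical (each hypertrophy group vs control), per-1-SD continuous, and
joint models (total + one regional mass) that expose whether a regional
effect survives adjustment for total LVM. The genetics module filters
variants (MAF ≥ 0.01, INFO ≥ 0.3), runs a covariate-adjusted linear scan,
clumps genome-wide-significant hits (p < 5e-8, r² > 0.6 within ±500 kb),
scores subjects with additive allele-aligned weights, and associates the
score (per SD / top decile / top 5%) with outcomes.

Everything is testable offline: the package ships generators for annular
myocardium phantoms with closed-form ground-truth masses, simulated
cohorts with exponential survival under known hazard ratios, and genotype
panels with calibrated LD-block structure.

## Worked example

```r
library(cardiomass)

# a 10-slice tapered annulus phantom with known truth
spec <- phantom_spec(grid_shape = c(180, 180), pixel_spacing = 0.5,
                     n_slices = 10, inner_radius = 20, outer_radius = 28,
                     septal_arc = c(60, 150), apical_taper = 0.06)
ph <- generate_phantom_stack(spec, subject_id = "demo")
quantify_subject(ph$stack)
#> demo: total 77.58 g, apical 20.29 g, septal 19.44 g (QC passed)
ph$truth[c("total_mass_g", "apical_mass_g", "septal_mass_g")]
#> 77.62, 20.32, 19.41   (analytic truth: all three within 0.2%)
```

The three computed masses agree with the closed-form annulus truth to a
fraction of a percent at 0.5 mm spacing; the septal arc spans 90°, so
septal mass is one quarter of the total.

```r
# a simulated cohort with a true hazard ratio of 2.27 per 22 g of LVM
cohort <- generate_cohort(sim_cohort_spec(
  n_subjects = 5000, seed = 1,
  log_hazard_coefficients = list(cardiomyopathy = c(total_mass_g = log(2.27) / 20)),
  baseline_hazard = 0.002))
cohort <- assign_categories(add_hypertrophy_flags(cohort))
table(cohort$hypertrophy_group)
#> control  global  isolated_apical  isolated_septal  combined
#>    4082     501              234              149        34

inc <- remove_prevalent(cohort, "cardiomyopathy")$incident
fit_cox(inc, "cardiomyopathy", predictors = "total_mass_g",
        standardize = "total_mass_g")[1, ]
#>          term  hazard_ratio  ci_low  ci_high    p_value  sd_used
#>  total_mass_g         2.512   2.360     2.67  1.11e-182     22.3
```

The fitted hazard ratio of 2.51 per 1 SD (22.3 g) is the estimate of the
generative per-SD effect in this particular draw; across replicates the
nominal 95% intervals cover the truth at their nominal rate (this is one
of the acceptance properties below). `hypertrophy_hazard_table()`,
`joint_mass_models()`, `linear_scan()`, `clump()`, `prs_score()` and
`prs_outcome_association()` follow the same pattern, and
`run_pipeline(default_run_config())` chains all stages (phantoms →
quantify → cohort → Cox → scan → clump → PRS) deterministically into TSV
artifacts plus a JSON manifest.

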