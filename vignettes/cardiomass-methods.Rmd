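---
title: "Regional left-ventricular mass quantification and risk modelling: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Regional left-ventricular mass quantification and risk modelling: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cardiomass)
```

## The measurement

`cardiomass` quantifies three masses from a labelled short-axis cardiac MRI
segmentation stack (background / LV cavity / LV myocardium / RV cavity,
stored base-to-apex):

* **Total LV mass.** Every myocardial pixel contributes
  `pixel_area × (slice_thickness + slice_gap) × 1.055e-3 g/mm³`. The
  density constant is the standard myocardial density of 1.055 g/cm³. Using
  thickness *plus* gap treats each slice as representative of its full
  coverage interval — the contiguous-coverage convention. The alternative
  (`slice_coverage = "thickness_only"`) is exposed because some sites treat
  the gap as unsampled; it rescales all masses by a constant factor and
  changes no downstream inference that standardises per SD.
* **Apical mass.** The same conversion restricted to the four most
  apex-ward slices *containing myocardium* (`n_apical = 4`, configurable).
  Trailing slices with no myocardium are common in real acquisitions, so
  selection filters before taking the tail rather than using the raw array
  end.
* **Septal mass.** Per slice, the centroid of the LV (cavity plus
  myocardium — more stable than the myocardium alone on thin-wall slices)
  defines a polar frame; myocardial pixels 8-adjacent to the RV cavity form
  the contact set; the smallest circular angular interval containing all
  contact angles gives the two RV insertion points. Myocardial pixels whose
  centre angle falls in the closed interval are septal. Working on pixel
  centres (no subpixel contour fitting) matches the pixel-summing nature of
  the whole measurement; the angular quantisation error is one pixel at the
  epicardial radius (≈ 1° at 0.5 mm spacing and a 28 mm epicardium).

Two conventions need care. First, circular arithmetic: an interval such as
(330°, 30°) must be kept in that orientation, which the minimal-covering
construction guarantees; intervals spanning ≥ 180° are anatomically
implausible for a septum and are flagged as degenerate, and the slice is
excluded. Second, slices with no RV contact contribute nothing to septal
mass by default (`no_contact = "zero"`), because an extrapolated insertion
angle cannot be verified; `"nearest"` reuses the nearest contact-bearing
slice's angles for users who prefer coverage over conservatism.

## Quality control

Stacks are screened before measurement with four structural checks, each
reported by code rather than raised: enough myocardium-bearing slices
(default ≥ 6); RV visible somewhere in the middle third of the stack; a
closed myocardial ring in every mid-third slice; and a capped apex (the
most apical myocardial slice's cavity below half the mid-stack maximum). A
subtlety: a radial cut through the wall leaves the myocardium as a single
connected arc, so component counting alone cannot detect it. Ring
integrity is therefore tested as *one 8-connected myocardial component
whose cavity is not 4-connected to the border background* — the
4-/8-connectivity pairing is the standard duality that makes the enclosure
test consistent. Failed stacks yield records with `NA` masses and the
failure codes attached, never silent exclusion.

## Cohort construction

Hypertrophy is classified per region against the *sex-specific* 90th
percentile of the analysis cohort (type-7 linear-interpolation quantiles,
strict `>` so ties never inflate the flagged set). The three binary flags
partition subjects into eight cells; analysis uses the coarser five-level
grouping — control, global (any global flag), isolated apical, isolated
septal, and combined regional hypertrophy without global — with control as
the Cox reference. Percentile thresholds describe anatomy, not outcomes,
so they are computed before prevalent-case removal.

For each outcome, subjects whose first event predates baseline are
prevalent and removed; the rest get an event indicator and follow-up in
years (days/365.25) from baseline to the first event, or to the end of
follow-up. The operation is idempotent, so re-running a cohort through the
builder is safe.

## Survival modelling

All hazard ratios come from Cox proportional-hazards fits
(`survival::coxph`, Efron tie handling, Newton iteration to 1e-9, Wald 95%
intervals), adjusted for sex, age, pulse rate, and hypertension (plus BMI
for polygenic-score models). Continuous masses are reported per 1 SD of
the fitted sample, with the SD in grams carried alongside so effect sizes
remain interpretable. Three families mirror the analysis structure: the
categorical hypertrophy model against control; single-mass per-SD models;
and joint models pairing total LV mass with one regional mass. The joint
septal model is the attenuation contrast: when a regional mass predicts
risk only by proxying total mass, its joint per-SD hazard ratio collapses
to the null.

Defensive choices: fits are complete-case; unstable fits (|coefficient| >
15 or SE > 100, i.e. separation) raise diagnostic errors naming the term;
a hypertrophy category with subjects but no events is reported without an
estimate (its hazard ratio is not estimable) instead of destabilising the
whole categorical fit; collinear mass pairs (condition number > 1e8) are
rejected. Breslow tie handling is available (`ties = "breslow"`) because
it makes integer case weights exactly equivalent to row replication, which
is the cleanest replication-invariance check; Efron remains the default as
the better tie approximation. Death is treated as censoring, not a
competing risk.

## The genetic stand-ins

The scan is an ordinary-least-squares per-variant regression of the
phenotype on dosage plus covariates (covariates projected out once via QR,
then per-variant slopes and t-tests). A mixed-model scan would be the
choice on real biobank data with relatedness and stratification; synthetic
panels have neither, so OLS is calibrated under the null by construction
(genomic-control λ ≈ 1), and the per-variant t-test is exact. Variants are
pre-filtered at MAF ≥ 0.01 and INFO ≥ 0.3, both inclusive.

Clumping is greedy: significant variants (p < 5e-8) in ascending p-value
order become leads unless they sit within ±500 kb of an accepted lead on
the same chromosome *and* have r² > 0.6 with it — the conventional reading
of "independent SNPs", under which high-LD neighbours are absorbed. The
distance and LD conditions are conjunctive; LD is supplied as an explicit
pairwise r² table (computed from in-sample dosages within the window), and
a missing pair inside a window is a configuration error, never silently
treated as independence.

Polygenic scores are additive: `score = Σ weight × dosage` after allele
alignment, with the weight's sign flipped when its effect allele is the
panel's reference allele. The sign-flip convention (rather than using
`2 − dosage`) differs only by a per-subject constant from the
complement-dosage convention — absorbed by the per-SD standardisation and
the Cox partial likelihood — and has the advantage that flipping a
panel's ref/alt labels while negating weights leaves scores bitwise
unchanged. Score-outcome association fits per-1-SD, top-decile, and top-5%
indicator models (strict `>` at type-7 quantiles, as for hypertrophy).

## What the generators emulate — and what they do not

**Phantoms** are concentric annuli: cavity inside the endocardial radius,
myocardium between the radii, and an RV segment of configurable radial
extent touching the epicardium exactly over the declared arc, so the
insertion-point ground truth is exact by construction. Radii shrink by a
per-slice taper toward the apex (default 6%/slice), giving the apex-capped
geometry QC expects. Closed-form truth: annulus area π(R₂² − R₁²) per
slice, times coverage and density; the septal truth is the arc fraction of
the slice mass. Phantoms exercise every code path of the measurement but
are deliberately idealised: no papillary muscles, no wall-thickness
variation around the circumference, no segmentation noise, no
partial-volume effects at the apex. Passing phantom tests therefore
demonstrates the *computation* is right, not that segmentation-quality
problems of real CMR are handled.

Pixelation error of a single phantom oscillates with the exact radii (a
2 mm grid can beat a 1 mm grid by luck), so convergence with grid
refinement is asserted on the mean error over a family of radii, which
decreases cleanly (≈ 2.0% → 0.5% → 0.13% for total mass at 2/1/0.5 mm).

**Cohorts** draw sex-specific trivariate-normal masses (defaults chosen as
a realistic biobank imaging cohort: male total 103 ± 20 g, female 77 ± 16
g; correlation targets 0.86 septal–total and 0.66 apical–total, i.e. r² of
0.74 and 0.44; age 64 ± 7.5, pulse 69 ± 11, 30% hypertension, BMI 26.6 ±
4.4), truncated at zero. Event times are exponential with hazard
`baseline × exp(linear predictor)` and independent exponential censoring
truncated at five years — the simplest model in which every Cox estimate
has a closed-form target. Real data violate this in known ways
(non-constant baseline hazard, covariate-dependent censoring, competing
mortality); the simulations validate estimator calibration, not those
robustness properties.

**Genotype panels** draw per-variant MAFs uniformly and realise LD blocks
by a Gaussian-copula threshold model: two latent haplotype draws per
subject with a compound-symmetric latent correlation, thresholded at the
MAF quantile and summed to dosages in {0, 1, 2}. Thresholding attenuates
correlation, so the latent correlation is calibrated numerically (uniroot
on the bivariate-normal orthant probability) to make the *dosage*
correlation hit the declared r target; blocks share one MAF so that target
is well defined. This produces exactly the pairwise-r structure clumping
needs and nothing more — no realistic recombination maps, no MAF–LD
coupling, no population structure.

## Numerical and reproducibility choices

All generators are deterministic under their seed fields; the pipeline
derives per-stage seeds from the global seed with a fixed integer mix (all
below 2³¹), so stages can be re-run independently and whole runs reproduce
byte-identical TSV outputs. Degenerate inputs error early with the
offending value named (unknown labels, non-positive spacing, non-PSD
correlation targets, zero-width annuli, arcs ≥ 180°, missing LD pairs,
mismatched alleles). Geometry comes from the NIfTI header (gap = slice
spacing − thickness); when the header is unusable the common short-axis
protocol defaults of 8 mm thickness + 2 mm gap are assumed with a warning.

Problem sizes used by the test suite and the acceptance script were chosen
as the smallest at which the checked statistics are stable: phantom
accuracy on radii 15–35 mm at 0.5 mm spacing; Cox coverage over 200
replicate cohorts of n = 5 000 (pooled across the checked quantities, since
a per-quantity ±2% window at 200 replicates is narrower than its own
binomial noise); scan calibration pooled over five null panels of 2 000
variants; hazard-recovery demonstrations at n = 35 000 and polygenic-score
recovery at n = 40 000 with a proportionally raised baseline hazard.

## Known limitations

* End-diastolic label masks only: no DICOM, no cine frames, no
  registration, no papillary-muscle handling beyond the input labels.
* Insertion points are pixel-resolution; very coarse grids (> 2 mm) make
  the septal boundary visibly ragged.
* The OLS scan is not a substitute for mixed models on data with
  relatedness or stratification, and in-sample LD is not a reference
  panel.
* Percentile thresholds assume the analysis cohort is the reference
  population; no external normative ranges are built in.
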