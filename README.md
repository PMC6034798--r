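# acgtools

Simulation and analysis toolkit for **acoustocerebrography (ACG)** —
transcranial transmission-ultrasound spectroscopy that characterizes brain
tissue from how the components of a multifrequency pulse are delayed and
attenuated on their way through the head. The package is aimed at people
studying multifrequency phase-based time-of-flight estimation and at
epidemiologists who want a fully synthetic, calibrated test bed for
ACG-style case-control analyses (for example hypertension detection in
atrial-fibrillation cohorts), where the raw patient recordings behind
published studies are not available.

## The method

A compound pulse of *n* = 10 sinusoids (0.7–2 MHz, uniform spacing) is
transmitted through a head-scale path of length *L*. The medium is
dispersive and attenuating: each component *k* travels at phase velocity
*c(f_k) = c₀ + slope·(f_k − f_ref)* and is scaled by
*exp(−α(f_k)·L)* with the soft-tissue power law
*α(f) = α₀ (f/1 MHz)^γ*.

From a received record, the per-component amplitude *A_k* and phase
*φ_k* are recovered by ordinary least squares on the known-frequency
cos/sin design (the frequencies are exact, so the fit is linear). The
transit time of component *k* follows from the transmit–receive phase
difference up to an integer number of cycles,

    t_k = (Δφ_k / 2π + m_k) / f_k ,

with the integers *m_k* resolved by a coarse delay estimate plus a
component-to-component ladder. Per-frequency attenuation is the
fractional amplitude loss *ATT_k = 1 − A_rx,k / A_tx,k*. Derived
quantities use *c = L/t* and the bulk modulus *K = ρc²*; under the
constant-*K* linearization a speed change *dc* maps to a relative
density change *dρ/ρ = −2·dc/c*.

On top of the signal layer the package provides:

* a **synthetic cohort generator** (75 hypertensive / 22 non-hypertensive
  subjects by default) whose per-subject media are calibrated so the
  extracted features match published per-frequency time-of-flight and
  attenuation distributions, with baseline covariates drawn at published
  prevalences;
* the study-style **group statistics**: two-sided Fisher exact tests
  (hypergeometric enumeration) for categorical variables and
  Kruskal–Wallis rank tests for quantitative ones;
* a **gradient-boosted classifier** of hypertension status with
  stratified 10 × 5-fold cross-validation, leakage-free per-fold
  z-scoring, and ROC/AUC/Youden operating-point reporting.

## Worked example

```r
library(acgtools)
library(dplyr)

cohort <- generate_cohort(cohort_config(seed = 1))
cohort
#> <acg_cohort> 97 subjects (75 hypertension / 22 no hypertension)

features <- cohort_features(cohort, seed = 2)
report <- compare_groups(
  select(features, group, ToA_f02, ToA_f06, ToA_f10, ATT_f04, ATT_f10),
  group = "group"
)
select(report, variable, summary_1, summary_2, p_formatted)
#> # A tibble: 5 × 4
#>   variable summary_1        summary_2       p_formatted
#>   <chr>    <chr>            <chr>                 <dbl>
#> 1 ToA_f02  97.24 (3)        99.43 (3.098)        0.0042
#> 2 ToA_f06  97.14 (2.983)    99.36 (3.113)        0.0041
#> 3 ToA_f10  97.05 (2.966)    99.28 (3.128)        0.0037
#> 4 ATT_f04  0.1488 (0.09684) 0.1383 (0.1014)      0.51
#> 5 ATT_f10  0.5227 (0.184)   0.5624 (0.1926)      0.44
```

Group 1 is the hypertensive group. Mean time of flight is about 1 µs
shorter in hypertension (stiffer tissue → faster sound) at every
calibration frequency, with standard deviations near 3 µs — the
configured separations. Classifying the same feature table:

```r
fit <- cross_validate(select(features, -subject_id, -group),
                      features$group, classifier_config(seed = 3))
glance(fit)
#> # A tibble: 1 × 7
#>     auc sensitivity specificity threshold     n n_pos n_neg
#>   <dbl>       <dbl>       <dbl>     <dbl> <int> <int> <int>
#> 1 0.581       0.947       0.409     0.576    97    75    22
autoplot(fit)   # ROC curve
```

At the published marginal effect sizes the cross-validated AUC is only
~0.58: the group separations reported for individual features are far
too small to explain a 0.958 AUC on their own, which is an informative
negative result of the simulation (see the vignette). Raising
`effect_scale` (e.g. to the value from `effect_scale_for_separation()`,
giving a Mahalanobis distance of 3 between group means) yields AUC ≥ 0.9.

The estimator's precision can be measured directly:

```r
tof_precision_summary(tof_precision_sim(n_reps = 100, seed = 4))
#> # A tibble: 1 × 3
#>   rms_tof_error_ns rms_speed_error_mps n_reps
#>              <dbl>               <dbl>  <int>
#> 1            0.751              0.0119    100
```

With per-component phase errors of 1°, the pooled 10-component
time-of-flight estimate is good to under a nanosecond RMS, i.e. a
speed-of-sound error of ~0.01 m/s over a 15 cm path.

## Command line

A thin CLI over the same functions lives at `inst/cli/acg.R`
(`cohort`, `simulate`, `extract`, `features`, `stats`, `classify`); run
it with `Rscript` and `--help`-style arguments as documented in the file
header.
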