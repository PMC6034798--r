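---
title: "Models and methods behind acgtools"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind acgtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette documents the models, conventions, and numerical choices
in `acgtools`, in the spirit of a methods section: what is simulated,
what is estimated, which knobs matter, and what the synthetic results do
and do not demonstrate.

## Forward signal model

Acoustocerebrography transmits a compound pulse of $n$ sinusoids through
the head and records it on the far side. The package models the
transmitted waveform as a continuous multitone,
$$y(t) = \sum_{k=1}^{n} A_k \sin(2\pi f_k t),$$
with $n = 10$ components uniformly spaced over 0.7–2 MHz, integer
amplitudes $A_k \in [1, 255]$, and a sampling rate of 25 MHz by default
(well above the 5$\times$ floor enforced on the top component). Whether
the real instrument transmits repeated short pulses or a continuous
multitone is not publicly specified; the phase-bundle picture of the
method is compatible with either, and the continuous multitone is the
cleaner choice for a phase-based simulator because every ground-truth
delay can be applied as an exact per-component phase shift rather than a
sample-grid interpolation. The consequences of that choice for delay
identifiability are discussed below.

The propagation path is one homogeneous dispersive, attenuating segment:

* phase velocity linear in frequency, $c(f) = c_0 + s\,(f - f_\mathrm{ref})$,
  with $f_\mathrm{ref}$ at band centre (1.35 MHz). Tissue dispersion
  exists but has no published functional form for this instrument; a
  linear law is the minimal model and matches the smoothness assumption
  the estimator itself relies on.
* soft-tissue power-law attenuation $\alpha(f) = \alpha_0 (f/1\,\mathrm{MHz})^{\gamma}$
  in Np/m, $\gamma \ge 0$.
* additive white Gaussian receiver noise specified as an SNR in dB
  relative to received signal power (`NULL` = noiseless).

Each component is delayed by $t_k = L / c(f_k)$ and scaled by
$e^{-\alpha(f_k) L}$, applied analytically, so round-trip tests can
demand sub-picosecond agreement.

## Spectral estimation

Component amplitudes and phases are recovered by ordinary least squares
on the cos/sin design at the known frequencies; the problem is linear,
and the normal equations are accumulated in streaming chunks so a
10 s $\times$ 25 MHz window never needs a dense design matrix in memory.
The phase convention is fixed throughout: a pure
$\sin(2\pi f t + \varphi)$ yields phase $\varphi$
($\varphi = \mathrm{atan2}(a, b)$ for $y \approx a\cos + b\sin$), and
window time is referenced to the record origin so phases are comparable
across windows. The fit residual is computed in a second streaming pass
(predictions subtracted directly); evaluating it through the
normal-equation identity cancels catastrophically on near-noiseless
records and would report residuals about a hundred times too large.

Records are processed in non-overlapping windows (10 s by default,
giving three windows per 30 s record), and exam-level features take the
component-wise median over all windows of all three records of an exam.
The median is used because it is the more specific of the two
aggregation rules quoted for the instrument (the mean is available via
`aggregate_exam(method = "mean")`), and it shields the exam feature from
a single bad window.

## Time of flight and cycle-ambiguity resolution

The transit time of component $k$ is encoded in the transmit–receive
phase difference up to an integer number of carrier cycles:
$t_k = (\Delta\varphi_k / 2\pi + m_k)/f_k$ with
$\Delta\varphi_k = \mathrm{wrap}(\varphi_{tx,k} - \varphi_{rx,k})$ (a
delay advances the received phase by $-2\pi f\tau$, so this difference
is positive for positive delays).

Resolving the integers $m_k$ is the only genuinely hard part, because a
uniform-grid continuous multitone is a poor ranging waveform:

* its envelope repeats every $1/\Delta f \approx 6.9\ \mu s$, so
  envelope correlation cannot distinguish lattice-shifted delays;
* the whole waveform repeats every $90\ \mu s$ (every $f_k \times 90\ \mu s$
  is an integer on the standard grid), so the absolute delay is only
  identifiable within a window narrower than that period;
* head-scale dispersion spreads per-component delays by more than a
  carrier cycle at 2 MHz, decohering the full-band carrier correlation.

The package therefore resolves ambiguity in two stages. The coarse
stage (`estimate_coarse_delay`) recovers both records' component phases
and scans candidate delays across a physically admissible search window
(60–140 µs by default, head-scale paths at soft-tissue speeds). Each
candidate is "ladder-resolved" — the candidate seeds the lowest
component, and each higher component's integer is chosen against the
previous component's recovered delay, whose tolerance
($0.4$ cycles $\approx 200$ ns at 2 MHz) comfortably exceeds
adjacent-component dispersion — and scored by the RMS lack-of-fit of
the resolved delays to a line in frequency. A wrong cycle branch
produces a jagged $1/f$-shaped delay profile with tens of nanoseconds
of lack-of-fit versus well under a nanosecond for the true branch, so
the true branch wins by an order of magnitude at the phase precisions
of interest (the margin shrinks once per-component phase errors reach
several degrees). `time_of_flight` then applies the same ladder from
the supplied coarse delay and raises an ambiguity error if any
component's cycle residual exceeds 0.4 cycles. A band-limited
cross-correlation fallback (one-sample resolution) is used when fewer
than three components are available.

## Attenuation, derived acoustics, FFT features

Per-component attenuation uses the fractional amplitude-loss convention
$ATT_k = 1 - A_{rx,k}/A_{tx,k}$, clipped to $[0,1]$. Published ACG
tables print unitless attenuation values in roughly $[0.14, 0.57]$
without defining the scale; this convention lands in that range, is
monotone in physical attenuation, and the cohort generator calibrates
in the same convention, so the scale is internally consistent without
claiming to match the instrument's absolute definition.

Derived acoustics take $c_k = L/t_k$, a band-average speed, and
$K = \rho_\mathrm{ref} c^2$ with $\rho_\mathrm{ref} = 1040$ kg/m³ (a
standard brain-tissue density; configurable). The constant-$K$
linearization $d\rho/\rho = -2\,dc/c$ maps the pipeline's speed
precision to a density-change sensitivity; at $dc = 1.25$ m/s and
$c = 1540$ m/s it gives $1.6\times10^{-3}$. The path length used for
derived quantities defaults to head circumference over $\pi$ scaled by
0.85 (a temporal-window chord); only derived quantities depend on it,
not the ToA/ATT features themselves.

Which FFT-derived features the original analysis used is not stated
anywhere; the package's declared stand-in is the integrated band energy
in $\pm\Delta f/2$ around each component plus the spectral centroid over
the pulse band, which captures the attenuation profile's shape in a
form an FFT naturally provides.

The record-quality criterion (pass when above 0.70) is defined here as
the received band energy of the two extreme components relative to a
reference energy: the transmitted band energy scaled by the expected
path gain from the device's transmit-amplitude selection step. The
published description names the extreme-component energy criterion but
not the reference; tying the reference to the calibrated gain makes a
nominal record score near 1 and a dropout score near 0, which is the
only reading under which realistic attenuating media can pass a 0.70
threshold at all.

## The synthetic cohort generator

The generator emulates the published study conditions: 75 hypertensive
and 22 non-hypertensive subjects, three 30 s records each, binary
covariates drawn at the published per-group prevalences, age at
64 ± 8 / 66 ± 6 years, and head circumference at 57 ± 2 cm. Each
subject's medium is calibrated (`calibrate_medium`) so that noiseless
extraction reproduces latent per-frequency targets drawn from the
published group means and SDs: time of flight at components 2, 6, 10
(microseconds — the published values near 98 match a head-scale path at
soft-tissue speed, though the table prints no unit) and attenuation at
components 4, 9, 10.

Design choices a reader should know:

* **The group signal lives in the medium**, not in post-hoc feature
  noise, so every stage of the pipeline is exercised. `effect_scale`
  scales the between-group difference about the size-weighted pooled
  mean; 0 gives an exact null.
* **Subject ToA variance is almost entirely common-mode.** A subject's
  transit times at different frequencies move together (head size and
  bulk velocity, split 50/50 by default); only a small share
  (`toa_dispersion_share`, default $5\times10^{-4}$) is differential
  across frequency. Making per-frequency ToA draws nearly independent
  (e.g. an AR(1) correlation of 0.8 between adjacent components) would
  imply per-subject dispersion slopes near 80 m/s/MHz — physically
  absurd for tissue and far outside the regime in which any phase-based
  multitone instrument can resolve cycle ambiguity, so such cohorts
  would be unmeasurable by the very device being simulated. The default
  puts subject dispersion at the ~1 m/s/MHz scale. Attenuation draws
  keep the AR(1)-style correlation (0.8 per component step).
* **Velocity line and power law are fitted, and the fitted values become
  the subject's truth.** Three ToA targets are projected onto the linear
  dispersion law and the two extreme ATT targets solve the power law
  exactly; the subject's stored latent values are the medium-implied
  ones, so noiseless round-trips are exact rather than
  approximation-limited. A consequence: the subject's ATT at component
  9 follows the power law through components 4 and 10 (≈0.43 at the
  published means) rather than the published 0.53 — the published
  three-point profile is not a power law (scattering from white-matter
  lesions is the usual explanation), and a two-parameter law cannot hit
  all three points.
* **Infeasible attenuation draws** (ATT₄ ≥ ATT₁₀, or outside (0,1)) are
  redrawn up to 100 times and finally clamped; with the published
  means/SDs roughly 13% of draws are redrawn, which truncates the ATT₄
  marginal upward by a few hundredths. ToA marginals are unaffected.
* **Feature tables** come in two modes. `latent` (default) evaluates
  each medium analytically — exactly what noiseless extraction recovers,
  a fact the test suite verifies by running the full waveform pipeline
  on small cohorts — plus per-record measurement noise at device-scale
  precisions (5.6 ns timing, 0.005 attenuation, 1% band energy) before
  the three-record median. `signal` runs the complete waveform chain and
  exists so the equivalence is testable; it is the slow path.

What the generator does **not** emulate: within-record nonstationarity
(pulsatility, motion), skull refraction and multipath, transducer
coupling variation, per-window heterogeneity (so per-window
classification adds no information here), and any real relationship
between covariates and tissue parameters beyond group membership.
Passing tests on these cohorts therefore demonstrates correctness of
the estimation and analysis chain under the stated model, not clinical
performance on real recordings.

## Group statistics and the classifier

Fisher's exact test is implemented by hypergeometric enumeration with
probability-mass ordering (the R `fisher.test` convention, which is what
the original analyses used); degenerate margins return $p = 1$.
Kruskal–Wallis uses mid-ranks with the standard tie correction and the
$\chi^2$ approximation, appropriate at these group sizes. Both are
cross-checked against their base-R references in the tests — the
package's own implementations are the ones used by the reporting
functions. p-values print at two significant figures; full precision is
retained. No multiple-testing correction is applied, matching the
original reporting. Note that the exact test is conservative on discrete
data: its true level at these group sizes sits below the nominal 5%,
which is a property of the test, not a defect.

The classifier is a gradient-boosted tree ensemble (xgboost, logistic
objective, single thread) with conventional small-cohort
hyperparameters: 200 trees, learning rate 0.05, depth 3, subsample 0.8 —
none are published for the original analysis, and all are configurable.
Validation is stratified 5-fold cross-validation repeated 10 times;
each training fold is z-scored and held-out folds are transformed with
the training fold's statistics only. Out-of-fold scores are averaged
per subject across repeats; ROC and AUC (trapezoid, ties half-credit —
equal to the concordant-pair definition) come from those averaged
scores, with the operating point at Youden's J by default. The unit of
classification is one exam-aggregated feature vector per subject:
per-window classification would let windows of one subject appear in
both training and test folds, and the generator produces no per-window
heterogeneity anyway.

At the published marginal effect sizes (`effect_scale = 1`) the
cross-validated AUC on synthetic cohorts is far below the published
0.958: the per-feature group separations reported in the summary tables
are simply too small to produce that discrimination, so the published
classifier must have exploited structure beyond those marginals (or
richer per-window features). The package treats 0.958 as not
reproducible from published information; its classifier benchmarks are
instead (a) exact-null cohorts, whose AUC distribution must cover 0.5,
and (b) cohorts with a configured Mahalanobis separation of 3, which
reach AUC ≥ 0.9.

## Numerical choices and problem sizes

* Windows are validated against the record duration; trailing partial
  windows are discarded; duplicate frequencies and near-Nyquist
  components are rejected before fitting.
* Sine arguments are reduced modulo one cycle before multiplication by
  $2\pi$ so phase accuracy does not degrade over long records.
* The cycle-residual guard in `time_of_flight` is 0.4 cycles;
  calibration errors name the violated constraint; `gamma_min` lets a
  caller forbid flat attenuation laws.
* Cohort and classifier randomness is seed-controlled end to end
  (`withr::with_seed`); xgboost runs single-threaded with a per-repeat
  seed, so results are bit-reproducible.
* The test suite runs the identical estimators on scaled-down signals —
  millisecond records at 12.5 MHz, 1 ms windows — which the round-trip
  tests show is enough to exercise every code path at full precision;
  cohort-level checks use the full 97-subject design, and the
  precision Monte Carlo uses 100 replicates of 4 ms records. These
  sizes are the package's choice of test conditions; the defaults
  remain the 30 s / 25 MHz study conditions.

## Known limitations

* Absolute delay is identifiable only within the configured search
  window (narrower than the waveform's 90 µs period); this is a
  property of continuous multitone ranging, not of the implementation.
* The homogeneous-path model cannot represent skull/tissue layering;
  reported speeds are path averages.
* The ATT scale is internally consistent but not tied to the
  instrument's absolute definition, and component-9 attenuation follows
  the fitted power law rather than the published three-point profile.
* The published AUC is out of reach by design of the public evidence;
  see above.
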