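---
title: "Noncompartmental analysis of sparse oral-dosing studies with scipk"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Noncompartmental analysis of sparse oral-dosing studies with scipk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scipk)
```

## The problem

scipk analyses serum concentration–time data from sparse, staggered sampling
designs: studies in which different subjects are bled at different time
points, so that no single animal carries a complete profile and the full
curve only exists at the group level. The package is built around a
single-oral-dose scyllo-inositol study in six Wistar rats (10 mg/kg by
gavage), whose complete dataset ships in `inst/extdata/` and loads with
`sci_study_profiles()`. Three rats were sampled at 0, 0.25, 0.5, 1, 1.5, 12
and 24 h post-dose and three at 2, 4, 8, 36 and 48 h; serum scyllo-inositol
was quantified by gas chromatography, with values below the limit of
quantification (LOQ) recorded as 0 mg/L and flagged BLQ.

Every quantity the package computes is a standard noncompartmental (NCA)
parameter: Cmax and Tmax, AUClast and AUMClast by the linear trapezoidal
rule, the terminal elimination rate constant K by log-linear regression, and
the derived chain

$$T_{0.5e} = \frac{\ln 2}{K}, \qquad MRT = \frac{1}{K}, \qquad
V_d = \frac{\mathrm{dose}}{K \cdot AUC_{last}}, \qquad CL = K \cdot V_d.$$

Units are fixed throughout: hours, mg/L, mg and grams. No unit inference is
attempted, because the data formats the package reads all use these units.

## BLQ handling in the trapezoid

How BLQ samples enter the AUC is the single most consequential policy in
sparse NCA, and reporting conventions differ between tools. The package
default, `blq_rule = "zero_through_first_blq"`, is:

* BLQ observations contribute concentration 0;
* integration starts at the profile's first *sampled* time (no time-zero
  point is imputed for subjects first sampled at 2 h);
* integration extends through the **first** BLQ sample after the last
  quantifiable observation, then stops;
* segments with BLQ at both ends contribute nothing.

This is the unique simple scheme under which the bundled study's six
per-rat AUClast values (40.78, 38.63, 29.7, 11.4, 25.3 and 22.6 mg·h/L) are
all reproduced exactly from the raw concentrations, which is why it is the
default. It is *documented behaviour inferred from the data*, not a
universal standard: two alternatives are available behind the same flag,
`"drop_blq"` (discard BLQ points and integrate quantifiable samples only)
and `"loq_half"` (replace BLQ by LOQ/2, the classical Beal substitution),
for sensitivity analyses.

```{r}
profiles <- sci_study_profiles()
integrate_trapezoid(profiles[["1"]])$auclast_mg_h_per_L
```

## Terminal-phase regression and the fixed-K escape hatch

`fit_lambda_z()` fits ordinary least squares of ln(concentration) on time.
The automatic window selector is deterministic: among all contiguous runs of
quantifiable points that end at the last quantifiable observation and start
at or after Tmax, it picks the run with the best adjusted R², preferring
runs of at least three points (a two-point run is used only when nothing
longer exists) and breaking ties in favour of more points. When Tmax *is*
the last quantifiable observation no terminal window exists; the trailing
quantifiable run is fitted and flagged non-declining if it rises, rather
than raising an error, so that batch runs degrade gracefully to partial
results.

The terminal rate constants reported with the bundled dataset (2.521,
0.01387, 0.0276, 0.9102, 0.161, 0.2861 and pooled 0.0689 h⁻¹) cannot be
reproduced by *any* contiguous-window log-linear regression on the shipped
concentrations — for rat 1 the terminal quantifiable segment is rising, and
for the others no window yields the reported slope. Their point selection is
undocumented and was not guessed. They are therefore shipped as data
(`sci_reference_k()`), accepted as fixed inputs
(`nca_config(lambda_z_mode = "fixed", fixed_k = ...)`) when reproducing the
reported parameter tables, and `lambda_z_divergence()` tabulates how far the
automatic fits sit from them. All derived parameters downstream of K are
pure arithmetic, so with the reference K values every reported Vd, CL,
T0.5e and MRT cell is recovered.

## The derived-parameter chain

Two choices deserve justification:

* **MRT = 1/K.** The moment-based estimator AUMClast/AUClast is the textbook
  noncompartmental MRT, but every reported MRT value of the bundled study
  equals 1/K exactly (e.g. 1/0.01387 = 72.09 h), so 1/K — the
  one-compartment steady-state residence time — is the default, and the
  moment estimator is offered as `mrt_method = "aumc"`, clearly labelled as
  the alternative.
* **ln 2 at full precision.** The half-life uses `log(2)` = 0.693147…, which
  matches the reported per-rat half-lives better than the truncated literal
  0.693 (0.693147/2.521 = 0.27495 → 0.2749); the literal is available as
  `ln2_constant = 0.693` for matching legacy reports.

The chain identities `t_half * K = ln 2`, `mrt * K = 1`,
`vd * K * auclast = dose` and `cl = K * vd` hold to floating-point accuracy
for every complete result the package emits, and are asserted as properties
in the test suite.

## Pooled mean profiles

For staggered designs the group-level curve is assembled by
`pooled_mean_profile()`: the time grid is the union of all sampled times and
the concentration at each time is the mean over the subjects actually
sampled there, counting BLQ as 0; the pooled dose is the mean dose. An
optional `rounding_dp` rounds the means (half away from zero) *before*
integration: the bundled study's reported pooled AUClast (23.47 mg·h/L) was
evidently computed from means rounded to two decimals — unrounded means give
23.50 — so reproducing it requires `rounding_dp = 2`. Rounding is off by
default because full precision is the better default for new analyses;
rounding at the reporting layer only is the package-wide rule everywhere
else.

## Group summaries

`summarize_values()` reports mean, SEM (sample standard deviation over
√n) and a symmetric two-sided interval mean ± q·SEM. The quantile q is
Student t on n−1 degrees of freedom by default: with n = 3 per subgroup,
q = 4.3027, which is exactly the ratio the bundled study's printed intervals
bear to their SEMs, confirming t rather than normal quantiles were used
(`method = "normal"` is available). Bounds are reported as computed — a
negative lower bound for a nonnegative quantity like Vd is not truncated,
preferring fidelity to cosmetics.

## The synthetic-data generator

`simulate_profile()` and `generate_study()` produce study-like datasets with
known ground truth from a one-compartment first-order-absorption model with
a zero-order endogenous input:

$$C(t) = \frac{F D k_a}{V_d (k_a - k_e)} \left(e^{-k_e t} - e^{-k_a t}\right)
       + \frac{R_0}{V_d k_e} \left(1 - e^{-k_e t}\right),$$

with the k_a = k_e case replaced by its analytic limit
$F D k_a t e^{-k_a t} / V_d$. The first term is the Bateman curve; the
second is the approach to the endogenous plateau $R_0/(V_d k_e)$ from a zero
baseline. Measurement error is lognormal multiplicative
(σ² = log(1 + CV²)), chosen over additive noise so simulated concentrations
stay nonnegative; values below the LOQ are censored to BLQ/0, mirroring how
the real dataset reports them, rather than dropped.

Default parameters (`sim_params()`: dose 3.92 mg, k_a = 1.2 h⁻¹,
k_e = 0.45 h⁻¹, V_d = 0.35 L, F = 1, R_0 = 0, LOQ = 0.1 mg/L, CV = 0.2)
are chosen so the noise-free curve peaks near 6 mg/L around 1.3–1.5 h and
falls below the LOQ by 12 h, visually mimicking the bundled study's mean
profile. They are **illustrative, not estimates**: no model was fitted to
the study data (that is an explicit non-goal). R_0 defaults to 0 because the
study measured 0 mg/L at baseline; the endogenous term exists for
sensitivity studies. `generate_study()` defaults reproduce the study
conditions — six subjects in two staggered subgroups of three, body weights
drawn from a normal distribution centred at 392 g (the study's mean weight)
with SD 24 g (its observed spread), doses of 10 mg/kg rounded to two
decimals as dosing records are.

What the simulator deliberately does **not** emulate: between-subject
kinetic variability (all subjects share one parameter set unless the caller
varies it), absorption-phase irregularities such as double peaks or lag
times, assay heteroscedasticity beyond constant CV, and enterohepatic or
conversion processes. Passing recovery tests therefore demonstrates that the
*pipeline arithmetic* is faithful under the stated model, not that the model
captures everything in real rat data.

## Validation by parameter recovery

`recovery_experiment()` closes the loop: simulate under known kinetics, run
the full NCA pipeline, compare. The test suite runs it at three scales,
chosen to keep the whole suite fast while leaving no question unprobed:

* noise-free, 30-point grid to ten half-lives: the fitted K must land within
  1% of the true k_e and the trapezoidal AUClast within 2% of the
  closed-form integral (`analytic_auc()`);
* 200 noisy replicates (CV 0.2) regressed over the genuinely log-linear
  6–16 h span: the mean fitted K must sit within Monte-Carlo error (three
  standard errors of the replicate mean) of the truth — the window is fixed
  there because data-driven window selection is itself a biased procedure
  on noisy data and would confound the centring check;
* 50 replicates each on the study's sparse staggered grid versus a dense
  grid: the sparse design must show the larger root-mean-square error in K,
  quantifying what the staggered design costs.

## Numerical choices and edge cases

* Times are compared exactly; no tolerance merging of near-duplicate times.
* Cmax ties break to the earliest time.
* Reported values are rounded half away from zero (`round_half_away()`)
  only at the reporting layer; all internal arithmetic is full precision.
* An all-BLQ profile yields Cmax 0 with a warning and an incomplete NCA
  result, never an exception; a profile with no declining phase yields
  Cmax/Tmax/AUClast with K and its descendants `NA`.
* `read_concentration_table()` rejects duplicate (subject, time) pairs and
  negative times or concentrations by name; BLQ may be spelled `BLQ`,
  `<LOQ`, or `0` with a logical `blq` column.

## Known limitations

* AUC extrapolation to infinity (AUCinf, %extrapolated) is not implemented;
  the bundled study reports AUClast only.
* The automatic lambda-z selector considers contiguous windows only; tools
  that drop interior points can reach different fits.
* Vd and CL are per-animal litres and L/h, not weight-normalised — the
  dimensional convention the bundled study's values satisfy.
* No hypothesis testing between subgroups is provided (none was required);
  `summarize_table()` is descriptive.
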