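---
title: "Methods: TTD effects on DCD liver utilization and outcomes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: TTD effects on DCD liver utilization and outcomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dcdlivers)
```

# Scope and definitions

The package analyzes donation-after-circulatory-death (DCD) liver
registries around three warm-ischemia intervals, all in minutes:

* **TTD** — withdrawal of life-sustaining treatment (WLST) to asystole;
* **asystolic time** — asystole to abdominal aortic cold flush;
* **FTTD** — systolic blood pressure first below 50 mm Hg to cold
  flush.

Recovery pathway is inferred from asystolic time: donors more than 30
minutes from asystole to flush are classified as normothermic regional
perfusion (NRP), since in-situ perfusion ends at the cold flush; 30
minutes or less is super-rapid recovery (SRR). The boundary value is
SRR. FTTD as implemented runs to cold flush and therefore subsumes the
asystolic interval; whether it should instead end at asystole is
genuinely ambiguous in the field's printed definitions, so
`derive_times()` computes it as printed and the choice is isolated in
one place.

TTD strata are half-open `[lo, hi)` with default edges 0, 10, 15, 30,
45 minutes. Labels such as "15–30" are ambiguous at shared endpoints;
the boundary is assigned to the upper stratum (15.0 min is "15–30"),
configurable via `cohort_spec()`.

Outcome definitions: 1-year graft survival is a composite of graft loss
or death, truncated administratively at the horizon; early graft loss
is graft loss within 30 days; length of stay is analyzed as
time-to-discharge, with discharge the event, censored at 90 days and at
death or graft loss before discharge. In the time-to-discharge Cox
model a *higher* hazard means a *shorter* stay; the direction is
deliberate and documented here because it is the reverse of the usual
harm reading. The 90-day cap is applied before any horizon truncation.

# Models

Continuous predictors with plausibly nonlinear effects enter as
restricted cubic splines with 4 knots at the 5th/35th/65th/95th sample
percentiles (linear interpolation between order statistics, `quantile`
type 7). The basis is the truncated-power natural-spline basis: column
one is the variable, and the `k − 2` nonlinear columns are normalized
by `(t_k − t_1)²` so all coefficients live on the scale of the
predictor. The implied fit is linear beyond the boundary knots with
continuous value, first and second derivatives. Knots are computed on
the analysis cohort of the specific model (outcome models on
transplanted recipients, utilization models on all donors), for
internal consistency. A spline block is reported as a single joint Wald
test `βᵀV⁻¹β ~ χ²(df)`; a singular covariance submatrix is an error
naming the aliased terms rather than a silent generalized inverse.

Effect curves divide out a reference value: the log ratio at `x` is the
basis contrast `(b(x) − b(x_ref))·β`, with a delta-method standard
error from the same contrast, so all additive terms cancel and only the
spline block's pooled covariance is needed. The default reference is
the first knot for utilization curves; outcome-model references are set
by the analyst and always printed. Curves are reference-free up to a
multiplicative rescaling, which the tests assert. Grid points outside
the 1st–99th percentile of the training values are returned but
flagged as extrapolation.

Right-skewed continuous covariates not splined are log2-transformed, so
effects are per doubling. A nonpositive value under log2 is a hard
error citing the `offset` option; silently shifting a lab scale is a
decision the analyst must own.

Cox models use the Efron tie approximation (registry times have day
granularity; ties are the norm). One-year and five-year analyses are
administrative truncations of follow-up at the horizon. Degenerate
inputs fail loudly: no events, a one-class binary outcome, or a
constant encoded column are errors naming the offending piece;
separation-like behavior (monotone partial likelihood, or logistic
coefficients beyond ±15) is flagged with a warning rather than an
error, since downstream pooling may still be meaningful. Center-level
frailty terms are not implemented; the fixed covariate set is the
contract, and a center identifier can be added as a categorical
covariate for sensitivity.

# Multiple imputation

Missing covariates are imputed by predictive mean matching (PMM), `m =
20` datasets by default. For each imputation and target variable the
predictive model — additive, with 3-knot restricted cubic splines for
continuous predictors — is refit on a bootstrap resample of the rows
with the target observed, which propagates model uncertainty between
imputations without explicit posterior draws. Each missing entry is
filled by sampling uniformly among the `k_pmm = 3` observed rows with
the closest predictions, so imputed values always belong to the
observed support. `k_pmm` and the match metric are not dictated by any
published default; 3-with-random-draw is a standard compromise between
bias (large k) and over-reuse of single donors (k = 1).

Outcome-aware auxiliaries keep imputations compatible with the analysis
model: for survival outcomes, the event indicator and the Nelson–Aalen
cumulative hazard `Ĥ(t) = Σ d_i/n_i` evaluated at each record's time;
for utilization models, the utilization flag. TTD and asystolic time
are never imputed — records missing the primary exposures are excluded
during cohort assembly, and both `inject_missingness()` and
`impute_pmm()` refuse to touch them.

Simplifications relative to full canonical-variate PMM machinery, all
deliberate: predictor missingness is median/mode-filled inside the
imputation design only; targets must be numeric, logical or two-level
categorical; targets do not predict one another. These keep the
imputer auditable; the MCAR coverage test (200 replicates) checks that
pooled 95% intervals cover at their nominal rate despite them.

Pooling follows Rubin's rules: pooled coefficients are means, pooled
covariance is `W + (1 + 1/m)B` with `W` the mean within-imputation
covariance and `B` the between-imputation covariance of the estimates.
Wald references are large-sample chi-square/normal — at registry scale
the small-sample degrees-of-freedom corrections are immaterial. Spline
group tests under multiple imputation are computed single-step from the
pooled coefficient vector and pooled covariance rather than by D1/D2
pooling; this is recorded as a limitation, and the pooled objects
expose everything needed to apply another rule. Knots and factor levels
are realized once (on the first completed dataset) and shared across
all `m` fits, since pooling requires identical term definitions.

# The counterfactual simulation

Within the SRR cohort, a logistic utilization model *excluding any TTD
term* is fitted to the reference stratum (TTD < 10 min) and applied to
each donor in a target stratum (15–30 or 30–45 min). The predicted
acceptance rate is the mean predicted probability (standardization over
the target covariate distribution); the absolute increase is predicted
minus actual in percentage points; the relative increase divides by the
actual rate; extra livers = stratum size × absolute increase / 100,
reported unrounded and rounded half-up.

Confidence intervals are percentile bootstrap, default 10,000
replicates: donors are resampled with replacement within the reference
and target strata independently (the strata play asymmetric roles, and
joint resampling would let stratum sizes fluctuate for no inferential
gain), the reference model is refit in full each replicate, and
interval endpoints are nearest-rank order statistics at the 2.5th and
97.5th percentiles. Spline knots and factor levels are frozen at their
full-data values across replicates. Replicates with a one-class
resample or a non-converged refit are counted as degenerate and
dropped; more than 5% of them is an error unless explicitly overridden.
A factor level present in the target but unseen in the reference
stratum is assigned the reference-level effect and counted in the
output.

When the pipeline runs under multiple imputation, the counterfactual is
computed on the first completed dataset; nesting the 20 imputations
inside 10,000 bootstrap replicates is supported by calling
`counterfactual_analysis()` per dataset but is off by default for cost,
and on this package's synthetic registries the donor-level missingness
rates are low enough that the choice is immaterial to the intervals'
order of magnitude.

# The synthetic registry and its truth

`generator_config()` defaults describe the study conditions the
analysis presumes:

* TTD log-normal with median exactly 13 min and interquartile *width* 8
  min (`sdlog = 0.4493`, quartiles 9.6/17.6). A log-normal cannot match
  median 13 and quartiles 9 and 17 simultaneously (9 × 17 ≠ 13²), so
  the median is matched exactly and the IQR width approximately.
* 9.6% of donors on the NRP pathway, with asystole-to-flush times
  log-normal around 12 min (SRR) and 60 min (NRP), so the 30-minute
  classification rule approximately recovers the pathway.
* Utilization logit flat for short TTD, declining linearly by
  0.065/min between 15 and 45 min, flat beyond. The decline window
  starts at 15 because the emulated utilization drop begins after the
  10–15 min range; the logit between 10 and 15 is therefore flat,
  which also makes the <10 min reference stratum exactly
  representative of TTD-free decision-making. The slope and the
  baseline rate (34.5% at reference covariates) were chosen once to
  place the stratum acceptance rates in a clinically plausible range,
  and are configurable.
* Utilization covariate effects linear in donor age, donor BMI and
  log2 peak ALT — scales on which the generated covariates are
  Gaussian. That restriction is what makes the analytic truth exact:
  the covariate score is Gaussian, so every population acceptance rate
  is a logistic-normal integral evaluated by Gauss–Hermite quadrature
  (60 nodes), and the stratum-conditional TTD law is integrated by
  equal-probability quantile quadrature (512 slices). No sampling is
  involved, so `truth_summary()` is seed-invariant, as the tests
  require.
* Graft-loss composite exponential, baseline tuned to ~90% 1-year
  graft survival, with a short-TTD log-hazard penalty fading linearly
  to zero at 10 min (ischemic injury accrued before death) and *no*
  prolonged-TTD penalty — the asymmetry whose consequences the package
  exists to quantify. Censoring is independent: uniform administrative
  censoring between 1 and 5 years (staggered entry with a guaranteed
  1-year minimum follow-up) plus a 10% early-loss rate.
* Skewed labs are log-normal so the downstream log2 rule is
  meaningful; missingness is missing-at-random with logistic dependence
  on always-observed variables, intercept calibrated by root-finding so
  marginal rates match the request exactly in expectation.

What the generator does **not** emulate — and what green tests
therefore do not establish about real registries: the joint covariate
distribution (covariates are independent given nothing), organ-offer
sequencing and center-level clustering, informative censoring,
pathway-dependent utilization curves, and any particular national
cohort's effect sizes. The generator's role is parameter recovery:
known truth in, estimate out.

# Numerical and testing choices

Determinism: one seed drives everything; pipeline stages derive fixed
offsets from it, so reruns are bit-identical (asserted on the emitted
JSON/CSV). Monotonicity of the estimated extra livers in the injected
decline is tested under common random numbers: utilization is drawn by
comparing one uniform draw per donor against the logit, so raising the
decline can only flip acceptances off.

Problem sizes in the test suite are the package's own choices for tight
feedback at sound power: calibration and recovery studies run 200
simulated registries of 3,000 donors with 500 bootstrap replicates
each; the type-I calibration of the spline Wald test runs 200
replicates of 1,500-donor registries with an inflated event rate
(~30%/year) so the 3-df Wald asymptotics are trustworthy at that size;
the demo pipeline in `scripts/acceptance.R` uses 20,000 donors, 10
imputations and 2,000 bootstrap replicates. The full-scale defaults
(41,443 donors, 20 imputations, 10,000 replicates) remain the
function defaults.

Known limitations, beyond those above: the single-step pooled spline
test; no competing-risks treatment of graft loss versus death; no
penalized or adaptive splines; the counterfactual adjusts only for the
covariates it is given — it is covariate standardization, not a causal
model of offer behavior.
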