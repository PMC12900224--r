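# dcdlivers

Donor warm-ischemia timing and liver transplantation after circulatory
death (DCD): survival and utilization modeling under multiple
imputation, and a counterfactual estimate of the livers lost to
time-to-death-based decline.

## The problem

When life-sustaining treatment is withdrawn from a potential DCD donor,
the interval from withdrawal to asystole — the **time to death (TTD)** —
is widely used by transplant teams as a proxy for warm-ischemic injury,
and livers from donors with prolonged TTD are frequently declined.
Whether that practice is justified is an empirical question with three
parts:

1. **Outcomes.** Does donor TTD actually predict recipient graft
   survival, patient survival, early graft loss, or hospital length of
   stay, after adjustment? TTD enters the models as a restricted cubic
   spline (4 knots at the 5th/35th/65th/95th percentiles), because the
   association is plausibly nonlinear: the modeled log hazard is
   `h(x) = β₁x + β₂s₂(x) + β₃s₃(x)` with `s_j` the truncated-power
   natural-spline terms, and the spline block is tested jointly by a
   Wald chi-square.
2. **Utilization.** How does the probability that a recovered liver is
   transplanted fall with TTD, adjusting for everything else known
   about the donor?
3. **The counterfactual.** If offers from donors with prolonged TTD
   (15–30 or 30–45 min) were evaluated the way short-TTD (<10 min)
   offers are, how many additional livers would be accepted? This is
   standardization (G-computation): fit a TTD-free logistic utilization
   model on the reference stratum, average its predicted probabilities
   over the target stratum's donors, and compare with the observed
   acceptance rate. Percentile-bootstrap resampling (10,000 replicates
   by default) gives confidence intervals; the absolute increase in
   percentage points times the stratum size is the count of extra
   livers.

Registry extracts with the required donor timing data are not public,
so the package ships a **synthetic donor-registry generator** whose
generating truth (utilization logits, graft hazards, missingness
mechanism) is known and whose counterfactual truth is computed
analytically (`true_counterfactual()`). Every pipeline stage — cohort
rules, splines, predictive-mean-matching multiple imputation with
Rubin's-rules pooling, Cox/logistic models, the bootstrap — is tested
against that truth.

## Worked example

Generate a registry of 10,000 potential donors, assemble the
utilization cohort, and ask what super-rapid-recovery (SRR) offers with
TTD 15–30 min would yield if evaluated like TTD <10 min offers:

```r
library(dcdlivers)

reg     <- generate_registry(generator_config(n_donors = 10000, seed = 2))
cohorts <- apply_inclusion(reg$donors, reg$transplants)
srr     <- subset(cohorts$utilization, pathway == "SRR")

spec <- counterfactual_spec(
  reference = c(0, 10), target = c(15, 30), reps = 2000, seed = 2,
  covariates = list(covariate("donor_age", "linear"),
                    covariate("donor_bmi", "linear"),
                    covariate("peak_alt", "log2")))
counterfactual_analysis(srr, spec)
#> Counterfactual utilization, TTD [15, 30) evaluated as TTD [0, 10)
#>   donors in target stratum: 3158 (accepted: 869)
#>   actual acceptance rate: 27.5%
#>   predicted acceptance rate: 35.1 (33.1-37.0)%
#>   absolute increase: 7.5 (5.1-10.1) percentage points
#>   relative increase: 27.4 (18.1-37.8)%
#>   extra organs: 238.4 (162.2-318.6) [rounded: 238]
#>   bootstrap: 2000 replicates (0 degenerate), seed 2
```

Reading the output: of 3,158 target-stratum donors, 869 livers (27.5%)
were actually accepted; had those offers been evaluated like reference
offers the model predicts 35.1% acceptance, i.e. 7.5 extra acceptances
per 100 donors, or about 238 extra livers in this registry. The
generator's analytic truth for this configuration is 194 extra livers,
inside the bootstrap interval.

`run_pipeline()` chains every stage (generation or CSV input, cohort
assembly, missingness injection and PMM multiple imputation, pooled Cox
graft-survival and logistic utilization models with spline effect
curves, Kaplan–Meier data, and the counterfactual) and writes all
artifacts — manifest, publication-style model tables, effect-curve and
KM CSVs, exclusion log, counterfactual JSON — to an output directory,
reproducibly from one seed.

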