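# pmvcea

Lifetime cost and cost-per-QALY estimation for prolonged-mechanical-
ventilation (PMV) cohorts — patients ventilator-dependent beyond 21
consecutive days, followed from day 21.

Registry follow-up for such cohorts is short (about ten years) and
heavily censored, but the quantities that matter to insurers, families
and policy are *lifetime* quantities: life expectancy (LE),
quality-adjusted life expectancy (QALE), lifetime insurer-paid and
out-of-pocket cost, and cost per QALY. pmvcea implements the full
estimation chain for biostatisticians and health economists working with
censored cohort data plus small cross-sectional surveys.

## What it computes

With `S(t)` the cohort survival and `S_ref(t)` the survival of an age-
and sex-matched reference population built from a national life table,
the survival ratio `W(t) = S(t) / S_ref(t)` has an approximately linear
logit in `t` under a constant excess hazard. The package:

1. estimates `S(t)` on follow-up by Kaplan-Meier;
2. builds `S_ref(t)` from the life table (exact expectation by default,
   Monte-Carlo referents optionally);
3. fits `logit W(t) = a + b t` by OLS over the latter half of follow-up
   and extrapolates `S(t) = S_ref(t) * expit(a + b t)` (continuity-
   spliced, monotone-clamped) to a 300-month horizon;
4. computes `LE = sum S(t)/12`, `QALE = sum S(t) q(t)/12` with `q(t)` a
   proximal-10% nearest-neighbour moving average of cross-sectional
   EQ-5D utilities (separately for partial and poor cognition), and
   `lifetime cost = sum c(t) S(t)` with `c(t)` the mean monthly cost
   among survivors (CPI-adjusted insurer claims; kernel-smoothed
   out-of-pocket survey);
5. reports `CER = lifetime cost / QALE`, banded against 1x and 3x GDP
   per capita (WHO-CHOICE);
6. groups patients by age-stratified latent class analysis of binary
   comorbidity indicators (Bernoulli-mixture EM, BIC selection);
7. attaches bootstrap standard errors (100 patient-level resamples,
   surveys resampled alongside) and validates the extrapolation by
   truncating follow-up and comparing against the full-data
   Kaplan-Meier restricted mean.

A synthetic-data generator with known ground truth (Gompertz-Makeham
background mortality, planted constant excess hazard, planted utility,
cost and latent-class structure) stands in for confidential claims data
and drives all tests.

## Worked example

```r
library(pmvcea)

scenario <- simulation_scenario()        # n = 2000, seeded defaults
cohort   <- simulate_cohort(scenario)
survey   <- simulate_utility_survey(scenario, cohort)
costs    <- simulate_costs(scenario, cohort)

cfg <- run_config(cohort, attr(cohort, "truth")$life_table, survey,
                  costs$claims, costs$oop_survey,
                  cpi_factors = scenario$cpi_factors, n_boot = 0,
                  seed = 2)
run_full_analysis(cfg)
#> <cer_report> 1 group(s), horizon 300 months
#>   group_label n_cases life_expectancy_years qale_partial qale_poor
#> 1   synthetic    2000                 3.003        1.045    0.3127
#>   lifetime_total cer_partial cer_poor
#> 1          68157       65241   217990
```

Read: an average patient in this synthetic cohort lives 3.00 more years
from day 21 of ventilation; weighting survival by measured quality of
life gives 1.05 QALYs if cognition is partial and 0.31 if poor; the
survival-weighted lifetime cost is 68,157 USD, i.e. 65,241 USD per QALY
(partial cognition) — "not cost-effective" against 3x a GDP per capita
of 18,588 USD — and 217,990 USD per QALY under poor cognition. The
planted truth behind this cohort is a 2.91-year life expectancy, so the
extrapolation error here is about +3%.

```r
validate_extrapolation(cohort, truncate_at = 48, evaluate_to = 120,
                       table = attr(cohort, "truth")$life_table)
#> <validation_report> truncate 48m -> evaluate 120m (rmst)
#>   extrapolated 2.7522 vs full-KM 2.8847; relative bias -4.59%
```

The numbered scripts under `analysis/` run the same flow as a narrative:
`01_simulate.R` writes the synthetic inputs, `02_survival_extrapolation.R`
fits and extrapolates survival, `03_cer_report.R` produces the
latent-class-grouped CER report with bootstrap SEs, and
`04_validation.R` runs the truncate-and-extrapolate validation and the
published-arithmetic checks; outputs land under `results/`.

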