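# ttcjm

Joint longitudinal-survival modelling of drug trough concentrations and
progression-free survival (PFS), built for exposure-response analysis of
oral targeted anticancer agents under therapeutic drug monitoring — the
motivating case is the ALK inhibitor alectinib in non-small-cell lung
cancer.

## What it does

Plasma samples drawn at routine visits are extrapolated to trough
concentrations (log-linear decay to the next scheduled trough, half-life
32 h, twice-daily dosing) and normalized onto a bounded 0-100 scale, the
*transformed trough concentration* (TTC), through a sigmoid Emax curve

    TTC = C^γ / (EC50^γ + C^γ) × 100,        EC50 = 600 ng/mL, γ = 1.5,

with γ calibrated so the TTC is approximately Gaussian. Exposure-response
is then analysed three ways, from simplest to most structured:

1. **Kaplan-Meier / Cox baselines** — per-patient median exposure as a
   continuous (median TTC) or dichotomized (median trough ≥ 435 ng/mL)
   covariate, plus reverse-KM median follow-up;
2. **Time-dependent Cox** — the current exposure carried forward between
   measurements (LVCF) in counting-process form, with backward elimination
   of baseline covariates at p < 0.05;
3. **Bayesian joint model** — a linear mixed-effects sub-model for each
   patient's TTC trajectory m_i(t) (random intercept and slope, dose at
   sampling as a categorical covariate) coupled to the hazard

       h_i(t) = h0(t) · exp( φᵀw_i + α_c · m_i(t) + α_a · m̄_i(t) ),

   where m̄_i(t) is the running average (1/t)∫₀ᵗ m_i. The three association
   structures — current value, average exposure, and their combination —
   are compared by WAIC and LPML. Estimation is by adaptive
   Metropolis-within-Gibbs with a piecewise-constant baseline hazard and
   Gauss-Legendre cumulative-hazard quadrature; coefficients are reported
   as hazard ratios per TTC unit with 95% credible intervals.

A synthetic cohort generator (`generate_cohort()`) emulates the study
design the pipeline targets — 100 patients, ~569 samples (median 5 per
patient, range 1-17), published covariate frequencies, dose reductions,
~46 progression events over a ~3-year follow-up — with known ground truth,
so the whole pipeline is validated by parameter recovery. See the methods
vignette (`vignettes/exposure-response-joint-models.Rmd`) for the model,
priors, numerical choices, and what the synthetic validation does and does
not show.

## Worked example

One TTC unit translated back to concentrations, at the default transform:

```r
library(ttcjm)
p <- sigmoid_params()            # EC50 600 ng/mL, gamma 1.5
ttc(350, p)                      # 30.8
unit_increase_equivalent(350, p) # 361.2  -> one TTC unit above 350 is ~361 ng/mL
```

A full analysis on a simulated cohort (the generator's default truth is a
pure average-exposure effect, HR 0.891 per TTC unit):

```r
cfg <- pipeline_config(models = c("km", "cox", "tdcox"), seed = 2024)
res <- run_pipeline(cfg)
print(res, digits = 3)
#> Median PFS 27.3 months; median follow-up 40.1 months
#>               model             variable    hr ci_low ci_high     p waic lpml
#>     Cox categorical exposure_catadequate 0.271  0.152   0.484 0.000   NA   NA
#>     Cox categorical           prior_alki 1.512  0.853   2.682 0.157   NA   NA
#>      Cox continuous           median_ttc 0.933  0.910   0.956 0.000   NA   NA
#>      Cox continuous           prior_alki 1.369  0.798   2.349 0.255   NA   NA
#>  TD-Cox categorical exposure_catadequate 0.182  0.101   0.326 0.000   NA   NA
#>  TD-Cox categorical           prior_alki 1.379  0.800   2.375 0.247   NA   NA
#>   TD-Cox continuous                  ttc 0.929  0.909   0.950 0.000   NA   NA
#>   TD-Cox continuous           prior_alki 1.549  0.893   2.686 0.119   NA   NA
```

Adding `"joint"` to `models` appends the three joint models (current
value, average exposure, combined) with WAIC/LPML columns filled; each row
reports the posterior-median hazard ratio per TTC unit. A single joint fit
directly:

```r
co  <- generate_cohort(seed = 7)                  # 100 patients, ~46 events
rec <- as_longitudinal_records(transform_troughs(co$longitudinal))
fit <- fit_joint(rec, co$survival,
                 jm_spec("current_plus_average", chains = 2,
                         warmup = 500, draws = 1000), seed = 7)
print(fit)
```

which prints the cohort dimensions, WAIC/LPML, the maximum split-R-hat,
and the hazard-ratio table; `(1 - HR) × 100` is reported as the percent
risk reduction per TTC unit, so an HR of 0.891 reads as an 11% lower
progression risk per unit of average TTC.

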