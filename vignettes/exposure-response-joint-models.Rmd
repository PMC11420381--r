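---
title: "Joint modelling of trough concentrations and progression-free survival"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modelling of trough concentrations and progression-free survival}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Oral targeted anticancer agents such as the ALK inhibitor alectinib are dosed
at a fixed label dose, yet plasma exposure varies several-fold between
patients. Whether patients with low trough concentrations progress earlier is
the central question of exposure-response analysis in therapeutic drug
monitoring (TDM). The standard tools — Cox models on a per-patient summary of
exposure, or time-dependent Cox models with the last measured value carried
forward (LVCF) — use the noisy measured concentrations directly and ignore
that exposure is an error-prone, irregularly sampled longitudinal process.
Joint models address both problems: a linear mixed-effects (LMM) sub-model
describes each patient's smooth underlying exposure trajectory, and a
survival sub-model lets the hazard of progression depend on features of that
trajectory. `ttcjm` implements this pipeline end to end, together with a
synthetic cohort generator with known ground truth, so that every stage can
be validated by parameter recovery rather than against an unavailable
patient-level dataset.

## From plasma samples to the longitudinal outcome

Samples drawn at routine visits are rarely troughs. With the time since the
last intake $t_{sld}$ (hours), the dosing interval $\tau = 12$ h (twice-daily
dosing) and the elimination half-life $t_{1/2} = 32$ h, each measured
concentration is decayed log-linearly forward to the next scheduled trough:

$$C_{trough} = C_{obs} \cdot 2^{-\Delta/t_{1/2}}, \qquad
  \Delta = (\tau - (t_{sld} \bmod \tau)) \bmod \tau .$$

Two conventions are deliberate. The decay runs *forward to the next trough*
(the concentration immediately before the next intake, the conventional TDM
trough), so a sample taken at trough is returned unchanged. Times beyond one
interval — late or missed intakes — are reduced modulo the interval, which
keeps the estimate a trough without modelling adherence; a consequence is
that $t_{sld} = 0$ is congruent to an at-trough sample and is also returned
unchanged. Because alectinib's half-life is long relative to the dosing
interval, the peak-trough ratio is small and this log-linear extrapolation is
an adequate substitute for population-PK trough estimation, which is out of
scope.

Troughs are right-skewed and bounded below, so they enter the models through
a sigmoid Emax (Hill) transform, the *transformed trough concentration*:

$$TTC = \frac{C^{\gamma}}{EC_{50}^{\gamma} + C^{\gamma}} \times 100 .$$

The transform normalizes the data (an LMM working assumption) and encodes
the pharmacological saturation of effect above the therapeutic range:
doubling a high concentration does not double the response. The defaults are
$EC_{50} = 600$ ng/mL — slightly above the 435 ng/mL efficacy target used to
dichotomize exposure — and $\gamma = 1.5$. The steepness is not a published
constant: it is fixed empirically so the TTC is approximately Gaussian
(`calibrate_gamma()` scores a grid of candidates by the Shapiro-Wilk W of
the transformed sample, breaking ties toward the smaller, flatter value).
The default 1.5 is the value implied by the printed unit-increase pairs: with
$EC_{50}=600$, requiring one TTC unit between troughs of 600 and 617 ng/mL
gives $\gamma = \log(51/49)/\log(617/600) \approx 1.43$, and under that curve
one unit above 350 ng/mL is 361 ng/mL; $\gamma = 1.5$ reproduces the same
pairs to three significant figures. Sensitivity presets $EC_{50} \in \{500,
700\}$ and $\gamma = 2$ are available through `sigmoid_params()`. These
values should be read as a normalization device, not as an estimated
concentration-effect relationship. All times are in months (1 month =
30.4375 days).

## The two sub-models and their coupling

The longitudinal sub-model (`fit_lmm()`, maximum likelihood via `lme4`) is

$$y_{ij} = (\beta_0 + b_{0i}) + (\beta_1 + b_{1i})\,t_{ij}
  + \beta_d[\mathrm{dose}_{ij}] + \varepsilon_{ij},$$

with correlated subject-level random intercepts and slopes and the dose at
sampling as a categorical covariate (reference = standard dose; the source
material does not say whether dose entered as milligrams or level, and the
level coding matches its categorical covariate handling). Patients with a
single sample are retained; their random effects shrink to the population
mean. If the random-effects covariance degenerates the model falls back to a
random intercept, with a warning. Each patient's trajectory $m_i(t)$ is then
piecewise-linear in time with a step of $\beta_d$ at each dose change,
evaluated left-continuously; between a patient's observed doses the level is
carried forward, and before the first sample the first value is carried
backward (exclusion of that interval is available in `expand_lvcf()`).

The survival outcome is progression-free survival (PFS): time from treatment
start to progression or death, censored otherwise. The joint model
(`fit_joint()`) links the two processes through the hazard

$$h_i(t) = h_0(t)\,\exp\!\big(\varphi^{T} w_i
  + \alpha_c\, m_i(t) + \alpha_a\, \bar m_i(t)\big), \qquad
  \bar m_i(t) = \tfrac{1}{t}\int_0^t m_i(s)\,ds ,$$

with three association structures: the *current value* ($\alpha_c$ only),
the *average exposure* ($\alpha_a$ only, the area under the TTC history
divided by time, computed in closed form per linear/stepped segment and
defined as $m_i(0)$ at $t=0$ by continuity), and their *combination*. The
time-dependent-slope structure is intentionally not implemented: it suits
biomarkers rather than the mechanism of action of an oral anticancer agent.
$w_i$ holds baseline covariates, by default prior ALK-inhibitor use, the one
covariate the backward-eliminated Cox models retain in the emulated study
design.

## Bayesian estimation choices

The source material specifies neither the baseline-hazard family, the
priors, nor the MCMC settings, so these are declared package choices:

* **Baseline hazard**: piecewise-constant on 5 intervals with knots at the
  observed event-time quintiles. This admits closed-form integration within
  pieces, an exact reduction to the piecewise-exponential model when the
  association is off, and a transparent dense-grid oracle in the tests. A
  spline baseline is a possible extension.
* **Cumulative hazard**: within each baseline piece, intersected with the
  patient's dose-change times, a fixed 15-node Gauss-Legendre rule
  (configurable, minimum 7). The integrand is smooth inside those segments,
  and the tests verify agreement with a dense midpoint-grid oracle to 1e-6.
* **Priors**: normal(0, 10^2) on all log-hazard-scale coefficients (baseline
  log-rates, covariate log-HRs, association coefficients per TTC unit);
  normal(0, 100^2) on the longitudinal fixed effects, which live on the TTC
  scale where an intercept near 45 is typical and a 10-SD prior would be
  unintentionally informative; half-t(3) priors on the three SDs (scales 25,
  5 and 10 for the random intercept, random slope and residual); uniform on
  the intercept-slope correlation (the 2x2 LKJ(1) prior).
* **Sampler**: adaptive Metropolis-within-Gibbs with blocks for the
  longitudinal fixed effects, all subject random effects (independent
  per-subject acceptance, plus a slope-only refresh), the residual SD, the
  random-effects covariance, the baseline log-rates, and the
  covariate/association coefficients. During warmup, proposal scales adapt
  toward 0.25-0.45 acceptance and the two coefficient blocks switch to
  empirical-covariance (Haario-type) proposals — the two association
  coefficients are strongly collinear and a diagonal walk mixes poorly.
  Two likelihood-invariant recentring moves shift mass between each fixed
  effect and its random effects to break the classic hierarchical ridges.
  Internally the hazard centres the TTC terms at the sample mean, which
  decorrelates the baseline log-rates from the association coefficients;
  the reported coefficients are unaffected. Chains initialize from the
  `fit_lmm()` and `cox_fit()` estimates, later chains with overdispersed
  starts. Defaults: 3 chains of 1000 warmup + 2000 kept draws; a seed is
  mandatory. Convergence is monitored by split-R-hat, with a warning when
  any association coefficient exceeds 1.05. The weakly identified
  random-slope SD mixes slowest; its R-hat can stay elevated at reduced
  settings while the association coefficients are stable.
* **Model comparison**: WAIC (smaller is better) and LPML (larger is
  better). The pointwise unit is the *subject* — the joint density of a
  subject's longitudinal and survival data — *conditional on the subject's
  random effects*. WAIC magnitudes depend on this convention; the marginal
  (integrated-random-effects) variant is out of scope, and printed WAIC
  values from other software are therefore not comparable.

## The baseline analyses

`km_fit()` (product-limit, Greenwood variance, log-log 95% CIs — the CI
method is unnamed in the source and log-log is the declared choice),
`reverse_km_followup()` (KM with the indicator flipped, estimating
follow-up), `cox_fit()` (Efron ties — more accurate than Breslow at monthly
resolution), `expand_lvcf()` + `td_cox_fit()` (counting-process LVCF Cox),
`dichotomize_exposure()` (adequate means median trough at or above the
435 ng/mL target, boundary included, dichotomized on the trough scale —
the source is ambiguous between trough and TTC scale here), and
`backward_eliminate()` (iterated removal of the worst candidate at
p >= 0.05, exposure always retained). The basic Cox models use the
per-patient median TTC (continuous) and median trough (categorical).

## The synthetic cohort generator

`generate_cohort()` is the package's test bed: it emulates the observable
structure of the study the pipeline targets — 100 patients, about 569
plasma samples with a per-patient count of median 5 in 1-17 (truncated
negative binomial, size 3, mean 5.65), Table-1 covariate frequencies (prior
ALK-inhibitor use 40%, male 47%, the published ECOG and prior-line
distributions), dose reductions over time, and roughly 46 progression
events over a follow-up whose reverse-KM median is near 3 years
(administrative censoring uniform on 18-54 months). Event times are drawn
exactly, by bisecting the cumulative hazard of the *true* trajectory to
1e-8 months, so the generator shares no quadrature code with the fitted
model. Observed concentrations are projected backward from the true trough
by a uniform 0-12 h offset, making trough extrapolation exact in the
noise-free limit. The default truth (TTC intercept 45, slope 0.05/month,
-8 TTC per dose reduction, random-effect SDs 12 and 0.3 with correlation
-0.2, residual SD 6) spreads the cohort across the 435 ng/mL target's TTC
image; the default association is a pure average-exposure effect of
log(0.891) per TTC unit with prior ALK-inhibitor use doubling the hazard.
The flat baseline rate is the one calibrated constant: it was fixed once,
by large-n simulation, so the default configuration reproduces the ~46/100
event fraction.

Deliberate simplifications: dose reductions happen only at 3-monthly
planned visits with probability 0.1 (the dose-adjustment process of the
real study is unpublished — these are placeholders); noise is additive
Gaussian on the TTC scale with no assay error structure, no adherence
lapses and no drug-drug interactions; noisy TTCs are clamped to
[0.5, 99.5] to stay invertible; sampling times are uniform over follow-up
rather than protocol-driven; weight and brain-metastasis distributions are
plausible but not published. Passing recovery tests on these cohorts shows
the estimator is consistent under its own assumptions — it cannot show
robustness to informative sampling, nonadherence, or model misspecification
in real data.

## Validation strategy and problem sizes

The test suite works at three levels. Exact oracles: Cox and TD-Cox partial
likelihoods against brute-force risk-set enumeration on toy datasets
(n <= 6); the joint likelihood against dense midpoint-grid integration; the
closed-form average exposure against 64-node quadrature split at dose
steps; the LMM against direct optimization of the multivariate-normal
marginal likelihood and the analytic conditional-mean (BLUP) formula.
Distributional checks: with the association off, generated event times
match the piecewise-exponential closed form (Kolmogorov-Smirnov at
n = 1000); covariate frequencies converge to the configuration. Recovery at
study scale: over 10 cohorts of 100 patients generated with a pure
average-exposure effect of log(0.891), the combined joint model's 95%
credible interval covers HR 0.891 in at least 8; with both associations
active the combined structure attains the smallest WAIC in the majority of
10 replicates of 150 patients — the generating effects are opposite in
sign (current value HR 1.25, average HR 0.78 per TTC unit), the one
pattern a single functional form cannot mimic, because same-sign pairs are
nearly collinear with either single form and the conditional-WAIC
Monte-Carlo noise then dominates the comparison; with both set to zero,
credible intervals cover HR 1 at
about the nominal rate over 20 replicates of 60 patients; and the LVCF
time-dependent Cox coefficient is attenuated toward zero relative to the
joint model's posterior mean, the measurement-error phenomenon that
motivates joint modelling in the first place. The MCMC checks run 2 chains
of 500 (or 400) warmup and 1000 (or 800) kept draws — enough for stable
association intervals, chosen so the whole suite completes in minutes;
convergence warnings at these settings are expected.

## Known limitations

Single longitudinal outcome only (no multivariate joint models); no
time-weighted (recency-weighted) association structure; no
proportional-hazards diagnostics, competing risks, or overall survival; no
dynamic individual prediction; the conditional-WAIC convention limits
comparability with marginal implementations; and the random-slope SD is
weakly identified at realistic sampling densities, which slows its mixing
without affecting the association estimates materially.
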