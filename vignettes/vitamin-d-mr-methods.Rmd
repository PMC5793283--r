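---
title: "Methods: a vitamin D genetic risk score as an instrument for cancer and mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: a vitamin D genetic risk score as an instrument for cancer and mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vitdmr)
```

## The question and the estimator

Observational cohorts often show an inverse association between circulating
25-hydroxyvitamin D (25OHD) and cancer incidence or mortality, but such
associations are easily confounded by adiposity, activity, diet and general
health. Mendelian randomization (MR) sidesteps much of that confounding by
using genotypes — fixed at conception and, to first order, randomly
assorted — as instruments for lifelong 25OHD exposure.

`vitdmr` implements the one-sample MR design used for this problem in large
women's cohorts:

1. **Instrument.** An unweighted allele-count genetic risk score (GRS) over
   five SNPs at three loci of the vitamin D pathway — DHCR7 (rs11234027,
   rs7944926), CYP2R1 (rs10741657, rs12794714) and GC (rs2282679) — counting
   at each SNP the number (0, 1, 2) of alleles associated with *higher*
   25OHD. The theoretical range is 0–10; a sensitivity variant excludes the
   GC SNP (range 0–8).
2. **First stage.** OLS regression of measured 25OHD (nmol/L) on the score
   in the biomarker subcohort gives the slope $\hat\beta_2$ (nmol/L per
   score unit), its $R^2$, and the single-predictor instrument-strength
   statistic $F = R^2 (n-2) / (1 - R^2)$.
3. **Outcome models.** Age-adjusted Cox proportional-hazards regressions of
   each endpoint (total, breast, colorectal and lung cancer; total and
   cancer mortality) on the score, continuously and in categories
   (0–5 reference, 6–7, 8–10), with Breslow handling of tied event times
   (Efron available behind a flag). The proportionality assumption is
   checked by the Schoenfeld-residual test with a rank transform of event
   time.
4. **Wald-ratio IV estimate.** For each endpoint,
   $\hat\beta_{IV} = s\,\hat\beta_1/\hat\beta_2$ with $s = 20$ nmol/L, and
   the first-order delta-method variance
   $SE_{IV}^2 = (s/\hat\beta_2)^2 SE_1^2 +
   (s\hat\beta_1/\hat\beta_2^2)^2 SE_2^2$, treating the two stages as
   independent. Exponentiation gives a ratio estimate per 20 nmol/L of
   genetically determined 25OHD with a 95% Wald CI. A "simple rescaling"
   variant multiplies $\hat\beta_1$ and $SE_1$ by $s/\hat\beta_2$, treating
   the slope as known; its SE is never larger than the delta-method SE.

The delta-method independence assumption matches the single-sample
convention even though the two stages here are estimated on nested samples
(subcohort ⊂ cohort); the correlation induced by the overlap is small
because the outcome fit is dominated by the ~92% of subjects outside the
subcohort.

Instrument strength is screened with the first-stage F: estimates computed
with $F < 10$ (or a first-stage $|\hat\beta_2|/SE_2 < 2$) carry a
weak-instrument flag, as ratio estimators are biased and unstable in that
regime. The flag is a warning, never an error.

Multiple testing across the five SNPs plus the score uses a plain
Bonferroni quotient, `bonferroni_threshold(0.05, 6)` = 0.00833. Published
analyses of this design sometimes print a different cut-off for the same
quotient; the package computes the arithmetic value and leaves any
alternative threshold to the caller rather than choosing silently.

## What the synthetic cohort emulates

Because the motivating cohort's individual-level data are not deposited,
every stage is validated against a seeded generator
(`generator_config()` + `simulate_cohort()`) whose defaults encode the
published marginal structure:

* **Cohort**: n = 23,294 women aged 45+ (age ~ Normal(54.7, 7.1) truncated
  at 45; BMI ~ Normal(25.9, 5.0) truncated at 15), administratively
  censored at 20 years.
* **Genotypes**: independent Hardy–Weinberg draws per SNP. Per-SNP minor
  allele frequencies are not published (only a 16–44% range), so the
  defaults (0.21, 0.42, 0.38, 0.40, 0.28) are documented stand-ins inside
  that range. For all five variants the minor allele predicts *lower*
  25OHD, so the counted allele is the major one with frequency `1 - maf`.
  This orientation matters: it puts the mean score near 6.6 and fills the
  0–5 / 6–7 / 8–10 categories in roughly 22/50/28% proportions, matching
  the published category denominators, whereas counting minor alleles would
  concentrate ~90% of subjects in the reference category. SNPs are
  simulated without LD: pairs share a gene, but the score is a plain sum,
  so only the total score variance matters for the first stage.
* **Imputation**: three of the five SNPs are flagged as imputed; their
  dosages are the true counts plus Normal(0, `noise_sd`) noise clamped to
  [0, 2], with `noise_sd` = 0.05 by default — a high-quality imputation
  regime in which rounding back to hard calls (`round_dosage()`, half-way
  points away from zero) recovers the truth except with folded-normal tail
  probability. Scores are always computed from rounded hard calls.
* **25OHD**: `ohd = intercept + beta_a * GRS + Normal(0, sigma_resid)`,
  with a common per-allele effect solved from the variance identity
  `beta_a^2 * Var(GRS) = R2_target * SD^2` — at the defaults
  (R² = 0.026, SD = 26.1, Var(GRS) = 2.173) this gives beta_a = 2.85
  nmol/L per allele — and the intercept/residual SD set so the population
  mean and SD are 67.8 and 26.1 nmol/L. Negative draws are clamped at zero
  with the clamping fraction logged; at the defaults zero is 2.6 SDs below
  the mean and the fraction is ~0.5%. The measured subcohort (n = 1782) is
  a simple random sample; the real subcohort was assembled from
  case–control substudies, a selection mechanism we deliberately do not
  model, so generator checks validate the code, not that selection.
  A consequence worth noting: the published lowest-to-highest quintile gap
  (56.9 to 73.2 nmol/L) is wider than a 2.6%-R² homoscedastic normal model
  can produce (~12 nmol/L), so quintile means are reported but not used as
  calibration targets.
* **Survival**: exponential event times per endpoint with subject hazard
  `lambda_e * exp(age_log_hr_e * (age - mean) + causal_e * (ohd_latent -
  mean))`. The *latent* (pre-missingness) 25OHD drives the causal
  mechanism for every subject, including the ~92% with no measured value.
  Centering 25OHD at its mean only reparameterises `lambda_e` (hazard
  ratios are unchanged) and keeps the baseline rate interpretable as that
  of an average subject. Default covariate and causal effects are zero, so
  the closed-form hazard calibration is exact.

### Endpoint structure and hazard calibration

Total death is the minimum of a cancer-death and an other-death exponential
(so cancer death implies total death at the same time), and the first
incident cancer carries a site label (breast/colorectal/lung/other) drawn
with probabilities proportional to the published counts (so any site event
coincides with the total-cancer event). Incidence endpoints are censored at
the death time — the standard cause-specific convention, not a formal
competing-risks model. Because one subject has at most one first cancer,
site-specific analyses in the generator share the total-cancer causal
effect; the generator is not designed to vary site effects independently.
A cancer death does not require a recorded incident cancer (the two
processes are drawn independently), a simplification that leaves all
published marginal counts intact.

`calibrate_incidence(e, n, T)` returns the textbook closed form
`-log(1 - e/n)/T`. Used naively for incidence endpoints, death censoring
would depress observed counts ~6% below target (e.g. ~3733 instead of 3985
total cancers), so the default configuration compensates: the cause-specific
incidence hazard solves
`n * lambda/(lambda+mu) * (1 - exp(-(lambda+mu)T)) = e`
(`calibrate_incidence_competing()`, with mu the total-death rate), and the
cancer-death rate solves the analogous closed form inside the fixed
total-death rate. With this compensation the *observed* event counts hit
the published targets in expectation for every endpoint, which is what the
calibration tests assert. Event-count targets are expressed at a reference
cohort size (23,294) and scale proportionally when smaller cohorts are
simulated.

## Numerical and design choices

* Cox fits use `survival::coxph` (Breslow ties, tight convergence control:
  relative log-likelihood tolerance 1e-10, up to 50 iterations); tests
  cross-check the coefficients against brute-force maximisation of a
  hand-written partial likelihood on tiny datasets and against an
  independently computed logrank statistic. Monotone likelihood (perfect
  separation) is reported as `converged = FALSE` with the divergent
  coefficient visible, never hidden.
* Covariates are mean-centered before Cox fitting (conditioning only; HRs
  unchanged). Missing data are handled by listwise deletion with a logged
  count.
* CIs use z = 1.959964 throughout.
* Quintiles of the discrete score are formed by exhaustive search over the
  (at most `choose(10, 4)`) contiguous partitions of observed score values,
  minimising the total deviation from 20% per bin; tied subjects are never
  split, and ties between equally good partitions resolve toward lower cut
  values. Fewer than five distinct values degrade gracefully with a
  warning.
* Half-way dosages (0.5, 1.5) round away from zero — a measure-zero case
  for continuous dosages, fixed by convention and documented.
* The delta-method SE agrees with a 10^6-draw parametric bootstrap to ~1%
  once the first-stage `|beta2|/se2` exceeds ~12; at moderate strength the
  gap follows the second-order term `(3/2)(se2/beta2)^2` of the exact ratio
  variance. The package reports the first-order SE, which is the
  field-standard choice and conservative relative to none at realistic
  instrument strengths (the default calibration has F ≈ 48).

## What the test suite establishes (and what it cannot)

Problem sizes were chosen so the whole suite runs in a few minutes: the
first-stage calibration is checked over 200 replicates at n = 1782; the
event-count calibration on one full-scale cohort (n = 23,294, 20 y); causal
recovery (true ratio 1.30 per 20 nmol/L on mortality, the benchmark value
from the Danish MR literature) over 100 replicates at n = 6,000; null
coverage and type-I error of the IV estimator over 500 replicates at
n = 4,000 with a subcohort of 1,500. At those sizes the mean recovered
ratio sits within Monte-Carlo noise of the truth; the residual ~2% upward
drift of the *mean* ratio is the expected convexity bias of exponentiating
a noisy log-ratio, not an implementation artefact.

Passing these tests shows the pipeline's arithmetic is right under its own
generative assumptions. It does not establish robustness to what the
generator deliberately omits: linkage disequilibrium, pleiotropy of the
instrument SNPs, seasonally varying 25OHD, assay batch effects,
non-random subcohort selection, age-varying baseline hazards (Weibull
shapes are a configuration extension, not the default), or informative
censoring. Real-data analyses should treat those as open threats exactly as
they would with any other MR toolchain.

## Session info

```{r}
sessionInfo()
```
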