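# vitdmr

One-sample Mendelian randomization of circulating 25-hydroxyvitamin D
(25OHD) against cancer incidence and mortality, built as a tested, reusable
R pipeline for epidemiologists who want the whole chain — genotype file to
instrumental-variable estimate — reproducible from a single seed.

## The analysis

Whether lifelong vitamin D status causally affects cancer risk cannot be
settled by ordinary cohort regressions: 25OHD is confounded by adiposity,
activity, diet and general health. The MR design instruments 25OHD with an
**unweighted allele-count genetic risk score (GRS)** over five SNPs at three
vitamin D loci — DHCR7 (rs11234027, rs7944926), CYP2R1 (rs10741657,
rs12794714) and GC (rs2282679) — counting at each SNP the number (0/1/2) of
alleles associated with higher 25OHD (score range 0–10; a sensitivity
variant drops the GC SNP, range 0–8).

The estimator is the Wald ratio, scaled to a 20 nmol/L increment of
genetically determined 25OHD:

    beta_IV = 20 * beta1 / beta2

where `beta1` is the log hazard ratio per score unit from an age-adjusted
Cox model (Breslow ties) and `beta2` the first-stage OLS slope of 25OHD on
the score (nmol/L per unit) in the biomarker subcohort. The delta-method
standard error, treating the stages as independent, is

    SE_IV^2 = (20/beta2)^2 * SE1^2 + (20*beta1/beta2^2)^2 * SE2^2

Instrument strength is indexed by the single-predictor F statistic
`F = R2 (n-2)/(1-R2)`; estimates with F < 10 carry a weak-instrument flag.
A seeded synthetic-cohort generator with known ground truth (Hardy–Weinberg
genotypes, calibrated first-stage variance explained, exponential survival
endpoints with competing death censoring) backs every stage with
parameter-recovery tests. See the methods vignette
(`vignettes/vitamin-d-mr-methods.Rmd`) for the model, its assumptions and
the design decisions.

## Worked example

Simulate a cohort with the default calibration (23,294 women followed 20
years, a 1,782-subject 25OHD subcohort, all causal effects null) and run
the full pipeline:

```r
library(vitdmr)

cfg <- generator_config(seed = 1)   # defaults encode the emulated cohort
report <- run_full_analysis(cfg)
print(report)
#> <vitdmr_report>
#>   cohort n = 23294, measured 25OHD n = 1782
#>   first stage: slope 2.835 nmol/L per score unit, R2 0.0267, F 48.8
#>   trend across quintiles: p = 5.32e-11
#>   IV estimates (delta method):
#>     total_cancer ratio 0.90 (0.77-1.05) per 20 nmol/L, p = 0.17
#>     breast       ratio 0.85 (0.66-1.08) per 20 nmol/L, p = 0.18
#>     colorectal   ratio 0.89 (0.53-1.51) per 20 nmol/L, p = 0.67
#>     lung         ratio 0.83 (0.49-1.41) per 20 nmol/L, p = 0.49
#>     total_death  ratio 0.96 (0.81-1.15) per 20 nmol/L, p = 0.69
#>     cancer_death ratio 0.73 (0.52-1.04) per 20 nmol/L, p = 0.085
```

Reading this: the score explains 2.7% of 25OHD variance in the subcohort
(F = 48.8, a strong instrument), 25OHD rises monotonically across score
quintiles, and — as it must under a null simulation — every IV ratio's 95%
CI includes 1. `report$table2` holds the endpoint-by-category association
rows (cases/n, rates per 1000 person-years, HRs with CIs), `report$per_snp`
the per-SNP Cox fits, and `report$iv` both score variants' IV estimates.
Passing `out_dir=` writes the tab-delimited tables, a full-precision JSON
mirror and a digest manifest; identical configs give byte-identical
bundles.

The pieces compose individually as well:

```r
iv <- wald_iv(beta1 = 0.012, se1 = 0.008, beta2 = 2.9, se2 = 0.42,
              scale = 20, f_stat = 48)
print(iv)
#> <iv_estimate> delta method, per 20 nmol/L 25OHD
#>   ratio 1.086 (95% CI 0.972-1.213), beta 0.0828 (SE 0.0565), p = 0.143
```

A thin CLI wraps the same functions for shell use
(`inst/cli/vitdmr.R`, subcommands `simulate`, `grs`, `associate`, `mr`,
`run-all`); it reads/writes the documented tab-delimited phenotype and
genotype formats and a minimal VCF 4.2 (GT for hard calls, DS for imputed
dosages).

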