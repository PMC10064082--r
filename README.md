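# mrgap

Two-sample Mendelian randomization and glycation-gap analysis in R.

## The problem

HbA1c — the standard diagnostic and monitoring measure for prediabetes and
type 2 diabetes — is not a pure readout of glycemia: red-cell mass and
turnover shift it independently of glucose. If insulin resistance with
compensatory hyperinsulinemia increases erythrocytosis, HbA1c will read
systematically *low* in exactly the patients at highest metabolic risk.
`mrgap` provides the analysis machinery for both ways of interrogating
that hypothesis:

* **Two-sample MR** from GWAS summary statistics: instrument selection at
  genome-wide significance, LD-proxy substitution, allele harmonization
  with palindromic-SNP handling, and the standard estimator suite — IVW,
  MR-Egger, weighted median, simple and weighted mode — with Cochran's
  Q / I², instrument F-statistics and leave-one-out sensitivity analysis;
  plus inverse-variance weighted **multivariable MR** with
  Sanderson–Windmeijer conditional F diagnostics.
* **Observational glycation-gap analysis**: cohort filters, glycemic
  classification, the triglyceride-glucose index (TGI), predicted HbA1c
  from fasting glucose, stratified gap-on-TGI regressions, plot-ready
  diagnostics, and 0.632-bootstrap optimism validation.
* **Seeded synthetic generators** for both GWAS summary statistics and
  patient-level cohorts, so every stage is testable without consortium
  data.

The core model: for SNP *j* with harmonized exposure/outcome effects
(β̂_Xj, σ_Xj) and (β̂_Yj, σ_Yj), the Wald ratio β̂_Yj/β̂_Xj estimates the
causal effect θ; IVW pools the ratios with weights 1/σ²_Yj (a
zero-intercept weighted regression of β̂_Yj on β̂_Xj), MR-Egger frees the
intercept to absorb directional pleiotropy, the weighted median tolerates
<50% invalid weight, and the mode-based estimators take the densest ratio
cluster. Heterogeneity is Cochran's Q with I² = max(0, (Q−df)/Q)·100%.
See the methods vignette (`vignettes/mr-glycation-methods.Rmd`) for the
full model and every numerical choice.

## Worked example

```r
library(mrgap)

## --- two-sample MR on simulated fasting-insulin -> hemoglobin data ----
sim <- simulate_two_sample_gwas(mr_scenario("fi_hb_like"), seed = 7)
set <- harmonize(sim$exposure, sim$outcome)   # 49 SNPs -> 44 after drops
fit <- mr_fit(set, n_boot = 500, seed = 7)
summary(fit)
#> Two-sample MR fit: simulated exposure -> outcome (44 SNPs)
#>                     method     b    se         p
#>                   MR Egger 0.531 0.008  1.66e-43
#>            Weighted median 0.532 0.008 2.23e-308
#>  Inverse variance weighted 0.540 0.004 2.23e-308
#>                Simple mode 0.541 0.012 2.23e-308
#>              Weighted mode 0.531 0.009 2.23e-308
#>
#> Heterogeneity:
#>                     method      Q df     p  I2(%)
#>                   MR Egger 53.269 42 0.114 21.155
#>  Inverse variance weighted 55.420 43 0.097 22.410
#>
#> Mean instrument F-statistic: 467.979
#> MR-Egger intercept: 0.0010 (se 0.0008, p = 0.2)
```

The scenario plants a causal effect of 0.54 with no pleiotropy: all five
estimators land on it, the Egger intercept is indistinguishable from zero,
and the instrument is strong. With real files, replace the simulation with
`read_summary_stats()` + `select_instrument()` (+ `proxy_substitute()`).

```r
## --- observational arm on a simulated 7600-patient cohort -------------
cohort <- simulate_cohort(n = 7600, seed = 7)
regress_gap_on_tgi(cohort)[, c("stratum", "n", "beta", "se", "pval")]
#>         stratum    n    beta      se     pval
#> 1        preT2D 1093 -0.0807 0.00990 9.28e-16
#> 2       healthy 6507  0.0223 0.00702 1.45e-03
#> 3       hba1c<5  795 -0.0247 0.00970 1.10e-02
#> 4   hba1c 5-5.4 3610 -0.0140 0.00485 3.86e-03
#> 5 hba1c 5.5-5.9 1968 -0.0166 0.00613 6.73e-03

bootstrap_validate_632(gap ~ tgi, cohort, n_boot = 200, seed = 7)
#> 0.632 bootstrap validation (200 replicates)
#>   R2 apparent 0.0149 -> corrected 0.0141 (optimism 0.0008)
#>   MSE change +0.05%, g-index change +0.04%, slope shrinkage -0.0069
#>   No evidence of overfitting
```

The generator plants a *negative* gap-vs-TGI slope (−0.087) in pre-T2D
and a positive one (+0.023) in normoglycemia; the stratified regressions
recover both signs and magnitudes within sampling error, and the
single-predictor model shows essentially no optimism.

```r
round(tgi(1.16, 5.10), 2)   # TGI at median TG/FG of a healthy stratum
#> [1] 8.46
```

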