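---
title: "Methods: two-sample MR estimators and the glycation gap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR estimators and the glycation gap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrgap)
```

## The scientific problem

HbA1c is used to diagnose and monitor prediabetes and type 2 diabetes, but
it reflects more than average glycemia: red-cell turnover and mass
(erythrocytosis) shift HbA1c independently of glucose. Insulin resistance
with compensatory hyperinsulinemia is suspected of increasing
erythrocytosis, which would make HbA1c read *lower* than glycemia warrants
in exactly the people at highest metabolic risk. `mrgap` implements the two
complementary analysis arms for this question:

1. **Two-sample Mendelian randomization (MR)** from GWAS summary
   statistics, treating genome-wide significant SNPs for an exposure
   (e.g. fasting insulin) as instrumental variables for outcomes such as
   hemoglobin or HbA1c, univariably and multivariably.
2. **An observational glycation-gap analysis** in an outpatient cohort:
   the gap between measured HbA1c and HbA1c predicted from fasting
   glucose, regressed on the triglyceride-glucose index (TGI), a routine
   surrogate for insulin resistance.

Neither consortium GWAS files nor patient records can ship with a package,
so a third arm — seeded synthetic generators with the statistical
structure both analyses assume — makes every stage testable end to end.

## Univariable MR model

For SNP $j$, let $\hat\beta_{Xj}, \sigma_{Xj}$ be its estimated
association with the exposure and $\hat\beta_{Yj}, \sigma_{Yj}$ with the
outcome, both expressed per copy of the same effect allele (that is what
harmonization guarantees). Each SNP's Wald ratio
$\hat\theta_j = \hat\beta_{Yj}/\hat\beta_{Xj}$ estimates the causal effect
$\theta$ if the SNP is a valid instrument. The estimators differ in how
they pool the ratios and which violations they tolerate:

* **IVW** — inverse-variance weighted meta-analysis of the ratios with
  weights $w_j = 1/\sigma_{Yj}^2$, equivalently the zero-intercept
  weighted regression of $\hat\beta_{Yj}$ on $\hat\beta_{Xj}$. Efficient,
  but biased by any directional pleiotropy.
* **MR-Egger** — the same regression with a free intercept. The slope is
  the causal estimate and the intercept the mean directional pleiotropic
  effect, unbiased when instrument strength is independent of the direct
  effects (InSIDE). Inference uses a $t$ reference with $J-2$ df.
* **Weighted median** — the weighted median of the ratios; consistent
  while SNPs carrying at least half the weight are valid.
* **Simple / weighted mode** — the argmax of a normal-kernel density of
  the ratios (weights $1$ or $1/\mathrm{se}(\hat\theta_j)^2$); consistent
  when the valid SNPs form the largest cluster.

Heterogeneity about a fit is Cochran's
$Q = \sum_j w_j(\hat\beta_{Yj} - a - \hat\theta\hat\beta_{Xj})^2$ with
$df = J-1$ (IVW, $a=0$) or $J-2$ (Egger), summarized as
$I^2 = \max(0, (Q-df)/Q)\cdot 100\%$. Instrument strength is the mean
per-SNP $F = \overline{(\hat\beta_{Xj}/\sigma_{Xj})^2}$, with the
conventional weak-instrument flag at $F<10$.

### Numerical and inferential choices

* **Error model.** IVW defaults to *multiplicative random effects*: the
  fixed-effects standard error is inflated by $\sqrt{\max(1, Q/df)}$.
  With the enormous $Q$ values real blood-trait instruments produce, the
  fixed-effects SE would be absurdly anti-conservative; the `max(1, )`
  floor keeps the random-effects SE from ever undercutting it.
  MR-Egger's two standard errors are scaled the same way.
* **Ratio standard errors** for the median/mode weights use the
  first-order delta method $\sigma_{Yj}/|\hat\beta_{Xj}|$ — the simplest
  defensible form; the second-order term is negligible at the instrument
  strengths involved.
* **Bootstrap SEs.** The median and mode have no convenient closed-form
  SE; a seeded parametric bootstrap (default 1000 replicates) resamples
  $\hat\beta_{Xj}, \hat\beta_{Yj}$ from their reported sampling
  distributions and takes the SD of the re-estimates.
* **Mode bandwidth.** $\varphi \cdot 0.9\min(\mathrm{sd},
  \mathrm{IQR}/1.349)J^{-1/5}$ with $\varphi = 1$; the density argmax is
  located on a 512-point grid spanning the ratios $\pm 3$ bandwidths
  (both configurable). If every ratio coincides the bandwidth collapses
  and that common ratio is returned.
* **Egger orientation.** Effects are oriented so every
  $\hat\beta_{Xj} > 0$ before fitting; the slope is invariant but the
  intercept is only meaningful under a consistent exposure-increasing
  orientation.
* **p-values** are two-sided, normal-reference except Egger's $t_{J-2}$,
  and floored at the smallest positive double rather than printed as 0.

## Harmonization and instrument plumbing

Selection keeps SNPs with $p < 5\times10^{-8}$ (strict inequality, the
genome-wide convention). Duplicate identifiers keep the lowest p-value.
Instrument SNPs absent from the outcome file can be replaced by an LD
proxy from a user-supplied `(snp, proxy, r2)` table when $r^2 > 0.8$;
computing LD from a genotype panel is deliberately out of scope, and the
substitution assumes the proxy is phased to the same trait-increasing
allele (an $r^2$ table cannot verify sign — flagged in the
documentation).

Harmonization aligns outcome rows to the exposure's effect allele:
matched alleles pass through, swapped alleles flip the outcome beta and
complement the frequency, anything else is dropped as irreconcilable (no
strand-flip guessing — silent complementing is exactly how palindromic
mistakes happen). Palindromic SNPs (A/T, C/G) default to
`infer_by_eaf`: alignment by allele-frequency concordance, dropping SNPs
whose frequency falls in the 0.42–0.58 ambiguity band on either side.
This is the common two-sample MR default; `drop_all` is available for
sensitivity analyses.

## Multivariable MR

With $K$ exposures the direct effects solve the zero-intercept weighted
regression of $\hat\beta_{Yj}$ on the $K$ exposure-effect columns, SEs
scaled by $\sqrt{\max(1, Q/(J-K))}$. Because the fit is through the
origin, the collinearity gate uses the *uncentered* weighted cosine
between exposure columns (default limit 0.95): exposures like fasting
glucose and type 2 diabetes share so much signal that their direct
effects are not separable, and the fit is refused unless forced.
Conditional instrument strength per exposure follows the
Sanderson–Windmeijer form: regress that exposure's SNP effects on the
remaining exposures' with weights $1/\sigma_{Xkj}^2$ and divide the
residual $Q_k$ by $J - K + 1$; $F_k < 10$ warns of a conditionally weak
instrument.

## The observational pipeline

Cohort filters mirror routine outpatient screening: age 18–65, fasting
glucose $< 7$ mmol/L, HbA1c $< 6.5\%$, hemoglobin inside the sex-specific
reference interval (defaults 130–170 g/L male, 120–160 g/L female —
laboratories differ, so the bounds are configurable; the filter logic is
what the tests pin down). A prior-diabetes-clinic flag is honored when
the column exists, since that criterion is administrative rather than
computable from laboratory values.

Glycemic classes: normoglycemia is HbA1c $< 6\%$ *and* glucose
$< 6$ mmol/L. The default `either` rule labels everyone else pre-T2D
(HbA1c 6–6.4% *or* glucose 6–6.9 mmol/L), so the two classes partition
the filtered cohort — the interpretation under which published stratum
counts add up to the full cohort. The conjunctive `both` rule is
implemented for sensitivity and returns an explicit `indeterminate`
class.

The TGI is $\ln[\mathrm{TG}\,(\mathrm{mg/dL}) \times
\mathrm{FG}\,(\mathrm{mg/dL})/2]$ with the standard mmol/L→mg/dL factors
88.57 and 18 applied internally (the factor 88.57 identifies the
conversion as mg/dL). Predicted HbA1c comes from OLS of HbA1c on fasting
glucose; the age/sex-adjusted model is fitted alongside, but the
glucose-only equation is the default prediction because the glycation
gap is conventionally quoted against it and because it is the form whose
coefficients reproduce published stratum medians. The gap is simply
measured minus predicted HbA1c. Stratified OLS of gap on TGI (per-class
plus HbA1c bands within normoglycemia) and of hemoglobin on TGI complete
the analysis; diagnostics are emitted as plot-ready tables (Q-Q of
standardized residuals with their normal-quantile correlation, residuals
vs fitted with a Wald–Wolfowitz runs test for curvature, residuals vs
TGI).

**0.632 bootstrap validation.** Each replicate refits on a resample and
evaluates on the out-of-bag records; corrected statistics are
$0.368\cdot\text{apparent} + 0.632\cdot\overline{\text{out-of-bag}}$ for
$R^2$, MSE, the g-index (Gini mean difference of predictions, computed by
the sorted-order closed form) and the calibration slope. Optimism is
apparent minus corrected $R^2$; above 0.1 the model is flagged overfit.
Default 200 replicates; resamples with fewer than two out-of-bag records
are redrawn and counted.

## What the generators emulate — and what they do not

### GWAS summary statistics

`simulate_two_sample_gwas()` draws minor allele frequencies uniformly on
(0.05, 0.5), per-SNP standard errors $1/\sqrt{2\,\mathrm{maf}(1-\mathrm{maf})\,n}$
(standardized traits), and true exposure z-statistics
$z_j = \pm(z_0 + |N(0, z_{sd})|)$, defaults $z_0 = 8$, $z_{sd} = 20$.
The floor keeps every SNP genome-wide significant — these are
*post-selection* instruments, like the published ones — while the
half-normal tail spreads effect magnitudes over an order of magnitude,
as lead signals of consortium-scale GWAS do. That spread matters: it
keeps exposure measurement error small relative to the between-SNP
effect variance (NOME), under which MR-Egger is unbiased and IVW's
attenuation is of order $1/F$ (about 0.15% at the default design). The
default sample sizes (151,013 exposure; 563,946 outcome) are those of
the fasting-insulin and hemoglobin GWAS the package emulates.

Pleiotropic effects are defined per exposure-increasing allele, so
"directional" pleiotropy pushes the outcome consistently — the
configuration under which IVW is biased by the mean pleiotropic effect
while the Egger intercept recovers it, and (at 40% invalid SNPs,
`median_robust` preset) the weighted median stays near the truth.
A 20% palindromic-allele fraction and 30% outcome-file allele swaps
exercise the harmonization path on every simulated dataset.

Not emulated: LD between instrument SNPs (inputs are modelled as already
pruned), winner's curse in the exposure effects, sample overlap between
the two GWAS, and allele-frequency differences between cohorts beyond
small noise. Passing recovery tests therefore demonstrate estimator
correctness under the two-sample model's own assumptions, not robustness
to those additional real-data pathologies.

### Patient cohort

`simulate_cohort()` assigns each participant a glycemic stratum
(pre-T2D fraction 0.144), draws glucose and triglyceride log-normally
with parameters matched to published stratum medians and interquartile
ranges, and builds HbA1c as the fixed prediction equation
$4.163 + 0.172\,\mathrm{FG}$ plus a gap of
$\text{intercept}_s + \text{slope}_s\cdot\mathrm{TGI} + \varepsilon$,
with stratum truths $(-0.087, 1.77)$ for pre-T2D and $(+0.023, 0.14)$
for normoglycemia; hemoglobin is $129 + 1.88\cdot\mathrm{TGI} +
\varepsilon$ clipped to a physiologic range. Residual SDs (0.16, 0.30
gap; 13 g/L hemoglobin) were back-calculated once from the published
regression standard errors and stratum sizes. Rejection sampling
enforces only the post-filter invariants (stratum glucose bound, HbA1c
$< 6.5\%$).

Two deliberate design choices deserve emphasis:

* The generating stratum label is kept in the `stratum` column and used
  by default for stratified regressions. Re-classifying simulated
  records by the HbA1c/glucose thresholds truncates the gap
  distribution at the class boundary (acceptance into "pre-T2D" depends
  on the very quantity being modelled) and would bias slope recovery by
  several standard errors — a selection effect that real
  threshold-defined strata genuinely carry, which is why the package
  also supports classification-based strata for realism studies.
* The gap is emitted directly rather than re-derived by refitting the
  prediction equation on the simulated cohort: refitting couples the
  strata through the shared equation and contaminates the planted
  slopes. Real analyses *do* refit, so recovered real-world slopes
  inherit that coupling; the generator separates the two effects so the
  regression machinery can be tested against a clean truth.

## Problem sizes and reproducibility

Every stochastic routine takes a `seed` and restores the caller's RNG
state. The package's own validation suite uses 200-replicate recovery
studies at $J=49$ SNPs, a 500-replicate null for the IVW type-I error,
one $n = 7600$ cohort for the observational round trip, and 100–200
bootstrap replicates for the 0.632 validation — sizes at which all
Monte-Carlo checks resolve comfortably while the whole suite runs in
well under a minute.

## Known limitations

* No MR-PRESSO, contamination-mixture, Steiger filtering or robust
  regression variants; no MVMR-Egger or median-based MVMR.
* Proxy substitution trusts the supplied $r^2$ table and allele phase;
  no reference-panel LD computation.
* The observational models are deliberately plain OLS — no splines,
  no medication adjustment, no post-prandial glycemia.
* The printed-equation default for predicted HbA1c omits the age/sex
  terms of the adjusted model; both forms are available, and which one a
  given published median reflects is ultimately an empirical question.
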