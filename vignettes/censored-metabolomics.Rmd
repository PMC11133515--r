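---
title: "Censoring-aware differential abundance for targeted metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Censoring-aware differential abundance for targeted metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(censmetab)
```

## The problem

Targeted metabolomics kits quantify a fixed panel of analytes — here a
188-metabolite plasma panel of 21 amino acids, 21 biogenic amines, one
hexose sum (H1), 40 acylcarnitines, 15 sphingolipids and 90
glycerophospholipids (14 lysoPC a, 38 PC aa, 38 PC ae) — each with its own
limit of detection (LOD). Concentrations below the LOD are *left-censored*:
the instrument tells us only that the true value lies below a known bound.
Low-abundance analytes (short-chain acylcarnitines, rare lysoPCs, some
biogenic amines) can have substantial censored fractions, and ignoring that
structure biases group comparisons toward the null or, with naive
substitution, in unpredictable directions.

The workflow implemented here is the one used in censored-data case-control
metabolomics studies (for example Prader-Willi syndrome versus essential
obesity, the 32-vs-32 design whose conventions this package's defaults
follow):

1. replace values `< LOD` with `LOD/2` for descriptive statistics;
2. keep only metabolites with at least 20% of observations above the LOD;
3. take natural logs and autoscale (subtract the mean, divide by the SD) so
   effect sizes are comparable across metabolites;
4. fit, per metabolite, a **left-censored Gaussian (Tobit) regression** of
   the standardized log concentration on the case/control contrast plus
   adjustment covariates (sex, diastolic blood pressure, C-reactive
   protein by default);
5. report model-based **geometric means** per group, their ratio as the
   **fold-change (FC)**, Wald 95% intervals and p-values, and
   **Benjamini–Hochberg FDR** across the tested panel;
6. display everything as a volcano plot of `log2(FC)` against
   `-log10(FDR p)`.

## The model

For metabolite $j$, let $w_{ij}$ be the concentration of sample $i$ and
$L_j$ its LOD. With $m_j$ and $s_j$ the mean and SD (divisor $n-1$) of
$\log w_{ij}$ after LOD/2 substitution, the standardized response is
$y_{ij} = (\log w_{ij} - m_j)/s_j$, and the censoring bound maps to
$c_j = (\log L_j - m_j)/s_j$ on the same scale — applying the transform to
the LOD itself yields exactly $c_j$, which is what ties the raw and model
scales together.

The latent model is $y^*_i = x_i^\top\beta + \varepsilon_i$,
$\varepsilon_i \sim N(0, \sigma^2)$, with $y_i = y^*_i$ observed when
$w_i \ge L$ and only $y^*_i < c$ known otherwise. The log-likelihood is the
standard censored-Gaussian form

$$\ell(\beta,\sigma) = \sum_{\text{obs}}\left[\log\phi\!\left(\frac{y_i -
x_i^\top\beta}{\sigma}\right) - \log\sigma\right] +
\sum_{\text{cens}}\log\Phi\!\left(\frac{c - x_i^\top\beta}{\sigma}\right),$$

evaluated with log-scale normal tail functions so it is finite for any
finite parameters. `tobit_fit()` maximises it over $(\beta, \log\sigma)$ —
the log parameterisation keeps $\sigma > 0$ without constraints — by BFGS
with the analytic gradient, followed by safeguarded Newton steps on a
central finite-difference Hessian. Convergence requires the gradient norm
below `tol * (1 + |loglik|)` (default `tol = 1e-8`), with a fallback on
parameter change below 1e-10; failures are reported per metabolite, never
silently dropped. The covariance is the inverse observed information at the
optimum, delta-method-transformed to $(\beta, \sigma)$; inference is Wald
with the normal reference, which matches the symmetric single-fit intervals
such studies report (a likelihood-ratio alternative would be more accurate
in small samples and is a documented limitation, not an option).

With no censoring the likelihood reduces to Gaussian ML, so the fit must —
and in the tests does — coincide with least squares with
$\hat\sigma = \sqrt{RSS/n}$.

### Geometric means and fold-change

Group geometric means are model predictions: with adjustment covariates
fixed at a common profile (whole-sample means for continuous covariates,
proportions for binary ones; a reference-level profile is available by
configuration), the linear predictor $\eta_g$ at group $g$ back-transforms
to $GM_g = \exp(m + s\,\eta_g)$ with interval
$\exp(m + s(\eta_g \pm 1.96\,SE(\eta_g)))$. Because the two profiles differ
only in the group indicator, the fold-change is exactly

$$FC = \frac{GM_{case}}{GM_{control}} = \exp(s\,\hat\beta_{group}),$$

an identity the pipeline asserts to 1e-10 on every row. The at-means choice
matters only for the absolute geometric means, not for FC or its test.

## Design choices where the convention is genuinely open

* **Autoscale basis.** Moments $m, s$ are computed on the LOD/2-substituted
  log values, because substitution precedes transformation in the workflow
  being implemented; `scale_basis = "observed_only"` restricts them to
  uncensored entries for sensitivity analysis.
* **Detection boundary.** A value exactly equal to the LOD counts as
  detected: equality is measure-zero in theory, and a value the instrument
  actually reported at the bound should not be censored by bookkeeping.
* **One LOD per metabolite.** Plate-specific LODs are assumed to be
  reduced upstream (minimum across plates); the package neither models
  plates nor batch effects.
* **Zeros and missings.** A zero concentration is below any positive LOD,
  hence censored; missing cells are excluded from that metabolite's $n$.
  This is the least destructive reading of silent conventions.
* **Aggregate ("sum") variables** such as `lysoPC_s` are recomputed from
  their members with LOD/2 for censored members rather than trusted from
  kit output, so synthetic and real data behave identically. A sum of
  positive terms is always observed, so aggregates carry no LOD and their
  Tobit fit reduces to Gaussian ML. Whether the original kit reported such
  sums directly or they were computed downstream is not documented in the
  sources this design follows; recomputation is the reproducible choice.
* **FDR family.** All metabolites tested in a run, aggregates included;
  `fdr_family = "measured_only"` excludes them.
* **Percentiles** use linear interpolation between order statistics
  (`quantile` type 7); **sample SD** uses $n-1$.
* **Cohort tests.** Student's equal-variance t by default (Welch by
  switch), Wilcoxon rank-sum with normal approximation and tie correction,
  Pearson chi-squared without continuity correction. The choice of test
  per variable is declared by the analyst, not automated from a normality
  test. The glucose unit converter uses the standard 0.0555 mmol/L per
  mg/dL (assay notes sometimes round this to 0.06; the package does not).
* **Decimal-comma input** is first-class because published concentration
  tables in this field frequently print it; all outputs use `"."`.

## The synthetic-cohort generator

`simulate_cohort()` generates the data-generating process the analysis
assumes: lognormal concentrations
$w_{ij} = \exp(\mu_j + g_i\,\delta_j + \text{covariate terms} +
\varepsilon_{ij})$ with per-metabolite log-mean $\mu_j$, group effect
$\delta_j$ (true FC $= e^{\delta_j}$), covariate effects on the log scale,
and noise SD. The LOD is placed at a configured quantile of the
control-group distribution, so the censoring fraction is controlled by
design and the realized fraction is testable against it. Raw values below
the LOD are stored as generated — mirroring instruments that report a value
regardless — so the LOD/2 rule and the Tobit bound can be validated against
the latent truth; a switch blanks them instead.

Defaults are the emulated study's conditions: 32 cases vs 32 controls,
23:9 F:M per group, DBP $\sim N(81, 7^2)$ mmHg, CRP lognormal with median
about 0.75 mg/dL, the packaged 188-metabolite panel with class-realistic
abundance ranges, log-SD 0.5 (about 50% biological CV), and a
class-patterned censoring profile under which most analytes are fully
detectable while a minority of acylcarnitines, biogenic amines and lysoPCs
sit partly or mostly below their LOD. Covariates are simulated
independently of group by default so that adjusted and unadjusted analyses
estimate the same contrast; confounding can be induced explicitly via the
covariate-effect parameters to exercise adjustment.

What the generator does *not* emulate — and therefore what passing tests do
not establish about real data: correlated metabolites (lipid species are
strongly co-regulated; the generator draws them independently), batch and
plate effects, heavy-tailed or mixture-distributed concentrations,
measurement error beyond lognormal noise, and missingness mechanisms other
than censoring.

## Numerical behaviour and operating characteristics

The suite checks, among others:

* exact agreement with Gaussian ML at zero censoring (1e-6) and with an
  independent survival-regression implementation on censored data;
* agreement of the fitted optimum with a nested grid-search maximiser of
  the same likelihood on a small fixture (1e-4) and dominance over random
  parameter clouds around the optimum;
* location-scale equivariance of $(\hat\beta, \hat\sigma)$;
* group-effect recovery without practically relevant bias (mean log-scale
  error below 0.02 at $n = 500+500$ with 30% censoring, 200 replicates);
* null calibration of the 5% Wald test at the study size ($n = 32+32$,
  20% censoring, 2000 replicates): the rejection rate sits near 0.055 —
  the mild liberal drift expected of Wald inference with an
  observed-information variance at this sample size — inside the binomial
  envelope around the nominal level used by the test;
* Benjamini–Hochberg agreement with a brute-force step-up implementation
  on random p-vectors, and full-pipeline all-null runs flagging nothing at
  FDR 0.05 in the large majority of replicates.

Problem sizes in the tests (2000 null replicates, 200 recovery replicates
at $n=1000$, 50 all-null full-panel runs, 25 in the acceptance script) were
chosen so the whole suite runs in about a minute while leaving the binomial
/ Monte-Carlo tolerances meaningful.

## Known limitations

Wald rather than likelihood-ratio inference; no plate/batch modelling; no
imputation beyond LOD/2 (the Tobit likelihood, not the substituted values,
drives inference wherever it matters); independence across metabolites in
the generator; and the packaged panel reproduces the published class
composition with standard analyte nomenclature, not a vendor-certified
analyte list.
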