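# censmetab

Differential-abundance analysis for **targeted metabolomics with
limit-of-detection (LOD) censoring**, built for case-control panel studies
(the packaged defaults follow a 32-vs-32 plasma cohort measured on a
188-metabolite panel: 21 amino acids, 21 biogenic amines, 1 hexose, 40
acylcarnitines, 15 sphingolipids, and 90 glycerophospholipids split
14 lysoPC a / 38 PC aa / 38 PC ae).

Concentrations below a metabolite's LOD are left-censored. `censmetab`
implements the censoring-aware workflow end to end:

* **LOD/2 substitution** for descriptive statistics and a **detection-rate
  filter** (keep metabolites with ≥ 20% of observations above the LOD);
* **log + autoscale transform** that carries the censoring bound onto the
  model scale: `y = (log w − m)/s`, bound `c = (log LOD − m)/s`;
* a from-scratch **left-censored Gaussian (Tobit) regression**,
  maximising

  ```
  l(beta, sigma) = sum_obs  [ log phi((y − x'beta)/sigma) − log sigma ]
                 + sum_cens   log Phi((c − x'beta)/sigma)
  ```

  over `(beta, log sigma)` with analytic gradients, Newton polish and
  observed-information Wald inference;
* model-based **geometric means** per group (covariates held at sample
  means), the **fold-change** `FC = GM_case / GM_control = exp(s·beta_group)`
  with 95% CIs, **Benjamini–Hochberg FDR**, and **volcano** coordinates /
  plots;
* Table-1-style **cohort comparisons** (t / Wilcoxon / chi-squared,
  HOMA-IR), delimited-text I/O including the decimal-comma dialect of
  published tables, and a **synthetic-cohort generator** with known truth
  for every stage.

## Worked example

Simulate a study-sized cohort in which 20 of the 188 metabolites carry a
true two-fold case/control effect, then run the adjusted pipeline:

```r
library(censmetab)

panel  <- default_panel()
k      <- sum(!panel$is_aggregate)
log_fc <- numeric(k)
log_fc[seq(5, by = 9, length.out = 20)] <- log(2)   # 20 true FC = 2 effects

sim <- simulate_cohort(sim_config(group_log_fc = log_fc, seed = 7))
res <- run_multivariable(sim$concentrations, sim$samples, sim$lods, panel)
res
#> Censored differential-abundance results: 181 metabolites tested, 20 significant at FDR < 0.05
#> Dropped by detection filter: 10
#>        metabolite n_below_lb  gm_case gm_control    fc   p_value     fdr_p
#> 1     PC aa C24:0          4   0.2304    0.09409 2.449 8.379e-17 1.517e-14
#> 2        SM C24:0          0 173.3407   77.89249 2.225 8.714e-13 7.886e-11
#> 3             Cit          0  86.4083   36.98441 2.336 7.222e-12 4.357e-10
#> ...
```

Reading the output: each row is one metabolite's adjusted Tobit fit.
`n_below_lb` counts observations below the LOD (censored in the fit, not
merely substituted); `gm_case`/`gm_control` are model geometric means in
µM with covariates (sex, DBP, CRP) held at whole-sample means; `fc` is
their ratio; `fdr_p` is the BH-adjusted Wald p-value across all 181 tested
metabolites. Here the pipeline flags 20 metabolites at FDR < 0.05 and the
estimated fold-changes of the true effects cluster around 2, as designed.
Ten low-abundance analytes fail the 20% detection filter and are excluded
before modelling.

The model itself is a first-class object:

```r
d <- data.frame(x = rnorm(100))
d$y <- pmax(1 + 0.5 * d$x + rnorm(100), 0)   # left-censored at 0
fit <- tobit(y ~ x, d, left = 0)
summary(fit); confint(fit); predict(fit, data.frame(x = 0:2))
```

A file-based driver (`cmd_run` / `cmd_simulate` / `cmd_describe`, with a
thin Rscript wrapper in `inst/scripts/censmetab-cli.R`) reads TSV/CSV
inputs in either decimal dialect and writes `results.tsv`,
`descriptives.tsv`, `volcano.tsv` and a volcano SVG, atomically and
deterministically.

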