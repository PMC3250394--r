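# quantpen

Quantile-dependent penetrance analysis of genetic risk scores.

## The problem

A standard regression of a phenotype on a genetic risk score (GRS) — the
weighted sum of risk-allele dosages, $\mathrm{GRS}_i = \sum_j d_{ij} w_j$
with published per-allele effects $w_j$ — summarizes the genotype-phenotype
relationship by one slope, as if the same per-allele effect applied to lean
and obese subjects alike, or to subjects at the bottom and top of the lipid
distribution. *Quantile-dependent penetrance* is the phenomenon in which
the slope instead varies with the population percentile of the phenotype.
Where it holds, the single regression slope mischaracterizes the
relationship (its 95% CI can cover the quantile slopes for only a minority
of the distribution) and understates the variance a score can explain.

`quantpen` is for biostatisticians and genetic epidemiologists who want to
test and quantify this: it builds risk scores from dosage data (TSV or
VCF) and published-effect tables, residualizes phenotype and score on
covariates (sex, age, age², study, smoking), estimates the slope
$\hat\beta(\tau)$ of adjusted phenotype on adjusted score at every
percentile $\tau \in \{0.05, \dots, 0.95\}$ by quantile regression
(pinball loss $\rho_\tau(u) = u(\tau - 1[u<0])$, exact vertex solver), and
then:

* **trend test** — the linear contrast
  $\hat\delta = \sum_k c_k\hat\beta(k) / \sum_k c_k^2$, $c_k = k - \bar k$,
  with variance $c^\top\Sigma c/(\sum c_k^2)^2$ from the paired-bootstrap
  covariance $\Sigma$ of the slope vector (subjects resampled with
  replacement, all quantiles refit per replicate);
* **variance explained under quantile-specific slopes** — each observation
  is projected to the mean score along its own percentile's slope
  (percentile ranks taken within GRS deciles, or within genotype classes
  for single SNPs), and $(\mathrm{Var}(y)-\mathrm{Var}(y^*))/\mathrm{Var}(y)$
  compared with the constant-slope projection (= classical $R^2$);
* **residual-permutation control** — permuting OLS residuals across fitted
  values enforces parallel quantile lines, so the trend test on permuted
  data must reject at only its nominal level;
* a **location–scale cohort simulator** with known truth
  $\beta(\tau) = 1 + (\theta\sigma/\mathrm{sd}(s))\Phi^{-1}(\tau)$ for
  validating all of the above.

See `vignettes/quantile-penetrance.Rmd` for the model and the numerical
choices.

## Worked example

The `analysis/` scripts run the whole chain on a simulated 1930-subject,
31-SNP cohort (triglyceride-like trait, θ = 0.3, σ = 20 mg/dL):

```sh
Rscript analysis/01_simulate_cohort.R
Rscript analysis/02_grs_adjust.R
Rscript analysis/03_quantile_profile.R
Rscript analysis/04_variance_explained.R
Rscript analysis/05_permutation_null.R
```

Output of steps 3–5 (written under `results/`):

```
Quantile-slope profile: 91 quantiles ( 5 - 95 ), n = 1930 , B = 1000 bootstrap replicates
  OLS slope 1.06 (SE 0.0487, R2 0.1976)
  slopes: 5%: 0.09097±0.128, 28%: 0.7208±0.0639, 50%: 1.111±0.059, 72%: 1.415±0.0556, 95%: 1.961±0.0937
Trend: 0.01722 ± 0.00109 per 1-percentile increase (z = 15.8, P = 2.78e-56)
slope 0.334 at the 10th vs 1.750 at the 90th percentile: 5.23-fold
OLS 95% CI covers only the 42..53th percentile slopes (87% outside)
Variance explained: 19.76% (constant slope) -> 25.59% (quantile-specific), improvement 29.5% [deciles]
Residual-permutation null: 200 permutations, rejection fraction at 0.05 = 0.040 (mean delta -1.09e-05)
```

Reading: each 1-percent increase in the trait percentile raises the
per-score-unit slope by 0.0172 ± 0.0011 mg/dL (P ≈ 3×10⁻⁵⁶) — the single
OLS slope (1.06) describes only the middle of the distribution, the
90th-percentile slope is 5.2-fold the 10th-percentile slope, and letting
the slope vary with the percentile raises the variance explained by the
GRS from 19.8% to 25.6%. The permutation control rejects at 4%,
confirming the trend is not a distributional artifact.

The same machinery runs on real data via
`run_config(genotypes=, weights=, phenotypes=, ...)` + `run_pipeline()`,
with dosages as TSV or VCF (DS field or GT hard calls) and weights as TSV
(`snp_id, effect_allele, other_allele, weight, trait`).

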