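---
title: "Quantile-dependent penetrance: model, estimation and validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-dependent penetrance: model, estimation and validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question

Classical regression summarizes a genotype-phenotype relationship by a
single slope, implicitly assuming the same per-allele effect applies whether
a subject sits at the 10th or the 90th percentile of the phenotype
distribution. *Quantile-dependent penetrance* is the phenomenon in which the
phenotypic expression of genetic variation — the slope of phenotype on
allele dose or on a genetic risk score (GRS) — instead varies with the
population percentile of the phenotype. When it is present, the standard
slope both mischaracterizes the relationship and underestimates the
proportion of variance a score can explain.

`quantpen` implements the full analysis chain: GRS construction from
published per-allele effects, covariate residualization, quantile-regression
slope profiles with paired-bootstrap covariance, a linear-contrast trend
test across percentiles, the projection method for variance explained under
quantile-specific slopes, and a residual-permutation artifact control —
together with a cohort simulator whose generative truth is known, so every
stage can be validated against closed forms.

## The risk score and adjustment

For subject $i$ with allele dosages $d_{ij} \in [0,2]$ (fractional for
imputed genotypes) and published per-allele effects $w_j$ (trait units per
allele),

$$\mathrm{GRS}_i = \sum_j d_{ij}\, w_j,$$

after orienting each dosage column to the effect allele (a column recorded
on the other allele contributes $2 - d_{ij}$). The score's unit is the
predicted trait unit. Strand flips are resolved when unambiguous; A/T and
C/G SNPs are accepted as recorded with a warning, the conservative
convention, since strand cannot be resolved for them from allele labels
alone. Missing dosages are mean-imputed per SNP so every subject keeps a
score.

Both the phenotype and the score are residualized on the same design —
intercept, sex, age, age², study indicators, smoking — before profiling.
Adjusting the two variables separately and regressing residual on residual
gives, for the least-squares fit, exactly the score coefficient of the
joint regression (the Frisch–Waugh property, tested to 1e-8), and mirrors
the two-step construction used in practice. Height analyses standardize to
z-scores; these are computed within sex, with the sample (n−1) SD — the
convention had to be chosen, and within-sex is flagged as a choice rather
than a claim.

## Quantile-slope profiles

For each quantile level $\tau$ on the grid $\{0.05, 0.06, \dots, 0.95\}$
(91 points; a coarser step is available for simulation loops), the slope
$\hat\beta(\tau)$ minimizes the pinball loss
$\sum_i \rho_\tau(y_i - a - b x_i)$, $\rho_\tau(u) = u(\tau - 1[u<0])$.

The two-parameter problem has an optimal solution interpolating two data
points, which fixes the solver design:

* $n \le 60$: exact enumeration of all lines through data-point pairs.
* larger $n$: iteratively reweighted least squares on a smoothed $|\cdot|$
  with a geometrically shrinking floor (floored at $10^{-11}$ of the
  residual scale), then an iterated "vertex polish" — refit through every
  pair among the lowest-|residual| points, repeating while the loss
  improves. The polish certifies a vertex solution; tests verify the
  attained loss equals the pair-enumeration minimum to 1e-9 up to n = 300.

Ties among optimal vertices are resolved by whichever vertex the descent
reaches; only the attained loss is contractual, and equivariance (shifts of
$y$, scalings of $x$) holds exactly on the enumeration path.

Standard errors and the full covariance of the slope vector across the grid
come from the paired bootstrap: subjects are resampled with replacement and
*all* quantiles are refitted on the same replicate — shared indices are
required for a valid cross-quantile covariance. B defaults to 1000; smaller
B values (not below 50) are intended for simulation loops and warn. A
replicate whose resampled score is constant is redrawn; more than 1% of
redraws aborts. The residual bootstrap is deliberately not used: with
heteroscedastic slopes the object of inference is the fan-out itself, which
residual resampling destroys.

## The trend test

With percentiles $k \in \{5,\dots,95\}$ and centered contrast weights
$c_k = k - \bar k$,

$$\hat\delta = \frac{\sum_k c_k \hat\beta(k)}{\sum_k c_k^2}, \qquad
\mathrm{Var}(\hat\delta) = \frac{c^\top \Sigma c}{(\sum_k c_k^2)^2},$$

with $\Sigma$ the bootstrap covariance: the least-squares slope of the
profile on the percentile, i.e. the canonical linear contrast, in trait
units per score unit per percent. "Linear contrast" does not by itself fix
the weighting; equal weighting is the default here, and a precision-weighted
variant (weights $\propto$ inverse bootstrap variance) is exposed as an
option for users who prefer to downweight the noisy extreme quantiles. $z =
\hat\delta/\mathrm{SE}$ is referred to the normal distribution — appropriate
at the cohort sizes involved (~2000 subjects, B = 1000). A bootstrap
covariance that fails positive semidefiniteness numerically is projected to
the nearest PSD matrix (eigenvalue clipping) with a warning.

Slopes at noninteger percentiles are linear interpolations of the grid;
outside the 5th–95th range the boundary slope is used (clamping), since the
profile carries no information beyond its grid.

## Variance explained by projection to the mean score

When slopes are parallel, projecting observations to any common score value
preserves their relative positions, so the classical $R^2$ needs no
reference point. When slopes vary with the percentile, the projection must
follow each observation's own trajectory. For each observation the package:

1. takes the percentile rank of the trait within its score decile (or,
   for a single SNP, within its genotype class) — rank $r$ of $m$ maps to
   $100(r-0.5)/m$, mid-ranks for ties, a symmetric convention that avoids
   the 0th/100th percentiles the profile cannot supply;
2. interpolates the profile at that percentile;
3. subtracts $\hat\beta(p_i)\,(x_i - \bar x)$ from the observation.

The variance explained is the variance-reduction ratio
$(\mathrm{Var}(y) - \mathrm{Var}(y^*))/\mathrm{Var}(y)$, computed under the
constant least-squares slope — where it reproduces the classical $R^2$
exactly (to 1e-6, tested) — and under the quantile-specific slopes; the
relative improvement is their percent difference, reported as missing when
the standard $R^2$ is below 1e-4 (a ratio on a near-zero base is noise).
Deciles are rank-based with ties to the lower bin, giving deterministic
groups whose sizes differ by at most one.

## The simulator and what it does (not) emulate

No generative mechanism for quantile dependence is established — observing
a fanning profile does not reveal whether the genotypes cause the extreme
values or penetrance is greater there. The simulator therefore uses the
simplest model that reproduces the phenomenon, a location–scale model:

$$y = \mu + s + \text{covariates} + \max(1 + \theta z_s,\, 0.1)\,\sigma\,
\varepsilon,$$

with $s = \sum_j \beta_j g_j$ the true score, $z_s$ its standardized value
and $\varepsilon$ standard normal. Its conditional quantile slopes have the
closed form

$$\beta(\tau) = 1 + \frac{\theta\sigma}{\mathrm{sd}(s)}\,\Phi^{-1}(\tau),$$

(the coefficient on $s$ is 1 by construction), which is what every
downstream estimate is validated against. The scale floor of 0.1 keeps the
model defined for extreme negative scores; with the default $\theta = 0.3$
it binds for ~0.1% of subjects and the closed form treats it as negligible.

Defaults emulate a two-study pharmacogenetics cohort:
1930 subjects; 31 independent SNPs (the triglyceride-score size) with
allele frequencies spread over (0.05, 0.5] and per-allele effects decaying
geometrically from 8 to 0.5 mg/dL, the shape of published lipid
meta-analysis tables; sex ~ Bernoulli(0.5), age ~ Uniform(30, 75), two
study labels, smoking ~ Bernoulli(0.2); $\sigma = 20$ mg/dL. With these
defaults the true quantile slope fans from about 0.2 (10th percentile) to
1.8 (90th) trait units per score unit — a pronounced version of the
several-fold 90th/10th ratios reported for lipids, deliberately strong so
recovery failures are visible. Genotypes are in Hardy–Weinberg proportions
with **no linkage
disequilibrium** and covariates are independent of genotype; passing tests
therefore show correctness of the estimators under the model, not
robustness to LD structure, genotype-covariate correlation, ascertainment,
or non-Gaussian trait noise — none of which the generator emulates. One RNG
stream per stage (genotypes, covariates, phenotype, bootstrap, permutation)
is derived from the master seed by a fixed offset rule, so each stage is
independently reproducible.

The Friedewald formula (LDL = TC − HDL − TG/5, mg/dL) ships as a utility
for assembling lipid panels; above 400 mg/dL triglycerides — the
conventional validity bound, chosen here since none is mandated — it
returns a flagged missing value rather than an error.

## Numerical and design choices

* **Solver tolerances.** IRLS floor $10^{-11}\times$ residual scale; polish
  accepts an improvement beyond $10^{-15}$ relative. Inside the bootstrap
  the polish searches 4 lowest-residual points rather than 10 — at that
  stage the solver is within $10^{-10}$ of the optimum and resampling noise
  dominates.
* **Degenerate inputs.** Constant $x$ errors; $n < 10$ errors; missing
  values are rejected at the fit level and dropped (with a message) at the
  adjustment level, keeping NA positions.
* **Permutation null.** Residuals of the OLS fit are permuted across fitted
  values — this preserves the fitted values and the marginal residual
  distribution exactly while enforcing parallel quantile lines, so the
  rejection fraction at 0.05 measures the artifact rate. The loop uses the
  5-percent-step grid and B = 200 by default (full resolution is a
  parameter away): the full 91-point, B = 1000 configuration inside a
  200-permutation loop is ~18 million quantile fits, far beyond what the
  check needs. The number of permutations (200) is a default; there is no
  canonical value for this control.
* **Problem sizes in the validation suite.** Closed-form recovery: 50
  replicates of n = 2000, 30 SNPs, $\theta = 0.3$, $\sigma = 20$, B = 200,
  5-percent grid. Type-I calibration: 500 replicates of the $\theta = 0$
  version at B = 100 — B enters only through the SE, and 100 replicates
  keep the bootstrap-SE noise small relative to the nominal level.
  Variance-improvement direction: 100 replicates at n = 1000, B = 50
  (only point slopes enter the projection). These sizes are the package's
  validation conditions and are stated here so the reported rates can be
  reproduced exactly.

## Known limitations

* Quantile crossing is reported as-is, not repaired; no simultaneous
  confidence bands.
* The trend test's normal reference is asymptotic in both n and B; at small
  n or B the test is approximate (the B = 100 choice above keeps the size
  within its Monte-Carlo band, ~4.7% in the package's own calibration).
* The variance-explained quantity is in-sample by construction; no
  cross-validated variant is provided.
* The two-component refit reproduces the *procedure* of giving a dominant
  SNP its own coefficient; the numerical coefficients depend on the sample
  and cannot be expected to match any published pair.
* Published-weight tables are user-supplied; the package ships none (the
  meta-analysis SNP lists are external publications).
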