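---
title: "Methods: two-sample MR screening and mediation analysis with mrmediate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-sample MR screening and mediation analysis with mrmediate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mrmediate)
```

## The problem

Observational associations between circulating metabolites, inflammatory
cytokines and venous thromboembolism (VTE, with subtypes DVT and PE) are
easily confounded. Two-sample Mendelian randomization (MR) sidesteps much of
that confounding by using genetic variants as instrumental variables: a SNP
that robustly shifts a metabolite's level, was assigned at conception, and
affects thrombosis risk only through that metabolite provides a natural
experiment for the metabolite's causal effect. `mrmediate` implements the
full analysis chain — instrument selection, harmonization, five univariable
estimators, heterogeneity/pleiotropy diagnostics, FDR tiering, and a
two-step/multivariable mediation calculus for questions of the form "does
the metabolite act on thrombosis *through* a cytokine such as PDGF-BB?" —
working entirely from GWAS summary statistics.

Three assumptions underlie every result: **relevance** (instruments are
strongly associated with the exposure — checked via per-SNP F-statistics),
**independence** (instruments are unrelated to confounders — supported by a
user-supplied confounder-SNP exclusion list), and **exclusion restriction**
(instruments affect the outcome only through the exposure — probed by the
Egger intercept, Cochran's Q, MR-PRESSO and leave-one-out diagnostics).

## Instrument selection

For exposure trait $X$ with per-SNP effects $\hat\gamma_j$ (standardized
scale), instruments are chosen by, in order:

1. **p-value screen**, strict inequality. Defaults: $p < 10^{-5}$ for
   metabolite-style panels with ~8k-sample GWAS, $p < 5\times10^{-6}$ for
   cytokine panels, $p < 5\times10^{-8}$ when a large case-control trait is
   the exposure (reverse-direction analyses).
2. **Greedy LD clumping** at $r^2 \le 0.001$ within 10,000 kb: variants are
   ranked by ascending p (ties broken by chromosome, then position, so the
   result is order-deterministic), the best remaining variant is kept, and
   correlated in-window variants are discarded. When an LD table is supplied
   but lacks an in-window pair, the conservative default treats the pair as
   correlated; with no LD table at all, variants are treated as independent.
3. **Palindromic exclusion**: A/T and C/G variants with effect-allele
   frequency in $[0.42, 0.58]$ are removed — at intermediate frequency
   neither the alleles nor the frequency can resolve the strand. The band is
   the dominant convention; outside it the frequency resolves the strand and
   the variant is kept.
4. **Confounder list exclusion** (e.g. BMI- or smoking-associated SNPs from
   an external lookup), a plain set difference.
5. **Weak-instrument filter**: per-SNP explained variance
   $R^2_j = 2\,\mathrm{MAF}_j(1-\mathrm{MAF}_j)(\hat\gamma_j/\mathrm{SD})^2$
   (SD = 1 for standardized traits; only this form is dimensionless and
   bounded) and $F_j = (N-2)R^2_j/(1-R^2_j)$; SNPs with $F_j < 10$ are
   dropped. The set-level
   $F = \frac{N-k-1}{k}\cdot\frac{\sum R^2_j}{1-\sum R^2_j}$ is reported as
   a diagnostic only — the exclusion is per-SNP.

Harmonization intersects variants across datasets and aligns every effect
to the exposure's effect allele: identical allele pairs are kept, swapped
pairs have the effect sign flipped and the frequency complemented,
palindromic variants are aligned through frequency concordance (and dropped
when either frequency is intermediate), and anything else is dropped with a
per-variant audit flag. The operation is idempotent.

## Estimators

With aligned SNP-exposure effects $\gamma_j$ and SNP-outcome effects
$\Gamma_j$ (standard errors $\sigma_{Y j}$), the per-SNP Wald ratio is
$\hat\beta_j = \Gamma_j/\gamma_j$ with first-order SE
$\sigma_{Y j}/|\gamma_j|$ (the usual two-sample convention; a second-order
SE including the $\gamma$ uncertainty is available behind a flag).

* **IVW** pools the ratios with weights $w_j = \gamma_j^2/\sigma_{Y j}^2$
  (equivalently, weighted regression of $\Gamma$ on $\gamma$ through the
  origin). The fixed-effect SE is $1/\sqrt{\sum w_j}$; when Cochran's
  $Q > J-1$ the SE is inflated by $\sqrt{Q/(J-1)}$ (multiplicative random
  effects). The random-effects trigger uses *exactly* the same Q as the
  reported heterogeneity diagnostic. p-values are two-sided normal.
* **MR-Egger** adds a free intercept to the weighted regression; the slope
  is consistent under InSIDE, and the intercept (with its p-value) is the
  directional-pleiotropy diagnostic. SEs use multiplicative overdispersion
  with the residual factor floored at 1; p-values are t on $J-2$ df.
* **Weighted median**: ratios ordered, inverse-variance weights normalized,
  the estimate linearly interpolated at cumulative weight 0.5 (each order
  statistic placed at $S_j - w_j/2$). Consistent when valid instruments
  carry $\ge$ 50% of the weight.
* **Weighted / simple mode**: argmax of a Gaussian-kernel density of the
  ratios (inverse-variance or uniform weights) on a fixed 512-point grid.
  Bandwidth is $0.9\min(\mathrm{sd},\mathrm{mad})J^{-1/5}$ times a
  user-scalable factor (default 1); the paper-trail methods name no
  bandwidth, so the rule mirrors common mode-estimator practice.
* Median and mode SEs come from a **seeded parametric bootstrap** (default
  1000 replicates) that redraws each SNP's $\gamma_j$ and $\Gamma_j$ from
  normals with their reported SEs. The seed is mandatory throughout the
  pipeline; identical inputs, config and seed reproduce every output
  bit-identically.

All effects on a binary outcome are log-odds; `beta_to_or()` converts to
OR with $\exp(\beta \pm 1.96\,\mathrm{SE})$ intervals.

## Sensitivity diagnostics

* **Cochran's Q** in IVW ($J-1$ df, deviations from the pooled ratio) and
  Egger ($J-2$ df, deviations from the fitted line) variants, upper
  chi-square tail.
* **MR-PRESSO**: per SNP, the leave-one-out IVW slope $\hat\beta_{-j}$
  defines a residual $r_j = \Gamma_j - \hat\beta_{-j}\gamma_j$; the observed
  weighted RSS is compared with `n_sim` parametric replicates
  ($\Gamma^*_j \sim N(\hat\beta_{-j}\gamma_j, \sigma_{Y j}^2)$, the full
  statistic recomputed each time). The global p uses the
  $(1+\#\{RSS^* \ge RSS\})/(n_{sim}+1)$ estimator, so it is never exactly 0
  and is bounded below by $1/(n_{sim}+1)$. Per-SNP outlier p-values come
  from each residual's own simulated null, Bonferroni-adjusted by $J$, and
  are reported only when the global test is itself significant. When
  outliers exist, the outlier-corrected IVW estimate is computed and a
  distortion test compares the induced estimate shift against random
  same-size removals (two-sided empirical p). Simulation draws are made in
  a canonical variant order, so the result is invariant to input row order.
* **Leave-one-out**: IVW re-estimated $J$ times, one instrument excluded at
  a time.

The screening pipeline applies the outlier policy downstream: an exposure
whose outlier-corrected IVW association is no longer significant
(p > 0.05) is removed from the report tables, with a reason-coded log line.

## Multiple testing

IVW p-values are BH-FDR adjusted (`stats::p.adjust`) within an
outcome-by-panel family; `fdr_m` lets the family reflect the full panel
size (e.g. 41 cytokines, or 1,400 metabolite traits) when only a subset is
re-analyzed, padding the family with p = 1 placeholders. Tiers follow the
convention: *significant* when FDR-adjusted p < 0.05, *suggestive* when
only the raw p < 0.05. Bonferroni is available as a stricter alternative.

## Mediation calculus

For an exposure $E$, mediator $M$ and outcome $O$:

1. **Two-step MR** estimates the three univariable IVW legs
   $\beta_{EM}$, $\beta_{MO}$, $\beta_{EO}$, and gates a candidate for
   multivariable confirmation only when all three have p < 0.05. A flagged
   triplet whose indirect-path sign ($\mathrm{sign}(\beta_{EM}\beta_{MO})$)
   opposes the total effect is additionally labelled inconsistent-direction.
2. **MVMR** regresses $\Gamma_j$ on $(\gamma_j, \delta_j)$ jointly (no
   intercept, weights $1/\sigma_{Y j}^2$, overdispersion floored at 1) to
   obtain the direct effects $\beta'_{EO}$ and $\beta'_{MO}$. The
   instrument set is the union of the exposure's and mediator's selected
   instruments, jointly re-clumped on the stronger of the two association
   p-values and re-harmonized to all three traits; the union is the
   dominant convention and keeps the design full-rank. A Q-statistic-based
   conditional instrument strength (weighted residual variance of one
   effect column after regressing out the other, over $J-2$ df) is
   reported per exposure as a diagnostic.
3. **Mediated effect**: $\beta_{EMO} = \beta_{EM}\cdot\beta'_{MO}$ with
   delta-method SE
   $\sqrt{\beta'^2_{MO}\mathrm{SE}^2_{EM} + \beta^2_{EM}\mathrm{SE}'^2_{MO}}$,
   95% CI $\beta_{EMO} \pm 1.96\,\mathrm{SE}_{EMO}$, two-sided normal p, and
   mediated proportion $\beta_{EMO}/\beta_{EO}$ (undefined at zero total
   effect; reported with a `ci_includes_zero` flag when the mediated-effect
   interval crosses zero, since such proportions are conventionally still
   printed). The p-value is computed from unrounded intermediates; published
   tables that derived theirs differently may not match it exactly, which is
   why the worked-example checks target the mediated effects and CI bounds
   rather than the p-values. `se_from_ci()` back-derives an SE from a
   printed symmetric interval, $(\mathrm{high}-\mathrm{low})/(2z)$, for
   consuming tables that print CIs only.

```{r worked-example}
# worked example: printed two-step and MVMR-adjusted coefficients for the
# glycocholate -> PDGF-BB -> VTE pathway
mediation_effect(beta_em = -0.097, se_em = 0.036,
                 beta_prime_mo = 0.089,
                 se_prime_mo = se_from_ci(0.041, 0.136),
                 beta_eo = -0.059)
```

## The synthetic-data generator

Real metabolite/cytokine/VTE GWAS cannot be bundled, so
`simulate_summary_stats()` generates the full three-trait summary-statistic
structure under a known structural model: exposure instruments
$\gamma_j$, mediator effects $\delta_j = \tau\gamma_j$ at exposure SNPs
plus mediator-specific instruments (which keep the MVMR design full rank),
and outcome effects
$\Gamma_j = \theta_{dir}\gamma_j + \theta_{MO}\delta_j + \alpha_j$ with
optional balanced or directional pleiotropy $\alpha_j$.

Defaults emulate the calibration study's conditions: continuous exposure and
mediator GWAS of 8,299 and 8,293 individuals, a case-control outcome of
21,021 cases / 391,160 controls with effective size
$N_{eff} = 4/(1/\mathrm{cases}+1/\mathrm{controls})$, 30 exposure
instruments, and structural coefficients
$\tau = -0.097$, $\theta_{MO} = 0.089$, $\theta_{dir} = -0.0504$ (total
$\approx -0.059$) — the glycocholate/PDGF-BB/VTE pathway. Standard errors
use the standardized-trait approximation
$1/\sqrt{2\,\mathrm{MAF}(1-\mathrm{MAF})N}$; observed effects add
$N(0, \mathrm{SE}^2)$ noise unless `noiseless = TRUE` (which makes exact
structural identities available to tests).

True instrument effects are drawn from a two-sided normal (scale
`effect_sd` = 0.25) *truncated to a per-SNP F-statistic band*, default
[30, 5000]. Published instrument panels are post-selection objects — every
SNP already cleared a genome-wide screen — and their observed per-SNP F
spans roughly 20 to 5,300; the floor sits at 30 rather than 20 because the
band constrains the *true* effects, and sampling noise would otherwise push
a material fraction of *observed* F below the envelope. MAFs are uniform on
[0.1, 0.45]; variants are placed 20 Mb apart on chromosomes 1–22 and allele
pairs drawn from the non-palindromic combinations (a configurable
palindromic fraction exercises the exclusion rule).

What the generator does **not** emulate: LD between instruments (clumping
is exercised with explicit synthetic LD tables instead), winner's-curse
inflation of the selected effects, allele-frequency differences between
cohorts, sample overlap, and population stratification. Passing the
calibration suite therefore shows the estimators and diagnostics are
implemented correctly under the stated model — not that real-data analyses
are immune to those phenomena.

## Calibration and recovery experiments

The test suite runs seeded simulation experiments sized to keep the default
run inside a few minutes: 200-replicate recovery panels for the five
estimators at $J = 50$ instruments and $N = 50{,}000$ per trait (each
estimator's mean within 3 Monte-Carlo SEs of truth), 1000 null simulations
for Cochran's Q type-I error, 100 seeded MR-PRESSO runs each for power
(10-SE injected outlier) and null calibration, 200-replicate MVMR and
mediated-proportion recovery, and a 1000-vector brute-force cross-check of
the BH step-up. Recovery experiments use the $N = 50$k convention because
at $N \approx 8$k the MVMR mediator coefficient shows ~1% regression
dilution — attenuation from sampling noise in the SNP–mediator effects,
a known finite-sample property of weighted MVMR (shared by the standard
tooling, and worst at exposure SNPs where $\delta_j = \tau\gamma_j$ is
comparable to its SE), not an implementation artifact. At study scale this
dilution slightly shrinks $\beta'_{MO}$ and hence the mediated effect; it
is listed under limitations below.

## Numerical choices

* Monte-Carlo p-values use $(1+\mathrm{count})/(n+1)$, never exactly zero.
* Duplicate variants on read keep the smallest p (first occurrence on
  ties); clumping ties break by (chromosome, position) — all deterministic.
* Table output rounds half away from zero to 3 decimals (journal
  convention; base R rounds half to even) and prints p-values as `9.29E-05`
  style scientific notation.
* Egger and MVMR overdispersion factors are floored at 1 (never deflate a
  fixed-effect SE); IVW inflates only when $Q/\mathrm{df} > 1$.
* `wald_ratios` excludes $\gamma_j = 0$ variants with a warning; estimator
  minima are 2 (IVW), 3 (Egger, median, modes), 4 (MR-PRESSO, MVMR).
* Multi-allelic and indel records are rejected on read (the harmonization
  rules are defined for single-nucleotide pairs only).

## Known limitations

* Regression dilution at small GWAS sample sizes, as described above.
* First-order Wald SEs ignore SNP-exposure uncertainty (standard, but
  optimistic for instruments near the F threshold); the second-order
  option is available.
* The weighted-mode bandwidth rule is a convention, not an optimum; results
  for small, diffuse instrument sets can be bandwidth-sensitive.
* Mediated proportions are ratios of estimates and can be unstable when the
  total effect is near zero; the CI-includes-zero flag should be heeded.
* No correlated-instrument (generalized) IVW; the LD input supports
  clumping, not modelling of residual correlation.
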