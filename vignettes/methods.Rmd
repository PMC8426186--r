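---
title: "Models and methods: cell-type enrichment and composition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: cell-type enrichment and composition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

sctypestats implements two statistical procedures that connect a single-cell
atlas to external data: an enrichment model that asks *which cell types
express the genes implicated by a GWAS*, and a mixed model that asks *which
clinical or technical factors shift cell-type composition across samples*.
This vignette describes both models, their assumptions, the tunable
parameters, the synthetic-data generators used to validate them, and the
numerical choices made along the way.

## 1. Cell-type enrichment of GWAS-associated genes

### From summary statistics to gene-level Bayes factors

For each variant $j$ with estimated log odds ratio $\hat\beta_j$ and
standard error $s_j$, the evidence for association is summarised by the
Wakefield approximate Bayes factor under a Gaussian effect prior
$\beta \sim N(0, W)$:

$$\ln \mathrm{ABF}_j = \tfrac12 \ln\!\frac{s_j^2}{s_j^2 + W}
  + \frac{z_j^2}{2}\,\frac{W}{s_j^2 + W}, \qquad z_j = \hat\beta_j / s_j.$$

We orient the factor so values above 1 favour association. The prior
variance defaults to $W = 0.04$ (prior standard deviation 0.2 on the log-OR
scale), the conventional choice for binary-trait GWAS effect sizes; it is a
configuration parameter, not a fitted quantity.

Each gene receives a cis window of 1 Mb centred on its transcription start
site (TSS; strand-resolved when read from a GTF: feature start on `+`,
feature end on `-`). Window edges are inclusive, coordinates are 1-based and
fully closed, and a variant inside two overlapping windows contributes to
both genes. Within a window, variant Bayes factors are averaged under an
exponential TSS-proximity prior,

$$\mathrm{RBF}_g = \frac{\sum_j e^{-\lambda d_{gj}}\,\mathrm{ABF}_j}
                        {\sum_j e^{-\lambda d_{gj}}},$$

with $d_{gj}$ the TSS distance in bp. Under a single-causal-variant
assumption, $\mathrm{RBF}_g$ is the Bayes factor for "some variant in this
region is causal". The decay rate defaults to $\lambda = 10^{-5}$ per bp
(mean regulatory distance 100 kb); `estimate_decay_rate()` provides the
closed-form exponential MLE $\hat\lambda = 1/\bar d$ when empirical
enhancer–promoter distances are available. The average is computed by
log-sum-exp, so per-variant log Bayes factors up to several hundred are
handled without overflow.

### The hierarchical feature-level prior

Expression enters through two standardized per-gene covariates. With
$E_{gc}$ the mean expression of gene $g$ in cell type $c$, we set
$f_{gc} = \ln(1 + E_{gc})$, take the focal cell type's column and the
per-gene mean across all cell types as the baseline, and z-score both
across genes (sample SD). The log transform bounds the leverage of very
highly expressed genes; standardization puts the enrichment coefficients of
all cell types on a common scale. A constant column cannot be standardized
and is flagged degenerate.

The prior probability that gene $g$ harbours a causal association is
modelled with a logistic link,

$$\pi_g = \mathrm{logit}^{-1}\left(\gamma_0 + \gamma_b\,x_{\text{base},g}
  + \gamma_c\,x_{c,g}\right),$$

chosen because it keeps $\pi_g \in (0,1)$ for any coefficients and is
standard practice for annotation-driven prior models of this kind. The
model marginal likelihood is
$\prod_g \left[(1-\pi_g) + \pi_g\,\mathrm{RBF}_g\right]$, and the
enrichment of a cell type is the MLE $\hat\gamma_c$ with a Wald standard
error from the observed information. Each cell type is fitted separately
(focal feature plus shared baseline) rather than jointly across all cell
types; this matches the per-cell-type reporting of the analysis and keeps
each fit a three-parameter problem.

Two identities make the computation stable and cheap: the per-gene log
likelihood is a log-add-exp of $\log(1-\pi_g)$ and
$\log\pi_g + \ln\mathrm{RBF}_g$, and with
$t_g = \mathrm{logit}^{-1}(\eta_g + \ln\mathrm{RBF}_g)$ — the posterior
probability that gene $g$ is causal — the score and curvature in the linear
predictor $\eta_g$ are $t_g - \pi_g$ and $t_g(1-t_g) - \pi_g(1-\pi_g)$.

### Optimization and inference

The likelihood is maximized by BFGS with the analytic gradient from four
starts, $(\mathrm{logit}(0.01), 0, 0)$, $(\mathrm{logit}(0.05), 0, 0)$ and
$(\mathrm{logit}(0.01), 0, \pm 0.5)$, the best log likelihood winning and
ties going to the first start; a Newton polish with the analytic Hessian
then drives the gradient infinity norm below $10^{-8}$ (relative to the log
likelihood magnitude). Fits where the information matrix is not positive
definite are flagged unconverged. If every gene has the same regional Bayes
factor the likelihood carries no information about $\gamma$; the fit is
flagged degenerate and reports $\gamma_c = 0$ with an infinite SE rather
than a spurious number.

Across cell types, two-sided Wald p-values are adjusted by
Benjamini–Hochberg, with calls at FDR 10% by default. The procedure is BH
(rather than, say, BY) because the per-cell-type tests share a common set
of gene-level Bayes factors and are positively dependent in the PRDS sense
BH tolerates.

## 2. Composition analysis with a Poisson GLMM

The count $y_{st}$ of cells of type $t$ in sample $s$ is modelled as

$$y_{st} \sim \mathrm{Poisson}(\mu_{st}), \qquad
  \log \mu_{st} = \mu + b_t + a_s + \sum_f u^{(f)}_{l_f(s),\,t},$$

with cell-type fixed effects $b_t$ under a reference-level constraint, a
per-sample random intercept $a_s \sim N(0, \sigma_s^2)$, and, for every
clinical or technical factor $f$, independent random effects
$u^{(f)}_{l,t} \sim N(0, \sigma_f^2)$ indexed by (factor level, cell type).
Treating the factors as random effects keeps the model identifiable despite
the collinearity among clinical and technical covariates, and the
interaction with cell type is exactly what "this factor shifts composition"
means. The sample intercept absorbs differences in per-sample totals, so no
offset is needed; factor main effects on totals are deliberately omitted
(they are not identifiable next to the sample intercept).

The model is fitted by the Laplace approximation via `lme4::glmer`
(`nAGQ = 1`, bobyqa for the variance parameters), the standard tool for
this model class. From the fit we report:

* **Variance components** $\hat\sigma_f$ — how much a factor moves
  composition overall.
* **Their standard errors**, from a central finite-difference Hessian
  (step $10^{-4}$) of the Laplace marginal log likelihood in
  $(\ln\sigma, \beta)$ coordinates, inverted and delta-method-mapped back
  to the $\sigma$ scale. Differentiating in $\ln\sigma$ respects
  positivity; including $\beta$ in the Hessian propagates fixed-effect
  uncertainty. A component estimated at the zero boundary, or a
  non-positive-definite information matrix, yields a missing SE with a
  warning rather than a fabricated number.
* **Posterior means and SDs** per coefficient — the conditional modes and
  the curvature-based conditional SDs of the Laplace approximation
  (diagonal of the inverse penalized-likelihood Hessian).
* **LTSR**, the local true sign rate
  $\Phi(|m|/s) \in [0.5, 1]$: the posterior probability that the true
  effect shares the sign of its posterior mean. Unlike a p-value it is a
  statement about the fitted effect's direction, which is the quantity of
  interest when screening many (level × cell type) effects.

When a variance component is estimated at zero its coefficients are
reported as exactly zero with LTSR 0.5 (the sign is unknowable), avoiding a
0/0 in the LTSR formula.

## 3. What the synthetic generators emulate

Both generators are first-class, seeded, and mirror the fitted models
exactly, which is what makes parameter recovery a meaningful check.

**GWAS generator** (`simulate_gwas_study`): expression is drawn with
$\ln(1+E)$ values $N(4, 1)$ i.i.d. (clipped at zero; negligible mass), so
the standardized features are approximately standard normal across genes;
causal genes follow the logistic prior computed from exactly the features
`build_features()` would produce; genes are laid out on synthetic
chromosomes of 200 genes with 1-Mb TSS spacing, so adjacent windows are
essentially disjoint and positions stay in a realistic coordinate range;
each causal gene has exactly one causal variant, chosen within the window
with probability proportional to $e^{-\lambda d}$ and effect
$\beta \sim N(0, W)$; observed effects add independent $N(0, s_j^2)$ noise
with $s_j = 0.03$ by default, a typical large-consortium log-OR standard
error. **No linkage disequilibrium is simulated** — the regional-BF
estimator assumes at most one causal variant per window, and the generator
honours that assumption rather than stress it. Consequently, passing
recovery tests show the estimator is correct under its own assumptions;
they do not show robustness to LD, allele-frequency structure, or
case/control sampling, none of which the generator models.

**Composition generator** (`simulate_composition`): factor levels are
assigned to samples in balanced random fashion (uniform in distribution,
balanced in count, which keeps every level identifiable at small $n$);
random effects and sample intercepts are drawn from their Gaussian laws and
counts from the conditional Poisson. Real single-cell data are
overdispersed relative to Poisson and have correlated cell-type fractions;
the model (and hence the generator) attributes all extra-Poisson variation
to the random effects, so calibration statements carry over to real data
only to the extent that this decomposition holds.

Random-number streams are separated per component (expression, causal
status, variant placement, effects, noise) so that, e.g., changing the
noise model does not perturb the gene layout.

## 4. Validation study designs

The test suite validates each layer against an independent oracle and the
pipelines end-to-end by parameter recovery. The problem sizes are chosen so
the whole suite runs on a laptop in minutes while leaving the statistical
checks well-powered:

* Wakefield ABF vs direct numerical quadrature of the defining integral on
  a 3 × 5 × 5 grid (relative error < $10^{-6}$).
* Regional BF vs brute-force raw-scale weighted averaging on 1,000 random
  instances, plus bound, order-invariance and weight-scaling properties.
* Enrichment recovery: 200 studies of 5,000 genes × 10 variants with true
  $\gamma_c = 1$; mean bias within ±0.1 and 95% Wald coverage in
  [0.90, 0.98]. Size: 500 null studies of 1,000 genes; rejection rate at
  $\alpha = 0.05$ inside the exact binomial 99% interval. FDR: 100
  complete-null studies of 100 cell types each; mean false discovery
  proportion at BH level 0.10 at most 0.10.
* GLMM: Laplace log likelihood vs dense quadrature on a 2 × 2 instance
  (the fixture uses counts near 1,000, where the Laplace approximation is
  in its asymptotic regime and the $10^{-3}$ agreement is a meaningful
  implementation check); recovery of $\sigma = (0.8, 0.3)$ at 200 samples
  × 9 cell types with 4 levels per factor over 20 seeds. Note that ML
  variance components are attenuated when a factor has few levels: the
  cell-type fixed effects absorb each factor's per-cell-type mean across
  levels, so roughly only the fraction $(L-1)/L$ of the generative variance
  is identifiable — about a 13% downward pull on $\sigma_f$ at $L = 4$ —
  and the recovery check reflects the estimator including this intrinsic
  bias, not just Monte Carlo noise; LTSR calibration pooled over 50 fits of 60
  samples × 6 cell types with $\sigma_f = 0.2$ and baseline counts near 20
  — parameters picked so that a substantial number of coefficients land in
  the LTSR 0.90–0.95 band being audited.

## 5. Degenerate inputs, ties, and other numerical choices

* Duplicate variant identifiers are a hard error (ambiguous input), never a
  silent de-duplication.
* Chromosome dialects (`chr1` vs `1`) are normalized by stripping the
  prefix before matching; variants on chromosomes absent from the
  annotation are dropped with a logged count.
* An empty variant table yields an empty pair table with a warning, not an
  error; a gene with no variants is simply absent from the regional-BF
  table.
* Genes shared between the Bayes-factor table and the feature table are
  joined by identifier; fewer than 50 shared genes is an error, since a
  three-parameter prior model on fewer genes is not meaningfully
  identifiable.
* The enrichment fit requires finite log regional Bayes factors; infinities
  indicate an upstream problem and are refused.
* In `enrich_all`, a cell type whose individual fit fails is recorded with
  `converged = FALSE` and excluded from the BH adjustment rather than
  aborting the remaining cell types.
* A counts matrix that is entirely zero is an error; an all-zero cell-type
  column is allowed (the Poisson likelihood handles it).

## 6. Known limitations

* The enrichment model scores one cell type at a time; correlated
  expression between cell types yields correlated (not independent)
  enrichment calls, which BH tolerates but a joint model would resolve.
* No LD modelling and no per-variant fine-mapping output: the regional BF
  is a gene-level summary only.
* The composition model is Poisson with Gaussian random effects fitted by
  Laplace; there is no negative-binomial or zero-inflated variant, and no
  MCMC posterior — LTSR rests on the Gaussian approximation at the mode.
* LTSR calibration is conditional on the estimated variance components;
  with very few levels per factor the plug-in $\hat\sigma_f$ understates
  uncertainty slightly.
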