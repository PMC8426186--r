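# sctypestats

Statistical tools linking single-cell atlases to disease genetics and to
sample metadata. The package is aimed at analysts who have (a) GWAS summary
statistics for a trait and a genes × cell-types mean-expression matrix, and
want to know **which cell types are enriched for the trait's associated
genes**; or (b) a samples × cell-types count table with clinical/technical
metadata, and want to know **which factors shift cell-type composition**.

## The two models

**1. Hierarchical enrichment of GWAS genes.** Per-variant association
statistics (log OR β̂ⱼ, SE sⱼ) become Wakefield approximate Bayes factors
under an effect prior N(0, W):

    ln ABFⱼ = ½ ln( sⱼ²/(sⱼ²+W) ) + (zⱼ²/2)·W/(sⱼ²+W),   zⱼ = β̂ⱼ/sⱼ

Variants in a 1-Mb window centred on each gene's TSS are averaged with
exponential proximity weights wⱼ = exp(−λdⱼ) into a regional Bayes factor
RBF_g — the gene-level evidence for association under a single-causal-variant
assumption. A logistic feature-level prior
π_g = logit⁻¹(γ₀ + γ_b·x_base + γ_c·x_c), built from the focal cell type's
standardized log1p expression and a baseline across all cell types,
multiplies the Bayes factors; the likelihood Π_g[(1−π_g) + π_g·RBF_g] is
maximized per cell type and γ̂_c, its Wald z and the BH-adjusted q-value
(FDR 10% by default) are reported per cell type.

**2. Poisson GLMM of composition.** Counts y_st of cell type t in sample s
follow

    y_st ~ Poisson(μ_st),  log μ_st = μ + b_t + a_s + Σ_f u⁽ᶠ⁾[l_f(s), t]

with cell-type fixed effects, a per-sample random intercept, and one random
(level × cell type) interaction block per clinical/technical factor,
u⁽ᶠ⁾ ~ N(0, σ_f²). The fit (Laplace approximation) yields per-factor σ̂_f
with finite-difference standard errors, posterior means/SDs per coefficient,
and the local true sign rate LTSR = Φ(|m|/s) — the posterior probability
the effect's sign is right.

Seeded generators (`simulate_gwas_study`, `simulate_composition`) mirror
both models with known ground truth and drive the parameter-recovery tests.

## Worked example

```r
library(sctypestats)

# a synthetic study with a known enriched cell type (gamma_c = 1 for ct001)
sim <- simulate_gwas_study(gwas_sim_config(n_genes = 5000, seed = 1))

gene_bfs <- map_variants_to_genes(sim$sumstats, sim$genes) |> regional_bf()
fit <- fit_enrichment(gene_bfs, build_features(sim$expression, "ct001"))
fit
#> Hierarchical enrichment fit for cell type 'ct001'
#>   genes: 5000   loglik: 13176.7966   converged: TRUE   degenerate: FALSE
#>           gamma0 gamma_base gamma_c
#> estimate -1.9309     0.0410  0.9828
#> se        0.0636     0.0576  0.0664
```

The generating coefficient γ_c = 1 is recovered as 0.98 ± 0.066; γ₀ = −2
(about 12% of genes causal) comes back as −1.93. Scoring all 10 cell types
and adjusting across them:

```r
res <- enrich_all(gene_bfs, sim$expression, fdr_level = 0.10)
head(res, 3)
#>   cell_type gamma0 gamma_base gamma_c     se      z        p        q
#> 1     ct001  -1.93      0.041   0.983 0.0664 14.795 1.57e-49 1.57e-48
#> 2     ct007  -1.67      0.334  -0.024 0.0535 -0.450 6.53e-01 6.53e-01
#> 3     ct006  -1.67      0.339  -0.040 0.0530 -0.763 4.46e-01 4.95e-01
autoplot(res)   # z-score dot plot with FDR calls highlighted
```

Only the truly enriched cell type has overwhelming evidence (z = 14.8,
q ≈ 10⁻⁴⁸). Composition works the same way:

```r
simc <- simulate_composition(composition_sim_config(
  n_samples = 60, n_cell_types = 5,
  factors = c(disease = 2L, region = 3L),
  sigma = c(disease = 0.5, region = 0.3),
  sigma_sample = 0.2, base_log_mean = log(50), seed = 11))
fitc <- fit_composition(simc$counts, simc$metadata)
variance_components(fitc)
#>   factor    sigma se_sigma
#> 1 disease   0.368   0.0855
#> 2 region    0.289   0.0591
tidy(fitc) |> head(3)
#>   factor  level    cell_type post_mean post_sd  ltsr
#> 1 disease disease1 ct01         0.369    0.146 0.994
#> 2 disease disease1 ct02        -0.129    0.145 0.813
#> 3 disease disease1 ct03        -0.394    0.146 0.996
autoplot(fitc)  # effect heat map, high-LTSR tiles outlined
```

A per-(level, cell type) effect with LTSR 0.994 has a 99.4% posterior
probability of pointing in the reported direction.

A command-line interface mirrors the same pipelines
(`inst/cli/sctypestats simulate-gwas|simulate-composition|enrich|compose|config-dump`);
every run writes a `manifest.json` with parameters, seed and input
checksums, and fixed-seed runs are byte-identical.

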