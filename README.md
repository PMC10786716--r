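# prsbridge

Cross-ancestry polygenic risk scores by two-stage Bayesian ridge regression.

## The problem

Polygenic risk scores (PRS) built from a large European-ancestry GWAS lose
much of their predictive power in other ancestries: linkage disequilibrium
(LD) patterns differ, allele frequencies drift, and causal effect sizes can
vary with environment. Yet causal effects are highly correlated across
ancestries, so a well-powered *discovery* GWAS still carries most of the
information needed to predict in an underpowered *target* population —
if its effect-size estimates can be carried across rather than its
ancestry-specific tags.

`prsbridge` bridges the two populations with conjugate Gaussian ("Bayesian
ridge") models at LD-defined loci, keeping all variants within each locus
instead of picking single best SNPs, so that causal signal survives even when
the causal variants themselves are untyped or poorly tagged.

## The model

All modelling is per locus (clumped regions with r² > 0.01 within 1 Mb of a
lead variant, assumed independent). With trait *y* ~ N(Xβ, ψI):

**Stage 1 (discovery population).** A zero-centred Gaussian prior
β ~ N(0, ψ diag(λ)) with frequency-dependent precision
λₖ = λ⁽⁰⁾(θₖ(1−θₖ))^α gives the conjugate posterior

    β | data ~ N(β̃, ψ Ω),   Ω = diag(λ) + Φ,   β̃ = Ω⁻¹ diag(Φ) β̂,

computed entirely from GWAS summary statistics (marginal effects β̂, allele
frequencies θ) and a genotypic covariance Φ estimated from an LD reference
panel; `diag(Φ) β̂` recovers the per-observation X᷀y (equal to 2θ(1−θ)β̂
under Hardy–Weinberg equilibrium). Models are fit over a grid of
α ∈ {0, …, 1} and λ⁽⁰⁾ ∈ {0.05, …, 5}; loci enter nested subsets S_k by
top-SNP p-value < 10⁻ᵏ, k = 1…8; the resulting 280 genome-wide candidate
scores are stacked by ridge regression on test individuals with the penalty
chosen by closed-form leave-one-out cross-validation.

**Stage 2 (target population).** The best-fitting stage-1 posterior becomes
the target-population prior, β₂ ~ N(β̃₁, ψτΩ₁), with τ controlling how
strongly target effects are pulled toward the discovery posterior
(τ → ∞ copies them; τ → 0 discards them):

    Ω₂ = τΩ₁ + Φ₂,   β̃₂ = Ω₂⁻¹(τΩ₁β̃₁ + diag(Φ₂) β̂₂).

Loci are ranked by a pseudo-F statistic
F = (n_eff − k)/(k σ²) · β̃₂ᵀΩ₂β̃₂ with n_eff = n(1+τ), quantile-matched so
each subset keeps as many loci as the p-value ranking. Variants missing from
the target data are handled by Gaussian conditioning of the stage-1
posterior on their effects being zero.

**Combining.** Three candidate models — M1 (two-stage), M2 (target-only
stage 1), M3 (ridge stack of both grids merged) — are weighted by approximate
posterior model probabilities wᵢ ∝ σᵢ⁻ⁿ from their cross-validated residual
variances, and exported as a single additive per-SNP weight file.

A two-population simulator (Balding–Nichols allele-frequency divergence,
AR(1) latent-Gaussian block LD, cross-population effect correlation,
configurable polygenicity and heritability) makes the whole pipeline testable
without external data.

## Worked example

```r
library(prsbridge)
library(dplyr)

world <- simulate_world(sim_config(
  n_pop1 = 4000, n_pop2 = 1000, n_test = 1000, n_valid = 1000,
  n_blocks = 30, block_size = 10, seed = 2024
))
#> <sim_world> 300 variants; pop1 4000+1000, pop2 1000+1000+1000;
#>             h2 0.50, causal 5%, FST 0.12, rho_beta 0.90

fit <- prs_bridge(
  world$sumstats1, world$pop1$test, world$pop1$test, world$pop1$pheno,
  world$sumstats2, world$pop2$test, world$pop2$test, world$pop2$pheno
)
fit
#> <bridge_fit>
#> <model_average> 3 models on 1000 samples
#>   M1: sigma^2 = 4.592, weight = 0.000
#>   M2: sigma^2 = 4.298, weight = 0.300
#>   M3: sigma^2 = 4.291, weight = 0.700
```

The model average leans on M3, the merged stack that lets discovery-informed
and target-only columns contribute jointly. Scoring the held-out validation
samples and measuring covariate-adjusted variance explained:

```r
scores <- predict(fit, world$pop2$valid)
bootstrap_r2(world$pop2$pheno, scores[c("sample_id", "prs")],
             n_boot = 1000, seed = 1)
#>      r2     se ci_low ci_high n_boot     n
#> 1 0.488 0.0218  0.444   0.529   1000  1000

# target-only model alone on the same samples
variance_explained(world$pop2$pheno,
                   rename(scores[c("sample_id", "M2")], prs = M2))
#> [1] 0.4845
```

The bridged PRS explains 48.8% of trait variance (of a simulated SNP
heritability of 50%), a gain over the 48.5% of the target-only model — small
here because this example's target GWAS is relatively well powered; the gain
grows as the target GWAS weakens. `tidy(fit)` returns the final per-SNP
weight table, `export_weights()`/`write_snp_weights()` produce a portable
scoring file, and `autoplot()` methods display stacked fits, grid accuracies
and model weights. A command-line front end over the same functions is in
`inst/cli/prsbridge.R` (subcommands `simulate`, `stage1`, `stage2`,
`combine`, `evaluate`, `run-all`).

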