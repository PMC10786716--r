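---
title: "Bridged polygenic scores: model, priors and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bridged polygenic scores: model, priors and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(prsbridge)
```

## The modelling problem

A polygenic risk score trained on one ancestry transfers poorly to another
because the best tagging variant for a causal allele differs between LD
structures, and allele frequencies drift. `prsbridge` treats this as an
effect-size *estimation* problem rather than a variant *selection* problem:
within each LD-defined locus all variants are retained and their joint
effects estimated by conjugate Gaussian (ridge-type) models, first in the
well-powered discovery population, then updated with the underpowered target
population's GWAS.

Assumptions worth stating explicitly:

* **Locus independence.** Loci produced by clumping (lead p ≤ 0.01, members
  p ≤ 0.01 within 1 Mb and r² > 0.01 with the lead) are modelled as
  independent blocks. Long-range LD that crosses locus boundaries is ignored.
* **Gaussian trait, additive coding.** The trait is modelled as
  y ~ N(Xβ, ψI) with X the 0–2 effect-allele dosage; binary traits are out
  of scope.
* **Summary statistics are internally consistent**: the marginal effects,
  standard errors, frequencies and sample size come from one GWAS on one
  scale. Statistics from a standardized-trait GWAS must first be rescaled
  (`rescale_sumstats()`), which preserves z-scores and p-values exactly.
* **The LD panel represents the GWAS population.** Φ is the sample
  genotypic covariance of panel dosages (denominator *n*, so X᷀X = nΦ
  exactly for an in-sample panel).

## From summary statistics to posteriors

The stage-1 prior is β ~ N(0, ψ diag(λ)), λₖ = λ⁽⁰⁾(θₖ(1−θₖ))^α; α = 0
makes effect size independent of frequency, α = 1 concentrates variance on
rare alleles. The posterior is N(β̃, ψΩ) with Ω = diag(λ) + Φ and
β̃ = Ω⁻¹ · diag(Φ)β̂.

One convention deserves a note. The per-observation X᷀y recovered from
summary data is written here as diag(Φ)β̂ — the panel genotypic variance
times the marginal effect — rather than the Hardy–Weinberg form 2θ(1−θ)β̂.
The two coincide under HWE, but the variance form makes two exact identities
hold at machine precision with an in-sample panel, and these identities
anchor the test suite: (i) for a single SNP, λ → 0 returns the marginal β̂
exactly; (ii) for any locus, the posterior mean equals penalized least
squares (X᷀X + n diag(λ))⁻¹X᷀y on the underlying individual-level data.
With an external reference panel the distinction is immaterial: diag(Φ) is
itself an estimate of 2θ(1−θ).

Stage 2 uses the best stage-1 posterior (selected by single-column test R²;
ties broken toward the smallest λ⁽⁰⁾, α, k) as the target-population prior
β₂ ~ N(β̃₁, ψτΩ₁). The bridging parameter τ is dimensionless: τ·Ω₁ plays
the role of prior observations per target observation, so n_eff = n(1+τ).
As τ → ∞ the target effects copy the discovery posterior; as τ → 0 the
update collapses to the target-only flat-prior solution. When target data
lack some locus members, the prior is the stage-1 Gaussian conditioned on
those effects being zero (mean β̃₁⁽ᵃ⁾ + (Ω₁⁽ᵃᵃ⁾)⁻¹Ω₁⁽ᵃᵇ⁾β̃₁⁽ᵇ⁾, precision
Ω₁⁽ᵃᵃ⁾) — precision-form conditioning, verified in tests against the dense
covariance-form Schur complement.

### Ranking loci in stage 2

Cross-population LD differences make single-SNP p-values a poor locus
ranking in the target population, so loci are ranked by a pseudo-F
statistic, F = (n_eff − k)/(kσ²) · β̃₂ᵀΩ₂β̃₂, the posterior analogue of the
classical multivariate F (to which it converges in the flat-prior limit as
the locus' variance explained goes to zero — the Taylor step in that
equivalence is the reason tests require the locus to explain < 1% of trait
variance). σ² is the phenotypic variance; since summary statistics do not
carry it directly, it is estimated as the median over variants of
2θⱼ(1−θⱼ)(n·seⱼ² + β̂ⱼ²), a robust per-variant inversion of the marginal
regression identities. F-quantile cuts are matched to the p-value ranking's
subset sizes so both rankings populate S_k equally; ties at a cut are
included (deterministic, errs toward inclusion).

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `alpha_grid` | 0, 0.25, 0.5, 0.75, 1 | frequency-dependence of prior effect variance (dimensionless) |
| `lambda0_grid` | 0.05–5 (7 values) | base prior precision, per-observation scale |
| `tau_grid` | 1–500 (10 values) | bridging strength, prior observations per target observation |
| `k_grid` | 1–8 | locus-subset thresholds 10⁻ᵏ on the lead p-value (strict `<`) |
| `p1, p2, kb, r2` | 0.01, 0.01, 1000, 0.01 | clumping: lead/member p, window (kb), r² with lead |
| `jitter` | 0 | optional diagonal ridge on Φ; unnecessary for λ > 0 since Ω = diag(λ)+Φ is always invertible |

The stacking penalty grid is 50 values log-spaced over [10⁻⁴, 10⁴] times the
mean column variance; columns are centred and scaled to unit variance first
so one grid serves columns of wildly different magnitudes, and weights are
transformed back to the raw column scale afterwards. The penalty minimizes
the exact leave-one-out squared error, computed in closed form from the SVD
hat-matrix diagonal (the intercept contributes its 1/n leverage). A fresh
ridge path costs one SVD of the test-samples × columns matrix.

### Model averaging

The three candidate models' log marginal likelihoods are approximated by
−(n/2)·log σᵢ² up to a shared constant, with σᵢ² each model's leave-one-out
residual variance on the common test samples; weights are softmax-normalized
in log space. The sign is chosen so that *lower* residual variance gives
*higher* weight — the approximation is only useful under that orientation —
and equal variances give exactly equal weights. Any number of component
models can enter (`build_models()` accepts arbitrarily many named stacks
plus the merged grid), so additional source populations slot in unchanged.

## What the simulator emulates — and what it does not

`simulate_world()` generates the package's standard desk-scale study:
two populations whose allele frequencies diverge by a Balding–Nichols Beta
model at F_ST 0.12 around shared ancestral frequencies; 50 independent LD
blocks of 20 variants (2 Mb apart, so no clumping window spans blocks) with
latent-Gaussian AR(1) haplotypes at correlation 0.9 (discovery) / 0.7
(target); causal effects on 5% of variants drawn bivariate-Gaussian with
cross-population correlation 0.9; additive phenotypes at SNP heritability
0.5; GWAS of 8000 discovery and 2000 target training samples with 2000
test and 2000 validation samples. Ancestral frequencies are drawn
block-coherently (block base ± small jitter): tightly linked variants can
only be strongly correlated when their frequencies are similar, so
coherence is required for the LD targets to be attainable at all.

Deliberately not emulated: recombination-map LD decay and haplotype
mosaics, selection, X chromosome, genotyping error and missingness
structure, covariate confounding and population stratification within a
GWAS. Passing tests on this world therefore demonstrate the estimator's
internal correctness and the qualitative portability gain under
block-independent LD and clean marginal GWAS — not performance on real
biobank data, where locus boundaries are fuzzier and effect-size priors are
misspecified in ways the simulator does not produce.

All randomness flows from a single seed in `sim_config()`; identical
configurations give bit-identical worlds, and `run_all()` manifests carry
MD5 hashes so reruns are verifiable.

## Numerical choices and degenerate inputs

* Φ uses denominator *n* and mean-centred dosages; rank-deficient Φ
  (duplicate variants, tiny panels) is accepted because the prior precision
  keeps Ω positive definite.
* Posterior solves use dense `solve()` on k × k systems; loci are small by
  construction (clumping bounds k), so no sparse machinery is warranted.
* Zero-variance grid columns get scale 1 and weight exactly 0; empty locus
  subsets yield labelled all-zero columns rather than errors, keeping the
  grid geometry stable across seeds.
* Monomorphic variants are dropped (or rejected, per flag) at panel load;
  missing dosages are mean-filled per variant, keeping X᷀X consistent with
  the frequency formulas downstream.
* Clumping ties on the minimal p-value break by (chrom, pos); assigned
  variants leave the pool, so loci partition the sub-threshold variants.
* Strand-ambiguous (A/T, C/G) variants are dropped at harmonization by
  default; frequency-based disambiguation is unreliable near θ = 0.5, and
  the policy is a flag rather than an assertion.
* Model weights are computed with max-subtraction in log space; n ~ 10⁷
  with distinct variances still yields exact 0/1 weights without under- or
  overflow.

## Design choices where the design was open

* **Best stage-1 prior by single-column R²** rather than by largest stacked
  ridge weight: the selected posterior must stand alone as the stage-2
  prior, so its own predictive fit is the relevant criterion.
* **Selection of α is weakly identified**: α rescales the overall shrinkage
  level as well as its frequency profile, so neighbouring (α, λ⁽⁰⁾)
  combinations are near-equivalent. The test suite asserts responsiveness
  (selected α shifts upward when effects truly concentrate on rare
  variants) rather than exact recovery.
* **σ² from summary statistics** by the median implied-variance formula:
  robust, and uses no fields beyond those already required.
* **Percentile bootstrap** for R² intervals: R² is bounded and skewed near
  its boundaries, where normal-approximation intervals misbehave.
* **Negative adjusted R² is reported as computed**, preserving
  comparability of small differences across methods.
* **The effect-allele variant key is (chrom, pos, unordered allele pair)**,
  not rsID: identifiers drift across builds and cohorts, positions with
  alleles do not.

## Known limitations

Continuous traits only (no liability-scale modelling); two-population
bridging per run (multi-source extension via `build_models()` operates at
the stacking level, not in the locus posteriors); no cross-population joint
LD model; locus definitions come from the discovery population in stage 2
(by design — the target-only model supplies target-defined loci); the
simulator's problem sizes (thousands of samples, ~10³ variants) are chosen
for fast, deterministic verification, and the methods vignette and test
suite state results only at those sizes.
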