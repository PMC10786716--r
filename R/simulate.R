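#' Configuration for the two-population simulator
#'
#' Defines a synthetic two-population world with diverged allele frequencies
#' (Balding-Nichols Beta model around a shared ancestral frequency), distinct
#' within-block LD per population (latent Gaussian AR(1) haplotypes), causal
#' effects correlated across populations, and additive phenotypes at a target
#' SNP heritability. Defaults describe the package's standard desk-scale
#' study: a well-powered discovery GWAS (8000) bridged to an underpowered
#' target GWAS (2000), 50 independent 20-variant LD blocks spaced 2 Mb apart,
#' 5% causal variants, heritability 0.5, cross-population effect correlation
#' 0.9 and FST 0.12.
#'
#' @param n_pop1,n_pop2 GWAS (training) sample sizes per population.
#' @param n_test,n_valid Test and validation sample sizes (validation is
#'   generated for the target population only).
#' @param n_blocks,block_size Number of LD blocks and variants per block.
#' @param fst Allele-frequency divergence in `[0, 1)`.
#' @param rho_ld_1,rho_ld_2 Within-block adjacent-variant latent correlation
#'   per population, in `[0, 1)`.
#' @param causal_fraction Fraction of variants with nonzero effects, `(0, 1]`.
#' @param h2 SNP heritability in `(0, 1)`, both populations.
#' @param rho_beta Cross-population correlation of causal effects, `[0, 1]`.
#' @param seed Integer seed; identical configurations reproduce bit-identical
#'   worlds.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_pop1 = 8000, n_pop2 = 2000,
                       n_test = 2000, n_valid = 2000,
                       n_blocks = 50, block_size = 20,
                       fst = 0.12, rho_ld_1 = 0.9, rho_ld_2 = 0.7,
                       causal_fraction = 0.05, h2 = 0.5, rho_beta = 0.9,
                       seed = 1) {
  cfg <- list(
    n_pop1 = n_pop1, n_pop2 = n_pop2, n_test = n_test, n_valid = n_valid,
    n_blocks = n_blocks, block_size = block_size, fst = fst,
    rho_ld_1 = rho_ld_1, rho_ld_2 = rho_ld_2,
    causal_fraction = causal_fraction, h2 = h2, rho_beta = rho_beta,
    seed = as.integer(seed)
  )
  stopifnot(
    cfg$fst >= 0, cfg$fst < 1,
    cfg$rho_ld_1 >= 0, cfg$rho_ld_1 < 1, cfg$rho_ld_2 >= 0, cfg$rho_ld_2 < 1,
    cfg$causal_fraction > 0, cfg$causal_fraction <= 1,
    cfg$h2 > 0, cfg$h2 < 1, cfg$rho_beta >= 0, cfg$rho_beta <= 1,
    cfg$block_size >= 1, cfg$n_blocks >= 1
  )
  structure(cfg, class = "sim_config")
}

#' Draw diverged population allele frequencies
#'
#' Ancestral frequencies are uniform on (0.05, 0.95), drawn coherently within
#' each LD block (a block-level base frequency plus a small per-variant
#' jitter): tightly linked variants can only be strongly correlated when
#' their allele frequencies are similar, so block coherence is required for
#' the simulator's LD targets to be attainable. Each population's frequency
#' is then Beta-distributed around the ancestral value with dispersion set by
#' `fst` (Balding-Nichols): `Beta(theta (1 - F) / F, (1 - theta)(1 - F) / F)`.
#' `fst = 0` returns the ancestral frequencies for both populations.
#'
#' @param cfg A [sim_config].
#' @return Tibble with `variant`, `ancestral`, `pop1`, `pop2`.
#' @export
draw_frequencies <- function(cfg) {
  m <- cfg$n_blocks * cfg$block_size
  base <- runif(cfg$n_blocks, 0.10, 0.90)
  theta <- rep(base, each = cfg$block_size) + runif(m, -0.05, 0.05)
  if (cfg$fst == 0) {
    p1 <- theta
    p2 <- theta
  } else {
    a <- theta * (1 - cfg$fst) / cfg$fst
    b <- (1 - theta) * (1 - cfg$fst) / cfg$fst
    p1 <- rbeta(m, a, b)
    p2 <- rbeta(m, a, b)
    # keep strictly polymorphic
    p1 <- pmin(pmax(p1, 1e-4), 1 - 1e-4)
    p2 <- pmin(pmax(p2, 1e-4), 1 - 1e-4)
  }
  tibble(variant = seq_len(m), ancestral = theta, pop1 = p1, pop2 = p2)
}

# AR(1) latent Gaussian matrix: n x m within one block
ar1_latent <- function(n, m, rho) {
  z <- matrix(rnorm(n * m), nrow = n, ncol = m)
  if (rho > 0 && m > 1) {
    for (j in 2:m) {
      z[, j] <- rho * z[, j - 1] + sqrt(1 - rho^2) * z[, j]
    }
  }
  z
}

#' Draw block-structured genotypes for one population
#'
#' Each haplotype is a latent Gaussian AR(1) vector per block; the allele
#' indicator is the latent value exceeding the frequency-matched threshold
#' `qnorm(1 - theta)`, and the dosage is the sum over two haplotypes. Marginal
#' frequencies match the target frequencies in expectation; blocks are
#' independent and placed 2 Mb apart so they cannot share a clumping window.
#'
#' @param freqs Numeric vector of per-variant frequencies for this population.
#' @param cfg A [sim_config].
#' @param n Number of individuals.
#' @param rho Within-block adjacent-variant latent correlation.
#' @param pop_label Label used in sample ids.
#' @return A [geno_panel].
#' @export
draw_genotypes <- function(freqs, cfg, n, rho, pop_label = "pop") {
  m <- cfg$n_blocks * cfg$block_size
  stopifnot(length(freqs) == m)
  thr <- qnorm(1 - freqs)
  dosages <- matrix(0L, nrow = n, ncol = m)
  for (b in seq_len(cfg$n_blocks)) {
    cols <- ((b - 1) * cfg$block_size + 1):(b * cfg$block_size)
    hap <- (ar1_latent(n, cfg$block_size, rho) >
      rep(thr[cols], each = n)) +
      (ar1_latent(n, cfg$block_size, rho) > rep(thr[cols], each = n))
    dosages[, cols] <- hap
  }
  variants <- tibble(
    id = sprintf("snp_%05d", seq_len(m)),
    chrom = "1",
    pos = as.integer((rep(seq_len(cfg$n_blocks), each = cfg$block_size) - 1L) * 2000000L +
      rep(seq_len(cfg$block_size), cfg$n_blocks) * 1000L),
    effect_allele = "A",
    other_allele = "G"
  )
  geno_panel(
    dosages, variants,
    sprintf("%s_%06d", pop_label, seq_len(n))
  )
}

#' Draw correlated causal effects for two populations
#'
#' Samples the causal set uniformly (size `round(causal_fraction * m)`, at
#' least 1) and, per causal variant, a bivariate Gaussian effect pair with
#' correlation `rho_beta`; non-causal effects are zero. Effect scale is
#' arbitrary since the phenotype model normalizes noise to the target
#' heritability.
#'
#' @param cfg A [sim_config].
#' @param variant_ids Character vector of variant ids.
#' @return Tibble with `id`, `causal`, `beta1`, `beta2`.
#' @export
draw_effects <- function(cfg, variant_ids) {
  m <- length(variant_ids)
  n_causal <- max(1L, round(cfg$causal_fraction * m))
  causal <- sort(sample.int(m, n_causal))
  z1 <- rnorm(n_causal)
  z2 <- cfg$rho_beta * z1 + sqrt(1 - cfg$rho_beta^2) * rnorm(n_causal)
  beta1 <- numeric(m)
  beta2 <- numeric(m)
  beta1[causal] <- z1
  beta2[causal] <- z2
  tibble(
    id = variant_ids, causal = seq_len(m) %in% causal,
    beta1 = beta1, beta2 = beta2
  )
}

#' Generate additive phenotypes at a target heritability
#'
#' `y = X beta + e`, with the noise variance set from the realized genetic
#' variance: `Var(e) = Var(g) (1 - h2) / h2`, so the realized heritability
#' `Var(g) / Var(y)` is `h2` in expectation.
#'
#' @param panel A [geno_panel].
#' @param effects Numeric vector of per-variant effects aligned to the panel's
#'   variants.
#' @param h2 Target SNP heritability in `(0, 1)`.
#' @return A tibble with `sample_id`, `trait` and the genetic value `g`.
#' @export
make_phenotypes <- function(panel, effects, h2) {
  stopifnot(h2 > 0, h2 < 1)
  g <- as.vector(panel$dosages %*% effects)
  vg <- var(g)
  if (vg == 0) {
    abort("no causal genetic variation in panel", class = "prsbridge_argument_error")
  }
  e <- rnorm(length(g), sd = sqrt(vg * (1 - h2) / h2))
  tibble(sample_id = panel$sample_ids, trait = g + e, g = g)
}

#' Per-variant marginal GWAS
#'
#' Simple linear regression of the trait on each variant's dosage (with
#' intercept): effect, standard error, two-sided t-test p-value, effect-allele
#' frequency and sample size. Zero-variance variants are dropped with a
#' message.
#'
#' @param panel A [geno_panel].
#' @param pheno Phenotype tibble with `sample_id` and `trait` covering the
#'   panel's samples.
#' @return A [`sumstats`][as_sumstats] tibble.
#' @export
run_gwas <- function(panel, pheno) {
  idx <- match(panel$sample_ids, pheno$sample_id)
  if (anyNA(idx)) {
    abort("phenotypes missing for some panel samples", class = "prsbridge_argument_error")
  }
  y <- pheno$trait[idx]
  n <- length(y)
  if (n < 30) abort("need at least 30 samples for a GWAS", class = "prsbridge_argument_error")
  X <- panel$dosages
  xm <- unname(colMeans(X))
  sxx <- unname(colSums(X^2)) - n * xm^2
  zero_var <- sxx <= 0
  if (any(zero_var)) {
    inform(sprintf("Dropping %d zero-variance variant(s) from the GWAS.", sum(zero_var)))
  }
  yc <- y - mean(y)
  sxy <- as.vector(crossprod(X, yc))
  syy <- sum(yc^2)
  beta <- sxy / sxx
  rss <- syy - beta^2 * sxx
  se <- sqrt(pmax(rss, 0) / (n - 2) / sxx)
  tstat <- beta / se
  pval <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  out <- tibble(
    id = panel$variants$id, chrom = panel$variants$chrom,
    pos = panel$variants$pos,
    effect_allele = panel$variants$effect_allele,
    other_allele = panel$variants$other_allele,
    beta = beta, se = se, freq = xm / 2, n = n,
    pval = pmax(pval, .Machine$double.xmin)
  )
  as_sumstats(out[!zero_var, ])
}

#' Simulate a complete two-population study
#'
#' Draws diverged frequencies, block-LD genotypes for the discovery
#' (train + test) and target (train + test + validation) populations,
#' correlated causal effects, phenotypes at the target heritability, and GWAS
#' summary statistics from each population's training split. All randomness
#' flows from `cfg$seed`, so identical configurations give bit-identical
#' worlds.
#'
#' @param cfg A [sim_config].
#' @return A `sim_world`: list with `freqs`, `effects`, per-population panels
#'   and phenotypes split into `train` / `test` (/ `valid` for the target
#'   population), `sumstats1`, `sumstats2` and the `config`.
#' @export
simulate_world <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  freqs <- draw_frequencies(cfg)

  pop1 <- draw_genotypes(freqs$pop1, cfg, cfg$n_pop1 + cfg$n_test,
    rho = cfg$rho_ld_1, pop_label = "pop1"
  )
  pop2 <- draw_genotypes(freqs$pop2, cfg, cfg$n_pop2 + cfg$n_test + cfg$n_valid,
    rho = cfg$rho_ld_2, pop_label = "pop2"
  )
  effects <- draw_effects(cfg, pop1$variants$id)

  pheno1 <- make_phenotypes(pop1, effects$beta1, cfg$h2)
  pheno2 <- make_phenotypes(pop2, effects$beta2, cfg$h2)

  split1 <- list(
    train = seq_len(cfg$n_pop1),
    test = cfg$n_pop1 + seq_len(cfg$n_test)
  )
  split2 <- list(
    train = seq_len(cfg$n_pop2),
    test = cfg$n_pop2 + seq_len(cfg$n_test),
    valid = cfg$n_pop2 + cfg$n_test + seq_len(cfg$n_valid)
  )

  world <- list(
    config = cfg, freqs = freqs, effects = effects,
    pop1 = list(
      train = subset_panel(pop1, samples = split1$train),
      test = subset_panel(pop1, samples = split1$test),
      pheno = pheno1
    ),
    pop2 = list(
      train = subset_panel(pop2, samples = split2$train),
      test = subset_panel(pop2, samples = split2$test),
      valid = subset_panel(pop2, samples = split2$valid),
      pheno = pheno2
    )
  )
  world$sumstats1 <- run_gwas(world$pop1$train, pheno1)
  world$sumstats2 <- run_gwas(world$pop2$train, pheno2)
  class(world) <- "sim_world"
  world
}

#' @export
print.sim_world <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<sim_world> %d variants; pop1 %d+%d, pop2 %d+%d+%d; h2 %.2f, causal %.0f%%, FST %.2f, rho_beta %.2f\n",
    cfg$n_blocks * cfg$block_size, cfg$n_pop1, cfg$n_test,
    cfg$n_pop2, cfg$n_test, cfg$n_valid, cfg$h2,
    100 * cfg$causal_fraction, cfg$fst, cfg$rho_beta
  ))
  invisible(x)
}

#' Theoretical PRS portability under independent causal variants
#'
#' The expected fraction of heritability captured by a clumping-and-
#' thresholding score with `m` independent causal variants, GWAS sample size
#' `n` and heritability `h2` is `r2 / h2 = 1 / (1 + m / (n h2))`: power is
#' governed by `n h2 / m`, so doubling heritability is equivalent to doubling
#' the sample size.
#'
#' @param n GWAS sample size.
#' @param h2 SNP heritability in `(0, 1]`.
#' @param m Number of causal variants.
#' @return The expected `r2 / h2` ratio.
#' @export
theoretical_portability <- function(n, h2, m) {
  stopifnot(n >= 1, m >= 1, h2 > 0, h2 <= 1)
  1 / (1 + m / (n * h2))
}
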