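# Shared in-code fixtures: no data files, everything generated per run.

# Binomial HWE genotype panel with given allele frequencies.
make_panel <- function(n, freqs, seed = NULL, chrom = "1",
                       pos = seq_along(freqs) * 1000L, prefix = "s") {
  if (!is.null(seed)) set.seed(seed)
  m <- length(freqs)
  dosages <- sapply(freqs, function(p) rbinom(n, 2, p)) + 0.0
  geno_panel(
    dosages,
    tibble::tibble(
      id = sprintf("v%03d", seq_len(m)), chrom = chrom, pos = as.integer(pos),
      effect_allele = "A", other_allele = "G"
    ),
    sprintf("%s%05d", prefix, seq_len(n))
  )
}

# Panel + trait + marginal GWAS from the same individuals (in-sample LD),
# for conjugacy oracles.
make_gwas_fixture <- function(n, k, seed, ld = 0.6, beta_sd = 0.1) {
  set.seed(seed)
  freqs <- runif(k, 0.1, 0.9)
  panel <- make_panel(n, freqs)
  # blend neighbouring columns to create LD
  if (k > 1 && ld > 0) {
    d <- panel$dosages
    for (j in 2:k) {
      swap <- runif(n) < ld
      d[swap, j] <- d[swap, j - 1]
    }
    panel <- geno_panel(d, panel$variants, panel$sample_ids)
  }
  beta <- rnorm(k, 0, beta_sd)
  y <- as.vector(panel$dosages %*% beta) + rnorm(n)
  pheno <- tibble::tibble(sample_id = panel$sample_ids, trait = y)
  ss <- run_gwas(panel, pheno)
  list(panel = panel, pheno = pheno, sumstats = ss, beta = beta, y = y)
}

# Small simulated two-population world, cached per session because several
# tests only need any consistent world.
small_world <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cache <<- simulate_world(sim_config(
        n_pop1 = 1500, n_pop2 = 600, n_test = 500, n_valid = 500,
        n_blocks = 15, block_size = 8, seed = 99
      ))
    }
    cache
  }
})

# Fit of the full pipeline on the small world, cached.
small_fit <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      w <- small_world()
      cache <<- suppressMessages(prs_bridge(
        w$sumstats1, w$pop1$test, w$pop1$test, w$pop1$pheno,
        w$sumstats2, w$pop2$test, w$pop2$test, w$pop2$pheno
      ))
    }
    cache
  }
})

expect_rel_equal <- function(actual, expected, tol) {
  expect_lt(max(abs(actual - expected)) / max(abs(expected)), tol)
}
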