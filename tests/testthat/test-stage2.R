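random_posterior_block <- function(k, seed) {
  set.seed(seed)
  A <- matrix(rnorm(k * k), k, k)
  omega <- crossprod(A) + diag(0.5, k)
  structure(
    list(
      ids = sprintf("v%03d", seq_len(k)),
      beta_tilde = rnorm(k, 0, 0.2),
      omega = omega,
      prior = list(lambda0 = 1, alpha = 0)
    ),
    class = "posterior_block"
  )
}

test_that("conditional prior equals dense covariance-form Gaussian conditioning", {
  # Oracle: work in covariance space. For x ~ N(mu, Sigma), conditioning on
  # x_b = 0 gives mean mu_a - Sigma_ab Sigma_bb^{-1} mu_b and covariance
  # Sigma_aa - Sigma_ab Sigma_bb^{-1} Sigma_ba (Schur complement); the
  # conditional precision is its inverse.
  for (draw in 1:50) {
    k <- sample(2:6, 1)
    pb <- random_posterior_block(k, seed = 1000 + draw)
    keep <- sort(sample(seq_len(k), sample(seq_len(k - 1), 1)))
    drop <- setdiff(seq_len(k), keep)

    Sigma <- solve(pb$omega)
    S_ab <- Sigma[keep, drop, drop = FALSE]
    S_bb <- Sigma[drop, drop, drop = FALSE]
    mean_oracle <- pb$beta_tilde[keep] -
      as.vector(S_ab %*% solve(S_bb, pb$beta_tilde[drop]))
    cov_oracle <- Sigma[keep, keep, drop = FALSE] -
      S_ab %*% solve(S_bb, t(S_ab))

    cp <- conditional_prior(pb, keep)
    expect_lt(max(abs(cp$beta_tilde - mean_oracle)), 1e-8)
    expect_lt(max(abs(solve(cp$omega) - cov_oracle)), 1e-8)
  }
})

test_that("conditional prior identity and block-diagonal cases", {
  pb <- random_posterior_block(4, seed = 5)
  expect_identical(conditional_prior(pb, 1:4), pb)

  # block-diagonal precision: conditioning on the independent block changes nothing
  pb2 <- random_posterior_block(4, seed = 6)
  pb2$omega[1:2, 3:4] <- 0
  pb2$omega[3:4, 1:2] <- 0
  cp <- conditional_prior(pb2, 1:2)
  expect_equal(cp$beta_tilde, pb2$beta_tilde[1:2])

  expect_error(conditional_prior(pb, integer(0)), class = "prsbridge_empty_error")
})

test_that("bridged posterior hits both tau limits and the augmented-data oracle", {
  fx1 <- make_gwas_fixture(n = 600, k = 4, seed = 71)
  fx2 <- make_gwas_fixture(n = 500, k = 4, seed = 72)
  # align variant ids so the two populations share the locus
  fx2$sumstats$id <- fx1$sumstats$id

  blk1 <- compute_phi(fx1$sumstats$id, fx1$panel)
  prior1 <- posterior_update(blk1, fx1$sumstats, lambda0 = 0.5, alpha = 0.25)
  blk2 <- compute_phi(fx2$panel$variants$id, fx2$panel)
  blk2$ids <- fx1$sumstats$id

  # tau -> infinity: population-1 posterior mean reproduced
  big <- posterior_update2(blk2, fx2$sumstats, prior1, tau = 1e6)
  expect_lt(
    max(abs(big$beta_tilde - prior1$beta_tilde)),
    1e-3 * max(abs(prior1$beta_tilde))
  )

  # tau -> 0: population-2 flat-prior (lambda -> 0) solution
  small <- posterior_update2(blk2, fx2$sumstats, prior1, tau = 1e-6)
  idx <- match(blk2$ids, fx2$sumstats$id)
  flat <- solve(blk2$phi, diag(blk2$phi) * fx2$sumstats$beta[idx])
  expect_lt(max(abs(small$beta_tilde - flat)), 1e-3 * max(abs(flat)))

  # interior tau: independent augmented-system oracle on individual-level
  # population-2 data: minimize ||y2c - X2c b||^2 / n2 + tau (b - m1)' Omega1 (b - m1)
  for (tau in c(1, 10)) {
    post <- posterior_update2(blk2, fx2$sumstats, prior1, tau = tau)
    X2c <- scale(fx2$panel$dosages, scale = FALSE)
    y2c <- fx2$y - mean(fx2$y)
    n2 <- nrow(X2c)
    oracle <- solve(
      crossprod(X2c) / n2 + tau * prior1$omega,
      crossprod(X2c, y2c) / n2 + tau * prior1$omega %*% prior1$beta_tilde
    )
    expect_rel_equal(post$beta_tilde, as.vector(oracle), 1e-6)
  }

  expect_error(posterior_update2(blk2, fx2$sumstats, prior1, tau = 0),
    class = "prsbridge_argument_error"
  )
})

test_that("bridging distance to the discovery posterior shrinks as tau grows", {
  for (seed in 101:120) {
    k <- sample(2:6, 1)
    fx1 <- make_gwas_fixture(n = 400, k = k, seed = seed)
    fx2 <- make_gwas_fixture(n = 300, k = k, seed = seed + 500)
    fx2$sumstats$id <- fx1$sumstats$id
    blk1 <- compute_phi(fx1$sumstats$id, fx1$panel)
    prior1 <- posterior_update(blk1, fx1$sumstats, lambda0 = 0.5, alpha = 0)
    blk2 <- compute_phi(fx2$panel$variants$id, fx2$panel)
    blk2$ids <- fx1$sumstats$id
    dist <- vapply(default_tau_grid(), function(tau) {
      p <- posterior_update2(blk2, fx2$sumstats, prior1, tau)
      sqrt(sum((p$beta_tilde - prior1$beta_tilde)^2))
    }, numeric(1))
    expect_true(all(diff(dist) <= 1e-12))
  }
})

test_that("pseudo-F matches the classical F statistic in the flat-prior limit", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 2000
    k <- 3
    freqs <- runif(k, 0.2, 0.8)
    panel <- make_panel(n, freqs)
    # small locus contribution: variance explained below 1%
    beta_true <- rnorm(k, 0, 0.02)
    y <- as.vector(panel$dosages %*% beta_true) + rnorm(n)
    ph <- tibble::tibble(sample_id = panel$sample_ids, trait = y)
    ss <- run_gwas(panel, ph)
    blk <- compute_phi(ss$id, panel)
    prior_flat <- posterior_update(blk, ss, lambda0 = 1e-10, alpha = 0)
    post <- posterior_update2(blk, ss, prior_flat, tau = 1e-10)
    sigma2 <- sum((y - mean(y))^2) / n
    f_bayes <- pseudo_f(post, n = n, tau = 1e-10, sigma2 = sigma2)

    fit1 <- lm(y ~ panel$dosages)
    rss1 <- sum(resid(fit1)^2)
    rss0 <- sum((y - mean(y))^2)
    f_classic <- (n - k) / k * (rss0 - rss1) / rss1
    ve <- (rss0 - rss1) / rss0
    expect_lt(ve, 0.01)
    expect_lt(abs(f_bayes$f_bayes - f_classic) / f_classic, 0.02)
  }
})

test_that("pseudo-F scales and degenerates as expected", {
  pb <- random_posterior_block(3, seed = 9)
  f1 <- pseudo_f(pb, n = 1000, tau = 2, sigma2 = 1)
  expect_equal(f1$n_eff, 3000)
  f2 <- pseudo_f(pb, n = 1000, tau = 2, sigma2 = 2)
  expect_equal(f2$f_bayes, f1$f_bayes / 2)

  pb0 <- pb
  pb0$beta_tilde <- rep(0, 3)
  expect_equal(pseudo_f(pb0, 1000, 2, 1)$f_bayes, 0)

  expect_error(pseudo_f(pb, 1000, 2, 0), class = "prsbridge_argument_error")
  expect_error(pseudo_f(pb, 1, 0.5, 1), class = "prsbridge_argument_error")
})

test_that("summary-implied phenotypic variance is calibrated", {
  set.seed(7)
  n <- 2000
  m <- 500
  freqs <- runif(m, 0.1, 0.9)
  panel <- make_panel(n, freqs)
  g <- as.vector(panel$dosages %*% rnorm(m, 0, 0.01))
  y <- g + rnorm(n, 0, sqrt(max(1 - var(g), 0.5)))
  y <- y / sd(y) # Var(Y) = 1 exactly
  ss <- run_gwas(panel, tibble::tibble(sample_id = panel$sample_ids, trait = y))
  est <- estimate_sigma2(ss)
  expect_gt(est, 0.9)
  expect_lt(est, 1.1)

  # doubling all standard errors quadruples the estimate (beta^2 term is tiny)
  ss2 <- ss
  ss2$se <- ss$se * 2
  expect_equal(estimate_sigma2(ss2) / est, 4, tolerance = 0.01)

  # single variant: that variant's implied variance
  one <- ss[1, ]
  expect_equal(
    estimate_sigma2(one),
    2 * one$freq * (1 - one$freq) * (one$n * one$se^2 + one$beta^2)
  )
})

test_that("quantile matching preserves subset cardinalities and ordering", {
  # F ranking identical to p ranking: identical subsets
  loci <- tibble::tibble(locus_id = paste0("l", 1:10))
  pv <- dplyr::mutate(loci, top_pval = 10^-(10:1))
  fs <- dplyr::mutate(loci, f_bayes = 10:1) # same order: smallest p = largest F
  mq <- match_quantiles(fs, pv)
  expect_equal(mq, assign_subsets(pv))

  # 3 loci below 1e-2, arbitrary F: S_2 is the top 3 by F
  pv2 <- dplyr::mutate(loci, top_pval = c(1e-5, 1e-4, 1e-3, rep(0.5, 7)))
  set.seed(2)
  fs2 <- dplyr::mutate(loci, f_bayes = sample(1:10))
  mq2 <- match_quantiles(fs2, pv2)
  expect_equal(sort(mq2[["2"]]), sort(fs2$locus_id[order(-fs2$f_bayes)][1:3]))

  # cardinality match over 100 random tie-free fixtures
  set.seed(33)
  for (rep in 1:100) {
    nl <- sample(5:40, 1)
    pvr <- tibble::tibble(locus_id = paste0("x", 1:nl), top_pval = 10^-runif(nl, 0, 9))
    fsr <- tibble::tibble(locus_id = pvr$locus_id, f_bayes = rnorm(nl))
    mqr <- match_quantiles(fsr, pvr)
    sub_p <- assign_subsets(pvr)
    for (k in names(mqr)) {
      expect_equal(length(mqr[[k]]), length(sub_p[[k]]))
    }
  }

  # ties at the cut are included inclusively
  fst <- tibble::tibble(locus_id = paste0("l", 1:10), f_bayes = c(5, 5, 5, 1:7 / 10))
  expect_message(match_quantiles(fst, pv2, k_grid = 3), "ties")
  mqt <- suppressMessages(match_quantiles(fst, pv2))
  expect_equal(sort(mqt[["2"]]), c("l1", "l2", "l3"))
  expect_equal(sort(mqt[["3"]]), c("l1", "l2", "l3")) # inclusive ties exceed the count
})

test_that("stage-2 fit bridges, ranks and stacks on the small world", {
  w <- small_world()
  fit <- small_fit()
  s2 <- fit$stage2
  expect_s3_class(s2, "stage2_fit")
  expect_equal(length(s2$posteriors), length(default_tau_grid()))
  expect_equal(ncol(s2$grid$scores), length(default_tau_grid()) * 8)
  expect_equal(s2$ranking, "fstat")
  expect_true(all(s2$fstats$f_bayes >= 0))
  # pval ranking variant runs too and shares the locus set
  s2p <- suppressMessages(fit_stage2(
    fit$stage1, w$sumstats2, w$pop2$test, w$pop2$test, w$pop2$pheno,
    tau_grid = c(1, 10), ranking = "pval"
  ))
  expect_equal(ncol(s2p$grid$scores), 2 * 8)
})
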