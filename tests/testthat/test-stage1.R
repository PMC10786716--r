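test_that("prior precision follows the frequency-dependence law", {
  theta <- c(0.1, 0.3, 0.5)
  expect_equal(prior_precision(theta, 2, 0), rep(2, 3))
  expect_equal(prior_precision(0.5, 2, 1), 0.5)
  expect_error(prior_precision(c(0, 0.5), 1, 0), class = "prsbridge_argument_error")
  expect_error(prior_precision(0.5, -1, 0), class = "prsbridge_argument_error")
  expect_error(prior_precision(0.5, 1, 2), class = "prsbridge_argument_error")
  # default grids give the 5 x 7 x 8 = 280-column stage-1 design
  expect_equal(
    length(default_alpha_grid()) * length(default_lambda0_grid()) *
      length(default_k_grid()),
    280
  )
})

test_that("summary-statistic posterior equals individual-level penalized least squares", {
  for (seed in 1:5) {
    k <- sample(2:10, 1)
    fx <- make_gwas_fixture(n = 500, k = k, seed = seed)
    blk <- compute_phi(fx$sumstats$id, fx$panel)
    for (l0 in c(0.05, 1)) {
      post <- posterior_update(blk, fx$sumstats, lambda0 = l0, alpha = 0.5)
      lam <- prior_precision(fx$sumstats$freq, l0, 0.5)
      X <- fx$panel$dosages[, fx$sumstats$id]
      Xc <- scale(X, scale = FALSE)
      yc <- fx$y - mean(fx$y)
      oracle <- solve(crossprod(Xc) + nrow(X) * diag(lam), crossprod(Xc, yc))
      expect_rel_equal(post$beta_tilde, as.vector(oracle), 1e-6)
    }
  }
})

test_that("posterior limits: total shrinkage and one-SNP marginal recovery", {
  fx <- make_gwas_fixture(n = 400, k = 4, seed = 7)
  blk <- compute_phi(fx$sumstats$id, fx$panel)
  post <- posterior_update(blk, fx$sumstats, lambda0 = 1e12, alpha = 0)
  expect_lt(max(abs(post$beta_tilde)), 1e-6 * max(abs(fx$sumstats$beta)))

  blk1 <- compute_phi(fx$sumstats$id[1], fx$panel)
  post1 <- posterior_update(blk1, fx$sumstats, lambda0 = 1e-300, alpha = 0)
  expect_equal(post1$beta_tilde, fx$sumstats$beta[1], tolerance = 1e-12)
})

test_that("posterior mean norm shrinks monotonically in lambda0 (diagonal LD)", {
  set.seed(31)
  freqs <- runif(6, 0.2, 0.8)
  panel <- make_panel(2000, freqs)
  y <- as.vector(panel$dosages %*% rnorm(6, 0, 0.1)) + rnorm(2000)
  ss <- run_gwas(panel, tibble::tibble(sample_id = panel$sample_ids, trait = y))
  blk <- compute_phi(ss$id, panel)
  blk$phi <- diag(diag(blk$phi)) # diagonal-LD fixture
  norms <- vapply(c(0.05, 0.2, 1, 5, 50), function(l0) {
    sqrt(sum(posterior_update(blk, ss, l0, 0.25)$beta_tilde^2))
  }, numeric(1))
  expect_true(all(diff(norms) < 0))
})

test_that("locus subsets use strict thresholds and are nested", {
  loci <- tibble::tibble(
    locus_id = c("l1", "l2", "l3"),
    top_pval = c(1e-5, 0.05, 1e-9)
  )
  subsets <- assign_subsets(loci)
  expect_true(all(vapply(subsets[1:4], function(s) "l1" %in% s, logical(1))))
  expect_false("l1" %in% subsets[["5"]]) # strict: 1e-5 is not < 1e-5
  expect_false("l2" %in% unlist(subsets[2:8]))
  expect_true("l3" %in% subsets[["8"]])

  # all loci weak: all subsets empty
  weak <- tibble::tibble(locus_id = "a", top_pval = 0.2)
  expect_true(all(lengths(assign_subsets(weak)) == 0))

  # nesting property over random p-values
  set.seed(17)
  for (rep in 1:20) {
    rnd <- tibble::tibble(
      locus_id = paste0("x", 1:30),
      top_pval = 10^-runif(30, 0, 10)
    )
    ss <- assign_subsets(rnd)
    for (k in 2:8) {
      expect_true(all(ss[[as.character(k)]] %in% ss[[as.character(k - 1)]]))
    }
  }
})

test_that("PRS grid scores equal brute-force per-sample summation", {
  fx <- make_gwas_fixture(n = 300, k = 9, seed = 13)
  # three 3-SNP loci with distinct top p-values
  ids <- fx$sumstats$id
  blocks <- list(
    A = compute_phi(ids[1:3], fx$panel),
    B = compute_phi(ids[4:6], fx$panel),
    C = compute_phi(ids[7:9], fx$panel)
  )
  posteriors <- list(
    a0_l1 = list(
      params = list(alpha = 0, lambda0 = 1),
      blocks = lapply(blocks, posterior_update, s = fx$sumstats, lambda0 = 1, alpha = 0)
    ),
    a1_l5 = list(
      params = list(alpha = 1, lambda0 = 5),
      blocks = lapply(blocks, posterior_update, s = fx$sumstats, lambda0 = 5, alpha = 1)
    )
  )
  subsets <- list("1" = c("A", "B", "C"), "3" = c("B"), "8" = character())
  grid <- score_grid(posteriors, subsets, fx$panel)
  expect_equal(ncol(grid$scores), 6)

  # brute force: per sample, sum dosage * beta_tilde over loci in the subset
  bt <- posteriors$a0_l1$blocks
  manual <- numeric(300)
  for (lc in c("A", "B", "C")) {
    X <- fx$panel$dosages[, bt[[lc]]$ids, drop = FALSE]
    manual <- manual + as.vector(X %*% bt[[lc]]$beta_tilde)
  }
  expect_equal(unname(grid$scores[, "a0_l1_k1"]), manual)
  # empty subset: all-zero column retained, labelled
  expect_true(all(grid$scores[, "a0_l1_k8"] == 0))
  expect_true("a1_l5_k8" %in% colnames(grid$scores))
})

test_that("single-SNP score column is the dosage times the posterior mean", {
  panel <- make_panel(3, 0.5, seed = 2)
  panel$dosages[, 1] <- c(0, 1, 2)
  post <- list(one = list(
    params = list(alpha = 0, lambda0 = 1),
    blocks = list(L = structure(
      list(
        ids = panel$variants$id, beta_tilde = 0.5,
        omega = matrix(1), prior = list()
      ),
      class = "posterior_block"
    ))
  ))
  grid <- score_grid(post, list("1" = "L"), panel)
  expect_equal(unname(grid$scores[, 1]), c(0, 0.5, 1.0))
})

test_that("ridge stacking recovers generative column weights and kills null columns", {
  set.seed(41)
  n <- 400
  c1 <- rnorm(n)
  c2 <- rnorm(n)
  c1 <- c1 / sd(c1)
  c2 <- resid(lm(c2 ~ c1))
  c2 <- c2 / sd(c2)
  y <- 2 * c1 + 1 * c2 + rnorm(n, 0, 0.3)
  scores <- cbind(a = c1, b = c2, zero = rep(0, n))
  grid <- structure(
    list(
      scores = matrix(scores,
        ncol = 3,
        dimnames = list(paste0("s", 1:n), c("a", "b", "zero"))
      ),
      info = tibble::tibble(column = c("a", "b", "zero"), k = 1:3),
      beta = matrix(0, 1, 3, dimnames = list("v001", c("a", "b", "zero"))),
      variants = tibble::tibble(
        id = "v001", chrom = "1", pos = 1L,
        effect_allele = "A", other_allele = "G"
      ),
      sample_ids = paste0("s", 1:n)
    ),
    class = "prs_grid"
  )
  pheno <- tibble::tibble(sample_id = paste0("s", 1:n), trait = y)
  st <- stack_ridge(grid, pheno)
  w <- st$weights$weight
  expect_lt(abs(w[1] / w[2] - 2), 0.2)
  expect_lt(abs(w[3]), 1e-8)
  expect_gt(cor(st$prs$prs, y), 0.95)

  # a column equal to y is found at high accuracy
  grid2 <- grid
  grid2$scores[, 2] <- y
  st2 <- stack_ridge(grid2, pheno)
  expect_gt(cor(st2$prs$prs, y), 0.99)

  # stacked LOO error does not exceed the best single column's LOO error
  single_loo <- function(x, y) {
    n <- length(y)
    errs <- vapply(seq_len(n), function(i) {
      df <- data.frame(x = x[-i], y = y[-i])
      fit <- lm(y ~ x, data = df)
      y[i] - predict(fit, data.frame(x = x[i]))[[1]]
    }, numeric(1))
    mean(errs^2)
  }
  best_single <- min(
    single_loo(scores[, 1], y),
    single_loo(scores[, 2], y)
  )
  expect_lte(st$loo_sigma2, best_single)

  expect_error(stack_ridge(grid, pheno[1, ]), class = "prsbridge_argument_error")
})

test_that("best-prior selection picks the predictive column and breaks ties lexicographically", {
  set.seed(51)
  n <- 200
  y <- rnorm(n)
  mk_grid <- function(cols, info) {
    structure(
      list(
        scores = matrix(cols, ncol = ncol(cols),
          dimnames = list(paste0("s", 1:n), info$column)
        ),
        info = info, beta = NULL, variants = NULL,
        sample_ids = paste0("s", 1:n)
      ),
      class = "prs_grid"
    )
  }
  pheno <- tibble::tibble(sample_id = paste0("s", 1:n), trait = y)

  info <- tibble::tibble(
    column = c("good", "noise1", "noise2"),
    k = c(2L, 1L, 3L), alpha = c(0.5, 0, 1), lambda0 = c(0.2, 0.05, 5)
  )
  grid <- mk_grid(cbind(y + rnorm(n, 0, 0.1), rnorm(n), rnorm(n)), info)
  best <- select_best_prior(grid, pheno)
  expect_equal(best$column, "good")

  # identical columns: smallest (lambda0, alpha, k) wins
  info2 <- tibble::tibble(
    column = c("c1", "c2"), k = c(4L, 2L),
    alpha = c(0.5, 0.5), lambda0 = c(1, 0.1)
  )
  grid2 <- mk_grid(cbind(y, y), info2)
  best2 <- select_best_prior(grid2, pheno)
  expect_equal(best2$column, "c2")
})

test_that("prior selection responds to the generative frequency dependence of effects", {
  # Fit stage 1 on worlds where the per-SNP effect variance is constant
  # (generative alpha = 0) versus inversely proportional to the heterozygosity
  # (generative alpha = 1). The best-fitting alpha should concentrate low in
  # the first regime and shift up in the second; exact recovery is not
  # expected because alpha also rescales the overall shrinkage level.
  sel_for <- function(alpha_true, seed) {
    set.seed(seed * 1000 + alpha_true)
    m <- 200
    n <- 1000
    ntest <- 1200
    freqs <- runif(m, 0.05, 0.95)
    panel <- draw_genotypes(
      freqs, sim_config(n_blocks = 25, block_size = 8, fst = 0),
      n + ntest,
      rho = 0.8, pop_label = "p"
    )
    beta <- rnorm(m) / (2 * freqs * (1 - freqs))^(alpha_true / 2)
    ph <- make_phenotypes(panel, beta, 0.5)
    train <- subset_panel(panel, samples = seq_len(n))
    test <- subset_panel(panel, samples = n + seq_len(ntest))
    ss <- run_gwas(train, ph)
    fit <- suppressMessages(fit_stage1(ss, test, test, ph))
    fit$best$alpha
  }
  sel0 <- vapply(1:8, sel_for, numeric(1), alpha_true = 0)
  sel1 <- vapply(1:8, sel_for, numeric(1), alpha_true = 1)
  expect_lt(mean(sel0), mean(sel1))
  expect_lte(median(sel0), 0.25)
})

test_that("the ridge solution agrees with glmnet at a matched penalty", {
  skip_if_not_installed("glmnet")
  set.seed(71)
  n <- 300
  p <- 8
  X <- matrix(rnorm(n * p), n, p)
  y <- X %*% rnorm(p, 0, 0.5) + rnorm(n)
  y <- as.vector(y)
  # ||y - Xb||^2 + t ||b||^2 corresponds to glmnet lambda = t * sd_n(y) / n at
  # alpha = 0 (glmnet standardizes the response internally)
  t_pen <- 5
  sd_n <- sqrt(mean((y - mean(y))^2))
  fit <- ridge_loo(X, y, penalties = t_pen)
  gl <- glmnet::glmnet(X, y,
    alpha = 0, lambda = t_pen * sd_n / n,
    standardize = FALSE, intercept = TRUE, thresh = 1e-14
  )
  expect_equal(fit$coefficients, as.vector(gl$beta), tolerance = 1e-5)
  expect_equal(fit$intercept, as.vector(gl$a0), tolerance = 1e-5)
})
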