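#' Frequency-dependent prior precision
#'
#' The zero-centred Gaussian prior on SNP effects at a locus has SNP-specific
#' precision `lambda0 * (theta * (1 - theta))^alpha`, where `theta` is the
#' effect-allele frequency. `alpha = 0` makes effect size and frequency a
#' priori independent; `alpha = 1` encodes larger effects at rarer alleles.
#'
#' @param theta Allele frequencies, strictly inside (0, 1).
#' @param lambda0 Positive base shrinkage.
#' @param alpha Frequency-dependence exponent in \[0, 1\].
#' @return Vector of prior precisions.
#' @export
prior_precision <- function(theta, lambda0, alpha) {
  if (any(theta <= 0 | theta >= 1)) {
    abort("allele frequencies must lie strictly inside (0, 1)",
      class = "prsbridge_argument_error"
    )
  }
  if (lambda0 <= 0) abort("`lambda0` must be positive", class = "prsbridge_argument_error")
  if (alpha < 0 || alpha > 1) abort("`alpha` must lie in [0, 1]", class = "prsbridge_argument_error")
  lambda0 * (theta * (1 - theta))^alpha
}

#' Default prior grids
#'
#' All combinations of `alpha` in \{0, 0.25, 0.5, 0.75, 1\} and base shrinkage
#' `lambda0` in \{0.05, 0.1, 0.2, 0.5, 1, 2, 5\} are fit at each locus in
#' stage 1; stage 2 bridges over `tau` in \{1, 2, 5, 10, 15, 20, 50, 100, 200,
#' 500\}; locus subsets use p-value thresholds `10^-k`, `k = 1..8`.
#'
#' @name default_grids
#' @export
default_alpha_grid <- function() c(0, 0.25, 0.5, 0.75, 1)

#' @rdname default_grids
#' @export
default_lambda0_grid <- function() c(0.05, 0.1, 0.2, 0.5, 1, 2, 5)

#' @rdname default_grids
#' @export
default_tau_grid <- function() c(1, 2, 5, 10, 15, 20, 50, 100, 200, 500)

#' @rdname default_grids
#' @export
default_k_grid <- function() 1:8

#' Conjugate posterior update at one locus (stage 1)
#'
#' Under the zero-centred Gaussian prior with precision `diag(lambda)` (in
#' per-observation units, i.e. already rescaled by the GWAS sample size) and
#' Gaussian likelihood summarized by marginal effects and the locus genotypic
#' covariance, the posterior of the SNP effects is Gaussian with precision
#' `Omega = diag(lambda) + phi` (up to the residual-variance scalar, which
#' cancels from the mean) and mean `solve(Omega, diag(phi) * beta_hat)`. The
#' right-hand side is the per-observation `X^T y` recovered from summary
#' statistics: the genotypic variance times the marginal effect, equal to
#' `2 * theta * (1 - theta) * beta_hat` under Hardy-Weinberg equilibrium.
#'
#' @param block An [`ld_block`][compute_phi].
#' @param s A [`sumstats`][as_sumstats] tibble covering all block members
#'   (matched by id), harmonized to the block's panel.
#' @param lambda0,alpha Prior parameters, see [prior_precision()].
#' @return A `posterior_block`: list with `ids`, `beta_tilde`, `omega` and
#'   `prior` (list of `lambda0`, `alpha`).
#' @export
posterior_update <- function(block, s, lambda0, alpha) {
  idx <- match(block$ids, s$id)
  if (anyNA(idx)) {
    abort("summary statistics do not cover all locus members",
      class = "prsbridge_argument_error"
    )
  }
  lam <- prior_precision(s$freq[idx], lambda0, alpha)
  omega <- block$phi + diag(lam, length(lam))
  beta_tilde <- solve(omega, diag(block$phi) * s$beta[idx])
  structure(
    list(
      ids = block$ids,
      beta_tilde = as.vector(beta_tilde),
      omega = omega,
      prior = list(lambda0 = lambda0, alpha = alpha)
    ),
    class = "posterior_block"
  )
}

#' Nested locus subsets by top-SNP p-value
#'
#' `S_k` collects the loci whose most-associated SNP has p-value strictly
#' below `10^-k`; subsets are nested, `S_(k+1)` inside `S_k`.
#'
#' @param loci Locus tibble from [clump()] (or any tibble with `locus_id` and
#'   `top_pval`).
#' @param k_grid Integer thresholds (default `1:8`).
#' @return Named list mapping `k` to a character vector of locus ids.
#' @export
assign_subsets <- function(loci, k_grid = default_k_grid()) {
  per_locus <- dplyr::distinct(loci, .data$locus_id, .data$top_pval)
  out <- lapply(k_grid, function(k) per_locus$locus_id[per_locus$top_pval < 10^-k])
  names(out) <- as.character(k_grid)
  out
}

# Build the variants x columns weight matrix from a list of posterior blocks.
# posteriors: named list combo_label -> list(params = list(...), blocks =
# named list locus_id -> posterior_block). subsets: k -> locus ids.
build_weight_matrix <- function(posteriors, subsets) {
  first <- posteriors[[1]]$blocks
  locus_ids <- names(first)
  var_ids <- unlist(lapply(first, `[[`, "ids"), use.names = FALSE)
  locus_of <- rep(locus_ids, vapply(first, function(b) length(b$ids), integer(1)))

  n_combo <- length(posteriors)
  W0 <- matrix(0, nrow = length(var_ids), ncol = n_combo,
    dimnames = list(var_ids, names(posteriors))
  )
  for (cb in names(posteriors)) {
    W0[, cb] <- unlist(lapply(posteriors[[cb]]$blocks, `[[`, "beta_tilde"),
      use.names = FALSE
    )
  }

  cols <- list()
  info <- list()
  for (k in names(subsets)) {
    mask <- locus_of %in% subsets[[k]]
    Wk <- W0
    Wk[!mask, ] <- 0
    colnames(Wk) <- paste0(names(posteriors), "_k", k)
    cols[[k]] <- Wk
    info[[k]] <- dplyr::bind_cols(
      tibble(column = colnames(Wk), k = as.integer(k)),
      dplyr::bind_rows(lapply(posteriors, function(p) as_tibble(p$params)))
    )
  }
  list(
    beta = do.call(cbind, cols),
    info = dplyr::bind_rows(info),
    variant_ids = var_ids,
    locus_of = locus_of
  )
}

#' Genome-wide PRS grid from per-locus posteriors
#'
#' Scores each sample under every combination of prior setting and locus
#' subset: the column for `(prior, k)` is the dosage-weighted sum of posterior
#' mean effects over all loci in `S_k`. Variants absent from the genotype
#' panel contribute zero and are counted in a message.
#'
#' @param posteriors Named list of prior settings, each a list with `params`
#'   (named list of prior parameters) and `blocks` (named list of
#'   [`posterior_block`][posterior_update]s by locus id).
#' @param subsets Named list from [assign_subsets()] (or the pseudo-F matched
#'   subsets in stage 2).
#' @param geno A [geno_panel] for the samples to score.
#' @param variants Optional variant metadata tibble (id, chrom, pos, alleles)
#'   used for weight export; defaults to the panel's metadata.
#' @return A `prs_grid`: list with `scores` (samples x columns matrix), `info`
#'   (one row per column: prior parameters and `k`), `beta` (variants x
#'   columns weight matrix) and `variants`.
#' @export
score_grid <- function(posteriors, subsets, geno, variants = NULL) {
  wm <- build_weight_matrix(posteriors, subsets)
  idx <- match(wm$variant_ids, geno$variants$id)
  absent <- is.na(idx)
  if (any(absent)) {
    inform(sprintf(
      "%d variant(s) in the posterior absent from the scoring panel contribute 0.",
      sum(absent)
    ))
  }
  scores <- matrix(0, nrow = length(geno$sample_ids), ncol = ncol(wm$beta),
    dimnames = list(geno$sample_ids, colnames(wm$beta))
  )
  if (any(!absent)) {
    scores <- geno$dosages[, idx[!absent], drop = FALSE] %*%
      wm$beta[!absent, , drop = FALSE]
  }
  if (is.null(variants)) {
    variants <- geno$variants[idx[!absent], ]
    if (any(absent)) {
      variants <- dplyr::bind_rows(
        variants,
        tibble(
          id = wm$variant_ids[absent], chrom = NA_character_,
          pos = NA_integer_, effect_allele = NA_character_,
          other_allele = NA_character_
        )
      )[match(wm$variant_ids, c(wm$variant_ids[!absent], wm$variant_ids[absent])), ]
    }
  } else {
    variants <- variants[match(wm$variant_ids, variants$id), ]
  }
  structure(
    list(
      scores = scores, info = wm$info, beta = wm$beta,
      variants = variants, sample_ids = geno$sample_ids
    ),
    class = "prs_grid"
  )
}

#' @export
print.prs_grid <- function(x, ...) {
  cat(sprintf(
    "<prs_grid> %d samples x %d columns over %d variants\n",
    nrow(x$scores), ncol(x$scores), nrow(x$beta)
  ))
  invisible(x)
}

#' Stack a PRS grid by cross-validated ridge regression
#'
#' Combines the candidate score columns into a single PRS by ridge regression
#' on test-sample phenotypes: covariates are first regressed out of the trait,
#' columns are centred and scaled to unit variance, and the ridge penalty is
#' chosen from a 50-point logarithmic grid by exact leave-one-out
#' cross-validation (closed form via the hat-matrix diagonal). Weights are
#' returned on the original column scale.
#'
#' @param grid A [`prs_grid`][score_grid].
#' @param pheno Phenotype tibble (`sample_id`, `trait`, covariates).
#' @param penalties Optional penalty grid; default 50 values log-spaced over
#'   `[1e-4, 1e4]` times the mean column variance.
#' @return A `stacked_prs`: list with per-column `weights` tibble (ridge
#'   weight, centring and scaling constants), `intercept`, selected `penalty`,
#'   `loo_sigma2` (leave-one-out residual variance), `prs` (tibble of fitted
#'   scores for the stacking samples) and the underlying `grid` (for weight
#'   export and out-of-sample scoring).
#' @export
stack_ridge <- function(grid, pheno, penalties = NULL) {
  common <- intersect(rownames(grid$scores), pheno$sample_id)
  if (length(common) < 2) {
    abort("need at least 2 overlapping samples between grid and phenotypes",
      class = "prsbridge_argument_error"
    )
  }
  ph <- pheno[match(common, pheno$sample_id), ]
  covars <- ph[, covariate_cols(ph), drop = FALSE]
  y <- residualize(ph$trait, if (ncol(covars)) covars else NULL)
  X <- grid$scores[common, , drop = FALSE]

  ctr <- colMeans(X)
  scl <- sqrt(matrixStats_colVars(X))
  scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, "/")

  fit <- ridge_loo(Xs, y, penalties)
  w_std <- fit$coefficients
  w_orig <- w_std / scl
  # fit$intercept is on the standardized-column scale: y ~ Xs w_std + b0;
  # on the raw-column scale y ~ X w_orig + (b0 - sum(ctr * w_orig)).
  intercept <- fit$intercept - sum(ctr * w_orig)

  structure(
    list(
      weights = dplyr::mutate(grid$info,
        weight = w_orig, weight_std = w_std, center = ctr, scale = scl
      ),
      intercept = intercept,
      penalty = fit$penalty,
      loo_sigma2 = fit$loo_sigma2,
      loo_mse_path = tibble(penalty = fit$penalties, loo_mse = fit$loo_mse),
      prs = tibble(sample_id = common, prs = as.vector(X %*% w_orig) + intercept),
      y = tibble(sample_id = common, trait_resid = y),
      grid = grid
    ),
    class = "stacked_prs"
  )
}

#' @export
print.stacked_prs <- function(x, ...) {
  cat(sprintf(
    "<stacked_prs> %d columns stacked on %d samples; penalty %.4g, LOO sigma^2 %.4g\n",
    nrow(x$weights), nrow(x$prs), x$penalty, x$loo_sigma2
  ))
  invisible(x)
}

#' Score new samples with a stacked PRS
#'
#' @param object A [`stacked_prs`][stack_ridge].
#' @param geno A [geno_panel]; variants absent from the posterior weight set
#'   contribute zero.
#' @param ... Unused.
#' @return A tibble with `sample_id` and `prs`.
#' @export
predict.stacked_prs <- function(object, geno, ...) {
  w <- snp_weight_vector(object)
  idx <- match(names(w), geno$variants$id)
  keep <- !is.na(idx)
  score <- as.vector(geno$dosages[, idx[keep], drop = FALSE] %*% w[keep]) +
    object$intercept
  tibble(sample_id = geno$sample_ids, prs = score)
}

# collapse a stacked fit to one additive weight per variant
snp_weight_vector <- function(stacked) {
  w <- as.vector(stacked$grid$beta %*% stacked$weights$weight)
  names(w) <- rownames(stacked$grid$beta)
  w
}

#' Select the best-fitting single prior setting
#'
#' Evaluates each grid column's squared correlation with the
#' covariate-residualized trait on the test samples and returns the
#' `(lambda0, alpha, k)` (or `(tau, k)`) setting of the best column. Ties are
#' broken lexicographically on the smallest parameter values.
#'
#' @param grid A [`prs_grid`][score_grid].
#' @param pheno Phenotype tibble.
#' @return A one-row tibble: the winning column's `info` row plus its `r2`.
#' @export
select_best_prior <- function(grid, pheno) {
  common <- intersect(rownames(grid$scores), pheno$sample_id)
  ph <- pheno[match(common, pheno$sample_id), ]
  covars <- ph[, covariate_cols(ph), drop = FALSE]
  y <- residualize(ph$trait, if (ncol(covars)) covars else NULL)
  X <- grid$scores[common, , drop = FALSE]
  r2 <- apply(X, 2, function(col) {
    if (sd(col) == 0) 0 else cor(col, y)^2
  })
  info <- dplyr::mutate(grid$info, r2 = as.vector(r2))
  ord_cols <- intersect(c("lambda0", "alpha", "tau", "k"), names(info))
  info_ord <- dplyr::arrange(
    info,
    dplyr::desc(.data$r2),
    !!!rlang::syms(ord_cols)
  )
  info_ord[1, ]
}

#' Fit the single-population stage-1 model
#'
#' Clumps the summary statistics against the LD panel, computes per-locus
#' genotypic covariances, fits the conjugate ridge posterior under every
#' `(alpha, lambda0)` prior combination, scores the test samples over all
#' prior-by-threshold columns, stacks them by cross-validated ridge, and
#' records the best-fitting single prior setting (whose posterior seeds
#' stage 2).
#'
#' @param sumstats A [`sumstats`][as_sumstats] tibble (harmonized to `panel`;
#'   variants absent from the panel are dropped).
#' @param panel LD reference [geno_panel].
#' @param test_geno,test_pheno Test-sample genotypes and phenotypes for
#'   stacking and prior selection.
#' @param alpha_grid,lambda0_grid,k_grid Prior and threshold grids; defaults
#'   [default_alpha_grid()], [default_lambda0_grid()], [default_k_grid()].
#' @param p1,p2,kb,r2 Clumping parameters, see [clump()].
#' @param jitter Diagonal ridge for degenerate panels, see [compute_phi()].
#' @return A `stage1_fit`: list with `loci`, `blocks`, `posteriors`, `grid`,
#'   `stacked`, `best` (best prior's info row) and `best_posterior` (that
#'   setting's posterior blocks, mean and precision per locus).
#' @export
fit_stage1 <- function(sumstats, panel, test_geno, test_pheno,
                       alpha_grid = default_alpha_grid(),
                       lambda0_grid = default_lambda0_grid(),
                       k_grid = default_k_grid(),
                       p1 = 0.01, p2 = 0.01, kb = 1000, r2 = 0.01,
                       jitter = 0) {
  keep <- sumstats$id %in% panel$variants$id
  if (!all(keep)) {
    inform(sprintf("Dropping %d sumstat variant(s) absent from the LD panel.", sum(!keep)))
    sumstats <- sumstats[keep, ]
  }
  loci <- clump(sumstats, panel, p1 = p1, p2 = p2, kb = kb, r2 = r2)
  if (nrow(loci) == 0) {
    abort("no loci found at the clumping thresholds", class = "prsbridge_empty_error")
  }
  locus_ids <- unique(loci$locus_id)
  blocks <- lapply(setNames(locus_ids, locus_ids), function(lid) {
    compute_phi(loci$member_id[loci$locus_id == lid], panel, jitter = jitter)
  })

  combos <- expand.grid(lambda0 = lambda0_grid, alpha = alpha_grid,
    KEEP.OUT.ATTRS = FALSE
  )
  posteriors <- lapply(seq_len(nrow(combos)), function(i) {
    l0 <- combos$lambda0[i]
    al <- combos$alpha[i]
    list(
      params = list(alpha = al, lambda0 = l0),
      blocks = lapply(blocks, posterior_update, s = sumstats, lambda0 = l0, alpha = al)
    )
  })
  names(posteriors) <- sprintf("a%s_l%s", combos$alpha, combos$lambda0)

  subsets <- assign_subsets(loci, k_grid)
  variant_meta <- sumstats[match(
    unlist(lapply(blocks, `[[`, "ids"), use.names = FALSE), sumstats$id
  ), c("id", "chrom", "pos", "effect_allele", "other_allele")]
  grid <- score_grid(posteriors, subsets, test_geno, variants = variant_meta)
  stacked <- stack_ridge(grid, test_pheno)
  best <- select_best_prior(grid, test_pheno)
  best_label <- sprintf("a%s_l%s", best$alpha, best$lambda0)

  structure(
    list(
      sumstats = sumstats, loci = loci, blocks = blocks,
      posteriors = posteriors, subsets = subsets, grid = grid,
      stacked = stacked, best = best,
      best_posterior = posteriors[[best_label]],
      k_grid = k_grid
    ),
    class = "stage1_fit"
  )
}

#' @export
print.stage1_fit <- function(x, ...) {
  cat(sprintf(
    "<stage1_fit> %d loci, %d prior settings, best (alpha = %s, lambda0 = %s, k = %d), column R^2 = %.4f\n",
    length(x$blocks), length(x$posteriors), x$best$alpha, x$best$lambda0,
    x$best$k, x$best$r2
  ))
  invisible(x)
}
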