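#' Condition a stage-1 posterior on absent variants having zero effect
#'
#' When the target population's variant set does not cover a whole stage-1
#' locus, the prior for the overlapping variants `a` is the stage-1 Gaussian
#' conditioned on the effects of the non-overlapping variants `b` being zero:
#' mean `beta_tilde[a] + solve(Omega[aa], Omega[ab] %*% beta_tilde[b])` with
#' precision `Omega[aa]`.
#'
#' @param post1 A stage-1 [`posterior_block`][posterior_update].
#' @param keep Indices (or ids) of the overlapping variants `a`.
#' @return A `posterior_block` restricted to `a`. Errors if `keep` is empty.
#' @export
conditional_prior <- function(post1, keep) {
  if (is.character(keep)) keep <- match(keep, post1$ids)
  k <- length(post1$ids)
  if (length(keep) == 0 || anyNA(keep)) {
    abort("no overlapping variants to condition on", class = "prsbridge_empty_error")
  }
  keep <- sort(unique(keep))
  drop <- setdiff(seq_len(k), keep)
  if (length(drop) == 0) {
    return(post1)
  }
  om_aa <- post1$omega[keep, keep, drop = FALSE]
  om_ab <- post1$omega[keep, drop, drop = FALSE]
  mean_a <- post1$beta_tilde[keep] +
    as.vector(solve(om_aa, om_ab %*% post1$beta_tilde[drop]))
  structure(
    list(
      ids = post1$ids[keep], beta_tilde = mean_a, omega = om_aa,
      prior = post1$prior
    ),
    class = "posterior_block"
  )
}

#' Bridged posterior update at one locus (stage 2)
#'
#' Updates the discovery-population posterior (used as the target-population
#' prior, with its precision scaled by the bridging parameter `tau`) with the
#' target-population GWAS summary statistics:
#' `Omega2 = tau * Omega1 + phi2` and
#' `beta_tilde2 = solve(Omega2, tau * Omega1 %*% beta_tilde1 +
#' diag(phi2) * beta_hat2)`. Large `tau` pins the target effects to the
#' discovery posterior mean; small `tau` washes the prior out, leaving the
#' target-only ridge solution.
#'
#' @param block2 Target-population [`ld_block`][compute_phi] for the locus
#'   (restricted to the overlapping variants).
#' @param s2 Target-population [`sumstats`][as_sumstats] covering the members.
#' @param prior1 The (possibly conditioned) stage-1
#'   [`posterior_block`][posterior_update] on the same variants.
#' @param tau Positive bridging parameter.
#' @return A `posterior_block` with `prior = list(tau = tau)`.
#' @export
posterior_update2 <- function(block2, s2, prior1, tau) {
  if (tau <= 0) abort("`tau` must be positive", class = "prsbridge_argument_error")
  if (!identical(block2$ids, prior1$ids)) {
    abort("variant sets of the target LD block and the stage-1 prior differ",
      class = "prsbridge_argument_error"
    )
  }
  idx <- match(block2$ids, s2$id)
  if (anyNA(idx)) {
    abort("target summary statistics do not cover all locus members",
      class = "prsbridge_argument_error"
    )
  }
  omega2 <- tau * prior1$omega + block2$phi
  rhs <- tau * as.vector(prior1$omega %*% prior1$beta_tilde) +
    diag(block2$phi) * s2$beta[idx]
  structure(
    list(
      ids = block2$ids,
      beta_tilde = as.vector(solve(omega2, rhs)),
      omega = omega2,
      prior = list(tau = tau)
    ),
    class = "posterior_block"
  )
}

#' Pseudo-F locus association statistic
#'
#' A quadratic-form analogue of the multivariate-regression F statistic with
#' the maximum-likelihood quantities replaced by posterior summaries:
#' `F = (n_eff - k) / (k * sigma2) * t(beta_tilde) %*% omega %*% beta_tilde`,
#' with `n_eff = n * (1 + tau)` the effective number of observations
#' accounting for the prior, `k` the locus dimension and `sigma2` the
#' phenotypic variance. In the flat-prior limit it converges to the classical
#' F statistic when the locus explains little trait variance.
#'
#' @param post2 A stage-2 [`posterior_block`][posterior_update2].
#' @param n Target-population GWAS sample size.
#' @param tau Bridging parameter used in the update.
#' @param sigma2 Positive phenotypic variance (see [estimate_sigma2()]).
#' @return A one-row tibble: `f_bayes`, `n_eff`, `k`.
#' @export
pseudo_f <- function(post2, n, tau, sigma2) {
  if (sigma2 <= 0) abort("`sigma2` must be positive", class = "prsbridge_argument_error")
  k <- length(post2$beta_tilde)
  n_eff <- n * (1 + tau)
  if (n_eff <= k) {
    abort("effective sample size must exceed the locus dimension",
      class = "prsbridge_argument_error"
    )
  }
  q <- as.vector(t(post2$beta_tilde) %*% post2$omega %*% post2$beta_tilde)
  tibble(f_bayes = (n_eff - k) / (k * sigma2) * q, n_eff = n_eff, k = k)
}

#' Phenotypic variance implied by summary statistics
#'
#' Each variant's marginal regression implies a phenotypic variance
#' `2 * theta * (1 - theta) * (n * se^2 + beta_hat^2)`; the median over
#' variants is a robust estimate of `Var(Y)` that uses only fields already in
#' the summary-statistics table.
#'
#' @param s A [`sumstats`][as_sumstats] tibble.
#' @return Positive scalar estimate of the phenotypic variance.
#' @export
estimate_sigma2 <- function(s) {
  if (nrow(s) == 0) abort("empty summary statistics", class = "prsbridge_empty_error")
  v <- 2 * s$freq * (1 - s$freq) * (s$n * s$se^2 + s$beta^2)
  median(v)
}

#' Quantile-matched locus subsets by pseudo-F
#'
#' For each threshold `k`, selects by pseudo-F exactly as many loci as the
#' top-SNP p-value ranking places below `10^-k`: the cut `q_k` is the F value
#' of the `c_k`-th largest statistic, where `c_k = #\{p < 10^-k\}`. Loci tied
#' with the cut value are all included (logged when this exceeds the count).
#'
#' @param fstats Tibble with `locus_id` and `f_bayes` (one row per locus).
#' @param top_pvals Tibble with `locus_id` and `top_pval` over the same loci.
#' @param k_grid Integer thresholds (default `1:8`).
#' @return Named list mapping `k` to locus ids, as in [assign_subsets()].
#' @export
match_quantiles <- function(fstats, top_pvals, k_grid = default_k_grid()) {
  m <- dplyr::inner_join(fstats, top_pvals, by = "locus_id")
  if (nrow(m) != nrow(fstats)) {
    abort("fstats and top_pvals must cover the same loci", class = "prsbridge_argument_error")
  }
  out <- lapply(k_grid, function(k) {
    count <- sum(m$top_pval < 10^-k)
    if (count == 0) {
      return(character())
    }
    cut <- sort(m$f_bayes, decreasing = TRUE)[count]
    sel <- m$locus_id[m$f_bayes >= cut]
    if (length(sel) > count) {
      inform(sprintf(
        "pseudo-F ties at the k = %d cut: %d loci selected for a target of %d.",
        k, length(sel), count
      ))
    }
    sel
  })
  names(out) <- as.character(k_grid)
  out
}

#' Fit the bridged stage-2 model
#'
#' Intersects the stage-1 (discovery-defined) loci with the target
#' population's variants, conditions the stage-1 posterior on the missing
#' variants, updates each locus with the target GWAS under every `tau` in the
#' bridging grid, ranks loci by pseudo-F (quantile-matched to the top-SNP
#' p-value counts) or by top-SNP p-value, scores the target test samples over
#' the `tau`-by-`k` grid, and stacks by cross-validated ridge.
#'
#' @param stage1 A [`stage1_fit`][fit_stage1] for the discovery population.
#' @param sumstats2 Target-population [`sumstats`][as_sumstats], harmonized to
#'   the discovery data.
#' @param panel2 Target-population LD reference [geno_panel].
#' @param test_geno,test_pheno Target-population test data for stacking.
#' @param tau_grid Bridging grid; default [default_tau_grid()].
#' @param k_grid Threshold grid; default the stage-1 fit's.
#' @param ranking `"fstat"` (default) or `"pval"`.
#' @param jitter Diagonal ridge for [compute_phi()].
#' @return A `stage2_fit`: list with `posteriors` (per `tau`), `fstats`,
#'   `subsets`, `grid`, `stacked`, `sigma2`, `dropped_loci`.
#' @export
fit_stage2 <- function(stage1, sumstats2, panel2, test_geno, test_pheno,
                       tau_grid = default_tau_grid(),
                       k_grid = stage1$k_grid,
                       ranking = c("fstat", "pval"),
                       jitter = 0) {
  ranking <- match.arg(ranking)
  available <- intersect(sumstats2$id, panel2$variants$id)

  priors <- list()
  blocks2 <- list()
  dropped <- character()
  for (lid in names(stage1$best_posterior$blocks)) {
    p1 <- stage1$best_posterior$blocks[[lid]]
    keep <- which(p1$ids %in% available)
    if (length(keep) == 0) {
      dropped <- c(dropped, lid)
      next
    }
    priors[[lid]] <- conditional_prior(p1, keep)
    blocks2[[lid]] <- compute_phi(priors[[lid]]$ids, panel2, jitter = jitter)
  }
  if (length(dropped) > 0) {
    inform(sprintf(
      "Dropping %d stage-1 locus/loci with no variants in the target data.",
      length(dropped)
    ))
  }
  if (length(priors) == 0) {
    abort("no stage-1 loci overlap the target data", class = "prsbridge_empty_error")
  }

  n2 <- as.integer(round(median(sumstats2$n)))
  sigma2 <- estimate_sigma2(sumstats2)

  posteriors <- lapply(tau_grid, function(tau) {
    list(
      params = list(tau = tau),
      blocks = lapply(setNames(names(priors), names(priors)), function(lid) {
        posterior_update2(blocks2[[lid]], sumstats2, priors[[lid]], tau)
      })
    )
  })
  names(posteriors) <- sprintf("t%s", tau_grid)

  top_pvals <- dplyr::distinct(
    stage1$loci[stage1$loci$locus_id %in% names(priors), ],
    .data$locus_id, .data$top_pval
  )

  # Subsets per tau: the pseudo-F depends on tau, so each tau ranks its own
  # posterior; the p-value ranking is shared across tau.
  grids <- list()
  fstats_all <- list()
  for (tl in names(posteriors)) {
    tau <- posteriors[[tl]]$params$tau
    if (ranking == "fstat") {
      fstats <- dplyr::bind_rows(lapply(
        names(posteriors[[tl]]$blocks),
        function(lid) {
          dplyr::mutate(
            pseudo_f(posteriors[[tl]]$blocks[[lid]], n = n2, tau = tau, sigma2 = sigma2),
            locus_id = lid, tau = tau
          )
        }
      ))
      subsets <- match_quantiles(fstats, top_pvals, k_grid)
      fstats_all[[tl]] <- fstats
    } else {
      subsets <- assign_subsets(top_pvals, k_grid)
    }
    grids[[tl]] <- score_grid(posteriors[tl], subsets, test_geno,
      variants = stage1$grid$variants
    )
  }

  grid <- merge_grids(grids)
  stacked <- stack_ridge(grid, test_pheno)

  structure(
    list(
      posteriors = posteriors,
      fstats = if (length(fstats_all)) dplyr::bind_rows(fstats_all) else NULL,
      grid = grid, stacked = stacked, sigma2 = sigma2, n2 = n2,
      ranking = ranking, dropped_loci = dropped, k_grid = k_grid
    ),
    class = "stage2_fit"
  )
}

#' @export
print.stage2_fit <- function(x, ...) {
  cat(sprintf(
    "<stage2_fit> %d tau settings x %d thresholds (%s ranking), LOO sigma^2 %.4g\n",
    length(x$posteriors), length(x$k_grid), x$ranking, x$stacked$loo_sigma2
  ))
  invisible(x)
}

#' Concatenate PRS grids column-wise
#'
#' The grids must score the same samples; variant weight matrices are aligned
#' on the union of variants.
#'
#' @param grids List of [`prs_grid`][score_grid] objects.
#' @return A single `prs_grid`.
#' @export
merge_grids <- function(grids) {
  grids <- unname(grids)
  if (length(grids) == 1) {
    return(grids[[1]])
  }
  ids <- rownames(grids[[1]]$scores)
  for (g in grids[-1]) {
    if (!identical(rownames(g$scores), ids)) {
      abort("grids score different samples", class = "prsbridge_argument_error")
    }
  }
  all_vars <- unique(unlist(lapply(grids, function(g) rownames(g$beta))))
  beta <- do.call(cbind, lapply(grids, function(g) {
    out <- matrix(0, nrow = length(all_vars), ncol = ncol(g$beta),
      dimnames = list(all_vars, colnames(g$beta))
    )
    out[rownames(g$beta), ] <- g$beta
    out
  }))
  variants <- dplyr::distinct(
    dplyr::bind_rows(lapply(grids, `[[`, "variants")), .data$id,
    .keep_all = TRUE
  )
  variants <- variants[match(all_vars, variants$id), ]
  scores <- do.call(cbind, lapply(grids, `[[`, "scores"))
  info <- dplyr::bind_rows(lapply(grids, `[[`, "info"))
  if (anyDuplicated(info$column)) {
    info$column <- make.unique(info$column)
    colnames(scores) <- info$column
    colnames(beta) <- info$column
  }
  structure(
    list(
      scores = scores, info = info, beta = beta, variants = variants,
      sample_ids = ids
    ),
    class = "prs_grid"
  )
}
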