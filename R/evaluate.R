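#' Covariate-adjusted variance explained by a PRS
#'
#' `R^2 = 1 - Var(y | M1) / Var(y | M0)`, where `M0` regresses the trait on
#' the covariates (plus intercept) and `M1` adds the PRS. With no covariates
#' this reduces to the squared correlation between trait and PRS. Negative
#' values (possible out of sample) are reported as computed.
#'
#' @param pheno Phenotype tibble (`sample_id`, `trait`, covariates).
#' @param prs Tibble with `sample_id` and `prs`, or a numeric vector aligned
#'   to `pheno`.
#' @return Scalar variance explained.
#' @export
variance_explained <- function(pheno, prs) {
  if (is.numeric(prs)) {
    prs <- tibble(sample_id = pheno$sample_id, prs = prs)
  }
  common <- intersect(pheno$sample_id, prs$sample_id)
  if (length(common) < 3) {
    abort("need at least 3 overlapping samples", class = "prsbridge_argument_error")
  }
  ph <- pheno[match(common, pheno$sample_id), ]
  if (sd(ph$trait) == 0) {
    abort("constant trait", class = "prsbridge_argument_error")
  }
  covars <- ph[, covariate_cols(ph), drop = FALSE]
  score <- prs$prs[match(common, prs$sample_id)]
  resid0 <- residualize(ph$trait, if (ncol(covars)) covars else NULL)
  if (sd(score) == 0) {
    return(0)
  }
  df1 <- data.frame(.y = ph$trait, .prs = score, covars)
  fit1 <- lm(.y ~ ., data = df1)
  1 - var(resid(fit1)) / var(resid0)
}

#' Bootstrap uncertainty for variance explained
#'
#' Resamples individuals with replacement (`boot` package), recomputing the
#' covariate-adjusted R-squared per replicate; reports the bootstrap standard
#' error and a percentile 95% interval.
#'
#' @param pheno,prs As in [variance_explained()].
#' @param n_boot Number of bootstrap replicates (default 10000; reduce for
#'   quick checks).
#' @param seed Integer seed for the resampling.
#' @return An `r2_result` tibble row: `r2`, `se`, `ci_low`, `ci_high`,
#'   `n_boot`, `n`.
#' @export
bootstrap_r2 <- function(pheno, prs, n_boot = 10000, seed = 1) {
  if (n_boot < 1) abort("`n_boot` must be at least 1", class = "prsbridge_argument_error")
  if (is.numeric(prs)) {
    prs <- tibble(sample_id = pheno$sample_id, prs = prs)
  }
  common <- intersect(pheno$sample_id, prs$sample_id)
  ph <- pheno[match(common, pheno$sample_id), ]
  sc <- prs[match(common, prs$sample_id), ]
  point <- variance_explained(ph, sc)
  dat <- data.frame(i = seq_along(common))
  stat <- function(d, w) {
    variance_explained(
      dplyr::mutate(ph[w, ], sample_id = as.character(seq_along(w))),
      tibble(sample_id = as.character(seq_along(w)), prs = sc$prs[w])
    )
  }
  set.seed(seed)
  b <- boot::boot(dat, stat, R = n_boot)
  reps <- as.vector(b$t)
  se <- if (n_boot > 1) sd(reps) else 0
  ci <- if (n_boot > 1) quantile(reps, c(0.025, 0.975), names = FALSE) else c(point, point)
  out <- tibble(
    r2 = point, se = se, ci_low = ci[1], ci_high = ci[2],
    n_boot = as.integer(n_boot), n = length(common)
  )
  class(out) <- c("r2_result", class(out))
  out
}

#' Compare two methods' variance explained across traits
#'
#' For each trait, a z statistic for the difference in R-squared is
#' `(r2_a - r2_b) / sqrt(se_a^2 + se_b^2)`; under the null of equal accuracy
#' the sum of the z statistics is Gaussian with mean 0 and variance equal to
#' the number of traits, from which a two-tailed p-value is derived.
#'
#' @param r2_a,r2_b Tibbles (or [`r2_result`][bootstrap_r2] rows bound
#'   together) with columns `r2` and `se`, paired by trait order.
#' @return A one-row tibble with `z_sum`, `n_traits`, `p_value`.
#' @export
compare_methods <- function(r2_a, r2_b) {
  if (nrow(r2_a) != nrow(r2_b)) {
    abort("method results must be paired by trait", class = "prsbridge_argument_error")
  }
  if (any(r2_a$se == 0) || any(r2_b$se == 0)) {
    abort("zero standard errors; bootstrap with more replicates",
      class = "prsbridge_argument_error"
    )
  }
  z <- (r2_a$r2 - r2_b$r2) / sqrt(r2_a$se^2 + r2_b$se^2)
  n_traits <- length(z)
  z_sum <- sum(z)
  p <- 2 * pnorm(abs(z_sum) / sqrt(n_traits), lower.tail = FALSE)
  tibble(z_sum = z_sum, n_traits = n_traits, p_value = p)
}
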