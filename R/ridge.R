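# Closed-form leave-one-out ridge regression via SVD.
#
# Fits y ~ X b + intercept with an L2 penalty on b over a grid of penalties,
# selecting the penalty that minimizes the exact leave-one-out squared error
# computed from the hat-matrix diagonal. X is used as supplied (standardize
# before calling); y and X are centred internally, and the intercept's 1/n
# leverage is included in the hat diagonal.
ridge_loo <- function(X, y, penalties = NULL) {
  n <- nrow(X)
  if (n < 2) abort("need at least 2 samples for ridge stacking", class = "prsbridge_argument_error")
  if (sd(y) == 0) abort("constant response in ridge stacking", class = "prsbridge_argument_error")
  if (is.null(penalties)) {
    col_vars <- matrixStats_colVars(X)
    scale_ref <- mean(col_vars[col_vars > 0])
    if (!is.finite(scale_ref) || scale_ref <= 0) scale_ref <- 1
    penalties <- 10^seq(-4, 4, length.out = 50) * scale_ref
  }
  xm <- colMeans(X)
  ym <- mean(y)
  Xc <- sweep(X, 2, xm)
  yc <- y - ym
  sv <- svd(Xc)
  d <- sv$d
  uty <- crossprod(sv$u, yc)
  U2 <- sv$u^2

  loo_mse <- vapply(penalties, function(t) {
    shrink <- d^2 / (d^2 + t)
    fitted <- sv$u %*% (shrink * uty)
    h <- U2 %*% shrink + 1 / n
    h <- pmin(h, 1 - 1e-12)
    mean(((yc - fitted) / (1 - h))^2)
  }, numeric(1))

  best <- which.min(loo_mse)
  t_best <- penalties[best]
  shrink <- d^2 / (d^2 + t_best)
  coef_std <- sv$v %*% ((d / (d^2 + t_best)) * uty)
  fitted <- as.vector(sv$u %*% (shrink * uty)) + ym

  list(
    coefficients = as.vector(coef_std),
    intercept = ym - sum(coef_std * xm),
    penalty = t_best,
    penalties = penalties,
    loo_mse = loo_mse,
    loo_sigma2 = loo_mse[best],
    fitted = fitted
  )
}

# Covariate columns of a phenotype tibble. The column `g` is reserved for the
# simulator's true genetic value and is never used as a covariate.
covariate_cols <- function(pheno) {
  setdiff(names(pheno), c("sample_id", "trait", "g"))
}

# Regress covariates (plus intercept) out of y; returns residuals.
# Collinear covariates are dropped by lm with a warning.
residualize <- function(y, covariates = NULL) {
  if (is.null(covariates) || ncol(covariates) == 0) {
    return(y - mean(y))
  }
  df <- data.frame(.y = y, covariates)
  fit <- lm(.y ~ ., data = df)
  if (anyNA(coef(fit))) {
    warn("collinear covariates dropped when residualizing the trait")
  }
  as.vector(resid(fit))
}
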