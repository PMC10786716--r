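#' Posterior model weights from cross-validated residual variances
#'
#' Approximates each candidate model's log-marginal likelihood by
#' `-(n/2) * log(sigma2_i)` up to a shared constant, where `sigma2_i` is the
#' model's cross-validated residual variance, and normalizes with equal prior
#' model weight. Lower residual variance therefore yields a higher weight;
#' computation is in log space with max subtraction for stability.
#'
#' @param sigma2 Positive numeric vector of cross-validated residual
#'   variances, one per model.
#' @param n Number of observations the residual variances were estimated on.
#' @return Numeric vector of weights summing to 1.
#' @export
model_weights <- function(sigma2, n) {
  if (any(!is.finite(sigma2) | sigma2 <= 0)) {
    abort("all residual variances must be positive", class = "prsbridge_argument_error")
  }
  if (n <= 0) abort("`n` must be positive", class = "prsbridge_argument_error")
  lw <- -(n / 2) * log(sigma2)
  lw <- lw - max(lw)
  w <- exp(lw)
  w / sum(w)
}

#' Build and weight the candidate PRS models
#'
#' Combines the two-stage bridged model (M1), the target-only single-ancestry
#' model (M2) and the merged model (M3, a fresh ridge stack of the
#' concatenated M1 and M2 score grids) into a model average, with weights from
#' each model's leave-one-out residual variance via [model_weights()]. Any
#' number of component models may be supplied; the merged model is always
#' added last.
#'
#' @param ... Named [`stacked_prs`][stack_ridge] components (at least one),
#'   all stacked on the same test samples; conventionally `M1` (two-stage)
#'   and `M2` (target-only).
#' @param pheno Test-sample phenotype tibble used to stack the merged model.
#' @param merged_name Name for the merged model (default `"M3"`). Set
#'   `merge = FALSE` to skip it.
#' @param merge Add the merged-grid model (default `TRUE`).
#' @return A `model_average`: list with `components` (named list of stacked
#'   fits), `sigma2`, `n`, `weights`.
#' @export
build_models <- function(..., pheno, merged_name = "M3", merge = TRUE) {
  components <- list(...)
  if (length(components) == 1 && is.list(components[[1]]) &&
    !inherits(components[[1]], "stacked_prs")) {
    components <- components[[1]]
  }
  if (is.null(names(components)) || any(names(components) == "")) {
    names(components) <- paste0("M", seq_along(components))
  }
  for (cmp in components) {
    if (!inherits(cmp, "stacked_prs")) {
      abort("all components must be stacked_prs objects", class = "prsbridge_argument_error")
    }
  }
  ids <- components[[1]]$prs$sample_id
  for (cmp in components) {
    if (!identical(cmp$prs$sample_id, ids)) {
      abort("component models are stacked on different samples",
        class = "prsbridge_argument_error"
      )
    }
  }
  if (merge && length(components) > 1) {
    merged_grid <- merge_grids(lapply(components, `[[`, "grid"))
    components[[merged_name]] <- stack_ridge(merged_grid, pheno)
  }
  sigma2 <- vapply(components, `[[`, numeric(1), "loo_sigma2")
  n <- length(ids)
  structure(
    list(
      components = components, sigma2 = sigma2, n = n,
      weights = model_weights(sigma2, n)
    ),
    class = "model_average"
  )
}

#' @export
print.model_average <- function(x, ...) {
  cat(sprintf("<model_average> %d models on %d samples\n", length(x$components), x$n))
  for (nm in names(x$components)) {
    cat(sprintf("  %s: sigma^2 = %.4g, weight = %.3f\n", nm, x$sigma2[nm], x$weights[nm]))
  }
  invisible(x)
}

#' Export final per-SNP additive weights
#'
#' Collapses the model average into one additive per-allele weight per
#' variant: each model's ridge-stacked posterior-mean weights are combined
#' with the posterior model weights. Scoring a genotype panel with this file
#' reproduces the model-averaged PRS exactly up to the global intercept.
#'
#' @param avg A [`model_average`][build_models].
#' @param drop_zero Omit variants with weight exactly zero (default `FALSE`).
#' @return A `snp_weights` tibble: `id`, `chrom`, `pos`, `effect_allele`,
#'   `weight`, with the combined intercept in attribute `"intercept"`.
#' @export
export_weights <- function(avg, drop_zero = FALSE) {
  tables <- lapply(names(avg$components), function(nm) {
    cmp <- avg$components[[nm]]
    w <- snp_weight_vector(cmp)
    tibble(id = names(w), weight = avg$weights[nm] * unname(w))
  })
  combined <- dplyr::summarise(
    dplyr::group_by(dplyr::bind_rows(tables), .data$id),
    weight = sum(.data$weight), .groups = "drop"
  )
  meta <- dplyr::distinct(
    dplyr::bind_rows(lapply(avg$components, function(cmp) cmp$grid$variants)),
    .data$id,
    .keep_all = TRUE
  )
  out <- dplyr::left_join(combined, meta, by = "id")
  out <- out[order(out$chrom, out$pos), c(
    "id", "chrom", "pos", "effect_allele", "other_allele", "weight"
  )]
  if (drop_zero) out <- out[out$weight != 0, ]
  intercept <- sum(avg$weights * vapply(avg$components, `[[`, numeric(1), "intercept"))
  attr(out, "intercept") <- intercept
  class(out) <- c("snp_weights", class(out))
  out
}

#' Score a genotype panel with a per-SNP weight file
#'
#' @param geno A [geno_panel].
#' @param weights A [`snp_weights`][export_weights] tibble (or any tibble with
#'   `id` and `weight`); variants absent from the panel contribute zero.
#' @return A tibble with `sample_id` and `prs`.
#' @export
score_panel <- function(geno, weights) {
  idx <- match(weights$id, geno$variants$id)
  keep <- !is.na(idx)
  intercept <- attr(weights, "intercept")
  if (is.null(intercept)) intercept <- 0
  prs <- as.vector(geno$dosages[, idx[keep], drop = FALSE] %*% weights$weight[keep]) +
    intercept
  tibble(sample_id = geno$sample_ids, prs = prs)
}

#' Predict the model-averaged PRS for new samples
#'
#' @param object A [`model_average`][build_models].
#' @param geno A [geno_panel].
#' @param ... Unused.
#' @return Tibble with `sample_id`, one column per component model, and the
#'   weighted `prs`.
#' @export
predict.model_average <- function(object, geno, ...) {
  per_model <- lapply(object$components, predict, geno = geno)
  out <- tibble(sample_id = geno$sample_ids)
  for (nm in names(per_model)) out[[nm]] <- per_model[[nm]]$prs
  comp_mat <- as.matrix(out[names(per_model)])
  out$prs <- as.vector(comp_mat %*% object$weights)
  out
}

#' Write / read a per-SNP weight file
#'
#' Tab-delimited `id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `weight`; the intercept travels in a `# intercept:` header comment.
#'
#' @param weights A [`snp_weights`][export_weights] tibble.
#' @param path File path.
#' @return The tibble (read) or `weights` invisibly (write).
#' @export
write_snp_weights <- function(weights, path) {
  intercept <- attr(weights, "intercept")
  writeLines(
    sprintf("# intercept: %.17g", if (is.null(intercept)) 0 else intercept),
    path
  )
  readr::write_tsv(as_tibble(weights), path, append = TRUE, col_names = TRUE)
  invisible(weights)
}

#' @rdname write_snp_weights
#' @export
read_snp_weights <- function(path) {
  header <- readLines(path, n = 1)
  intercept <- 0
  if (grepl("^# intercept:", header)) {
    intercept <- as.numeric(sub("^# intercept:", "", header))
  }
  out <- as_tibble(data.table::fread(path, skip = 1, header = TRUE, data.table = FALSE))
  attr(out, "intercept") <- intercept
  class(out) <- c("snp_weights", class(out))
  out
}

#' Fit the full bridged PRS pipeline
#'
#' Runs stage 1 on the discovery population, bridges to the target population
#' in stage 2, fits the target-only stage-1 model, combines the two-stage
#' (M1), target-only (M2) and merged (M3) models by approximate posterior
#' model probabilities, and exports final per-SNP weights.
#'
#' @param sumstats1,panel1,test_geno1,test_pheno1 Discovery-population GWAS
#'   summary statistics, LD reference panel, and test genotype/phenotype data.
#' @param sumstats2,panel2,test_geno2,test_pheno2 The same for the target
#'   population.
#' @param alpha_grid,lambda0_grid,tau_grid,k_grid Prior grids (defaults as in
#'   [default_grids]).
#' @param ranking Stage-2 locus ranking, `"fstat"` (default) or `"pval"`.
#' @param p1,p2,kb,r2,jitter Clumping and covariance options.
#' @return A `bridge_fit`: list with `stage1`, `stage2`, `target_only`
#'   (stage-1 fit on the target data), `models` (the [`model_average`]),
#'   `snp_weights`.
#' @export
prs_bridge <- function(sumstats1, panel1, test_geno1, test_pheno1,
                       sumstats2, panel2, test_geno2, test_pheno2,
                       alpha_grid = default_alpha_grid(),
                       lambda0_grid = default_lambda0_grid(),
                       tau_grid = default_tau_grid(),
                       k_grid = default_k_grid(),
                       ranking = c("fstat", "pval"),
                       p1 = 0.01, p2 = 0.01, kb = 1000, r2 = 0.01,
                       jitter = 0) {
  ranking <- match.arg(ranking)
  stage1 <- fit_stage1(sumstats1, panel1, test_geno1, test_pheno1,
    alpha_grid = alpha_grid, lambda0_grid = lambda0_grid, k_grid = k_grid,
    p1 = p1, p2 = p2, kb = kb, r2 = r2, jitter = jitter
  )
  stage2 <- fit_stage2(stage1, sumstats2, panel2, test_geno2, test_pheno2,
    tau_grid = tau_grid, k_grid = k_grid, ranking = ranking, jitter = jitter
  )
  target_only <- fit_stage1(sumstats2, panel2, test_geno2, test_pheno2,
    alpha_grid = alpha_grid, lambda0_grid = lambda0_grid, k_grid = k_grid,
    p1 = p1, p2 = p2, kb = kb, r2 = r2, jitter = jitter
  )
  models <- build_models(
    M1 = stage2$stacked, M2 = target_only$stacked,
    pheno = test_pheno2
  )
  structure(
    list(
      stage1 = stage1, stage2 = stage2, target_only = target_only,
      models = models, snp_weights = export_weights(models)
    ),
    class = "bridge_fit"
  )
}

#' @export
print.bridge_fit <- function(x, ...) {
  cat("<bridge_fit>\n")
  print(x$models)
  invisible(x)
}

#' @export
predict.bridge_fit <- function(object, geno, ...) {
  predict(object$models, geno = geno, ...)
}
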