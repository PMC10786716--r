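#' Tidy a stacked PRS fit
#'
#' One row per grid column with its prior parameters, ridge weight and
#' scaling constants.
#'
#' @param x A [`stacked_prs`][stack_ridge].
#' @param ... Unused.
#' @return A tibble.
#' @method tidy stacked_prs
#' @export
tidy.stacked_prs <- function(x, ...) {
  as_tibble(x$weights)
}

#' @rdname tidy.stacked_prs
#' @method glance stacked_prs
#' @export
glance.stacked_prs <- function(x, ...) {
  y <- x$y$trait_resid
  fitted <- x$prs$prs
  tibble(
    n = nrow(x$prs),
    n_columns = nrow(x$weights),
    penalty = x$penalty,
    loo_sigma2 = x$loo_sigma2,
    r2_fit = if (sd(fitted) > 0) cor(fitted, y)^2 else 0
  )
}

#' Tidy a model average
#'
#' @param x A [`model_average`][build_models].
#' @param ... Unused.
#' @return One row per component model: `model`, `sigma2`, `weight`.
#' @method tidy model_average
#' @export
tidy.model_average <- function(x, ...) {
  tibble(
    model = names(x$components),
    sigma2 = unname(x$sigma2),
    weight = unname(x$weights)
  )
}

#' @rdname tidy.model_average
#' @method glance model_average
#' @export
glance.model_average <- function(x, ...) {
  tibble(
    n = x$n, n_models = length(x$components),
    best_model = names(x$components)[which.max(x$weights)],
    max_weight = max(x$weights)
  )
}

#' Tidy a full bridged fit
#'
#' @param x A [`bridge_fit`][prs_bridge].
#' @param ... Unused.
#' @return The final per-SNP weight table as a tibble.
#' @method tidy bridge_fit
#' @export
tidy.bridge_fit <- function(x, ...) {
  as_tibble(x$snp_weights)
}

#' @rdname tidy.bridge_fit
#' @method glance bridge_fit
#' @export
glance.bridge_fit <- function(x, ...) {
  dplyr::bind_cols(
    glance(x$models),
    tibble(
      stage1_loci = length(x$stage1$blocks),
      stage1_best_alpha = x$stage1$best$alpha,
      stage1_best_lambda0 = x$stage1$best$lambda0
    )
  )
}

#' Plot a stacked PRS against the residualized trait
#'
#' @param object A [`stacked_prs`][stack_ridge].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot stacked_prs
#' @export
autoplot.stacked_prs <- function(object, ...) {
  df <- dplyr::inner_join(object$prs, object$y, by = "sample_id")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$prs, y = .data$trait_resid)) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
      linewidth = 0.6, colour = "firebrick"
    ) +
    ggplot2::labs(
      x = "stacked PRS", y = "trait (covariate-residualized)",
      title = sprintf("Stacked PRS, LOO sigma^2 = %.3g", object$loo_sigma2)
    ) +
    ggplot2::theme_minimal()
}

#' Plot posterior model weights
#'
#' @param object A [`model_average`][build_models].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot model_average
#' @export
autoplot.model_average <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$model, y = .data$weight)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = NULL, y = "posterior model weight",
      title = "Candidate PRS models"
    ) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}

#' Plot a PRS grid's column accuracies
#'
#' Squared correlation of each grid column with the trait (optionally
#' covariate-residualized), faceted by threshold index.
#'
#' @param object A [`prs_grid`][score_grid].
#' @param pheno Phenotype tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot prs_grid
#' @export
autoplot.prs_grid <- function(object, pheno, ...) {
  common <- intersect(rownames(object$scores), pheno$sample_id)
  ph <- pheno[match(common, pheno$sample_id), ]
  covars <- ph[, covariate_cols(ph), drop = FALSE]
  y <- residualize(ph$trait, if (ncol(covars)) covars else NULL)
  r2 <- apply(object$scores[common, , drop = FALSE], 2, function(col) {
    if (sd(col) == 0) 0 else cor(col, y)^2
  })
  df <- dplyr::mutate(object$info, r2 = as.vector(r2))
  param <- if ("tau" %in% names(df)) "tau" else "lambda0"
  ggplot2::ggplot(df, ggplot2::aes(
    x = factor(.data[[param]]), y = .data$r2,
    colour = if ("alpha" %in% names(df)) factor(.data$alpha) else NULL
  )) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~k, labeller = ggplot2::label_both) +
    ggplot2::labs(
      x = param, y = expression(R^2), colour = "alpha",
      title = "Per-column test accuracy of the PRS grid"
    ) +
    ggplot2::theme_minimal()
}
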