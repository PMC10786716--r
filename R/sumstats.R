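#' GWAS summary statistics
#'
#' A summary-statistics table holds one row per variant with the marginal
#' (single-SNP) regression estimates from a GWAS: effect size `beta` on the
#' effect-allele count scale, its standard error `se`, effect-allele frequency
#' `freq`, GWAS sample size `n` and two-sided p-value `pval`, together with the
#' variant identity columns `id`, `chrom`, `pos` (1-based), `effect_allele` and
#' `other_allele`.
#'
#' `as_sumstats()` validates a data frame and returns it as a tibble with class
#' `sumstats`. Rows with `freq` outside (0, 1) or `se <= 0` are dropped with a
#' message, since downstream shrinkage formulas require both.
#'
#' @param x A data frame with the columns listed above.
#' @return A tibble of class `sumstats`.
#' @examples
#' ss <- as_sumstats(data.frame(
#'   id = "rs1", chrom = "1", pos = 100L, effect_allele = "A",
#'   other_allele = "G", beta = 0.1, se = 0.02, freq = 0.3,
#'   n = 1000L, pval = 1e-6
#' ))
#' @export
as_sumstats <- function(x) {
  required <- c(
    "id", "chrom", "pos", "effect_allele", "other_allele",
    "beta", "se", "freq", "n", "pval"
  )
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0(
      "summary statistics are missing required column(s): ",
      paste(missing_cols, collapse = ", ")
    ), class = "prsbridge_format_error")
  }
  out <- as_tibble(x)[required]
  out$chrom <- as.character(out$chrom)
  out$pos <- as.integer(out$pos)
  out$n <- as.integer(out$n)
  bad <- !is.finite(out$freq) | out$freq <= 0 | out$freq >= 1 |
    !is.finite(out$se) | out$se <= 0
  if (any(bad)) {
    inform(sprintf(
      "Dropping %d variant(s) with allele frequency outside (0, 1) or non-positive standard error.",
      sum(bad)
    ))
    out <- out[!bad, ]
  }
  if (anyDuplicated(out[c("chrom", "pos", "effect_allele", "other_allele")])) {
    abort("duplicate (chrom, pos, allele pair) rows in summary statistics",
      class = "prsbridge_format_error"
    )
  }
  if (any(out$pos < 1L)) {
    abort("positions must be 1-based (>= 1)", class = "prsbridge_format_error")
  }
  if (any(out$effect_allele == out$other_allele)) {
    abort("effect and other allele identical for some variants",
      class = "prsbridge_format_error"
    )
  }
  class(out) <- c("sumstats", class(out))
  out
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a whitespace- or tab-delimited file with a header and maps its columns
#' onto the canonical summary-statistics fields. Rows failing validation
#' (frequency on the boundary, non-positive standard error) are dropped with a
#' message.
#'
#' @param path Path to a delimited text file with a header row.
#' @param column_map Named character vector mapping canonical names
#'   (`id`, `chrom`, `pos`, `effect_allele`, `other_allele`, `beta`, `se`,
#'   `freq`, `n`, `pval`) to the column names used in the file. Canonical names
#'   absent from the map are assumed to appear verbatim in the file.
#' @return A [`sumstats`][as_sumstats] tibble.
#' @export
read_sumstats <- function(path, column_map = NULL) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  if (!is.null(column_map)) {
    for (canonical in names(column_map)) {
      file_col <- column_map[[canonical]]
      if (!file_col %in% names(dt)) {
        abort(sprintf("mapped column '%s' (for '%s') not found in %s",
          file_col, canonical, path
        ), class = "prsbridge_format_error")
      }
      names(dt)[names(dt) == file_col] <- canonical
    }
  }
  as_sumstats(dt)
}

#' Write summary statistics to tab-delimited text
#'
#' @param s A [`sumstats`][as_sumstats] tibble.
#' @param path Output path.
#' @return `s`, invisibly.
#' @export
write_sumstats <- function(s, path) {
  readr::write_tsv(as_tibble(s), path)
  invisible(s)
}

#' Rescale standardized summary statistics to trait units
#'
#' GWAS run on a trait standardized to unit variance report effects in
#' standard-deviation units. To combine them with statistics on a raw trait
#' scale, the effects and standard errors are multiplied by the target trait
#' standard deviation; z-scores, p-values and allele frequencies are unchanged.
#'
#' @param s A [`sumstats`][as_sumstats] tibble computed on a unit-variance trait.
#' @param target_sd Positive scalar, the standard deviation of the target-scale
#'   trait.
#' @return A `sumstats` tibble on the target scale.
#' @export
rescale_sumstats <- function(s, target_sd) {
  if (!is.numeric(target_sd) || length(target_sd) != 1 || target_sd <= 0) {
    abort("`target_sd` must be a positive scalar", class = "prsbridge_argument_error")
  }
  s$beta <- s$beta * target_sd
  s$se <- s$se * target_sd
  s
}
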