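#' Define loci by greedy LD clumping
#'
#' Repeatedly takes the unassigned variant with the smallest p-value at most
#' `p1` as the lead of a new locus, and assigns to it every unassigned variant
#' with p-value at most `p2`, within `kb` kilobases of the lead on the same
#' chromosome, and squared correlation with the lead exceeding `r2` in the
#' reference panel. Assigned variants leave the candidate pool, so loci are
#' disjoint. Ties on the minimal p-value are broken by (chrom, pos).
#'
#' @param s A [`sumstats`][as_sumstats] tibble, harmonized to `panel`.
#' @param panel A [geno_panel] supplying the LD reference.
#' @param p1 Lead-variant p-value threshold (default 0.01).
#' @param p2 Member p-value threshold (default 0.01).
#' @param kb Window half-width around the lead, kilobases (default 1000).
#' @param r2 Squared-correlation threshold with the lead; membership requires
#'   r^2 strictly greater (default 0.01).
#' @return A tibble with one row per member variant: `locus_id`, `lead_id`,
#'   `member_id`, `chrom`, `pos`, `pval` and the locus-level `top_pval`
#'   (minimum member p-value). Empty tibble when no variant reaches `p1`.
#' @export
clump <- function(s, panel, p1 = 0.01, p2 = 0.01, kb = 1000, r2 = 0.01) {
  idx_panel <- match(s$id, panel$variants$id)
  if (anyNA(idx_panel)) {
    abort("summary statistics contain variants absent from the panel; harmonize first",
      class = "prsbridge_argument_error"
    )
  }
  ord <- order(s$pval, s$chrom, s$pos)
  candidate <- s$pval <= p2
  assigned <- rep(FALSE, nrow(s))
  X <- panel$dosages

  out <- list()
  locus_counter <- 0L
  for (i in ord) {
    if (assigned[i] || s$pval[i] > p1) next
    lead <- i
    in_window <- which(
      !assigned & candidate &
        s$chrom == s$chrom[lead] &
        abs(s$pos - s$pos[lead]) <= kb * 1000
    )
    if (length(in_window) > 1) {
      r2_with_lead <- as.vector(cor(X[, idx_panel[lead]], X[, idx_panel[in_window]]))^2
      members <- in_window[in_window == lead | r2_with_lead > r2]
    } else {
      members <- lead
    }
    assigned[members] <- TRUE
    locus_counter <- locus_counter + 1L
    out[[locus_counter]] <- tibble(
      locus_id = sprintf("locus_%04d", locus_counter),
      lead_id = s$id[lead],
      member_id = s$id[members],
      chrom = s$chrom[members],
      pos = s$pos[members],
      pval = s$pval[members],
      top_pval = min(s$pval[members])
    )
  }
  if (locus_counter == 0L) {
    return(tibble(
      locus_id = character(), lead_id = character(), member_id = character(),
      chrom = character(), pos = integer(), pval = double(), top_pval = double()
    ))
  }
  dplyr::bind_rows(out)
}

#' Per-locus genotypic covariance
#'
#' Computes the allele-aligned genotypic covariance matrix of a locus from a
#' reference panel: mean-centred dosages cross-multiplied with denominator `n`
#' (so that for an in-sample panel `X^T X = n * phi` exactly), plus an optional
#' ridge `jitter` on the diagonal for degenerate panels. The posterior adds a
#' positive prior precision to the diagonal, so rank-deficient `phi` is
#' acceptable and returned as-is by default.
#'
#' @param member_ids Character vector of member variant ids (lead included).
#' @param panel A [geno_panel] containing all members.
#' @param jitter Non-negative ridge added to the diagonal (default 0).
#' @return A list of class `ld_block` with elements `ids`, `phi`
#'   (symmetric PSD matrix) and `freq` (panel effect-allele frequencies).
#' @export
compute_phi <- function(member_ids, panel, jitter = 0) {
  idx <- match(member_ids, panel$variants$id)
  if (anyNA(idx)) {
    abort(paste0(
      "variants absent from panel: ",
      paste(member_ids[is.na(idx)], collapse = ", ")
    ), class = "prsbridge_argument_error")
  }
  if (jitter < 0) abort("`jitter` must be non-negative", class = "prsbridge_argument_error")
  X <- panel$dosages[, idx, drop = FALSE]
  n <- nrow(X)
  Xc <- sweep(X, 2, colMeans(X))
  phi <- crossprod(Xc) / n
  phi <- (phi + t(phi)) / 2
  if (jitter > 0) phi <- phi + diag(jitter, ncol(phi))
  structure(
    list(ids = member_ids, phi = phi, freq = colMeans(X) / 2),
    class = "ld_block"
  )
}

#' Serialize / read a locus table
#'
#' Tab-delimited with columns `locus_id`, `lead_id`, `member_id`, `chrom`,
#' `pos`, `pval`, `top_pval`.
#'
#' @param loci A locus tibble from [clump()].
#' @param path File path.
#' @return The tibble (read) or `loci` invisibly (write).
#' @export
write_loci <- function(loci, path) {
  readr::write_tsv(loci, path)
  invisible(loci)
}

#' @rdname write_loci
#' @export
read_loci <- function(path) {
  as_tibble(data.table::fread(path, header = TRUE, data.table = FALSE,
    colClasses = list(character = c("chrom"))
  ))
}
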