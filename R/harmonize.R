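#' Harmonize two variant-bearing datasets
#'
#' Matches variants between two summary-statistics tables and/or genotype
#' panels by genomic position and unordered allele pair, and reorients the
#' second dataset onto the effect alleles of the first. Where the effect
#' alleles are swapped between sources, effects are negated and frequencies
#' complemented (for summary statistics) or dosages reflected (`2 - dosage`,
#' for panels). Strand-ambiguous (A/T, C/G) variants are dropped by default
#' since their orientation cannot be resolved from alleles alone.
#'
#' @param a,b A [`sumstats`][as_sumstats] tibble or a [geno_panel].
#' @param keep_ambiguous Keep strand-ambiguous palindromic variants
#'   (default `FALSE`: drop them).
#' @return A list with elements `a`, `b` (aligned to identical variant order
#'   and orientation) and `report`, a one-row tibble with counts of matched,
#'   flipped, ambiguous-dropped and unmatched variants.
#' @export
harmonize <- function(a, b, keep_ambiguous = FALSE) {
  va <- variant_table(a)
  vb <- variant_table(b)

  key_a <- variant_key(va)
  key_b <- variant_key(vb)
  idx_b <- match(key_a, key_b)
  matched_a <- which(!is.na(idx_b))
  matched_b <- idx_b[matched_a]
  if (length(matched_a) == 0) {
    abort("no overlapping variants between datasets", class = "prsbridge_harmonize_error")
  }

  ea_a <- va$effect_allele[matched_a]
  ea_b <- vb$effect_allele[matched_b]
  flipped <- ea_a != ea_b

  ambiguous <- is_palindromic(va$effect_allele[matched_a], va$other_allele[matched_a])
  n_ambiguous_dropped <- 0L
  if (!keep_ambiguous && any(ambiguous)) {
    n_ambiguous_dropped <- sum(ambiguous)
    matched_a <- matched_a[!ambiguous]
    matched_b <- matched_b[!ambiguous]
    flipped <- flipped[!ambiguous]
  }
  if (length(matched_a) == 0) {
    abort("no overlapping variants after removing strand-ambiguous sites",
      class = "prsbridge_harmonize_error"
    )
  }

  a_out <- take_variants(a, matched_a)
  b_out <- take_variants(b, matched_b)
  b_out <- orient_to(b_out, flipped, template = variant_table(a_out))

  report <- tibble(
    n_a = nrow(va), n_b = nrow(vb),
    n_matched = length(matched_a),
    n_flipped = sum(flipped),
    n_ambiguous_dropped = n_ambiguous_dropped,
    n_unmatched_a = nrow(va) - length(matched_a) - n_ambiguous_dropped,
    n_unmatched_b = nrow(vb) - length(matched_a) - n_ambiguous_dropped
  )
  list(a = a_out, b = b_out, report = report)
}

variant_table <- function(x) {
  if (inherits(x, "geno_panel")) x$variants else as_tibble(x)
}

variant_key <- function(v) {
  pair <- ifelse(v$effect_allele < v$other_allele,
    paste0(v$effect_allele, "/", v$other_allele),
    paste0(v$other_allele, "/", v$effect_allele)
  )
  paste(v$chrom, v$pos, pair, sep = ":")
}

is_palindromic <- function(a1, a2) {
  comp <- c(A = "T", T = "A", C = "G", G = "C")
  !is.na(comp[a1]) & comp[a1] == a2
}

take_variants <- function(x, idx) {
  if (inherits(x, "geno_panel")) {
    subset_panel(x, variants = idx)
  } else {
    x[idx, ]
  }
}

# Reorient flipped variants of x onto the template's effect alleles.
orient_to <- function(x, flipped, template) {
  if (!any(flipped)) {
    return(sync_alleles(x, template))
  }
  if (inherits(x, "geno_panel")) {
    x$dosages[, flipped] <- 2 - x$dosages[, flipped]
  } else {
    x$beta[flipped] <- -x$beta[flipped]
    x$freq[flipped] <- 1 - x$freq[flipped]
  }
  sync_alleles(x, template)
}

sync_alleles <- function(x, template) {
  if (inherits(x, "geno_panel")) {
    x$variants$effect_allele <- template$effect_allele
    x$variants$other_allele <- template$other_allele
  } else {
    x$effect_allele <- template$effect_allele
    x$other_allele <- template$other_allele
  }
  x
}
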