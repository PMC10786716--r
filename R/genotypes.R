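#' Genotype panel
#'
#' A `geno_panel` bundles a samples-by-variants dosage matrix (effect-allele
#' counts in \[0, 2\], possibly fractional) with its variant metadata and sample
#' identifiers. Dosages are stored dense; column order matches the variant
#' table.
#'
#' @param dosages Numeric matrix, samples in rows, variants in columns.
#' @param variants Data frame with columns `id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`; the dosage columns count copies of
#'   `effect_allele`.
#' @param sample_ids Character vector of unique sample identifiers.
#' @return An object of class `geno_panel`.
#' @export
geno_panel <- function(dosages, variants, sample_ids = rownames(dosages)) {
  variants <- as_tibble(variants)
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(nrow(dosages)))
  stopifnot(
    nrow(variants) == ncol(dosages),
    length(sample_ids) == nrow(dosages),
    !anyDuplicated(sample_ids)
  )
  if (anyDuplicated(variants$id)) {
    abort("duplicate variant ids in panel", class = "prsbridge_format_error")
  }
  rng <- range(dosages, na.rm = TRUE)
  if (rng[1] < 0 || rng[2] > 2) {
    abort("dosages must lie in [0, 2]", class = "prsbridge_format_error")
  }
  dimnames(dosages) <- list(sample_ids, variants$id)
  structure(
    list(dosages = dosages, variants = variants, sample_ids = as.character(sample_ids)),
    class = "geno_panel"
  )
}

#' @export
print.geno_panel <- function(x, ...) {
  cat(sprintf(
    "<geno_panel> %d samples x %d variants (chrom %s)\n",
    length(x$sample_ids), nrow(x$variants),
    paste(unique(x$variants$chrom), collapse = ",")
  ))
  invisible(x)
}

#' @export
dim.geno_panel <- function(x) dim(x$dosages)

#' Subset a genotype panel
#'
#' @param x A [geno_panel].
#' @param samples,variants Indices, logical masks or identifier vectors
#'   selecting samples / variants; `NULL` keeps all.
#' @return A `geno_panel`.
#' @export
subset_panel <- function(x, samples = NULL, variants = NULL) {
  si <- if (is.null(samples)) seq_along(x$sample_ids) else samples
  if (is.character(si)) si <- match(si, x$sample_ids)
  vi <- if (is.null(variants)) seq_len(nrow(x$variants)) else variants
  if (is.character(vi)) vi <- match(vi, x$variants$id)
  if (anyNA(si) || anyNA(vi)) {
    abort("unknown sample or variant identifiers in subset", class = "prsbridge_format_error")
  }
  geno_panel(x$dosages[si, vi, drop = FALSE], x$variants[vi, ], x$sample_ids[si])
}

# Fill missing dosages with the per-variant mean; drop or fail on variants with
# zero variance after filling.
finalize_dosages <- function(dosages, variants, sample_ids, monomorphic = c("drop", "error")) {
  monomorphic <- match.arg(monomorphic)
  nmiss <- colSums(is.na(dosages))
  if (any(nmiss > 0)) {
    for (j in which(nmiss > 0)) {
      m <- mean(dosages[, j], na.rm = TRUE)
      dosages[is.na(dosages[, j]), j] <- m
    }
  }
  v <- matrixStats_colVars(dosages)
  mono <- v <= 0 | !is.finite(v)
  if (any(mono)) {
    if (monomorphic == "error") {
      abort(paste0(
        "monomorphic variant(s): ",
        paste(head(variants$id[mono], 5), collapse = ", ")
      ), class = "prsbridge_format_error")
    }
    inform(sprintf("Dropping %d monomorphic variant(s).", sum(mono)))
    dosages <- dosages[, !mono, drop = FALSE]
    variants <- variants[!mono, ]
  }
  geno_panel(dosages, variants, sample_ids)
}

# column variances with denominator n - 1, no dependency on matrixStats
matrixStats_colVars <- function(m) {
  n <- nrow(m)
  if (n < 2) return(rep(0, ncol(m)))
  mu <- colMeans(m)
  (colSums(m^2) - n * mu^2) / (n - 1)
}

#' Read a PLINK bed/bim/fam fileset
#'
#' Reads variant-major PLINK 1 binary genotypes (magic bytes `0x6c 0x1b 0x01`).
#' Dosages count copies of the bim A1 allele, which is taken as the effect
#' allele. Missing calls are filled with the variant's mean dosage.
#'
#' @param prefix Path prefix; `<prefix>.bed`, `.bim` and `.fam` must exist.
#' @param monomorphic Policy for zero-variance variants after mean filling:
#'   `"drop"` (default) or `"error"`.
#' @return A [geno_panel].
#' @export
read_plink <- function(prefix, monomorphic = c("drop", "error")) {
  bed <- paste0(prefix, ".bed")
  bim <- paste0(prefix, ".bim")
  fam <- paste0(prefix, ".fam")
  for (f in c(bed, bim, fam)) {
    if (!file.exists(f)) {
      abort(paste0("missing PLINK companion file: ", f), class = "prsbridge_format_error")
    }
  }
  bim_dt <- data.table::fread(bim, header = FALSE, data.table = FALSE)
  names(bim_dt) <- c("chrom", "id", "cm", "pos", "a1", "a2")
  fam_dt <- data.table::fread(fam, header = FALSE, data.table = FALSE)
  sample_ids <- as.character(fam_dt[[2]])
  n <- length(sample_ids)
  m <- nrow(bim_dt)

  raw <- readBin(bed, what = "raw", n = file.size(bed))
  if (length(raw) < 3 || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b) ||
    raw[3] != as.raw(0x01)) {
    abort("not a variant-major PLINK bed file", class = "prsbridge_format_error")
  }
  bytes_per_variant <- ceiling(n / 4)
  if (length(raw) - 3 != bytes_per_variant * m) {
    abort("bed payload size inconsistent with bim/fam dimensions",
      class = "prsbridge_format_error"
    )
  }
  # per-byte lookup: 4 two-bit genotypes, LSB first.
  # 00 -> 2 copies of A1, 10 -> 1, 11 -> 0, 01 -> missing
  code_map <- c(`0` = 2, `2` = 1, `3` = 0, `1` = NA_real_)
  byte_codes <- matrix(0L, nrow = 256, ncol = 4)
  for (b in 0:255) {
    byte_codes[b + 1, ] <- bitwAnd(bitwShiftR(b, c(0L, 2L, 4L, 6L)), 3L)
  }
  lookup <- matrix(code_map[as.character(byte_codes)], nrow = 256)

  payload <- as.integer(raw[-(1:3)])
  dim(payload) <- c(bytes_per_variant, m)
  dosages <- matrix(NA_real_, nrow = n, ncol = m)
  keep <- seq_len(n)
  for (j in seq_len(m)) {
    g <- lookup[payload[, j] + 1L, , drop = FALSE]
    dosages[, j] <- t(g)[keep]
  }
  variants <- tibble(
    id = as.character(bim_dt$id), chrom = as.character(bim_dt$chrom),
    pos = as.integer(bim_dt$pos),
    effect_allele = as.character(bim_dt$a1),
    other_allele = as.character(bim_dt$a2)
  )
  finalize_dosages(dosages, variants, sample_ids, monomorphic)
}

#' Write a genotype panel as a PLINK bed/bim/fam fileset
#'
#' Fractional dosages are rounded to the nearest integer genotype. The effect
#' allele is written as bim A1.
#'
#' @param panel A [geno_panel].
#' @param prefix Output path prefix.
#' @return `prefix`, invisibly.
#' @export
write_plink <- function(panel, prefix) {
  n <- length(panel$sample_ids)
  m <- nrow(panel$variants)
  bim <- data.frame(
    chrom = panel$variants$chrom, id = panel$variants$id, cm = 0,
    pos = panel$variants$pos, a1 = panel$variants$effect_allele,
    a2 = panel$variants$other_allele
  )
  readr::write_tsv(bim, paste0(prefix, ".bim"), col_names = FALSE)
  fam <- data.frame(
    fid = panel$sample_ids, iid = panel$sample_ids,
    pat = 0, mat = 0, sex = 0, pheno = -9
  )
  readr::write_tsv(fam, paste0(prefix, ".fam"), col_names = FALSE)

  # dosage -> 2-bit code: 2 copies A1 -> 00, 1 -> 10, 0 -> 11
  code_of <- c(`2` = 0L, `1` = 2L, `0` = 3L)
  bytes_per_variant <- ceiling(n / 4)
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  pad <- bytes_per_variant * 4 - n
  for (j in seq_len(m)) {
    g <- round(panel$dosages[, j])
    codes <- c(code_of[as.character(g)], rep(3L, pad))
    cm <- matrix(codes, nrow = 4)
    byte_vals <- cm[1, ] + cm[2, ] * 4L + cm[3, ] * 16L + cm[4, ] * 64L
    writeBin(as.raw(byte_vals), con)
  }
  invisible(prefix)
}

#' Read a plain-text dosage matrix
#'
#' The dosage file is tab-delimited with a header: first column `sample_id`,
#' remaining columns one per variant (named by variant id) holding effect-allele
#' dosages in \[0, 2\]. Variant metadata comes from a companion tab-delimited
#' file with columns `id`, `chrom`, `pos`, `effect_allele`, `other_allele`.
#'
#' @param path Dosage matrix file.
#' @param variants_path Variant metadata file.
#' @param monomorphic Policy for zero-variance variants, as in [read_plink()].
#' @return A [geno_panel].
#' @export
read_dosage <- function(path, variants_path, monomorphic = c("drop", "error")) {
  dt <- data.table::fread(path, header = TRUE, data.table = FALSE)
  variants <- as_tibble(data.table::fread(variants_path, header = TRUE, data.table = FALSE))
  variants$chrom <- as.character(variants$chrom)
  variants$pos <- as.integer(variants$pos)
  sample_ids <- as.character(dt[[1]])
  mat <- as.matrix(dt[, -1, drop = FALSE])
  if (!setequal(colnames(mat), variants$id) || ncol(mat) != nrow(variants)) {
    abort("dosage columns do not match variant metadata", class = "prsbridge_format_error")
  }
  mat <- mat[, variants$id, drop = FALSE]
  finalize_dosages(mat, variants, sample_ids, monomorphic)
}

#' Write a dosage matrix and companion variant table
#'
#' @param panel A [geno_panel].
#' @param path,variants_path Output files (see [read_dosage()]).
#' @return `path`, invisibly.
#' @export
write_dosage <- function(panel, path, variants_path) {
  df <- data.frame(sample_id = panel$sample_ids, panel$dosages, check.names = FALSE)
  readr::write_tsv(df, path)
  readr::write_tsv(panel$variants, variants_path)
  invisible(path)
}

#' Read a phenotype / covariate table
#'
#' Tab- or whitespace-delimited with header; must contain `sample_id` and the
#' trait column, all other columns are treated as covariates.
#'
#' @param path File path.
#' @param trait Name of the trait column (default `"trait"`).
#' @return A tibble with columns `sample_id`, `trait`, then covariates.
#' @export
read_phenotypes <- function(path, trait = "trait") {
  dt <- as_tibble(data.table::fread(path, header = TRUE, data.table = FALSE))
  if (!"sample_id" %in% names(dt) || !trait %in% names(dt)) {
    abort(sprintf("phenotype file must contain 'sample_id' and '%s' columns", trait),
      class = "prsbridge_format_error"
    )
  }
  names(dt)[names(dt) == trait] <- "trait"
  dt$sample_id <- as.character(dt$sample_id)
  if (anyDuplicated(dt$sample_id)) {
    abort("duplicate sample_id in phenotype table", class = "prsbridge_format_error")
  }
  if (anyNA(dt$trait)) {
    abort("missing trait values in phenotype table", class = "prsbridge_format_error")
  }
  dplyr::relocate(dt, "sample_id", "trait")
}
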