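#' Assemble and validate a pipeline run configuration
#'
#' A run configuration is a plain named list (readable from a YAML file via
#' [read_run_config()]) with the grids, clumping parameters, seeds and either
#' a `sim` block (simulator parameters, see [sim_config()]) or an `inputs`
#' block of file paths (`sumstats1`, `sumstats2`, `panel1`, `panel2`,
#' `test_geno1`, `test_pheno1`, `test_geno2`, `test_pheno2`, optionally
#' `valid_geno2`, `valid_pheno2`; genotype paths are PLINK prefixes).
#'
#' `validate_config()` returns a tibble of diagnostics (empty when the
#' configuration is valid) rather than erroring, so a caller can report all
#' problems at once.
#'
#' @param cfg A named list.
#' @return `run_config()`: the completed configuration.
#'   `validate_config()`: a tibble with columns `field` and `message`.
#' @export
run_config <- function(cfg = list()) {
  defaults <- list(
    alpha_grid = default_alpha_grid(),
    lambda0_grid = default_lambda0_grid(),
    tau_grid = default_tau_grid(),
    k_grid = default_k_grid(),
    ranking = "fstat",
    p1 = 0.01, p2 = 0.01, kb = 1000, r2 = 0.01, jitter = 0,
    n_boot = 200, seed = 1,
    out_dir = "prsbridge_out",
    write_genotypes = FALSE
  )
  out <- modifyList(defaults, cfg)
  if (is.null(out$sim) && is.null(out$inputs)) out$sim <- list()
  structure(out, class = "run_config")
}

#' @rdname run_config
#' @export
validate_config <- function(cfg) {
  cfg <- run_config(unclass(cfg))
  diag <- list()
  note <- function(field, message) {
    diag[[length(diag) + 1]] <<- tibble(field = field, message = message)
  }
  if (length(cfg$alpha_grid) == 0) note("alpha_grid", "empty grid")
  if (any(cfg$alpha_grid < 0 | cfg$alpha_grid > 1)) {
    note("alpha_grid", "alpha values must lie in [0, 1]")
  }
  if (length(cfg$lambda0_grid) == 0) note("lambda0_grid", "empty grid")
  if (any(cfg$lambda0_grid <= 0)) note("lambda0_grid", "lambda0 values must be positive")
  if (length(cfg$tau_grid) == 0) note("tau_grid", "empty grid")
  if (any(cfg$tau_grid <= 0)) note("tau_grid", "tau values must be positive")
  if (length(cfg$k_grid) == 0) note("k_grid", "empty grid")
  if (!cfg$ranking %in% c("fstat", "pval")) {
    note("ranking", "must be 'fstat' or 'pval'")
  }
  if (cfg$n_boot < 1) note("n_boot", "must be at least 1")
  if (!is.null(cfg$sim)) {
    ok <- tryCatch(
      {
        do.call(sim_config, cfg$sim)
        TRUE
      },
      error = function(e) conditionMessage(e)
    )
    if (!isTRUE(ok)) note("sim", ok)
  }
  if (!is.null(cfg$inputs)) {
    needed <- c(
      "sumstats1", "sumstats2", "panel1", "panel2",
      "test_geno1", "test_pheno1", "test_geno2", "test_pheno2"
    )
    for (field in needed) {
      path <- cfg$inputs[[field]]
      if (is.null(path)) {
        note(paste0("inputs.", field), "missing path")
      } else {
        probe <- if (grepl("geno|panel", field)) paste0(path, ".bed") else path
        if (!file.exists(probe)) note(paste0("inputs.", field), paste0("file not found: ", probe))
      }
    }
  }
  if (length(diag) == 0) {
    tibble(field = character(), message = character())
  } else {
    dplyr::bind_rows(diag)
  }
}

#' Read a run configuration from a YAML file
#'
#' @param path YAML file with the fields of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

#' Run the full pipeline from a configuration
#'
#' Executes simulate (or load) -> stage 1 -> stage 2 -> combine -> evaluate in
#' dependency order, writing summary statistics, score files, the per-SNP
#' weight file, model weights and an evaluation table into `cfg$out_dir`,
#' together with a `manifest.tsv` recording an MD5 content hash per artifact.
#' Reruns with an identical configuration are bit-identical.
#'
#' @param cfg A [run_config()] (or plain list).
#' @return The manifest tibble, invisibly.
#' @export
run_all <- function(cfg = run_config()) {
  cfg <- run_config(unclass(cfg))
  diagnostics <- validate_config(cfg)
  if (nrow(diagnostics) > 0) {
    abort(paste0(
      "invalid configuration:\n",
      paste(sprintf("  %s: %s", diagnostics$field, diagnostics$message), collapse = "\n")
    ), class = "prsbridge_config_error")
  }
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  artifacts <- character()
  put <- function(obj, name, writer) {
    path <- file.path(cfg$out_dir, name)
    writer(obj, path)
    artifacts <<- c(artifacts, path)
    path
  }

  if (!is.null(cfg$sim)) {
    sim_args <- modifyList(list(seed = cfg$seed), as.list(cfg$sim))
    world <- simulate_world(do.call(sim_config, sim_args))
    sumstats1 <- world$sumstats1
    sumstats2 <- world$sumstats2
    panel1 <- world$pop1$test
    panel2 <- world$pop2$test
    test_geno1 <- world$pop1$test
    test_pheno1 <- world$pop1$pheno
    test_geno2 <- world$pop2$test
    test_pheno2 <- world$pop2$pheno
    valid_geno2 <- world$pop2$valid
    valid_pheno2 <- world$pop2$pheno
    put(sumstats1, "sumstats_pop1.tsv", write_sumstats)
    put(sumstats2, "sumstats_pop2.tsv", write_sumstats)
    if (isTRUE(cfg$write_genotypes)) {
      panels <- list(
        pop1_train = world$pop1$train, pop1_test = world$pop1$test,
        pop2_train = world$pop2$train, pop2_test = world$pop2$test,
        pop2_valid = world$pop2$valid
      )
      for (nm in names(panels)) {
        prefix <- file.path(cfg$out_dir, nm)
        write_plink(panels[[nm]], prefix)
        artifacts <- c(artifacts, paste0(prefix, c(".bed", ".bim", ".fam")))
      }
      put(world$pop1$pheno, "pheno_pop1.tsv", function(x, p) readr::write_tsv(x, p))
      put(world$pop2$pheno, "pheno_pop2.tsv", function(x, p) readr::write_tsv(x, p))
    }
  } else {
    inp <- cfg$inputs
    sumstats1 <- read_sumstats(inp$sumstats1, cfg$column_map)
    sumstats2 <- read_sumstats(inp$sumstats2, cfg$column_map)
    panel1 <- read_plink(inp$panel1)
    panel2 <- read_plink(inp$panel2)
    test_geno1 <- read_plink(inp$test_geno1)
    test_pheno1 <- read_phenotypes(inp$test_pheno1)
    test_geno2 <- read_plink(inp$test_geno2)
    test_pheno2 <- read_phenotypes(inp$test_pheno2)
    valid_geno2 <- if (!is.null(inp$valid_geno2)) read_plink(inp$valid_geno2)
    valid_pheno2 <- if (!is.null(inp$valid_pheno2)) read_phenotypes(inp$valid_pheno2) else test_pheno2
  }

  fit <- prs_bridge(
    sumstats1, panel1, test_geno1, test_pheno1,
    sumstats2, panel2, test_geno2, test_pheno2,
    alpha_grid = cfg$alpha_grid, lambda0_grid = cfg$lambda0_grid,
    tau_grid = cfg$tau_grid, k_grid = cfg$k_grid,
    ranking = cfg$ranking,
    p1 = cfg$p1, p2 = cfg$p2, kb = cfg$kb, r2 = cfg$r2, jitter = cfg$jitter
  )

  put(fit$snp_weights, "snp_weights.tsv", write_snp_weights)
  put(tidy(fit$models), "model_weights.tsv", function(x, p) readr::write_tsv(x, p))
  put(fit$stage1$loci, "loci_pop1.tsv", write_loci)
  put(fit$target_only$loci, "loci_pop2.tsv", write_loci)

  if (!is.null(valid_geno2)) {
    scores <- predict(fit, valid_geno2)
    put(scores, "validation_scores.tsv", function(x, p) readr::write_tsv(x, p))
    eval_rows <- dplyr::bind_rows(
      dplyr::mutate(
        bootstrap_r2(valid_pheno2, scores[c("sample_id", "prs")],
          n_boot = cfg$n_boot, seed = cfg$seed
        ),
        model = "weighted"
      ),
      dplyr::mutate(
        bootstrap_r2(
          valid_pheno2,
          dplyr::rename(scores[c("sample_id", "M2")], prs = "M2"),
          n_boot = cfg$n_boot, seed = cfg$seed
        ),
        model = "target_only"
      )
    )
    put(eval_rows, "evaluation.tsv", function(x, p) readr::write_tsv(x, p))
  }

  manifest <- tibble(
    file = basename(artifacts),
    md5 = unname(vapply(artifacts, digest::digest, character(1), file = TRUE, algo = "md5"))
  )
  readr::write_tsv(manifest, file.path(cfg$out_dir, "manifest.tsv"))
  invisible(manifest)
}
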