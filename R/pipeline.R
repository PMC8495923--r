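#' Validate a run configuration
#'
#' A run configuration is a plain named list. Required: `geno`,
#' `pheno`, `trait`, `out_dir`. Optional: `map`, `covariates`,
#' `dialect` (`"tsv"`/`"plink_raw"`), `scaling`
#' (`"vanraden"`/`"raw"`), `additive_methods` (subset of `p3d`,
#' `gblup`, `exact`), `epistasis_methods` (subset of `qk`, `q2k`,
#' `remma`, `aux`), `prune` (list `r2`, `window_kb`, `step_kb`),
#' `seed`.
#'
#' @param config Named list.
#' @return The config, with defaults filled in.
#' @export
validate_run_config <- function(config) {
  need <- c("geno", "pheno", "trait", "out_dir")
  miss <- setdiff(need, names(config))
  if (length(miss) > 0L)
    stop("run config is missing: ", paste(miss, collapse = ", "))
  for (f in intersect(c("geno", "pheno", "map"), names(config)))
    if (!is.null(config[[f]]) && !file.exists(config[[f]]))
      stop("config path does not exist (--", f, "): ", config[[f]])
  defaults <- list(map = NULL, covariates = character(), dialect = "tsv",
                   scaling = "vanraden", additive_methods = c("p3d", "gblup"),
                   epistasis_methods = character(), prune = NULL, seed = 1L)
  for (nm in names(defaults))
    if (is.null(config[[nm]])) config[[nm]] <- defaults[[nm]]
  config
}

#' End-to-end GWAS run
#'
#' Reads genotypes and phenotypes, optionally LD-prunes, builds the
#' genomic relationship matrices, fits the null model(s) once (P3D) and
#' runs the requested additive and/or epistatic scans, writing one
#' results TSV per method plus the fitted variance components into
#' `out_dir`.
#'
#' @param config A run configuration (see [validate_run_config()]).
#' @return Invisibly, a list with the fitted objects and scan tibbles.
#' @export
run_gwas <- function(config) {
  config <- validate_run_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  gm <- read_genotype_matrix(config$geno, dialect = config$dialect,
                             map = config$map)
  gm <- impute_and_code(gm)
  if (!is.null(config$prune)) {
    keep <- ld_prune(gm, r2_threshold = config$prune$r2,
                     window = config$prune$window_kb * 1000,
                     step = config$prune$step_kb * 1000)
    gm$codings <- gm$codings[, keep, drop = FALSE]
    if (!is.null(gm$map))
      gm$map <- gm$map[gm$map$marker %in% keep, , drop = FALSE]
  }
  ph <- read_phenotype_table(config$pheno, trait = config$trait,
                             covariates = config$covariates, genotypes = gm)
  gm$codings <- gm$codings[ph$samples, , drop = FALSE]
  ks <- build_additive_grm(gm, scaling = config$scaling)
  results <- list()
  log <- character()
  two_kernel_methods <- intersect(config$epistasis_methods,
                                  c("q2k", "remma", "aux"))
  if (length(c(two_kernel_methods)) > 0L)
    ks <- build_epistatic_grm(ks)
  if (length(config$additive_methods) > 0L ||
      "qk" %in% config$epistasis_methods) {
    vc1 <- suppressWarnings(reml_one_kernel(ph, ks$G))
    write_variance_components(vc1, file.path(config$out_dir, "vc_one_kernel.tsv"))
    log <- c(log, sprintf("one-kernel REML: logLik = %.4f, lambda = %.6g",
                          vc1$restricted_loglik, vc1$lambda))
    op1 <- projection_operator(ph, ks, vc1, force = TRUE)
    for (mth in config$additive_methods) {
      res <- switch(mth,
        p3d = scan_additive_p3d(ph, ks, op1, vc1),
        gblup = scan_additive_gblup(ph, ks, op1, vc1),
        exact = scan_additive_exact(ph, ks),
        stop("unknown additive method: ", mth))
      fn <- file.path(config$out_dir, paste0("additive_", mth, ".tsv"))
      write_scan_results(res, fn)
      results[[paste0("additive_", mth)]] <- res
    }
    if ("qk" %in% config$epistasis_methods) {
      res <- scan_epistasis_qk(ph, ks, NULL, op1, vc1)
      write_scan_results(res, file.path(config$out_dir, "epistasis_qk.tsv"))
      results$epistasis_qk <- res
    }
  }
  if (length(two_kernel_methods) > 0L) {
    vc2 <- suppressWarnings(reml_two_kernel(ph, ks$G, ks$H))
    write_variance_components(vc2, file.path(config$out_dir, "vc_two_kernel.tsv"))
    log <- c(log, sprintf(
      "two-kernel REML: logLik = %.4f, ratio = %.4g, h2 = %.4f",
      vc2$restricted_loglik, vc2$ratio, vc2$h2))
    op2 <- projection_operator(ph, ks, vc2, force = TRUE)
    for (mth in two_kernel_methods) {
      res <- switch(mth,
        q2k = scan_epistasis_q2k(ph, ks, NULL, op2, vc2),
        remma = scan_epistasis_remma(ph, ks, NULL, op2, vc2),
        aux = scan_epistasis_auxiliary(ph, ks, NULL, op2, vc2))
      fn <- file.path(config$out_dir, paste0("epistasis_", mth, ".tsv"))
      write_scan_results(res, fn)
      results[[paste0("epistasis_", mth)]] <- res
    }
  }
  writeLines(log, file.path(config$out_dir, "run_log.txt"))
  invisible(c(results, list(log = log, out_dir = config$out_dir)))
}

# rebuild a two-kernel variance_components object from stored estimates
.vc_from_estimates <- function(sA2, sAA2, se2, n, k = 1L) {
  new_variance_components(
    "two_kernel", sigma_A2 = sA2, sigma_AA2 = sAA2, sigma_e2 = se2,
    ratio = sA2 / sAA2, restricted_loglik = NA_real_, converged = TRUE,
    h2 = (sA2 + sAA2) / (sA2 + sAA2 + se2), n = n, k = k)
}

#' Run the full simulation comparison study
#'
#' Generates accepted datasets with [run_accept_reject()], performs the
#' three pairwise epistasis scans (extended Q+K, Q+2K, REMMA) on every
#' dataset under the P3D approximation (two-kernel components reused
#' from the acceptance fit; one-kernel components refitted once per
#' dataset), computes threshold-filtered correlations of `-log10(p)`
#' between REMMA and Q+2K and between Q+K and Q+2K, and summarises the
#' trend of those correlations against `log2(est_ratio)` per
#' heritability class.
#'
#' @param cfg A [simulation_config()].
#' @param d_grid Thresholds on `-log10(p)` for the filtered
#'   correlations.
#' @param min_pairs Minimum retained pairs for a non-NA correlation.
#' @param out_dir Optional output directory; when given, per-dataset
#'   TSVs and the records/trend summaries are written.
#' @param progress Print progress messages?
#' @return A list of class `sim_study_result`: `study` (the
#'   `sim_study`), `records` (per dataset x method pair x d:
#'   `dataset`, `true_ratio`, `true_h2`, `est_log2_ratio`, `est_h2`,
#'   `h2_class`, `method_pair`, `d`, `r`, `n_pairs_used`) and `trend`
#'   (per h2 class x method pair x d).
#' @export
run_simulation_study <- function(cfg, d_grid = c(1, 2, 3, 4), min_pairs = 10,
                                 out_dir = NULL, progress = FALSE) {
  study <- run_accept_reject(cfg, progress = progress)
  ks <- study$kinship
  ds <- study$datasets
  n <- cfg$n
  rec <- vector("list", nrow(ds))
  for (i in seq_len(nrow(ds))) {
    y <- ds$y[[i]]
    ph <- phenotype_table(y)
    vc2 <- .vc_from_estimates(ds$est_sigma_A2[i], ds$est_sigma_AA2[i],
                              ds$est_sigma_e2[i], n)
    op2 <- projection_operator(ph, ks, vc2, force = TRUE)
    vc1 <- suppressWarnings(reml_one_kernel(ph, ks$G))
    op1 <- projection_operator(ph, ks, vc1, force = TRUE)
    sc_qk <- scan_epistasis_qk(ph, ks, NULL, op1, vc1)
    sc_q2k <- scan_epistasis_q2k(ph, ks, NULL, op2, vc2)
    sc_remma <- scan_epistasis_remma(ph, ks, NULL, op2, vc2)
    cors <- dplyr::bind_rows(lapply(d_grid, function(d) dplyr::bind_rows(
      filtered_correlation(sc_remma, sc_q2k, d, min_pairs = min_pairs),
      filtered_correlation(sc_qk, sc_q2k, d, min_pairs = min_pairs))))
    cors$dataset <- ds$dataset[i]
    cors$true_ratio <- ds$true_ratio[i]
    cors$true_h2 <- ds$true_h2[i]
    cors$est_log2_ratio <- log2(ds$est_ratio[i])
    cors$est_h2 <- ds$est_h2[i]
    rec[[i]] <- cors
    if (progress)
      message(sprintf("dataset %d/%d scanned", i, nrow(ds)))
  }
  records <- dplyr::bind_rows(rec)
  records$h2_class <- classify_by_h2(records$est_h2)
  trend <- records |>
    dplyr::group_by(.data$method_pair, .data$d) |>
    dplyr::group_modify(function(gdf, key) {
      per_class <- dplyr::bind_rows(lapply(
        intersect(c("low", "mid", "high"), unique(as.character(gdf$h2_class))),
        function(cl) trend_analysis(gdf, h2_class = cl)))
      dplyr::bind_rows(per_class, trend_analysis(gdf))
    }) |>
    dplyr::ungroup()
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_genotype_matrix(study$genotypes,
                          file.path(out_dir, "genotypes.tsv"),
                          file.path(out_dir, "map.tsv"))
    meta <- ds[, setdiff(names(ds), "y")]
    readr::write_tsv(meta, file.path(out_dir, "datasets.tsv"))
    for (i in seq_len(nrow(ds))) {
      dd <- file.path(out_dir, sprintf("dataset_%03d", ds$dataset[i]))
      dir.create(dd, showWarnings = FALSE)
      readr::write_tsv(tibble::tibble(sample = rownames(study$genotypes$codings),
                                      y = ds$y[[i]]),
                       file.path(dd, "phenotype.tsv"))
    }
    readr::write_tsv(records, file.path(out_dir, "records.tsv"))
    readr::write_tsv(trend, file.path(out_dir, "trend.tsv"))
  }
  structure(list(study = study, records = records, trend = trend),
            class = "sim_study_result")
}

#' @export
print.sim_study_result <- function(x, ...) {
  cat(sprintf("<sim_study_result> %d datasets, %d comparison records\n",
              nrow(x$study$datasets), nrow(x$records)))
  print(x$trend, n = 20)
  invisible(x)
}
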