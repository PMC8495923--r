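#' Simulation configuration
#'
#' Defaults reproduce the design of the package's reference simulation
#' study: seven additive:epistatic variance ratios by nine broad-sense
#' heritabilities (63 cells), five accepted replicates per cell (315
#' datasets), with accept-reject filtering of the realised variance
#' components. The genotype panel is simulated once per study (an
#' inbred-style {0, 2} panel with first-order LD along the map) and
#' shared by all phenotype draws, mirroring how a real diversity panel
#' would be reused.
#'
#' @param n Samples per dataset.
#' @param p Markers.
#' @param ratio_grid Grid of `sigma_A2 / sigma_AA2` ratios.
#' @param h2_grid Grid of broad-sense heritabilities
#'   `(sigma_A2 + sigma_AA2) / (sigma_A2 + sigma_AA2 + sigma_e2)`.
#' @param reps_per_cell Accepted replicates required per grid cell.
#' @param ratio_tol Acceptance half-width on `log2(ratio)`.
#' @param h2_tol Acceptance half-width on `h2`.
#' @param seed Integer seed; all study randomness derives from it.
#' @param maf_range Allele-frequency interval for simulated markers.
#' @param ld_rho First-order autocorrelation of the latent process
#'   generating adjacent-marker LD (0 = linkage equilibrium).
#' @param spacing_bp Map spacing between adjacent markers.
#' @param max_attempts Hard cap on phenotype draws per grid cell.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n = 383, p = 1732,
                              ratio_grid = c(0.25, 0.5, 1, 2, 4, 8, 16),
                              h2_grid = seq(0.1, 0.9, by = 0.1),
                              reps_per_cell = 5, ratio_tol = 0.5,
                              h2_tol = 0.05, seed = 1,
                              maf_range = c(0.05, 0.5), ld_rho = 0.5,
                              spacing_bp = 10000, max_attempts = 200) {
  stopifnot(all(ratio_grid > 0), all(h2_grid > 0 & h2_grid < 1),
            reps_per_cell >= 1, ratio_tol > 0, h2_tol > 0,
            length(maf_range) == 2, maf_range[1] <= maf_range[2],
            ld_rho >= 0, ld_rho < 1)
  structure(list(n = n, p = p, ratio_grid = ratio_grid, h2_grid = h2_grid,
                 reps_per_cell = reps_per_cell, ratio_tol = ratio_tol,
                 h2_tol = h2_tol, seed = as.integer(seed),
                 maf_range = maf_range, ld_rho = ld_rho,
                 spacing_bp = spacing_bp, max_attempts = max_attempts),
            class = "simulation_config")
}

#' Design counts of a simulation study
#'
#' @param cfg A [simulation_config()].
#' @return One-row tibble: `grid_cells`, `reps_per_cell`,
#'   `datasets_retained` (= cells x reps, by construction of the
#'   accept-reject loop).
#' @export
study_design_counts <- function(cfg) {
  cells <- length(cfg$ratio_grid) * length(cfg$h2_grid)
  tibble::tibble(grid_cells = cells, reps_per_cell = cfg$reps_per_cell,
                 datasets_retained = cells * cfg$reps_per_cell)
}

#' Simulate an inbred-style genotype panel
#'
#' Allele frequencies are drawn uniformly from `maf_range`; {0, 2}
#' dosages are thresholded from a per-sample latent Gaussian process
#' with first-order autocorrelation `ld_rho` along the map, giving
#' adjacent-marker LD. The map places markers every `spacing_bp` base
#' pairs on one chromosome. Deterministic given the seed.
#'
#' @param cfg A [simulation_config()].
#' @param seed Seed (defaults to `cfg$seed`).
#' @return A [genotype_matrix()] (complete, no missing values).
#' @export
simulate_genotypes <- function(cfg, seed = cfg$seed) {
  set.seed(seed)
  n <- cfg$n; p <- cfg$p
  freqs <- stats::runif(p, cfg$maf_range[1], cfg$maf_range[2])
  Z <- matrix(0, n, p)
  Z[, 1L] <- stats::rnorm(n)
  if (p > 1L) {
    rho <- cfg$ld_rho
    for (j in 2L:p)
      Z[, j] <- rho * Z[, j - 1L] + sqrt(1 - rho^2) * stats::rnorm(n)
  }
  thr <- stats::qnorm(freqs)
  M <- 2 * (Z <= rep(thr, each = n))
  storage.mode(M) <- "double"
  dimnames(M) <- list(paste0("S", seq_len(n)), paste0("M", seq_len(p)))
  map <- tibble::tibble(marker = colnames(M), chrom = "1",
                        pos = 1L + (seq_len(p) - 1L) * as.integer(cfg$spacing_bp))
  genotype_matrix(M, map = map, imputed = TRUE)
}

# symmetric square root with clamped spectrum, for MVN sampling from a
# (possibly rank-deficient) kernel
.mvn_factor <- function(K) {
  eg <- eigen((K + t(K)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  eg$vectors %*% (t(eg$vectors) * sqrt(d))
}

.variance_split <- function(ratio, h2) {
  list(sigma_A2 = h2 * ratio / (1 + ratio),
       sigma_AA2 = h2 / (1 + ratio),
       sigma_e2 = 1 - h2)
}

#' Simulate a phenotype from additive and epistatic kernels
#'
#' Draws `y = g_A + g_AA + e` with `g_A ~ N(0, G sigma_A2)`,
#' `g_AA ~ N(0, H sigma_AA2)`, `e ~ N(0, I sigma_e2)`, where
#' `sigma_A2 = h2 * ratio/(1+ratio)`, `sigma_AA2 = h2/(1+ratio)`,
#' `sigma_e2 = 1 - h2`. No per-locus QTL effects are simulated. `G` and
#' `H` should be standardised to mean diagonal one
#' ([standardize_kernel()]) so `h2` is on the intended scale.
#'
#' @param G,H Standardised kernels.
#' @param ratio `sigma_A2 / sigma_AA2`.
#' @param h2 Broad-sense heritability in (0, 1).
#' @param seed Integer seed.
#' @return Numeric phenotype vector of length `nrow(G)`.
#' @export
simulate_phenotype <- function(G, H, ratio, h2, seed) {
  if (!(h2 > 0 && h2 < 1)) stop("h2 must lie strictly in (0, 1)")
  stopifnot(ratio > 0, nrow(G) == nrow(H))
  vs <- .variance_split(ratio, h2)
  .sim_y(.mvn_factor(G), .mvn_factor(H), vs$sigma_A2, vs$sigma_AA2,
         vs$sigma_e2, seed)
}

.sim_y <- function(FG, FH, sA2, sAA2, se2, seed) {
  set.seed(seed)
  n <- nrow(FG)
  gA <- sqrt(sA2) * drop(FG %*% stats::rnorm(n))
  gAA <- sqrt(sAA2) * drop(FH %*% stats::rnorm(n))
  e <- sqrt(se2) * stats::rnorm(n)
  gA + gAA + e
}

#' Accept-reject simulation of a full study
#'
#' Simulates the genotype panel once, builds VanRaden `G` and the
#' epistatic `H`, standardises both, and then for each grid cell draws
#' phenotypes until `reps_per_cell` datasets pass the acceptance
#' criterion: the two-kernel REML estimates must satisfy
#' `|log2(est_ratio) - log2(true_ratio)| <= ratio_tol` and
#' `|est_h2 - true_h2| <= h2_tol`. Exceeding `max_attempts` draws in a
#' cell is an error naming the cell.
#'
#' @param cfg A [simulation_config()].
#' @param genotypes Optional pre-simulated [genotype_matrix()] (the
#'   panel the study reuses).
#' @param progress Print per-cell progress?
#' @return A `sim_study` list: `config`, `genotypes`, `kinship`
#'   (standardised kernels), and `datasets`, a tibble with one row per
#'   accepted dataset (`dataset`, `true_ratio`, `true_h2`, `rep`,
#'   `seed_used`, `attempt`, `est_sigma_A2`, `est_sigma_AA2`,
#'   `est_sigma_e2`, `est_ratio`, `est_h2`, `accepted`, and the
#'   phenotype in list-column `y`).
#' @export
run_accept_reject <- function(cfg, genotypes = NULL, progress = FALSE) {
  stopifnot(inherits(cfg, "simulation_config"))
  gm <- if (is.null(genotypes)) simulate_genotypes(cfg) else genotypes
  ks <- build_epistatic_grm(build_additive_grm(gm, scaling = "vanraden"))
  Gs <- standardize_kernel(ks$G)
  Hs <- standardize_kernel(ks$H)
  ks$G <- Gs; ks$H <- Hs
  ks$coding_note <- paste0(ks$coding_note, "; kernels standardised to mean diagonal 1")
  FG <- .mvn_factor(Gs); FH <- .mvn_factor(Hs)
  n <- cfg$n
  X <- matrix(1, n, 1)
  U2 <- .complement_basis(X)
  Atil <- crossprod(U2, Gs %*% U2); Atil <- (Atil + t(Atil)) / 2
  Htil <- crossprod(U2, Hs %*% U2); Htil <- (Htil + t(Htil)) / 2
  egM <- eigen((Atil + Htil) / 2, symmetric = TRUE)
  dM <- pmax(egM$values, 0)
  m <- n - 1L
  grid <- tidyr::expand_grid(true_ratio = cfg$ratio_grid,
                             true_h2 = cfg$h2_grid)
  counter <- 0L
  rows <- vector("list", nrow(grid) * cfg$reps_per_cell)
  ri <- 0L
  for (ci in seq_len(nrow(grid))) {
    r <- grid$true_ratio[ci]; h <- grid$true_h2[ci]
    vs <- .variance_split(r, h)
    accepted <- 0L
    attempts <- 0L
    while (accepted < cfg$reps_per_cell) {
      if (attempts >= cfg$max_attempts)
        stop(sprintf(
          "accept-reject cap (%d) exceeded for cell ratio = %g, h2 = %g",
          cfg$max_attempts, r, h))
      attempts <- attempts + 1L
      counter <- counter + 1L
      seed_used <- (abs(cfg$seed) %% 20011L) * 100003L + counter
      y <- .sim_y(FG, FH, vs$sigma_A2, vs$sigma_AA2, vs$sigma_e2, seed_used)
      yproj <- drop(crossprod(U2, y))
      ytil <- drop(crossprod(egM$vectors, yproj))
      prof <- function(ll) {
        wv <- 1 + exp(ll) * dM
        -0.5 * (sum(log(wv)) + m * log(sum(ytil^2 / wv) / m))
      }
      lam0 <- max(exp(stats::optimize(prof, c(-8, 8), maximum = TRUE,
                                      tol = 1e-4)$maximum), 1e-3)
      fit <- tryCatch(
        .fit_two_kernel_proj(Atil, Htil, yproj, m, lam0, reltol = 1e-8),
        error = function(e) NULL)
      if (is.null(fit)) next
      sA <- fit$a * fit$s2e; sAA <- fit$b * fit$s2e
      est_ratio <- sA / sAA
      est_h2 <- (sA + sAA) / (sA + sAA + fit$s2e)
      ok <- is.finite(est_ratio) && est_ratio > 0 &&
        abs(log2(est_ratio) - log2(r)) <= cfg$ratio_tol &&
        abs(est_h2 - h) <= cfg$h2_tol
      if (ok) {
        accepted <- accepted + 1L
        ri <- ri + 1L
        rows[[ri]] <- tibble::tibble(
          dataset = ri, true_ratio = r, true_h2 = h, rep = accepted,
          seed_used = seed_used, attempt = attempts,
          est_sigma_A2 = sA, est_sigma_AA2 = sAA, est_sigma_e2 = fit$s2e,
          est_ratio = est_ratio, est_h2 = est_h2, accepted = TRUE,
          y = list(y))
      }
    }
    if (progress)
      message(sprintf("cell ratio = %g, h2 = %g: %d/%d accepted in %d draws",
                      r, h, accepted, cfg$reps_per_cell, attempts))
  }
  structure(list(config = cfg, genotypes = gm, kinship = ks,
                 datasets = dplyr::bind_rows(rows[seq_len(ri)])),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf("<sim_study> %d accepted datasets over %d grid cells (n = %d, p = %d)\n",
              nrow(x$datasets),
              length(x$config$ratio_grid) * length(x$config$h2_grid),
              x$config$n, x$config$p))
  invisible(x)
}

#' Write a genotype matrix to TSV
#'
#' Inverse of [read_genotype_matrix()] (tsv dialect): header of marker
#' IDs, first column `sample`.
#'
#' @param gm A [genotype_matrix()].
#' @param path Output path.
#' @param map_path Optional path for the marker map TSV.
#' @export
write_genotype_matrix <- function(gm, path, map_path = NULL) {
  df <- tibble::as_tibble(gm$codings, rownames = "sample")
  readr::write_tsv(df, path)
  if (!is.null(map_path) && !is.null(gm$map))
    readr::write_tsv(gm$map, map_path)
  invisible(path)
}
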