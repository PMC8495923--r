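# shared fixtures and independent oracles

# random dosage panel with marker map
rand_gm <- function(n, p, seed, maf = c(0.1, 0.5), inbred = FALSE) {
  set.seed(seed)
  f <- runif(p, maf[1], maf[2])
  M <- if (inbred) {
    sapply(f, function(fj) 2 * rbinom(n, 1, fj))
  } else {
    sapply(f, function(fj) rbinom(n, 2, fj))
  }
  dimnames(M) <- list(paste0("S", seq_len(n)), paste0("M", seq_len(p)))
  map <- tibble::tibble(marker = colnames(M), chrom = "1",
                        pos = 1L + (seq_len(p) - 1L) * 1000L)
  genotype_matrix(M, map = map, imputed = TRUE)
}

# full random instance: genotypes, kernels, phenotype with covariates
rand_instance <- function(n, p, k, seed, scaling = "vanraden",
                          h_coding = "raw") {
  gm <- rand_gm(n, p, seed)
  ks <- build_epistatic_grm(build_additive_grm(gm, scaling),
                            coding = h_coding)
  set.seed(seed + 1000L)
  X <- matrix(1, n, 1)
  if (k > 1) X <- cbind(X, matrix(rnorm(n * (k - 1L)), n))
  colnames(X) <- c("(Intercept)", if (k > 1) paste0("C", seq_len(k - 1L)))
  u <- rnorm(n)
  y <- drop(standardize_kernel(ks$G) %*% u) * 0.8 + rnorm(n) +
    drop(X %*% rnorm(k))
  list(gm = gm, ks = ks, ph = phenotype_table(y, X), X = X, y = y)
}

# brute-force GLS oracle: explicit inverses, written independently of the
# package's T-matrix algebra
oracle_gls <- function(y, Xfull, Sigma, test_cols) {
  Si <- solve(Sigma)
  A <- t(Xfull) %*% Si %*% Xfull
  bhat <- solve(A, t(Xfull) %*% Si %*% y)
  covb <- solve(A)
  gt <- bhat[test_cols]
  Vt <- covb[test_cols, test_cols, drop = FALSE]
  wald <- drop(t(gt) %*% solve(Vt) %*% gt)
  list(est = drop(bhat), cov = covb, wald = wald,
       z = drop(gt) / sqrt(diag(Vt)))
}

# one-kernel null fit + operator for an instance
fit_one_kernel <- function(inst) {
  vc <- suppressWarnings(reml_one_kernel(inst$ph, inst$ks$G))
  op <- projection_operator(inst$ph, inst$ks, vc, force = TRUE)
  list(vc = vc, op = op)
}

fit_two_kernel <- function(inst, reltol = 1e-8) {
  vc <- suppressWarnings(reml_two_kernel(inst$ph, inst$ks$G, inst$ks$H,
                                         reltol = reltol))
  op <- projection_operator(inst$ph, inst$ks, vc, force = TRUE)
  list(vc = vc, op = op)
}

# frozen (P3D-style) components for small-instance oracle checks, where a
# REML fit could legitimately sit on the boundary
frozen_one_kernel <- function(inst, lambda = 1.5, sigma_e2 = 0.8) {
  vc <- epiblup:::new_variance_components(
    "one_kernel", sigma_g2 = lambda * sigma_e2, sigma_e2 = sigma_e2,
    lambda = lambda, restricted_loglik = NA_real_, converged = TRUE,
    h2 = lambda / (1 + lambda), n = length(inst$ph$y), k = ncol(inst$ph$X))
  list(vc = vc, op = projection_operator(inst$ph, inst$ks, vc, force = TRUE))
}

frozen_two_kernel <- function(inst, sA2 = 0.6, sAA2 = 0.4, se2 = 0.9) {
  vc <- epiblup:::new_variance_components(
    "two_kernel", sigma_A2 = sA2, sigma_AA2 = sAA2, sigma_e2 = se2,
    ratio = sA2 / sAA2, restricted_loglik = NA_real_, converged = TRUE,
    h2 = (sA2 + sAA2) / (sA2 + sAA2 + se2), n = length(inst$ph$y),
    k = ncol(inst$ph$X))
  list(vc = vc, op = projection_operator(inst$ph, inst$ks, vc, force = TRUE))
}
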