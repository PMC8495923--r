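test_that("one-kernel REML recovers lambda within its profile interval", {
  n <- 300
  gm <- rand_gm(n, 60, 501)
  G <- standardize_kernel(build_additive_grm(gm, "vanraden")$G)
  FG <- epiblup:::.mvn_factor(G)
  X <- cbind(1, rnorm(n))
  covered <- 0L
  for (r in 1:50) {
    set.seed(6000 + r)
    y <- drop(FG %*% rnorm(n)) * sqrt(2) + rnorm(n) + drop(X %*% c(1, 0.5))
    ph <- phenotype_table(y, X)
    vc <- suppressWarnings(reml_one_kernel(ph, G))
    # independent profile over a grid; 95% interval by the chi-square drop
    U2 <- qr.Q(qr(X), complete = TRUE)[, 3:n]
    eg <- eigen(crossprod(U2, G %*% U2), symmetric = TRUE)
    yt <- drop(crossprod(eg$vectors, crossprod(U2, y)))
    d <- pmax(eg$values, 0); m <- n - 2
    rll <- sapply(seq(-6, 6, length.out = 300), function(ll) {
      w <- 1 + exp(ll) * d
      -0.5 * (sum(log(w)) + m * log(sum(yt^2 / w) / m))
    })
    grid <- seq(-6, 6, length.out = 300)
    inside <- grid[rll >= max(rll) - qchisq(0.95, 1) / 2]
    if (log(2) >= min(inside) && log(2) <= max(inside)) covered <- covered + 1L
  }
  expect_gte(covered, 45L)
})

test_that("one-kernel REML maximises the restricted likelihood over an audit grid", {
  inst <- rand_instance(80, 12, 2, 71)
  vc <- suppressWarnings(reml_one_kernel(inst$ph, inst$ks$G))
  X <- inst$ph$X; y <- inst$ph$y; n <- length(y); k <- ncol(X)
  U2 <- qr.Q(qr(X), complete = TRUE)[, (k + 1):n]
  eg <- eigen(crossprod(U2, inst$ks$G %*% U2), symmetric = TRUE)
  yt <- drop(crossprod(eg$vectors, crossprod(U2, y)))
  d <- pmax(eg$values, 0); m <- n - k
  prof <- function(ll) {
    w <- 1 + exp(ll) * d
    -0.5 * (sum(log(w)) + m * log(2 * pi * sum(yt^2 / w) / m) + m)
  }
  audit <- sapply(seq(-10, 10, length.out = 50), prof)
  expect_gte(prof(log(vc$lambda)) + 1e-8, max(audit))
  expect_equal(vc$restricted_loglik, prof(log(vc$lambda)), tolerance = 1e-8)
})

test_that("spectral and generic-optimizer one-kernel REML agree on lambda", {
  for (seed in 1:10) {
    inst <- rand_instance(60, 10, 2, 100 + seed)
    vc <- suppressWarnings(reml_one_kernel(inst$ph, inst$ks$G))
    direct <- epiblup:::.reml_one_kernel_direct(inst$ph, inst$ks$G)
    expect_equal(vc$lambda, direct$lambda, tolerance = 1e-4)
  }
})

test_that("a phenotype in the column space of X gives a flagged degenerate fit", {
  n <- 30
  gm <- rand_gm(n, 5, 81)
  G <- build_additive_grm(gm, "vanraden")$G
  X <- cbind(1, rnorm(n))
  ph <- phenotype_table(drop(X %*% c(2, -1)), X)
  expect_warning(vc <- reml_one_kernel(ph, G), "degenerate")
  expect_false(vc$converged)
  expect_equal(vc$sigma_e2, 0)
})

test_that("two-kernel REML recovers the variance ratio at simulation scale", {
  n <- 200
  gm <- rand_gm(n, 80, 901, inbred = TRUE)
  ks <- build_epistatic_grm(build_additive_grm(gm, "vanraden"),
                            coding = "as_g")
  Gs <- standardize_kernel(ks$G); Hs <- standardize_kernel(ks$H)
  FG <- epiblup:::.mvn_factor(Gs); FH <- epiblup:::.mvn_factor(Hs)
  vs <- epiblup:::.variance_split(1, 0.8)    # sigma_A2 = sigma_AA2
  hits <- 0L
  for (r in 1:20) {
    y <- epiblup:::.sim_y(FG, FH, vs$sigma_A2, vs$sigma_AA2, vs$sigma_e2,
                          7000 + r)
    vc <- suppressWarnings(reml_two_kernel(phenotype_table(y), Gs, Hs,
                                           reltol = 1e-7))
    if (is.finite(vc$ratio) && abs(log2(vc$ratio)) <= 1.5) hits <- hits + 1L
  }
  expect_gte(hits, 16L)
})

test_that("two-kernel REML collapses and swaps correctly", {
  inst <- rand_instance(50, 8, 1, 121)
  G <- inst$ks$G
  vc0 <- suppressWarnings(reml_two_kernel(inst$ph, G, matrix(0, 50, 50)))
  vc1 <- suppressWarnings(reml_one_kernel(inst$ph, G))
  expect_equal(vc0$sigma_AA2, 0)
  expect_equal(vc0$restricted_loglik, vc1$restricted_loglik, tolerance = 1e-6)

  H <- inst$ks$H
  fab <- suppressWarnings(reml_two_kernel(inst$ph, G, H))
  fba <- suppressWarnings(reml_two_kernel(inst$ph, H, G))
  expect_equal(fab$sigma_A2, fba$sigma_AA2, tolerance = 1e-3)
  expect_equal(fab$sigma_AA2, fba$sigma_A2, tolerance = 1e-3)
  expect_equal(fab$restricted_loglik, fba$restricted_loglik, tolerance = 1e-6)
})

test_that("projection operator matches closed forms and annihilates X", {
  # n = 2, X = intercept, G = I, lambda = 1
  ph2 <- phenotype_table(c(0, 1))
  vc2 <- epiblup:::new_variance_components(
    "one_kernel", sigma_g2 = 1, sigma_e2 = 1, lambda = 1,
    restricted_loglik = 0, converged = TRUE, h2 = 0.5, n = 2, k = 1)
  op2 <- projection_operator(ph2, diag(2), vc2)
  expect_equal(op2$T, matrix(c(0.25, -0.25, -0.25, 0.25), 2, 2))

  # lambda = 0, intercept-only: T is the centring matrix
  n <- 6
  ph <- phenotype_table(rnorm(n))
  vc0 <- epiblup:::new_variance_components(
    "one_kernel", sigma_g2 = 0, sigma_e2 = 1, lambda = 0,
    restricted_loglik = 0, converged = TRUE, h2 = 0, n = n, k = 1)
  G <- crossprod(matrix(rnorm(n * n), n))
  op0 <- projection_operator(ph, G, vc0)
  expect_equal(op0$T, diag(n) - matrix(1 / n, n, n), tolerance = 1e-12)

  inst <- rand_instance(40, 8, 3, 131)
  f <- fit_one_kernel(inst)
  expect_lt(max(abs(f$op$T %*% inst$ph$X)), 1e-10 * max(abs(f$op$T)))
  expect_equal(f$op$S %*% f$op$S, f$op$S, tolerance = 1e-10)
  expect_equal(f$op$S, t(f$op$S))
  # T = sigma_e2 * P, recomputed from the full covariance
  Sig <- f$vc$sigma_e2 * f$op$V
  Si <- solve(Sig)
  X <- inst$ph$X
  P <- Si - Si %*% X %*% solve(t(X) %*% Si %*% X, t(X) %*% Si)
  expect_equal(f$op$T, f$vc$sigma_e2 * P, tolerance = 1e-9)

  # rank-deficient covariates are refused
  Xbad <- cbind(1, 2)
  expect_error(phenotype_table(rnorm(2), cbind(1, c(1, 1))), "rank deficient")
})

test_that("T, z and Wald statistics are invariant to kernel rescaling", {
  inst <- rand_instance(50, 10, 2, 141)
  f <- fit_one_kernel(inst)
  cc <- 4
  vc_scaled <- f$vc
  vc_scaled$lambda <- cc * f$vc$lambda
  vc_scaled$sigma_g2 <- cc * f$vc$sigma_g2
  ks_scaled <- inst$ks
  ks_scaled$G <- inst$ks$G / cc
  op_scaled <- projection_operator(inst$ph, ks_scaled, vc_scaled, force = TRUE)
  expect_equal(op_scaled$T, f$op$T, tolerance = 1e-10)
  z1 <- scan_additive_p3d(inst$ph, inst$ks, f$op, f$vc)$statistic
  z2 <- scan_additive_p3d(inst$ph, ks_scaled, op_scaled, vc_scaled)$statistic
  expect_equal(z1, z2, tolerance = 1e-10)
})

test_that("BLUP back-solving agrees between its algebraic routes", {
  # zero variance: zero prediction with a note
  inst <- rand_instance(20, 5, 1, 151)
  f <- fit_one_kernel(inst)
  vcz <- f$vc; vcz$sigma_g2 <- 0
  bz <- blup_random(inst$ph, inst$ks, f$op, vcz, "g")
  expect_equal(bz$ghat, rep(0, 20))
  expect_equal(max(abs(bz$var_ghat)), 0)
  expect_match(bz$note, "zero")

  # invertible G (p > n, raw coding): M'G^-1 ghat equals sigma_a2 M'Py
  gm <- rand_gm(4, 6, 161)
  ks <- build_additive_grm(gm, "raw")
  ph <- phenotype_table(rnorm(4) + rowSums(ks$M) * 0.3)
  vc <- suppressWarnings(reml_one_kernel(ph, ks$G))
  op <- projection_operator(ph, ks, vc, force = TRUE)
  bl <- blup_random(ph, ks, op, vc, "g")
  P <- op$T / vc$sigma_e2
  lhs <- drop(crossprod(ks$M, solve(ks$G, bl$ghat)))
  rhs <- vc$sigma_g2 * drop(crossprod(ks$M, P %*% ph$y))
  expect_equal(lhs, rhs, tolerance = 1e-10)

  # Henderson variance via the direct closed form equals the projection form
  gm5 <- rand_gm(5, 3, 171)
  ks5 <- build_additive_grm(gm5, "raw")
  ph5 <- phenotype_table(rnorm(5))
  vc5 <- suppressWarnings(reml_one_kernel(ph5, ks5$G))
  op5 <- projection_operator(ph5, ks5, vc5, force = TRUE)
  expect_equal(marker_blup_variance_direct(ph5, ks5, vc5),
               marker_blup_variance_projection(ks5, op5, vc5),
               tolerance = 1e-10)

  # two-kernel additivity of BLUPs
  inst2 <- rand_instance(40, 8, 2, 181)
  f2 <- fit_two_kernel(inst2, reltol = 1e-7)
  bA <- blup_random(inst2$ph, inst2$ks, f2$op, f2$vc, "g_A")
  bAA <- blup_random(inst2$ph, inst2$ks, f2$op, f2$vc, "g_AA")
  P2 <- f2$op$T / f2$vc$sigma_e2
  total <- drop((f2$vc$sigma_A2 * inst2$ks$G + f2$vc$sigma_AA2 * inst2$ks$H)
                %*% P2 %*% inst2$ph$y)
  expect_equal(bA$ghat + bAA$ghat, total, tolerance = 1e-8)

  # GLS residual (not the BLUP) is V^-1-orthogonal to X
  X <- inst2$ph$X
  Vi <- solve(f2$op$V)
  bhat <- solve(t(X) %*% Vi %*% X, t(X) %*% Vi %*% inst2$ph$y)
  expect_lt(max(abs(t(X) %*% Vi %*% (inst2$ph$y - X %*% bhat))), 1e-8)
})

test_that("gls_wald matches OLS when V = I and handles edge cases", {
  n <- 4
  ph <- phenotype_table(c(1.2, 0.7, -0.3, 2.1), cbind(1, c(0, 1, 0, 1)))
  vcI <- epiblup:::new_variance_components(
    "one_kernel", sigma_g2 = 0, sigma_e2 = 1.3, lambda = 0,
    restricted_loglik = 0, converged = TRUE, h2 = 0, n = n, k = 2)
  op <- projection_operator(ph, diag(n), vcI)
  extra <- matrix(c(0.5, -1, 2, 0), n, 1)
  gw <- gls_wald(ph, extra, op, vcI)
  Xf <- cbind(ph$X, extra)
  ols <- solve(crossprod(Xf), crossprod(Xf, ph$y))
  covb <- vcI$sigma_e2 * solve(crossprod(Xf))
  expect_equal(unname(gw$estimates), drop(ols), tolerance = 1e-10)
  expect_equal(gw$wald, ols[3]^2 / covb[3, 3], tolerance = 1e-10)

  # duplicated covariate in the tested position: NA with a reason, no error
  gw2 <- gls_wald(ph, ph$X[, 2, drop = FALSE], op, vcI)
  expect_true(is.na(gw2$wald))
  expect_equal(gw2$reason, "collinear")

  # df-1 Wald equals the squared t-type z
  inst <- rand_instance(30, 6, 2, 191)
  f <- fit_one_kernel(inst)
  m <- inst$ks$M[, 3, drop = FALSE]
  gw3 <- gls_wald(inst$ph, m, f$op, f$vc)
  z <- scan_additive_p3d(inst$ph, inst$ks, f$op, f$vc)$statistic[3]
  expect_equal(gw3$wald, z^2, tolerance = 1e-8)
})
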