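#' Variance-component container
#'
#' @param .kind `"one_kernel"` or `"two_kernel"`.
#' @param ... Named fields (see [reml_one_kernel()], [reml_two_kernel()]).
#' @return Object of class `variance_components`.
#' @keywords internal
new_variance_components <- function(.kind, ...) {
  structure(c(list(kind = .kind), list(...)), class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat(sprintf("<variance_components> %s fit%s\n", x$kind,
              if (isTRUE(x$converged)) "" else " (not converged)"))
  if (x$kind == "one_kernel") {
    cat(sprintf("  sigma_g2 = %.6g  sigma_e2 = %.6g  lambda = %.6g\n",
                x$sigma_g2, x$sigma_e2, x$lambda))
  } else {
    cat(sprintf("  sigma_A2 = %.6g  sigma_AA2 = %.6g  sigma_e2 = %.6g\n",
                x$sigma_A2, x$sigma_AA2, x$sigma_e2))
  }
  cat(sprintf("  h2 = %.4f  restricted logLik = %.4f\n", x$h2,
              x$restricted_loglik))
  invisible(x)
}

# orthonormal basis of the complement of col(X): n x (n-k)
.complement_basis <- function(X) {
  n <- nrow(X); k <- ncol(X)
  qr.Q(qr(X), complete = TRUE)[, (k + 1L):n, drop = FALSE]
}

# small ridge guarding REML spectral/cholesky steps on rank-deficient kernels
.ridge <- function(K, eps = 1e-8) {
  K + diag(eps * mean(diag(K)), nrow(K))
}

#' One-kernel REML by spectral profiling
#'
#' Fits `y = X beta + g + e`, `g ~ N(0, G sigma_g2)`,
#' `e ~ N(0, I sigma_e2)` by restricted maximum likelihood. The
#' restricted likelihood is profiled over `lambda = sigma_g2/sigma_e2`
#' after an eigendecomposition of `G` projected onto the orthogonal
#' complement of `X`, so each candidate `lambda` costs O(n); the profile
#' is maximised over `log(lambda)` by golden-section/parabolic search.
#'
#' @param ph A [phenotype_table()].
#' @param G n x n symmetric PSD kernel.
#' @param loglambda_range Search interval for `log(lambda)`.
#' @param tol Convergence tolerance on `log(lambda)`.
#' @return A `variance_components` object (kind `"one_kernel"`) with
#'   fields `sigma_g2`, `sigma_e2`, `lambda`, `restricted_loglik`,
#'   `converged`, `h2`, `n`, `k`.
#' @export
reml_one_kernel <- function(ph, G, loglambda_range = c(-10, 10), tol = 1e-8) {
  stopifnot(inherits(ph, "phenotype_table"))
  X <- ph$X; y <- ph$y
  n <- length(y); k <- ncol(X)
  if (n <= k + 1L) stop("too few records for REML (n <= k + 1)")
  if (nrow(G) != n) stop("kernel dimension does not match phenotypes")
  U2 <- .complement_basis(X)
  A <- crossprod(U2, G %*% U2)
  eg <- eigen((A + t(A)) / 2, symmetric = TRUE)
  d <- pmax(eg$values, 0)
  ytil <- drop(crossprod(eg$vectors, crossprod(U2, y)))
  m <- n - k
  ss <- sum(ytil^2)
  if (ss < 1e-12 * max(sum(y^2), 1)) {
    warning("phenotype lies in the column space of X: degenerate fit")
    return(new_variance_components("one_kernel", sigma_g2 = 0, sigma_e2 = 0,
                                   lambda = 0, restricted_loglik = NA_real_,
                                   converged = FALSE, h2 = 0, n = n, k = k))
  }
  prof <- function(loglam) {
    w <- 1 + exp(loglam) * d
    s2e <- sum(ytil^2 / w) / m
    -0.5 * (sum(log(w)) + m * log(2 * pi * s2e) + m)
  }
  opt <- stats::optimize(prof, interval = loglambda_range, maximum = TRUE,
                         tol = tol)
  loglam <- opt$maximum
  at_edge <- min(loglam - loglambda_range[1L],
                 loglambda_range[2L] - loglam) < 1e-3
  if (at_edge) warning("lambda estimate at the search boundary")
  lam <- exp(loglam)
  w <- 1 + lam * d
  s2e <- sum(ytil^2 / w) / m
  new_variance_components(
    "one_kernel",
    sigma_g2 = lam * s2e, sigma_e2 = s2e, lambda = lam,
    restricted_loglik = opt$objective, converged = !at_edge,
    h2 = lam / (1 + lam), n = n, k = k)
}

# generic-optimizer one-kernel REML on the unprojected (cholesky) likelihood;
# internal cross-check for the spectral route (constants differ, argmax agrees)
.reml_one_kernel_direct <- function(ph, G, loglambda_range = c(-10, 10)) {
  X <- ph$X; y <- ph$y
  n <- length(y); k <- ncol(X); m <- n - k
  f <- function(loglam) {
    V <- diag(n) + exp(loglam) * G
    R <- chol(.ridge(V, 1e-10))
    Xi <- backsolve(R, X, transpose = TRUE)
    yi <- backsolve(R, y, transpose = TRUE)
    B <- crossprod(Xi)
    bh <- solve(B, crossprod(Xi, yi))
    rss <- sum((yi - Xi %*% bh)^2)
    s2e <- rss / m
    -0.5 * (2 * sum(log(diag(R))) + determinant(B)$modulus +
              m * log(2 * pi * s2e) + m)
  }
  opt <- stats::optimize(f, interval = loglambda_range, maximum = TRUE,
                         tol = 1e-9)
  list(lambda = exp(opt$maximum), loglik = opt$objective)
}

# core two-kernel REML on X-complement projections (m = n - k)
.fit_two_kernel_proj <- function(Atil, Htil, yproj, m, lam0,
                                 start_ratios = c(0.1, 0.5, 1, 2, 10),
                                 reltol = 1e-8, maxit = 2000) {
  rll <- function(th) {
    if (any(abs(th) > 15)) return(-1e10)
    a <- exp(th[1L]); b <- exp(th[2L])
    W <- diag(m) + a * Atil + b * Htil
    R <- tryCatch(chol(W), error = function(e) NULL)
    if (is.null(R)) return(-1e10)
    u <- backsolve(R, yproj, transpose = TRUE)
    s2e <- sum(u^2) / m
    -0.5 * (2 * sum(log(diag(R))) + m * log(2 * pi * s2e) + m)
  }
  best <- NULL
  for (r in start_ratios) {
    th0 <- log(c(lam0 * 2 * r / (1 + r), lam0 * 2 / (1 + r)))
    fit <- stats::optim(th0, rll, method = "Nelder-Mead",
                        control = list(fnscale = -1, reltol = reltol,
                                       maxit = maxit))
    if (is.null(best) || fit$value > best$value) best <- fit
  }
  if (is.null(best) || best$value <= -1e9)
    stop("two-kernel REML failed from every starting point")
  th <- best$par
  a <- exp(th[1L]); b <- exp(th[2L])
  W <- diag(m) + a * Atil + b * Htil
  R <- chol(W)
  u <- backsolve(R, yproj, transpose = TRUE)
  s2e <- sum(u^2) / m
  boundary <- any(abs(th) > 14)
  list(a = a, b = b, s2e = s2e, loglik = best$value, boundary = boundary)
}

#' Two-kernel REML (additive + epistatic kernels)
#'
#' Fits `y = X beta + g_A + g_AA + e` with `g_A ~ N(0, G sigma_A2)`,
#' `g_AA ~ N(0, H sigma_AA2)`, `e ~ N(0, I sigma_e2)` by restricted
#' maximum likelihood. The residual variance is profiled out
#' analytically and the two variance ratios are maximised on the log
#' scale by Nelder-Mead from five deterministic starting points whose
#' additive:epistatic ratios span 0.1 to 10.
#'
#' A numerically zero kernel collapses the model to the one-kernel fit
#' with the corresponding component pinned at zero.
#'
#' @inheritParams reml_one_kernel
#' @param H n x n symmetric PSD epistatic kernel.
#' @return A `variance_components` object (kind `"two_kernel"`) with
#'   `sigma_A2`, `sigma_AA2`, `sigma_e2`, `ratio`, `restricted_loglik`,
#'   `converged`, `h2`, `n`, `k`.
#' @export
reml_two_kernel <- function(ph, G, H, reltol = 1e-8, maxit = 2000) {
  stopifnot(inherits(ph, "phenotype_table"))
  X <- ph$X; y <- ph$y
  n <- length(y); k <- ncol(X)
  if (n <= k + 1L) stop("too few records for REML (n <= k + 1)")
  if (nrow(G) != n || nrow(H) != n)
    stop("kernel dimension does not match phenotypes")
  sc <- max(abs(G), abs(H), 1e-300)
  if (max(abs(H)) < 1e-12 * sc) {
    fit1 <- reml_one_kernel(ph, G)
    return(new_variance_components(
      "two_kernel", sigma_A2 = fit1$sigma_g2, sigma_AA2 = 0,
      sigma_e2 = fit1$sigma_e2, ratio = Inf,
      restricted_loglik = fit1$restricted_loglik,
      converged = fit1$converged,
      h2 = fit1$sigma_g2 / (fit1$sigma_g2 + fit1$sigma_e2), n = n, k = k))
  }
  if (max(abs(G)) < 1e-12 * sc) {
    fit1 <- reml_one_kernel(ph, H)
    return(new_variance_components(
      "two_kernel", sigma_A2 = 0, sigma_AA2 = fit1$sigma_g2,
      sigma_e2 = fit1$sigma_e2, ratio = 0,
      restricted_loglik = fit1$restricted_loglik,
      converged = fit1$converged,
      h2 = fit1$sigma_g2 / (fit1$sigma_g2 + fit1$sigma_e2), n = n, k = k))
  }
  U2 <- .complement_basis(X)
  Atil <- crossprod(U2, G %*% U2); Atil <- (Atil + t(Atil)) / 2
  Htil <- crossprod(U2, H %*% U2); Htil <- (Htil + t(Htil)) / 2
  yproj <- drop(crossprod(U2, y))
  f0 <- suppressWarnings(reml_one_kernel(ph, (G + H) / 2))
  lam0 <- max(f0$lambda, 1e-3)
  fit <- .fit_two_kernel_proj(Atil, Htil, yproj, n - k, lam0,
                              reltol = reltol, maxit = maxit)
  if (fit$boundary)
    warning("two-kernel REML solution at the parameter-space boundary")
  sA <- fit$a * fit$s2e; sAA <- fit$b * fit$s2e
  new_variance_components(
    "two_kernel", sigma_A2 = sA, sigma_AA2 = sAA, sigma_e2 = fit$s2e,
    ratio = sA / sAA, restricted_loglik = fit$loglik,
    converged = !fit$boundary,
    h2 = (sA + sAA) / (sA + sAA + fit$s2e), n = n, k = k)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy variance-component estimates
#'
#' @param x A `variance_components` object.
#' @param ... Unused.
#' @return Tibble with columns `component`, `estimate`.
#' @export
tidy.variance_components <- function(x, ...) {
  if (x$kind == "one_kernel") {
    tibble::tibble(component = c("sigma_g2", "sigma_e2", "lambda", "h2"),
                   estimate = c(x$sigma_g2, x$sigma_e2, x$lambda, x$h2))
  } else {
    tibble::tibble(
      component = c("sigma_A2", "sigma_AA2", "sigma_e2", "ratio", "h2"),
      estimate = c(x$sigma_A2, x$sigma_AA2, x$sigma_e2, x$ratio, x$h2))
  }
}

#' One-line fit summary
#'
#' @param x A `variance_components` object.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.variance_components <- function(x, ...) {
  tibble::tibble(kind = x$kind, restricted_loglik = x$restricted_loglik,
                 converged = x$converged, h2 = x$h2, n = x$n, k = x$k)
}

#' Write variance components to a TSV
#'
#' @param vc A `variance_components` object.
#' @param path Output path.
#' @export
write_variance_components <- function(vc, path) {
  readr::write_tsv(tidy(vc), path)
}
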