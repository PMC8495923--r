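#' Projection operator of the P3D mixed-model tests
#'
#' Builds the matrices that every P3D test statistic is computed from:
#' the covariance shape `V` (phenotypic covariance = `sigma_e2 * V`),
#' the annihilator
#' `T = V^-1 - V^-1 X (X' V^-1 X)^-1 X' V^-1` (so `T X = 0` and
#' `T = sigma_e2 * P` with `P` the usual REML projection), and the
#' ordinary projection `S = I - X (X'X)^-1 X'`.
#'
#' Contexts: for a one-kernel fit `V = I + lambda * G`; for a
#' two-kernel (epistatic-null) fit
#' `V = I + (sigma_A2/sigma_e2) G + (sigma_AA2/sigma_e2) H`, i.e. the
#' shape of `sigma_A2 G + sigma_AA2 H + sigma_e2 I` divided by
#' `sigma_e2`.
#'
#' @param ph A [phenotype_table()].
#' @param ks A `kinship_set` (needs `H` for the two-kernel context), or
#'   a plain `G` matrix for the one-kernel context.
#' @param vc A `variance_components` fit matching the context.
#' @param force Proceed even if `vc$converged` is `FALSE`.
#' @return Object of class `projection_operator` with fields `V`, `T`,
#'   `S`, `cholV`, `context`, `X`, `n`, `k`.
#' @export
projection_operator <- function(ph, ks, vc, force = FALSE) {
  stopifnot(inherits(ph, "phenotype_table"),
            inherits(vc, "variance_components"))
  if (!isTRUE(vc$converged) && !force)
    stop("variance components not converged; pass force = TRUE to override")
  X <- ph$X
  n <- length(ph$y); k <- ncol(X)
  G <- if (inherits(ks, "kinship_set")) ks$G else as.matrix(ks)
  if (nrow(G) != n) stop("kernel dimension does not match phenotypes")
  if (vc$kind == "one_kernel") {
    V <- diag(n) + vc$lambda * G
    context <- "one_kernel"
  } else {
    if (!inherits(ks, "kinship_set") || is.null(ks$H))
      stop("two-kernel context needs a kinship_set with H")
    V <- diag(n) + (vc$sigma_A2 / vc$sigma_e2) * G +
      (vc$sigma_AA2 / vc$sigma_e2) * ks$H
    context <- "epistatic_null"
  }
  V <- (V + t(V)) / 2
  dimnames(V) <- NULL
  R <- chol(V)
  Vinv <- chol2inv(R)
  W <- Vinv %*% X
  B <- crossprod(X, W)
  if (rcond(B) < 1e-12) stop("X' V^-1 X is singular (rank-deficient covariates)")
  Tm <- Vinv - W %*% solve(B, t(W))
  Tm <- (Tm + t(Tm)) / 2
  XtX <- crossprod(X)
  S <- diag(n) - X %*% solve(XtX, t(X))
  S <- (S + t(S)) / 2
  structure(list(V = V, T = Tm, S = S, cholV = R, context = context,
                 X = X, n = n, k = k),
            class = "projection_operator")
}

#' @export
print.projection_operator <- function(x, ...) {
  cat(sprintf("<projection_operator> context = %s, n = %d, k = %d\n",
              x$context, x$n, x$k))
  invisible(x)
}

#' BLUP of a random genetic component with Henderson-sense variance
#'
#' With `P = T / sigma_e2`, the predictor of a component with kernel `K`
#' and variance `s2` is `ghat = s2 * K P y` and its (Henderson-sense)
#' variance -- the variance of the predictor itself, not the prediction
#' error variance -- is `Var(ghat) = s2^2 * K P K`.
#'
#' @param ph A [phenotype_table()].
#' @param ks A `kinship_set` (or `G` matrix for the one-kernel model).
#' @param op A [projection_operator()] for the matching null model.
#' @param vc The `variance_components` used to build `op`.
#' @param component `"g"` (one-kernel), or `"g_A"`, `"g_AA"`, `"g_T"`
#'   (two-kernel; `g_T = g_A + g_AA`).
#' @return Object of class `blup_result`: `ghat`, `var_ghat`,
#'   `component`, `note`.
#' @export
blup_random <- function(ph, ks, op, vc,
                        component = c("g", "g_A", "g_AA", "g_T")) {
  component <- match.arg(component)
  G <- if (inherits(ks, "kinship_set")) ks$G else as.matrix(ks)
  P <- op$T / vc$sigma_e2
  pick <- switch(component,
    g = {
      stopifnot(vc$kind == "one_kernel")
      list(K = G, s2 = vc$sigma_g2)
    },
    g_A = {
      stopifnot(vc$kind == "two_kernel")
      list(K = G, s2 = vc$sigma_A2)
    },
    g_AA = {
      stopifnot(vc$kind == "two_kernel", !is.null(ks$H))
      list(K = ks$H, s2 = vc$sigma_AA2)
    },
    g_T = {
      stopifnot(vc$kind == "two_kernel", !is.null(ks$H))
      list(K = vc$sigma_A2 * G + vc$sigma_AA2 * ks$H, s2 = 1)
    })
  note <- NA_character_
  if (pick$s2 == 0) {
    note <- "component variance is zero; BLUP is identically zero"
    ghat <- rep(0, op$n)
    vg <- matrix(0, op$n, op$n)
  } else {
    KP <- pick$s2 * pick$K %*% P
    ghat <- drop(KP %*% ph$y)
    vg <- pick$s2 * KP %*% pick$K
    vg <- (vg + t(vg)) / 2
  }
  structure(list(ghat = ghat, var_ghat = vg, component = component,
                 note = note),
            class = "blup_result")
}

#' Generalised least squares with a Wald test under the P3D covariance
#'
#' Fits `y` on `[X | extra_fixed]` by GLS with error covariance
#' `sigma_e2 * V` (from the projection operator), and returns the Wald
#' statistic for the requested columns of `extra_fixed`:
#' `W = g' [Var(g)]^-1 g`, df = number of tested columns, referred to
#' the upper tail of a chi-square.
#'
#' Rank deficiency that involves a tested column yields an `NA` result
#' (reason `"collinear"`) rather than an error, so genome scans never
#' abort; deficient non-tested extra columns are silently dropped.
#'
#' @param ph A [phenotype_table()].
#' @param extra_fixed n x q matrix of additional fixed covariates.
#' @param op A [projection_operator()].
#' @param vc Matching `variance_components` (supplies `sigma_e2`).
#' @param test_cols Columns of `extra_fixed` to test (default: all).
#' @return List: `estimates` (named, for `[X | extra]`), `covariance`,
#'   `wald`, `df`, `p`, `ok`, `reason`.
#' @export
gls_wald <- function(ph, extra_fixed, op, vc,
                     test_cols = seq_len(ncol(extra_fixed))) {
  extra_fixed <- as.matrix(extra_fixed)
  X <- ph$X
  k <- ncol(X); q <- ncol(extra_fixed)
  stopifnot(length(test_cols) >= 1L, all(test_cols >= 1L), all(test_cols <= q))
  Xs <- cbind(X, extra_fixed)
  R <- op$cholV
  Aw <- backsolve(R, Xs, transpose = TRUE)
  yw <- backsolve(R, ph$y, transpose = TRUE)
  dec <- qr(Aw)
  bad <- list(estimates = NULL, covariance = NULL, wald = NA_real_,
              df = NA_integer_, p = NA_real_, ok = FALSE,
              reason = "collinear")
  if (dec$rank < ncol(Aw)) {
    dropped <- dec$pivot[(dec$rank + 1L):ncol(Aw)]
    test_abs <- k + test_cols
    if (any(dropped <= k) || any(dropped %in% test_abs)) return(bad)
    keep <- setdiff(seq_len(ncol(Aw)), dropped)
    Aw <- Aw[, keep, drop = FALSE]
    Xs <- Xs[, keep, drop = FALSE]
    test_abs <- match(test_abs, keep)
  } else {
    test_abs <- k + test_cols
  }
  XtVX <- crossprod(Aw)
  if (rcond(XtVX) < 1e-12) return(bad)
  est <- drop(solve(XtVX, crossprod(Aw, yw)))
  covb <- vc$sigma_e2 * solve(XtVX)
  names(est) <- colnames(Xs)
  dimnames(covb) <- list(colnames(Xs), colnames(Xs))
  gt <- est[test_abs]
  Vt <- covb[test_abs, test_abs, drop = FALSE]
  if (rcond(Vt) < 1e-12) return(bad)
  wald <- drop(crossprod(gt, solve(Vt, gt)))
  df <- length(test_abs)
  list(estimates = est, covariance = covb, wald = wald, df = df,
       p = stats::pchisq(wald, df, lower.tail = FALSE), ok = TRUE,
       reason = NA_character_)
}
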