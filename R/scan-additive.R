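#' Single-marker additive scan under the P3D Q+K model
#'
#' For each marker m the fixed-effect estimate and test under the
#' one-kernel null covariance are
#' `a_hat = m'Ty / m'Tm`, `Var(a_hat) = sigma_e2 / m'Tm`,
#' `z = m'Ty / (sigma_e * sqrt(m'Tm))`,
#' with a two-sided p-value from a t distribution on `n - k - 1`
#' degrees of freedom. Markers with `m'Tm <= 1e-12` (monomorphic or in
#' the column space of X) yield `NA` rows, never errors.
#'
#' @param ph A [phenotype_table()].
#' @param ks A `kinship_set`; its effective marker matrix is scanned.
#' @param op One-kernel [projection_operator()] from the null model.
#' @param vc The matching `variance_components`.
#' @return A scan-result tibble (`marker`, `estimate`, `variance`,
#'   `statistic`, `df`, `p`, `method`, `reason`).
#' @export
scan_additive_p3d <- function(ph, ks, op, vc) {
  stopifnot(op$context == "one_kernel")
  .scan_additive_T(ph, ks, op, vc, route = "p3d")
}

#' Single-marker additive scan by GBLUP back-solving
#'
#' Back-solves per-marker effects from the fitted GBLUP model:
#' `a_hat = (sigma_a2 / sigma_e2) m'Ty` with Henderson-sense variance
#' `Var(a_hat) = (sigma_a2^2 / sigma_e2) m'Tm`, and
#' `z = a_hat / sqrt(Var(a_hat))`. With the kernel's scaling constant
#' absorbed into the effective marker matrix, `sigma_a2 = sigma_g2`.
#' The resulting z equals the P3D Q+K z for every marker.
#'
#' @inheritParams scan_additive_p3d
#' @return A scan-result tibble.
#' @export
scan_additive_gblup <- function(ph, ks, op, vc) {
  stopifnot(op$context == "one_kernel")
  .scan_additive_T(ph, ks, op, vc, route = "gblup")
}

.scan_additive_T <- function(ph, ks, op, vc, route) {
  M <- if (inherits(ks, "kinship_set")) ks$M else as.matrix(ks)
  y <- ph$y
  n <- op$n; k <- op$k
  Ty <- op$T %*% y
  TM <- op$T %*% M
  num <- unname(drop(crossprod(M, Ty)))
  den <- unname(colSums(M * TM))
  ok <- den > 1e-12
  df <- n - k - 1L
  s2e <- vc$sigma_e2
  if (route == "p3d") {
    est <- ifelse(ok, num / den, NA_real_)
    vv <- ifelse(ok, s2e / den, NA_real_)
    z <- ifelse(ok, num / (sqrt(s2e) * sqrt(den)), NA_real_)
    method <- "QK_P3D"
  } else {
    s2a <- vc$sigma_g2
    est <- ifelse(ok, (s2a / s2e) * num, NA_real_)
    vv <- ifelse(ok, (s2a^2 / s2e) * den, NA_real_)
    z <- ifelse(ok, est / sqrt(vv), NA_real_)
    method <- "GBLUP"
  }
  p <- 2 * stats::pt(-abs(z), df)
  new_scan_result(tibble::tibble(
    marker = colnames(M), estimate = est, variance = vv, statistic = z,
    df = df, p = p,
    reason = ifelse(ok, NA_character_, "in_X_span_or_monomorphic")),
    method)
}

#' Window-based additive test
#'
#' Tests the joint null that all additive effects of a group of `s`
#' markers are zero, via two algebraically equivalent routes that are
#' both computed and returned: a fixed-effect GLS of `y` on `[X | W]`
#' with Wald statistic `a_w' Var(a_w)^-1 a_w`, and a random-effect
#' route using the back-solved window effects
#' `a_w = sigma_a2 W'Py` with Henderson variance `sigma_a2^2 W'PW`.
#' The statistic is referred to a chi-square with df = rank of the
#' tested block; a rank-deficient window reduces df with reason
#' `"rank_deficient"`.
#'
#' @inheritParams scan_additive_p3d
#' @param markers Marker IDs or column indices forming the window.
#' @return One-row scan-result tibble with columns `window`,
#'   `statistic` (fixed route), `statistic_random`, `df`, `p`.
#' @export
test_window <- function(ph, ks, markers, op, vc) {
  M <- if (inherits(ks, "kinship_set")) ks$M else as.matrix(ks)
  idx <- if (is.character(markers)) match(markers, colnames(M)) else markers
  if (anyNA(idx)) stop("window markers not found in the genotype matrix")
  W <- M[, idx, drop = FALSE]
  s <- ncol(W)
  s2e <- vc$sigma_e2
  s2a <- vc$sigma_g2
  Ty <- op$T %*% ph$y
  WTy <- drop(crossprod(W, Ty))
  WTW <- crossprod(W, op$T %*% W)
  WTW <- (WTW + t(WTW)) / 2
  eg <- eigen(WTW, symmetric = TRUE)
  tolv <- max(eg$values, 0) * 1e-10
  pos <- eg$values > tolv
  rank <- sum(pos)
  if (rank == 0L) {
    return(new_scan_result(tibble::tibble(
      window = paste(colnames(W), collapse = ","), estimate = NA_real_,
      variance = NA_real_, statistic = NA_real_,
      statistic_random = NA_real_, df = NA_integer_, p = NA_real_,
      reason = "in_X_span_or_monomorphic"), "WINDOW"))
  }
  pinv <- eg$vectors[, pos, drop = FALSE] %*%
    (t(eg$vectors[, pos, drop = FALSE]) / eg$values[pos])
  # fixed route: GLS coefficients of the W block and their covariance
  a_fixed <- drop(pinv %*% WTy)
  cov_fixed <- s2e * pinv
  w_fixed <- drop(crossprod(a_fixed, WTy)) / s2e
  # random route: back-solved window effects, Henderson-sense variance
  a_rand <- (s2a / s2e) * WTy
  var_rand <- (s2a^2 / s2e) * WTW
  pinv_rand <- (s2e / s2a^2) * pinv          # pseudo-inverse of var_rand
  w_rand <- drop(crossprod(a_rand, pinv_rand %*% a_rand))
  reason <- if (rank < s) "rank_deficient" else NA_character_
  new_scan_result(tibble::tibble(
    window = paste(colnames(W), collapse = ","),
    estimate = NA_real_, variance = NA_real_,
    statistic = w_fixed, statistic_random = w_rand, df = rank,
    p = stats::pchisq(w_fixed, rank, lower.tail = FALSE),
    reason = reason), "WINDOW")
}

#' Exact (per-marker REML) Q+K additive scan
#'
#' Re-estimates the variance components for every marker by REML on the
#' model including that marker as a fixed covariate, then computes the
#' z statistic with the re-estimated variances. This is the exact Q+K
#' test that the P3D approximation replaces; intended as an oracle at
#' small scale.
#'
#' @inheritParams scan_additive_p3d
#' @return A scan-result tibble (method `"QK_EXACT"`).
#' @export
scan_additive_exact <- function(ph, ks) {
  M <- if (inherits(ks, "kinship_set")) ks$M else stop("need a kinship_set")
  G <- ks$G
  y <- ph$y; X <- ph$X
  n <- length(y); k <- ncol(X)
  df <- n - k - 1L
  out <- purrr::map(seq_len(ncol(M)), function(i) {
    m <- M[, i]
    Xi <- cbind(X, marker = m)
    if (qr(Xi)$rank < ncol(Xi))
      return(list(est = NA_real_, vv = NA_real_, z = NA_real_,
                  reason = "collinear"))
    fit <- tryCatch(
      suppressWarnings(reml_one_kernel(phenotype_table(y, Xi), G)),
      error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$restricted_loglik))
      return(list(est = NA_real_, vv = NA_real_, z = NA_real_,
                  reason = "reml_failed"))
    opi <- projection_operator(ph, G, fit, force = TRUE)
    den <- drop(crossprod(m, opi$T %*% m))
    if (den <= 1e-12)
      return(list(est = NA_real_, vv = NA_real_, z = NA_real_,
                  reason = "in_X_span_or_monomorphic"))
    num <- drop(crossprod(m, opi$T %*% y))
    list(est = num / den, vv = fit$sigma_e2 / den,
         z = num / (sqrt(fit$sigma_e2) * sqrt(den)), reason = NA_character_)
  })
  z <- purrr::map_dbl(out, "z")
  new_scan_result(tibble::tibble(
    marker = colnames(M),
    estimate = purrr::map_dbl(out, "est"),
    variance = purrr::map_dbl(out, "vv"),
    statistic = z, df = df, p = 2 * stats::pt(-abs(z), df),
    reason = purrr::map_chr(out, "reason")), "QK_EXACT")
}

#' Marker-effect BLUP variance: direct closed form
#'
#' Evaluates `Var(a_hat) = sigma_a2 I - sigma_e2 (sigma_e2/sigma_a2 I +
#' M'SM)^-1` with `S = I - X(X'X)^-1 X'`. Entrywise equal to the
#' projection shortcut [marker_blup_variance_projection()].
#'
#' @param ph A [phenotype_table()].
#' @param ks A `kinship_set` built with `scaling = "raw"` (so `G = MM'`).
#' @param vc One-kernel `variance_components`.
#' @return p x p covariance matrix of the back-solved marker effects.
#' @export
marker_blup_variance_direct <- function(ph, ks, vc) {
  M <- ks$M
  X <- ph$X
  S <- diag(nrow(X)) - X %*% solve(crossprod(X), t(X))
  s2a <- vc$sigma_g2; s2e <- vc$sigma_e2
  s2a * diag(ncol(M)) -
    s2e * solve((s2e / s2a) * diag(ncol(M)) + crossprod(M, S %*% M))
}

#' Marker-effect BLUP variance: projection shortcut
#'
#' Evaluates `Var(a_hat) = (sigma_a2^2 / sigma_e2) M'TM`.
#'
#' @param ks A `kinship_set`.
#' @param op One-kernel [projection_operator()].
#' @param vc One-kernel `variance_components`.
#' @return p x p covariance matrix.
#' @export
marker_blup_variance_projection <- function(ks, op, vc) {
  M <- ks$M
  (vc$sigma_g2^2 / vc$sigma_e2) * crossprod(M, op$T %*% M)
}
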