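#' Enumerate marker pairs
#'
#' All pairs (i, j) with i < j in lexicographic order, optionally
#' restricted to a subset of markers (both members must be in the
#' subset).
#'
#' @param p Number of markers (>= 2).
#' @param restrict Optional marker indices or IDs.
#' @param marker_ids Optional marker ID vector (length p) used to
#'   resolve character `restrict` and to label the pairs.
#' @return Tibble with columns `i`, `j`, `marker1`, `marker2`.
#' @export
enumerate_pairs <- function(p, restrict = NULL, marker_ids = NULL) {
  if (p < 2L) stop("need at least 2 markers to form pairs")
  if (is.null(marker_ids)) marker_ids <- paste0("M", seq_len(p))
  stopifnot(length(marker_ids) == p)
  keep <- seq_len(p)
  if (!is.null(restrict)) {
    keep <- if (is.character(restrict)) match(restrict, marker_ids)
            else as.integer(restrict)
    if (anyNA(keep) || any(keep < 1L | keep > p))
      stop("restrict contains unknown markers")
    keep <- sort(unique(keep))
  }
  if (length(keep) < 2L) stop("fewer than 2 markers after restriction")
  cmb <- utils::combn(keep, 2L)
  tibble::tibble(i = cmb[1L, ], j = cmb[2L, ],
                 marker1 = marker_ids[cmb[1L, ]],
                 marker2 = marker_ids[cmb[2L, ]])
}

# shared pairwise engine: partitioned-GLS Wald statistics computed from the
# annihilator T (T X = 0, so the [m_i, m_j, q] block has normal equations
# B'TB). `marginals` toggles the extended Q+K / Q+2K design (marker main
# effects included as fixed covariates) vs the auxiliary design (product
# column only).
.pair_scan_engine <- function(ph, ks, pairs, op, vc, marginals, method,
                              chunk = 5000L) {
  M <- ks$M_epi %||% ks$M
  y <- ph$y
  s2e <- vc$sigma_e2
  Ty <- drop(op$T %*% y)
  TM <- op$T %*% M
  MtTy <- drop(crossprod(M, Ty))
  dTT <- colSums(M * TM)
  npair <- nrow(pairs)
  est <- vv <- w <- rep(NA_real_, npair)
  reason <- rep(NA_character_, npair)
  for (lo in seq(1L, npair, by = chunk)) {
    hi <- min(lo + chunk - 1L, npair)
    ii <- pairs$i[lo:hi]; jj <- pairs$j[lo:hi]
    Q <- M[, ii, drop = FALSE] * M[, jj, drop = FALSE]
    TQ <- op$T %*% Q
    qTy <- unname(drop(crossprod(Q, Ty)))
    qTq <- unname(colSums(Q * TQ))
    if (marginals) {
      dij <- colSums(M[, ii, drop = FALSE] * TM[, jj, drop = FALSE])
      miq <- colSums(TM[, ii, drop = FALSE] * Q)
      mjq <- colSums(TM[, jj, drop = FALSE] * Q)
      for (t in seq_along(ii)) {
        g <- lo + t - 1L
        B <- matrix(c(dTT[ii[t]], dij[t], miq[t],
                      dij[t], dTT[jj[t]], mjq[t],
                      miq[t], mjq[t], qTq[t]), 3L, 3L)
        rhs <- c(MtTy[ii[t]], MtTy[jj[t]], qTy[t])
        if (qTq[t] <= 1e-12 || !is.finite(rcond(B)) || rcond(B) < 1e-12) {
          reason[g] <- "collinear"
          next
        }
        Binv <- solve(B)
        coefs <- Binv %*% rhs
        est[g] <- coefs[3L]
        vv[g] <- s2e * Binv[3L, 3L]
        w[g] <- est[g]^2 / vv[g]
      }
    } else {
      ok <- qTq > 1e-12
      g <- (lo:hi)[ok]
      est[g] <- (qTy / qTq)[ok]
      vv[g] <- (s2e / qTq)[ok]
      w[g] <- (qTy^2 / (s2e * qTq))[ok]
      reason[(lo:hi)[!ok]] <- "in_X_span_or_constant"
    }
  }
  new_scan_result(tibble::tibble(
    marker1 = pairs$marker1, marker2 = pairs$marker2,
    estimate = est, variance = vv, statistic = w, df = 1L,
    p = stats::pchisq(w, 1L, lower.tail = FALSE), reason = reason),
    method)
}

.resolve_pairs <- function(ks, pairs) {
  if (is.null(pairs)) {
    M <- ks$M_epi %||% ks$M
    enumerate_pairs(ncol(M), marker_ids = colnames(M))
  } else pairs
}

#' Pairwise epistasis scan under the extended Q+K model
#'
#' For every pair (i, j) the model adds `m_i`, `m_j` and the product
#' `m_i * m_j` (elementwise) as fixed covariates under the one-kernel
#' null covariance (`V = I + lambda G`), and tests the product
#' coefficient by a Wald test on one degree of freedom (chi-square,
#' upper tail). Variance components come from the one-kernel null fit
#' (P3D).
#'
#' @param ph A [phenotype_table()].
#' @param ks A `kinship_set`.
#' @param pairs Pair tibble from [enumerate_pairs()], or `NULL` for all.
#' @param op One-kernel [projection_operator()].
#' @param vc Matching one-kernel `variance_components`.
#' @return A scan-result tibble (method `"QK_EPI"`).
#' @export
scan_epistasis_qk <- function(ph, ks, pairs = NULL, op, vc) {
  stopifnot(op$context == "one_kernel", vc$kind == "one_kernel")
  .pair_scan_engine(ph, ks, .resolve_pairs(ks, pairs), op, vc,
                    marginals = TRUE, method = "QK_EPI")
}

#' Pairwise epistasis scan under the Q+2K model
#'
#' As [scan_epistasis_qk()] but under the two-kernel covariance
#' `sigma_A2 G + sigma_AA2 H + sigma_e2 I`, so both the additive and the
#' epistatic polygenic background are controlled. Variance components
#' come from the two-kernel null fit (P3D).
#'
#' @inheritParams scan_epistasis_qk
#' @param op Epistatic-null [projection_operator()] (two-kernel).
#' @param vc Matching two-kernel `variance_components`.
#' @return A scan-result tibble (method `"Q2K_EPI"`).
#' @export
scan_epistasis_q2k <- function(ph, ks, pairs = NULL, op, vc) {
  stopifnot(op$context == "epistatic_null", vc$kind == "two_kernel")
  .pair_scan_engine(ph, ks, .resolve_pairs(ks, pairs), op, vc,
                    marginals = TRUE, method = "Q2K_EPI")
}

#' Pairwise epistasis scan by REMMA back-solving
#'
#' Back-solves the pairwise effects from one fitted extended-GBLUP
#' (two-kernel) null model. With `q = m_i * m_j` and `P = T/sigma_e2`:
#' `aa_hat = sigma_AA2 q'Py`, Henderson-sense variance
#' `Var(aa_hat) = sigma_AA2^2 q'Pq`, and Wald statistic
#' `w = (q'Py)^2 / (q'Pq)` on one degree of freedom. All pairs are
#' scored from the single null fit; no per-pair model fitting. The
#' projection form is algebraically identical to the
#' `Q'H^-1`-transform of the epistatic BLUP when `H` is invertible, but
#' never inverts `H`.
#'
#' @inheritParams scan_epistasis_q2k
#' @return A scan-result tibble (method `"REMMA"`).
#' @export
scan_epistasis_remma <- function(ph, ks, pairs = NULL, op, vc) {
  stopifnot(op$context == "epistatic_null", vc$kind == "two_kernel")
  pairs <- .resolve_pairs(ks, pairs)
  M <- ks$M_epi %||% ks$M
  s2e <- vc$sigma_e2; s2aa <- vc$sigma_AA2
  Py <- drop(op$T %*% ph$y) / s2e
  npair <- nrow(pairs)
  est <- vv <- w <- rep(NA_real_, npair)
  reason <- rep(NA_character_, npair)
  chunk <- 5000L
  for (lo in seq(1L, npair, by = chunk)) {
    hi <- min(lo + chunk - 1L, npair)
    ii <- pairs$i[lo:hi]; jj <- pairs$j[lo:hi]
    Q <- M[, ii, drop = FALSE] * M[, jj, drop = FALSE]
    qPy <- unname(drop(crossprod(Q, Py)))
    qPq <- unname(colSums(Q * (op$T %*% Q))) / s2e
    ok <- qPq > 1e-12
    g <- (lo:hi)[ok]
    est[g] <- (s2aa * qPy)[ok]
    vv[g] <- (s2aa^2 * qPq)[ok]
    w[g] <- (qPy^2 / qPq)[ok]
    reason[(lo:hi)[!ok]] <- "in_X_span_or_constant"
  }
  new_scan_result(tibble::tibble(
    marker1 = pairs$marker1, marker2 = pairs$marker2,
    estimate = est, variance = vv, statistic = w, df = 1L,
    p = stats::pchisq(w, 1L, lower.tail = FALSE), reason = reason),
    "REMMA")
}

#' Pairwise epistasis scan under the auxiliary fixed-effect model
#'
#' Tests each product column `q = m_i * m_j` as the only extra fixed
#' covariate (no marker main effects) under the two-kernel covariance.
#' Its Wald statistic is identical to the REMMA statistic for every
#' pair.
#'
#' @inheritParams scan_epistasis_q2k
#' @return A scan-result tibble (method `"AUX"`).
#' @export
scan_epistasis_auxiliary <- function(ph, ks, pairs = NULL, op, vc) {
  stopifnot(op$context == "epistatic_null", vc$kind == "two_kernel")
  .pair_scan_engine(ph, ks, .resolve_pairs(ks, pairs), op, vc,
                    marginals = FALSE, method = "AUX")
}

# REMMA through the printed H^-1 transform of the epistatic BLUP; only
# valid when H is invertible. Internal cross-check of the projection route.
.remma_via_H_inverse <- function(ph, ks, op, vc, pairs = NULL) {
  pairs <- .resolve_pairs(ks, pairs)
  pd <- build_pair_design(ks)
  keep <- match(paste(pairs$marker1, pairs$marker2),
                paste(pd$pairs$marker1, pd$pairs$marker2))
  Q <- pd$Q[, keep, drop = FALSE]
  bl <- blup_random(ph, ks, op, vc, component = "g_AA")
  Hinv <- solve(ks$H)
  aa <- unname(drop(crossprod(Q, Hinv %*% bl$ghat)))
  Vaa <- crossprod(Q, Hinv %*% bl$var_ghat %*% Hinv) %*% Q
  w <- unname(aa^2 / diag(Vaa))
  tibble::tibble(marker1 = pairs$marker1, marker2 = pairs$marker2,
                 estimate = aa, variance = unname(diag(Vaa)), statistic = w)
}
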