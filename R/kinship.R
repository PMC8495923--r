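#' Additive genomic relationship matrix
#'
#' Builds `G = MM'/c` from the coded marker matrix. With
#' `scaling = "raw"` the codings are used as-is and `c = 1`, the
#' convention of the theory underlying the scans. With
#' `scaling = "vanraden"` columns are centred by twice the allele
#' frequency and `c = 2 * sum(p_j (1 - p_j))`, the standard choice for
#' data analysis.
#'
#' The returned object carries the *effective* marker matrix
#' `M = (codings - centre) / sqrt(c)` so that `G = MM'` exactly; all
#' back-solving operations (GBLUP marker effects, REMMA pair effects)
#' and the epistatic matrix `H` are defined in terms of this same `M`.
#'
#' @param gm A [genotype_matrix()], imputed (no missing values).
#' @param scaling `"vanraden"` (default) or `"raw"`.
#' @return A `kinship_set`: list with `G`, `c`, `M`, `coding_note`,
#'   and (after [build_epistatic_grm()]) `H`.
#' @export
build_additive_grm <- function(gm, scaling = c("vanraden", "raw")) {
  scaling <- match.arg(scaling)
  stopifnot(inherits(gm, "genotype_matrix"))
  M <- gm$codings
  if (anyNA(M)) stop("impute_and_code() the genotypes first")
  if (ncol(M) == 0L) stop("no markers")
  if (scaling == "vanraden") {
    pj <- colMeans(M) / 2
    cc <- 2 * sum(pj * (1 - pj))
    if (cc <= 0) stop("all markers monomorphic: VanRaden scaling undefined")
    M <- sweep(M, 2L, 2 * pj) / sqrt(cc)
    note <- "vanraden: columns centred by 2p, scaled by 1/sqrt(2*sum(p(1-p)))"
  } else {
    cc <- 1
    note <- "raw: codings as supplied, c = 1"
  }
  G <- tcrossprod(M)
  dimnames(G) <- list(rownames(M), rownames(M))
  structure(list(G = G, c = cc, M = M, M_epi = gm$codings, H = NULL,
                 coding_note = note),
            class = "kinship_set")
}

#' @export
print.kinship_set <- function(x, ...) {
  cat(sprintf("<kinship_set> n = %d, p = %d markers; %s%s\n",
              nrow(x$G), ncol(x$M), x$coding_note,
              if (is.null(x$H)) "" else "; epistatic H present"))
  invisible(x)
}

#' Epistatic (additive-by-additive) genomic relationship matrix
#'
#' Computes `H = (G * G - (M*M)(M*M)') / 2` (elementwise products). For
#' any real coding of `M`, with `G = MM'`, this equals `QQ'`, where the
#' columns of `Q` are the elementwise products of distinct marker
#' columns of `M`.
#'
#' Which marker coding enters `H` (and hence the pairwise product
#' columns that all epistasis scans test) is controlled by `coding`:
#' `"raw"` (default) uses the allele-dosage codings as supplied -- the
#' convention of the epistatic-GRM literature, under which product
#' columns retain their correlation with the marker main effects --
#' while `"as_g"` reuses the centred/scaled matrix that defined the
#' additive `G`. The choice is recorded in `coding_note` and the coding
#' used is stored as `M_epi`.
#'
#' @param ks A `kinship_set` from [build_additive_grm()], or a plain
#'   marker matrix `M` (then `G = MM'` is formed internally and the
#'   `H` matrix itself is returned).
#' @param G Optional explicit `G`; must match `M` row-dimension.
#' @param coding `"raw"` or `"as_g"` (ignored for matrix input).
#' @return The `kinship_set` with `H` and `M_epi` filled in (or, for
#'   matrix input, the `H` matrix).
#' @export
build_epistatic_grm <- function(ks, G = NULL, coding = c("raw", "as_g")) {
  if (is.matrix(ks)) {
    M <- ks
    if (is.null(G)) G <- tcrossprod(M)
    if (nrow(M) != nrow(G)) stop("dimension mismatch between G and M")
    return(.epistatic_grm(M, G))
  }
  coding <- match.arg(coding)
  stopifnot(inherits(ks, "kinship_set"))
  if (!is.null(G) && nrow(G) != nrow(ks$M))
    stop("dimension mismatch between G and M")
  Me <- if (coding == "raw") ks$M_epi else ks$M
  ks$H <- .epistatic_grm(Me, if (is.null(G)) tcrossprod(Me) else G)
  ks$M_epi <- Me
  ks$coding_note <- paste0(ks$coding_note, "; H and pair products from ",
                           if (coding == "raw") "raw dosage codings"
                           else "the same coding as G")
  ks
}

.epistatic_grm <- function(M, G) {
  M2 <- M * M
  H <- 0.5 * (G * G - tcrossprod(M2))
  (H + t(H)) / 2
}

#' Explicit pairwise product design
#'
#' Builds the n x p(p-1)/2 matrix `Q` whose column for the pair (i, j),
#' i < j in lexicographic order, is the elementwise product of marker
#' columns i and j of the effective marker matrix. Intended for small p
#' (oracle checks of the identity `H = QQ'` and of the REMMA
#' back-solve); the implicit projection route should be used at scale.
#'
#' @param ks A `kinship_set` or a marker matrix.
#' @param restrict Optional marker IDs/indices restricting the pairs.
#' @param cap Maximum number of pairs allowed.
#' @return List with `Q` (matrix) and `pairs` (tibble `i`, `j`,
#'   `marker1`, `marker2`).
#' @export
build_pair_design <- function(ks, restrict = NULL, cap = 250000L) {
  M <- if (inherits(ks, "kinship_set")) (ks$M_epi %||% ks$M) else as.matrix(ks)
  p <- ncol(M)
  if (p < 2L) stop("need at least 2 markers to form pairs")
  pairs <- enumerate_pairs(p, restrict = restrict,
                           marker_ids = colnames(M))
  if (nrow(pairs) > cap)
    stop("pair design has ", nrow(pairs), " columns (> cap = ", cap,
         "); use the implicit REMMA path instead")
  Q <- M[, pairs$i, drop = FALSE] * M[, pairs$j, drop = FALSE]
  colnames(Q) <- paste(pairs$marker1, pairs$marker2, sep = ":")
  list(Q = Q, pairs = pairs)
}

#' Scale a kernel to mean diagonal one
#'
#' Returns `K * n / trace(K)`, so that variance components attached to
#' the kernel are on the per-record scale used for heritability.
#'
#' @param Kmat Symmetric kernel matrix with nonzero trace.
#' @return Rescaled matrix.
#' @export
standardize_kernel <- function(Kmat) {
  tr <- sum(diag(Kmat))
  if (!is.finite(tr) || tr == 0) stop("kernel has zero trace")
  Kmat * nrow(Kmat) / tr
}
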