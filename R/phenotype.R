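#' Construct a phenotype table
#'
#' Holds the phenotype vector and the fixed-covariate design matrix of a
#' single-record mixed model (each genotype has exactly one phenotypic
#' record, so the random-effect design is the identity).
#'
#' @param y Numeric n-vector of phenotypic records.
#' @param X n x k fixed-covariate design matrix; an intercept column is
#'   prepended when none is present.
#' @param samples Sample identifiers, length n.
#' @return An object of class `phenotype_table` with elements `y`, `X`,
#'   `samples`.
#' @export
phenotype_table <- function(y, X = NULL, samples = names(y)) {
  y <- as.numeric(y)
  n <- length(y)
  if (is.null(samples)) samples <- paste0("S", seq_len(n))
  if (is.null(X)) X <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  X <- as.matrix(X)
  if (nrow(X) != n) stop("X and y have different numbers of rows")
  has_icpt <- any(apply(X, 2L, function(v) max(v) == min(v) && v[1] != 0))
  if (!has_icpt)
    X <- cbind(`(Intercept)` = 1, X)
  if (qr(X)$rank < ncol(X)) stop("fixed-covariate matrix X is rank deficient")
  structure(list(y = y, X = X, samples = as.character(samples)),
            class = "phenotype_table")
}

#' @export
print.phenotype_table <- function(x, ...) {
  cat(sprintf("<phenotype_table> n = %d records, k = %d fixed covariates\n",
              length(x$y), ncol(x$X)))
  invisible(x)
}

#' Read a phenotype/covariate table
#'
#' Reads a TSV with a sample-ID column, picks one numeric trait column
#' and builds the fixed design `X = [intercept | covariates]`. Character
#' or factor covariates are expanded to treatment-contrast dummies.
#' When a [genotype_matrix()] is supplied the samples are reordered to
#' match it; phenotyped samples absent from the genotypes are dropped
#' with a warning.
#'
#' @param path TSV file path.
#' @param trait Name of the trait column.
#' @param covariates Character vector of covariate column names (may be
#'   empty: intercept-only design).
#' @param genotypes Optional [genotype_matrix()] to align samples with.
#' @param id_col Name of the sample-ID column; defaults to the first column.
#' @return A [phenotype_table()].
#' @export
read_phenotype_table <- function(path, trait, covariates = character(),
                                 genotypes = NULL, id_col = NULL) {
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  if (is.null(id_col)) id_col <- names(tab)[1L]
  stopifnot(trait %in% names(tab), all(covariates %in% names(tab)))
  yv <- tab[[trait]]
  if (!is.numeric(yv)) {
    num <- suppressWarnings(as.numeric(yv))
    if (anyNA(num) && !all(is.na(yv[is.na(num)])))
      stop("trait column '", trait, "' is not numeric")
    yv <- num
  }
  ids <- as.character(tab[[id_col]])
  keep <- !is.na(yv)
  if (!is.null(genotypes)) {
    gs <- rownames(genotypes$codings)
    absent <- setdiff(ids[keep], gs)
    if (length(absent) == sum(keep))
      stop("no phenotyped sample overlaps the genotype matrix")
    if (length(absent) > 0L)
      warning(length(absent), " phenotyped sample(s) absent from genotypes; dropped")
    keep <- keep & ids %in% gs
  }
  tab <- tab[keep, , drop = FALSE]
  ids <- ids[keep]; yv <- yv[keep]
  if (!is.null(genotypes)) {
    ord <- order(match(ids, rownames(genotypes$codings)))
    tab <- tab[ord, , drop = FALSE]; ids <- ids[ord]; yv <- yv[ord]
  }
  if (length(covariates) > 0L) {
    fml <- stats::as.formula(paste("~", paste(covariates, collapse = " + ")))
    X <- stats::model.matrix(fml, data = tab)
  } else {
    X <- matrix(1, length(yv), 1, dimnames = list(NULL, "(Intercept)"))
  }
  phenotype_table(yv, X, samples = ids)
}
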