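#' Construct a genotype matrix object
#'
#' Bundles an n x p matrix of numeric marker codings (rows = samples,
#' columns = biallelic markers) with an optional marker map giving the
#' chromosome and base-pair position of every marker.
#'
#' @param codings Numeric matrix with sample IDs as rownames and marker IDs
#'   as colnames. Missing genotypes are `NA`.
#' @param map Optional tibble/data frame with columns `marker`, `chrom`,
#'   `pos` (1-based base pairs). Row order must follow `colnames(codings)`.
#' @param imputed Logical; has `impute_and_code()` been applied?
#' @param monomorphic Optional logical vector flagging zero-variance columns.
#'
#' @return An object of class `genotype_matrix`: a list with elements
#'   `codings`, `map`, `imputed`, `monomorphic`.
#' @export
genotype_matrix <- function(codings, map = NULL, imputed = FALSE,
                            monomorphic = NULL) {
  codings <- as.matrix(codings)
  storage.mode(codings) <- "double"
  if (nrow(codings) < 2L) stop("genotype matrix needs at least 2 samples")
  if (ncol(codings) < 1L) stop("genotype matrix needs at least 1 marker")
  if (is.null(colnames(codings)))
    colnames(codings) <- paste0("M", seq_len(ncol(codings)))
  if (is.null(rownames(codings)))
    rownames(codings) <- paste0("S", seq_len(nrow(codings)))
  if (anyDuplicated(colnames(codings)))
    stop("duplicate marker IDs: ",
         paste(unique(colnames(codings)[duplicated(colnames(codings))]),
               collapse = ", "))
  if (!is.null(map)) {
    map <- tibble::as_tibble(map)
    stopifnot(all(c("marker", "chrom", "pos") %in% names(map)))
    if (!identical(as.character(map$marker), colnames(codings)))
      map <- map[match(colnames(codings), map$marker), , drop = FALSE]
    if (anyNA(map$marker))
      stop("marker map does not cover all genotyped markers")
    bad <- map |>
      dplyr::group_by(.data$chrom) |>
      dplyr::summarise(ok = !is.unsorted(.data$pos)) |>
      dplyr::filter(!.data$ok)
    if (nrow(bad) > 0L)
      stop("positions not non-decreasing on chromosome(s): ",
           paste(bad$chrom, collapse = ", "))
  }
  structure(list(codings = codings, map = map, imputed = imputed,
                 monomorphic = monomorphic),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d samples x %d markers%s%s\n",
              nrow(x$codings), ncol(x$codings),
              if (x$imputed) ", imputed" else "",
              if (is.null(x$map)) "" else ", mapped"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codings)

.missing_tokens <- c("NA", "nan", "-9", "")

#' Read a genotype matrix from disk
#'
#' Two dialects are supported: a plain TSV whose header row names the
#' markers and whose first column holds sample IDs, and the PLINK
#' `--recode A` (".raw") dialect, in which the first six columns are the
#' standard pedigree fields (only IID is kept, as the sample ID).
#' The tokens `NA`, `nan`, `-9` and the empty string are read as missing.
#'
#' @param path Path to the genotype file.
#' @param dialect `"tsv"` or `"plink_raw"`.
#' @param map Optional marker map (tibble with `marker`, `chrom`, `pos`),
#'   or a path to a TSV with those columns.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, dialect = c("tsv", "plink_raw"),
                                 map = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("genotype file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("genotype file has no data rows: ", path)
  split_re <- if (dialect == "tsv") "\t" else "[ \t]+"
  cells <- strsplit(lines, split_re)
  header <- cells[[1L]]
  body <- cells[-1L]
  if (dialect == "plink_raw") {
    if (length(header) < 7L) stop("plink_raw file has no marker columns")
    drop <- seq_len(6L)
    id_col <- 2L   # IID
    markers <- header[-drop]
  } else {
    # header may or may not carry a label for the sample-ID column
    n_fields <- length(cells[[2L]])
    if (length(header) == n_fields - 1L) {
      markers <- header
    } else {
      markers <- header[-1L]
    }
    drop <- 1L
    id_col <- 1L
  }
  p <- length(markers)
  want <- p + max(drop)
  n <- length(body)
  out <- matrix(NA_real_, n, p)
  ids <- character(n)
  for (r in seq_len(n)) {
    row <- body[[r]]
    if (length(row) != want)
      stop(sprintf(
        "format error at line %d of %s: %d fields where %d were expected",
        r + 1L, path, length(row), want))
    ids[r] <- row[id_col]
    vals <- row[-drop]
    vals[vals %in% .missing_tokens] <- NA_character_
    num <- suppressWarnings(as.numeric(vals))
    if (any(is.na(num) & !is.na(vals)))
      stop(sprintf("non-numeric genotype code at line %d of %s", r + 1L, path))
    out[r, ] <- num
  }
  rownames(out) <- ids
  colnames(out) <- markers
  if (is.character(map) && length(map) == 1L) map <- read_marker_map(map)
  genotype_matrix(out, map = map)
}

#' Read a marker map
#'
#' @param path TSV with columns `marker`, `chrom`, `pos`.
#' @return A tibble.
#' @export
read_marker_map <- function(path) {
  m <- readr::read_tsv(path, show_col_types = FALSE)
  stopifnot(all(c("marker", "chrom", "pos") %in% names(m)))
  m$pos <- as.integer(m$pos)
  m
}

#' Impute missing genotypes and optionally centre columns
#'
#' Missing codes are replaced by the column mean; with `center = TRUE`
#' each column is then shifted to mean zero. Zero-variance (monomorphic)
#' columns are retained and flagged in the `monomorphic` field. The
#' operation is idempotent.
#'
#' @param gm A [genotype_matrix()].
#' @param center Centre each column to mean zero?
#' @return The imputed [genotype_matrix()].
#' @export
impute_and_code <- function(gm, center = FALSE) {
  stopifnot(inherits(gm, "genotype_matrix"))
  M <- gm$codings
  all_missing <- colSums(!is.na(M)) == 0L
  if (any(all_missing))
    stop("marker(s) entirely missing: ",
         paste(colnames(M)[all_missing], collapse = ", "))
  if (anyNA(M)) {
    mu <- colMeans(M, na.rm = TRUE)
    idx <- which(is.na(M), arr.ind = TRUE)
    M[idx] <- mu[idx[, 2L]]
  }
  if (center) M <- sweep(M, 2L, colMeans(M))
  mono <- apply(M, 2L, function(x) max(x) - min(x) == 0)
  genotype_matrix(M, map = gm$map, imputed = TRUE, monomorphic = mono)
}

# affine-invariant minor-allele-frequency proxy used as the pruning
# tie-break; equals the dosage MAF for {0,1,2}/{0,2} columns spanning
# both homozygote classes
.maf_proxy <- function(M) {
  rng <- apply(M, 2L, range)
  span <- rng[2L, ] - rng[1L, ]
  f <- ifelse(span == 0, 0, (colMeans(M) - rng[1L, ]) / span)
  pmin(f, 1 - f)
}

#' Greedy LD pruning of markers
#'
#' Slides a window of `window` base pairs (half-open, advanced by `step`)
#' along each chromosome. Within a window, while any retained pair of
#' markers has squared Pearson correlation above `r2_threshold`, one
#' member is removed: the one with the lower minor-allele frequency
#' (affine-invariant proxy), ties broken by removing the later column.
#'
#' @param gm A [genotype_matrix()] with a map.
#' @param r2_threshold Squared-correlation threshold in (0, 1].
#' @param window Window size in base pairs.
#' @param step Step size in base pairs.
#' @return Character vector of surviving marker IDs, in map order.
#' @export
ld_prune <- function(gm, r2_threshold = 0.2, window = 1e6, step = 1e4) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$map)) stop("ld_prune requires a marker map")
  stopifnot(r2_threshold > 0, r2_threshold <= 1)
  if (window < step)
    warning("window smaller than step: some marker pairs are never compared")
  M <- gm$codings
  map <- gm$map
  maf <- .maf_proxy(M)
  keep <- rep(TRUE, ncol(M))
  names(keep) <- colnames(M)
  for (chr in unique(map$chrom)) {
    on_chr <- which(map$chrom == chr)
    pos <- map$pos[on_chr]
    start <- min(pos)
    repeat {
      in_win <- on_chr[pos >= start & pos < start + window]
      in_win <- in_win[keep[in_win]]
      if (length(in_win) >= 2L) {
        repeat {
          cc <- suppressWarnings(stats::cor(M[, in_win, drop = FALSE]))
          cc[!is.finite(cc)] <- 0
          r2 <- cc^2
          diag(r2) <- 0
          if (max(r2) <= r2_threshold) break
          viol <- which(r2 == max(r2), arr.ind = TRUE)[1L, ]
          a <- in_win[viol[1L]]; b <- in_win[viol[2L]]
          drop <- if (maf[a] < maf[b]) a
                  else if (maf[b] < maf[a]) b
                  else max(a, b)
          keep[drop] <- FALSE
          in_win <- setdiff(in_win, drop)
          if (length(in_win) < 2L) break
        }
      }
      start <- start + step
      if (start > max(pos)) break
    }
  }
  colnames(M)[keep]
}
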