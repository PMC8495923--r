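#' Threshold-filtered correlation of two scans' -log10(p) values
#'
#' Keeps the marker pairs (or markers) whose `-log10(p)` exceeds the
#' threshold `d` in *at least one* of the two scans, then computes the
#' Pearson correlation of the `-log10(p)` values over the retained
#' tests. Tests with `NA` in either scan are excluded listwise. Fewer
#' than `min_pairs` retained tests give `r = NA` (a correlation over a
#' handful of points is meaningless).
#'
#' @param resA,resB Scan-result tibbles over identical keys, in the
#'   same order.
#' @param d Threshold on `-log10(p)` (0 keeps everything finite).
#' @param min_pairs Minimum retained tests for a non-NA correlation.
#' @return One-row tibble: `method_pair`, `d`, `r`, `n_pairs_used`.
#' @export
filtered_correlation <- function(resA, resB, d = 0, min_pairs = 10) {
  keysA <- do.call(paste, resA[intersect(c("marker", "marker1", "marker2"),
                                         names(resA))])
  keysB <- do.call(paste, resB[intersect(c("marker", "marker1", "marker2"),
                                         names(resB))])
  if (!identical(keysA, keysB)) stop("scan results have different keys")
  la <- -log10(resA$p); lb <- -log10(resB$p)
  ok <- is.finite(la) & is.finite(lb)
  keep <- ok & (pmax(la, lb) > d)
  nk <- sum(keep)
  r <- if (nk >= min_pairs) stats::cor(la[keep], lb[keep]) else NA_real_
  tibble::tibble(
    method_pair = paste(resA$method[1L], resB$method[1L], sep = "-"),
    d = d, r = r, n_pairs_used = nk)
}

#' Heritability classes
#'
#' Bins estimated broad-sense heritabilities into the three classes
#' used for stratified trend analysis: `high` (`h2 >= 0.7`), `mid`
#' (`0.4 <= h2 < 0.7`), `low` (`h2 < 0.4`).
#'
#' @param h2 Numeric vector of heritabilities.
#' @return Factor with levels `low`, `mid`, `high`.
#' @export
classify_by_h2 <- function(h2) {
  cut(h2, breaks = c(-Inf, 0.4, 0.7, Inf), labels = c("low", "mid", "high"),
      right = FALSE)
}

.signif_stars <- function(p) {
  dplyr::case_when(p < 0.01 ~ "***", p < 0.05 ~ "**", p < 0.1 ~ "*",
                   TRUE ~ "")
}

#' Trend of between-model similarity against the variance-component ratio
#'
#' Given per-dataset records (one row per simulated dataset with its
#' estimated `log2(sigma_A2/sigma_AA2)` and the correlation `r` between
#' two models' `-log10(p)` values in that dataset), computes the
#' Pearson correlation of `r` against `est_log2_ratio`, with a
#' two-sided p-value from the t transform and a significance class
#' (`*` p < 0.1, `**` p < 0.05, `***` p < 0.01).
#'
#' @param records Tibble with columns `est_log2_ratio` and `r` (and
#'   optionally `h2_class`).
#' @param h2_class Optional class label to filter `records` to.
#' @return One-row tibble: `h2_class`, `n`, `trend_r`, `p`, `signif`.
#' @export
trend_analysis <- function(records, h2_class = NULL) {
  if (!is.null(h2_class) && "h2_class" %in% names(records))
    records <- records[records$h2_class == h2_class, , drop = FALSE]
  records <- records[is.finite(records$r) &
                       is.finite(records$est_log2_ratio), , drop = FALSE]
  n <- nrow(records)
  if (n < 3L || stats::sd(records$r) == 0 ||
      stats::sd(records$est_log2_ratio) == 0) {
    return(tibble::tibble(h2_class = h2_class %||% "all", n = n,
                          trend_r = NA_real_, p = NA_real_, signif = NA_character_))
  }
  ct <- stats::cor.test(records$est_log2_ratio, records$r)
  tibble::tibble(h2_class = h2_class %||% "all", n = n,
                 trend_r = unname(ct$estimate), p = ct$p.value,
                 signif = .signif_stars(ct$p.value))
}

#' @importFrom rlang %||% .data
NULL

#' Scatter plot of per-dataset similarity against log2 ratio
#'
#' @param records Tibble with `est_log2_ratio`, `r`, and optionally
#'   `method_pair` / `d` facets.
#' @return A ggplot object.
#' @export
plot_trend <- function(records) {
  gg <- ggplot2::ggplot(records,
                        ggplot2::aes(x = .data$est_log2_ratio, y = .data$r)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         linewidth = 0.5) +
    ggplot2::labs(x = expression(log[2](sigma[A]^2 / sigma[AA]^2)),
                  y = "correlation of -log10(p) between models") +
    ggplot2::theme_minimal()
  if (all(c("method_pair", "d") %in% names(records)))
    gg <- gg + ggplot2::facet_grid(method_pair ~ d, labeller = "label_both")
  gg
}
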