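new_scan_result <- function(tbl, method) {
  tbl$method <- method
  class(tbl) <- c("scan_result", class(tibble::tibble()))
  tbl
}

#' Write scan results to a TSV
#'
#' Columns: `marker` (or `marker1`, `marker2` for pair scans, or
#' `window`), `estimate`, `variance`, `statistic`, `df`, `p`,
#' `neglog10p`. Row order is the scan order (map order for markers,
#' lexicographic pair order for pairs); skipped entries are kept with
#' `NA` tokens.
#'
#' @param res A scan-result tibble.
#' @param path Output path.
#' @export
write_scan_results <- function(res, path) {
  key_cols <- intersect(c("marker", "marker1", "marker2", "window"),
                        names(res))
  out <- res[, c(key_cols, "estimate", "variance", "statistic", "df", "p")]
  out$neglog10p <- -log10(res$p)
  readr::write_tsv(out, path)
}

#' Read back a scan-result TSV
#'
#' @param path Path written by [write_scan_results()].
#' @return A tibble.
#' @export
read_scan_results <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE)
}

#' @export
print.scan_result <- function(x, ...) {
  cat(sprintf("<scan_result> method = %s, %d tests (%d NA)\n",
              x$method[1L], nrow(x), sum(is.na(x$statistic))))
  NextMethod()
}

#' Manhattan-style plot of a scan result
#'
#' Plots `-log10(p)` against test index (map order for single markers,
#' lexicographic order for pairs).
#'
#' @param object A scan-result tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scan_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$index <- seq_len(nrow(df))
  df$neglog10p <- -log10(df$p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$index, y = .data$neglog10p)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.8) +
    ggplot2::labs(x = "test (scan order)", y = expression(-log[10](p)),
                  title = unique(df$method)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Scatter comparison of two scans' -log10(p) values
#'
#' @param resA,resB Scan results over identical keys.
#' @return A ggplot object.
#' @export
plot_method_agreement <- function(resA, resB) {
  df <- tibble::tibble(a = -log10(resA$p), b = -log10(resB$p))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = paste0("-log10(p), ", resA$method[1L]),
                  y = paste0("-log10(p), ", resB$method[1L])) +
    ggplot2::theme_minimal()
}
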