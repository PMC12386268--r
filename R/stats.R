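# Chi-square homogeneity test and median/IQR group summaries.

#' Pearson chi-square test of homogeneity
#'
#' Classic Pearson statistic `sum((O - E)^2 / E)` with expected counts
#' from the row/column margins, no continuity correction, and the upper
#' chi-square tail at `(rows - 1) * (cols - 1)` degrees of freedom. Used
#' to compare FUCCI cell-cycle state distributions between conditions.
#'
#' @param observed Matrix (or table) of nonnegative counts, at least 2x2.
#' @return Object of class `chi_square_result` with `statistic`, `df`,
#'   `p_value` and `expected`.
#' @examples
#' chi_square_test(rbind(c(20, 5), c(10, 15)))
#' @export
chi_square_test <- function(observed) {
  observed <- as.matrix(observed)
  if (nrow(observed) < 2 || ncol(observed) < 2) {
    stop("need at least a 2x2 table", call. = FALSE)
  }
  if (any(observed < 0)) stop("counts must be nonnegative", call. = FALSE)
  rs <- rowSums(observed); cs <- colSums(observed)
  if (any(rs == 0)) {
    bad <- rownames(observed)[rs == 0] %||% which(rs == 0)
    stop(sprintf("degenerate table: row margin zero for %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  if (any(cs == 0)) {
    bad <- colnames(observed)[cs == 0] %||% which(cs == 0)
    stop(sprintf("degenerate table: column margin zero for %s",
                 paste(bad, collapse = ", ")), call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(observed)
  stat <- sum((observed - expected)^2 / expected)
  df <- (nrow(observed) - 1) * (ncol(observed) - 1)
  structure(
    list(statistic = stat, df = df,
         p_value = stats::pchisq(stat, df, lower.tail = FALSE),
         expected = expected),
    class = "chi_square_result")
}

#' @export
print.chi_square_result <- function(x, ...) {
  cat(sprintf("Pearson chi-square: X^2 = %.4g, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' Median and interquartile summaries per group
#'
#' Quartiles use the inclusive linear-interpolation convention
#' (`stats::quantile` type 7). Output rows follow the canonical group
#' order Control, Uniform, In-field, Out-of-field; other groups are
#' appended alphabetically.
#'
#' @param values Numeric vector of per-cell metric values.
#' @param groups Group label per value.
#' @return Tibble with `group`, `n`, `median`, `q1`, `q3`.
#' @export
summarize_groups <- function(values, groups) {
  stopifnot(length(values) == length(groups))
  gs <- unique(as.character(groups))
  ordered <- c(intersect(.group_order, gs),
               sort(setdiff(gs, .group_order)))
  rows <- lapply(ordered, function(g) {
    v <- values[groups == g]
    if (length(v) == 0) stop(sprintf("group '%s' is empty", g), call. = FALSE)
    q <- stats::quantile(v, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    tibble::tibble(group = g, n = length(v), median = q[2], q1 = q[1],
                   q3 = q[3])
  })
  dplyr::bind_rows(rows)
}
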