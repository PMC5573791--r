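#' Two-sample Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples, the workhorse test for
#' differential-abundance calls throughout the pipeline. Uses the exact null
#' distribution when the combined sample size is at most `exact_limit` and
#' there are no ties, and the tie-corrected normal approximation otherwise.
#'
#' @param x,y Numeric vectors, each of length >= 1.
#' @param exact Force exact (`TRUE`) or normal-approximation (`FALSE`) mode;
#'   `NULL` (default) switches on combined size and presence of ties.
#' @param exact_limit Combined-size cutoff for automatic exact mode.
#' @return A `test_result` list: `statistic` (U for the first sample),
#'   `p_value` (two-sided), `method`.
#' @examples
#' mann_whitney_test(c(1, 2, 3), c(4, 5, 6))$p_value  # exact, 0.1
#' @export
mann_whitney_test <- function(x, y, exact = NULL, exact_limit = 20L) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 1L || length(y) < 1L)
    stop("both samples must be non-empty", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed", call. = FALSE)
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  # degenerate: no variation at all -> no evidence against the null
  if (length(unique(pooled)) == 1L)
    return(test_result(n * m / 2, 1, "mann_whitney"))
  ties <- anyDuplicated(pooled) > 0L
  if (is.null(exact)) exact <- (n + m <= exact_limit) && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)
  )
  p <- min(1, ht$p.value)
  test_result(unname(ht$statistic), p, "mann_whitney")
}

#' Benjamini-Hochberg false discovery rate
#'
#' Step-up q-values: q_i = min over p_(j) >= p_(i) of m * p_(j) / j, capped
#' at 1, returned in the input order.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return A `q_values` list with `p_values` and `q_values` (same order).
#' @export
bh_fdr <- function(p_values) {
  p <- as.numeric(p_values)
  if (length(p) == 0L) stop("empty p-value vector", call. = FALSE)
  if (anyNA(p) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  structure(list(p_values = p, q_values = q), class = "q_values")
}

#' Yates continuity-corrected chi-square test on a 2x2 table
#'
#' @param table 2x2 matrix of non-negative integer counts; both margins
#'   must be positive.
#' @return A `test_result` with the corrected chi-square statistic (1 df)
#'   and two-sided p-value.
#' @examples
#' chi_square_yates(matrix(c(25, 28, 35, 32), 2))  # Table-1-style gender split
#' @export
chi_square_yates <- function(table) {
  tab <- .check_2x2(table)
  ht <- suppressWarnings(stats::chisq.test(tab, correct = TRUE))
  test_result(unname(ht$statistic), unname(ht$p.value), "chi_square_yates")
}

#' Fisher's exact test on a 2x2 table
#'
#' The categorical test adopted for cohort-characteristics tables
#' (gender, smoking): on printed case/control splits it reproduces the
#' reference p-values to three decimals, which the continuity-corrected
#' chi-square does not quite manage for unbalanced tables.
#'
#' @inheritParams chi_square_yates
#' @return A `test_result`; `statistic` is the sample odds ratio.
#' @export
fisher_exact <- function(table) {
  tab <- .check_2x2(table)
  ht <- stats::fisher.test(tab)
  test_result(unname(ht$estimate), unname(ht$p.value), "fisher_exact")
}

.check_2x2 <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(2L, 2L))) stop("need a 2x2 table", call. = FALSE)
  if (anyNA(tab) || any(tab < 0) || any(tab != round(tab)))
    stop("cells must be non-negative integers", call. = FALSE)
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("all margins must be positive", call. = FALSE)
  tab
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks for ties). Constant
#' input is an error rather than a silent zero: an undefined correlation
#' must not look like "no association".
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return Correlation in \[-1, 1\].
#' @export
spearman_rho <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y)) stop("lengths differ", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (anyNA(x) || anyNA(y)) stop("NA values not allowed", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined for constant input", call. = FALSE)
  stats::cor(x, y, method = "spearman")
}

#' @rdname mann_whitney_test
#' @param statistic,p_value,method Fields of the result record.
#' @export
test_result <- function(statistic, p_value, method) {
  stopifnot(is.finite(statistic), p_value >= 0, p_value <= 1)
  structure(list(statistic = statistic, p_value = p_value, method = method),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  invisible(x)
}
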