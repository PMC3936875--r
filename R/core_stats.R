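#' Benjamini-Hochberg step-up adjustment, with top-slice support
#'
#' Adjusts raw p-values for multiple testing by the Benjamini-Hochberg
#' step-up procedure. Unlike a plain call over a full vector, `m_total`
#' may exceed `length(p)`: when only the k smallest of m raw p-values are
#' available (e.g. a published top-30 table out of 485,577 array probes),
#' the step-up rule is still exact for the supplied slice because adjusted
#' values are non-decreasing in rank. The caller asserts that the slice
#' contains the `length(p)` smallest raw p-values of the full family.
#'
#' @param p Numeric vector of raw p-values, each in \[0, 1\].
#' @param m_total Total number of tests the adjustment is over; defaults to
#'   `length(p)` and must be at least `length(p)`.
#' @return Numeric vector of BH-adjusted p-values aligned to the input
#'   order, each capped at 1.
#' @examples
#' bh_adjust(c(0.01, 0.02, 0.03, 0.04))        # all 0.04
#' bh_adjust(c(1e-6, 2e-4), m_total = 1000)    # top slice of a larger family
#' @export
bh_adjust <- function(p, m_total = length(p)) {
  if (length(p) == 0L) stop("`p` must be non-empty")
  if (anyNA(p) || any(p < 0 | p > 1)) {
    stop("raw p-values must lie in [0, 1] with no missing values")
  }
  if (length(m_total) != 1L || !is.finite(m_total) || m_total < length(p)) {
    stop("`m_total` must be a single number >= length(p)")
  }
  stats::p.adjust(p, method = "BH", n = as.integer(m_total))
}

#' Unpaired two-sample t-test
#'
#' Classical unpaired t-test between two numeric vectors; pooled-variance
#' (Student) by default, Welch behind `equal_variance = FALSE`. The t sign
#' follows `mean(x) - mean(y)`. When both groups have zero variance and
#' equal means the test is degenerate and `p = 1`, `t = 0` by convention;
#' zero pooled variance with unequal means is an error.
#'
#' @param x,y Numeric vectors, each of length >= 2.
#' @param equal_variance Use the pooled-variance statistic (default `TRUE`).
#' @return A list with elements `t` (statistic), `p` (two-sided p-value),
#'   `df` (degrees of freedom) and `n` (`c(length(x), length(y))`).
#' @export
unpaired_t_test <- function(x, y, equal_variance = TRUE) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) < 2L || length(y) < 2L) {
    stop("each group needs at least 2 non-missing values")
  }
  vx <- stats::var(x)
  vy <- stats::var(y)
  if (vx == 0 && vy == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, p = 1,
                  df = length(x) + length(y) - 2L,
                  n = c(length(x), length(y))))
    }
    stop("zero variance in both groups with unequal means: t undefined")
  }
  ht <- stats::t.test(x, y, var.equal = equal_variance)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), n = c(length(x), length(y)))
}

#' Hypergeometric upper-tail probability
#'
#' P(X >= overlap) for X ~ Hypergeometric(universe_size, category_size,
#' selected_size): the chance of drawing at least `overlap` category members
#' in a draw of `selected_size` from the universe. The over-representation
#' p-value used in GO enrichment.
#'
#' @param overlap Observed number of category members in the selection.
#' @param category_size Number of universe members in the category.
#' @param selected_size Size of the selection (query).
#' @param universe_size Size of the universe.
#' @return Upper-tail probability in (0, 1].
#' @export
hypergeom_tail <- function(overlap, category_size, selected_size,
                           universe_size) {
  args <- c(overlap, category_size, selected_size, universe_size)
  if (anyNA(args) || any(args < 0) || any(args != round(args))) {
    stop("all arguments must be non-negative integers")
  }
  if (category_size > universe_size || selected_size > universe_size) {
    stop("category and selection cannot exceed the universe")
  }
  if (overlap > min(category_size, selected_size)) {
    stop("`overlap` cannot exceed min(category_size, selected_size)")
  }
  stats::phyper(overlap - 1, category_size, universe_size - category_size,
                selected_size, lower.tail = FALSE)
}

#' Pearson product-moment correlation
#'
#' @param x,y Equal-length numeric vectors (length >= 3), both non-constant.
#' @return Correlation coefficient in \[-1, 1\].
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y)) stop("`x` and `y` must have equal length")
  keep <- !(is.na(x) | is.na(y))
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("need at least 3 paired values")
  if (stats::var(x) == 0 || stats::var(y) == 0) {
    stop("correlation undefined for a constant vector")
  }
  stats::cor(x, y)
}
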