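# Shared statistical primitives used by every analysis stage.

#' Correlation between two numeric vectors with a t-based p-value
#'
#' Computes Pearson's product-moment correlation or Spearman's rank
#' correlation (average ranks for ties) together with a two-sided p-value
#' from the t approximation `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom. The same t approximation is used for both methods so
#' that Pearson and Spearman scans are directly comparable; for Spearman at
#' the cohort sizes this package targets (n in the tens) the approximation
#' is standard practice.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   nonzero variance.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return An object of class `obrisk_cor`: a list with elements `method`,
#'   `r`, `p_value` and `n`.
#' @examples
#' correlate(1:10, (1:10)^2, method = "spearman")$r  # exactly 1
#' @export
correlate <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  x <- as.numeric(x)
  y <- as.numeric(y)
  if (length(x) != length(y)) {
    stop("x and y must have equal length", call. = FALSE)
  }
  ok <- stats::complete.cases(x, y)
  x <- x[ok]
  y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("undefined correlation: input has zero variance", call. = FALSE)
  }
  if (method == "spearman") {
    x <- rank(x)
    y <- rank(y)
  }
  r <- stats::cor(x, y)
  structure(
    list(method = method, r = r, p_value = .cor_p(r, n), n = n),
    class = "obrisk_cor"
  )
}

# Two-sided p for a correlation coefficient via the t transform.
.cor_p <- function(r, n) {
  if (abs(r) >= 1) return(0)
  t_stat <- r * sqrt((n - 2) / (1 - r^2))
  2 * stats::pt(-abs(t_stat), df = n - 2)
}

#' @export
print.obrisk_cor <- function(x, ...) {
  cat(sprintf("%s correlation: r = %.4f, p = %.4g (n = %d)\n",
              x$method, x$r, x$p_value, x$n))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate adjustment: for sorted p-values
#' p(1) <= ... <= p(m), the adjusted value at rank i is
#' `min over j >= i of min(1, m * p(j) / j)`, returned in input order.
#' Delegates to [stats::p.adjust()].
#'
#' @param p Numeric vector of p-values in \[0, 1\]. `NA`s are propagated
#'   and excluded from the family size.
#' @return Adjusted p-values in the input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = "BH")
}

#' One-way analysis of variance with a minimum group size rule
#'
#' Standard one-way fixed-effects ANOVA of `values` across the levels of
#' `groups`. Groups with fewer than `min_group_size` observations are
#' dropped before testing; if fewer than two groups remain the result is
#' flagged not testable (`testable = FALSE`) and carries `NA` statistics,
#' so it can be excluded from downstream multiple-testing families.
#'
#' @param values Numeric response vector.
#' @param groups Grouping vector (coerced to factor), same length.
#' @param min_group_size Minimum observations a group needs to enter the
#'   test (default 2; the F statistic needs within-group variance).
#' @return An object of class `obrisk_anova`: list with `f_stat`,
#'   `p_value`, `group_sizes` (named, post-filter), `df_between`,
#'   `df_within`, `testable` and `dropped_groups`.
#' @export
one_way_anova <- function(values, groups, min_group_size = 2L) {
  values <- as.numeric(values)
  groups <- factor(groups)
  if (length(values) != length(groups)) {
    stop("values and groups must have equal length", call. = FALSE)
  }
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- droplevels(groups[ok])
  sizes <- table(groups)
  keep <- names(sizes)[sizes >= min_group_size]
  dropped <- setdiff(levels(groups), keep)
  sel <- groups %in% keep
  values <- values[sel]
  groups <- droplevels(groups[sel])
  sizes <- table(groups)

  not_testable <- function(reason) {
    structure(
      list(f_stat = NA_real_, p_value = NA_real_,
           group_sizes = as.integer(sizes),
           df_between = NA_integer_, df_within = NA_integer_,
           testable = FALSE, dropped_groups = dropped, reason = reason),
      class = "obrisk_anova"
    )
  }
  if (nlevels(groups) < 2L) return(not_testable("fewer than 2 eligible groups"))
  if (stats::sd(values) == 0) return(not_testable("zero overall variance"))

  fit <- stats::lm(values ~ groups)
  tab <- stats::anova(fit)
  structure(
    list(f_stat = tab[["F value"]][1L],
         p_value = tab[["Pr(>F)"]][1L],
         group_sizes = stats::setNames(as.integer(sizes), names(sizes)),
         df_between = tab[["Df"]][1L],
         df_within = tab[["Df"]][2L],
         testable = TRUE, dropped_groups = dropped, reason = NULL),
    class = "obrisk_anova"
  )
}

#' @export
print.obrisk_anova <- function(x, ...) {
  if (!x$testable) {
    cat("one-way ANOVA: not testable (", x$reason, ")\n", sep = "")
  } else {
    cat(sprintf("one-way ANOVA: F(%d, %d) = %.4f, p = %.4g\n",
                x$df_between, x$df_within, x$f_stat, x$p_value))
  }
  invisible(x)
}

#' Adjusted R-squared
#'
#' `1 - (1 - r2) * (n - 1) / (n - p - 1)` for a model with `n_predictors`
#' slope terms fitted to `n` observations.
#'
#' @param r2 Coefficient of determination in \[0, 1\].
#' @param n Number of observations; must exceed `n_predictors + 1`.
#' @param n_predictors Number of predictors (excluding the intercept).
#' @return The penalized R-squared (can be negative).
#' @export
adjusted_r2 <- function(r2, n, n_predictors) {
  if (r2 < 0 || r2 > 1) stop("r2 must lie in [0, 1]", call. = FALSE)
  if (n <= n_predictors + 1) {
    stop("need n > n_predictors + 1", call. = FALSE)
  }
  1 - (1 - r2) * (n - 1) / (n - n_predictors - 1)
}
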