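#' Pearson correlation report
#'
#' Product-moment correlation with the quantities reported alongside it in
#' correlation tables: \eqn{r}, \eqn{r^2}, the two-sided p-value from the
#' t-transform with `n - 2` degrees of freedom, and a confidence interval
#' for \eqn{r} from the Fisher z-transform (reported for r, not for a
#' regression slope). At `n = 3` the Fisher interval is the whole of
#' `[-1, 1]` (its standard error `1/sqrt(n - 3)` diverges).
#'
#' @param data Optional data frame; when supplied, `x` and `y` are column
#'   selections evaluated in it.
#' @param x,y Numeric vectors (or columns of `data`), equal length,
#'   `n >= 3`, neither constant.
#' @param conf_level Confidence level for the Fisher interval.
#' @return A one-row tibble with columns `r`, `r2`, `p`, `ci_low`,
#'   `ci_high`, `n`.
#' @examples
#' pearson_report(x = c(1, 2, 3, 4, 5), y = c(2, 1, 4, 3, 5))
#' @export
pearson_report <- function(data = NULL, x, y, conf_level = 0.95) {
  if (!is.null(data)) {
    stopifnot(is.data.frame(data))
    x <- dplyr::pull(data, {{ x }})
    y <- dplyr::pull(data, {{ y }})
  }
  if (!is.numeric(x) || !is.numeric(y)) {
    abort("x and y must be numeric", class = "bw_error")
  }
  if (length(x) != length(y)) {
    abort("x and y must have equal length", class = "bw_error")
  }
  n <- length(x)
  if (n < 3L) abort("need at least 3 pairs", class = "bw_error")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("constant input has no defined correlation", class = "bw_error")
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  r <- unname(ct$estimate)
  if (abs(r) >= 1 - 1e-15) {
    ci <- c(r, r)
  } else if (n == 3L) {
    ci <- c(-1, 1)
  } else {
    z <- atanh(r)
    hw <- qnorm(1 - (1 - conf_level) / 2) / sqrt(n - 3)
    ci <- tanh(c(z - hw, z + hw))
  }
  tibble(r = r, r2 = r^2, p = unname(ct$p.value),
         ci_low = ci[1], ci_high = ci[2], n = n)
}

#' Cohen's d standardized effect size
#'
#' Difference of group means over the pooled standard deviation; used to
#' compare how well the Gabor+FFT index and the FFT-only baseline separate
#' adjacent degradation levels.
#'
#' @param x,y Numeric vectors (two groups), each of length >= 2.
#' @return A scalar; positive when `mean(x) > mean(y)`.
#' @export
cohens_d <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    abort("each group needs at least 2 observations", class = "bw_error")
  }
  nx <- length(x)
  ny <- length(y)
  sp2 <- ((nx - 1) * var(x) + (ny - 1) * var(y)) / (nx + ny - 2)
  if (sp2 == 0) {
    abort("zero pooled variance", class = "bw_error")
  }
  (mean(x) - mean(y)) / sqrt(sp2)
}
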