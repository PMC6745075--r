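#' Column statistics for a concentration vector
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator).
#' Non-detects should already have been substituted per the active policy
#' before the values reach this function.
#'
#' @param values Numeric vector with at least one value.
#' @return A one-row tibble with `n`, `mean`, `sd` (`sd` is `NA` for a
#'   single value).
#' @export
column_stats <- function(values) {
  if (length(values) == 0 || anyNA(values)) {
    stop("need at least one non-missing value", call. = FALSE)
  }
  tibble::tibble(
    n = length(values),
    mean = mean(values),
    sd = if (length(values) >= 2) stats::sd(values) else NA_real_
  )
}

#' Tie-corrected Kruskal-Wallis test
#'
#' Rank-based k-group test of identical distributions, used to probe
#' spatial variation of metal concentrations across stations or sites. The
#' tie-corrected statistic is
#' `H = [12 / (N (N + 1)) * sum(R_j^2 / n_j) - 3 (N + 1)] / C` with tie
#' correction `C = 1 - sum(t^3 - t) / (N^3 - N)`, referred to the upper
#' tail of a chi-square law with `k - 1` degrees of freedom. The statistic
#' and p-value are those of [stats::kruskal.test()]; the tie-correction
#' factor is reported alongside for auditability, and the fully degenerate
#' case in which all observations tie (`C = 0`) is defined as `H = 0`,
#' `p = 1`.
#'
#' @param data A data frame with one observation per row.
#' @param value Column of observations (tidy-eval).
#' @param group Column of group labels (tidy-eval); at least two groups,
#'   each non-empty, total N >= 3.
#'
#' @return A one-row tibble with `H`, `df`, `p`, and `tie_correction`.
#' @export
#' @examples
#' d <- tibble::tibble(conc = c(1, 2, 3, 4, 5, 6),
#'                     site = rep(c("a", "b"), each = 3))
#' kruskal_wallis(d, conc, site)
kruskal_wallis <- function(data, value, group) {
  x <- dplyr::pull(data, {{ value }})
  g <- factor(dplyr::pull(data, {{ group }}))
  if (anyNA(x) || anyNA(g)) stop("missing observations or labels", call. = FALSE)
  k <- nlevels(g)
  if (k < 2) stop("need at least two groups", call. = FALSE)
  n <- length(x)
  if (n < 3) stop("need at least three observations in total", call. = FALSE)

  ties <- table(x)
  tie_correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  if (tie_correction == 0) {
    return(tibble::tibble(H = 0, df = k - 1, p = 1, tie_correction = 0))
  }
  kt <- stats::kruskal.test(x, g)
  tibble::tibble(
    H = unname(kt$statistic),
    df = unname(kt$parameter),
    p = unname(kt$p.value),
    tie_correction = tie_correction
  )
}
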