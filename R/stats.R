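#' Nonparametric group comparisons
#'
#' Rank-based tests with effect sizes as used for swim-parameter group
#' comparisons: Kruskal-Wallis with epsilon-squared, Holm-Bonferroni
#' multiplicity correction, Mann-Whitney U with rank-biserial r, and
#' Fisher's exact test for categorical tables.
#'
#' @name group_stats
NULL

#' Kruskal-Wallis test with epsilon-squared effect size
#'
#' Tie-corrected rank-based H statistic (via [stats::kruskal.test()])
#' with the epsilon-squared effect size eps2 = H * (n + 1) / (n^2 - 1)
#' = H / (n - 1), n the total number of observations. Degenerate input
#' (all values identical) yields H = 0, eps2 = 0, p = 1.
#'
#' @param values numeric vector of observations.
#' @param groups factor/vector of group labels (>= 2 groups, each n >= 2).
#' @param covariates optional data frame of covariates (e.g. age, BMI);
#'   when given, the test runs on residuals of a rank-on-rank linear
#'   adjustment of `values` on the covariates.
#' @return list `H`, `df`, `p`, `epsilon2`, `n`.
#' @export
kruskal_epsilon2 <- function(values, groups, covariates = NULL) {
  groups <- factor(groups)
  stopifnot(nlevels(groups) >= 2, all(table(groups) >= 2))
  if (!is.null(covariates)) {
    rk <- data.frame(lapply(as.data.frame(covariates), rank))
    values <- stats::residuals(stats::lm(rank(values) ~ ., data = rk))
  }
  n <- length(values)
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p = 1, epsilon2 = 0, n = n))
  kt <- stats::kruskal.test(values, groups)
  H <- unname(kt$statistic)
  list(H = H, df = unname(kt$parameter), p = kt$p.value,
       epsilon2 = min(1, H * (n + 1) / (n^2 - 1)), n = n)
}

#' Holm-Bonferroni step-down adjustment
#'
#' Step-down adjusted p-values: monotone, capped at 1, always >= raw.
#'
#' @param p numeric vector of raw p-values in \[0, 1\].
#' @return adjusted p-values in input order.
#' @export
holm_bonferroni <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  stats::p.adjust(p, method = "holm")
}

#' Mann-Whitney U test with rank-biserial correlation
#'
#' Tie-corrected U test (via [stats::wilcox.test()], normal approximation
#' with continuity correction for larger samples, exact otherwise). U
#' counts pairs in which x exceeds y (ties count one half). The
#' rank-biserial correlation r = 2U/(n_x n_y) - 1 is +1 when every x
#' exceeds every y and 0 for complete overlap.
#'
#' @param x,y numeric samples (nonempty).
#' @return list `U`, `p`, `r`, `n_x`, `n_y`.
#' @export
mann_whitney_r <- function(x, y) {
  if (length(x) < 1 || length(y) < 1) stop("empty group")
  wt <- suppressWarnings(stats::wilcox.test(x, y))
  U <- unname(wt$statistic)
  list(U = U, p = wt$p.value, r = 2 * U / (length(x) * length(y)) - 1,
       n_x = length(x), n_y = length(y))
}

#' Fisher's exact test for 2 x k tables
#'
#' Exact conditional p-value for independence in a contingency table of
#' nonnegative integer counts (2 x 2 or 2 x k). A table with a zero
#' margin carries no evidence against independence and returns p = 1.
#'
#' @param tab integer matrix of counts.
#' @return exact p-value.
#' @export
fisher_exact_2xk <- function(tab) {
  tab <- as.matrix(tab)
  stopifnot(all(tab >= 0), all(tab == round(tab)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) return(1)
  stats::fisher.test(tab)$p.value
}
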