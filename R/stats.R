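#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA of a continuous waveform variable across groups
#' (circle-of-Willis variant groups in the cohort pipeline).  Groups with
#' fewer than 2 observations are excluded with a warning; fewer than 2 usable
#' groups is an error.
#'
#' @param data A data frame.
#' @param value Column with the continuous variable (tidy evaluation).
#' @param group Column with the grouping variable (tidy evaluation).
#'
#' @return A one-row tibble: `statistic` (F), `df1`, `df2`, `p_value`,
#'   `n_obs`, `n_groups`.
#' @export
#' @examples
#' df <- data.frame(g = rep(c("a", "b", "c"), each = 3),
#'                  y = c(1, 2, 3, 2, 3, 4, 3, 4, 5))
#' anova_oneway(df, y, g)
anova_oneway <- function(data, value, group) {
  y <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]
  g <- factor(g[ok])
  counts <- table(g)
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    warn(sprintf("Excluding group(s) with fewer than 2 observations: %s",
                 paste(small, collapse = ", ")))
    keep <- !g %in% small
    y <- y[keep]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2L) {
    abort("One-way ANOVA needs at least 2 groups with >= 2 observations each.")
  }
  fit <- stats::oneway.test(y ~ g, var.equal = TRUE)
  tibble(
    statistic = unname(fit$statistic),
    df1 = unname(fit$parameter["num df"]),
    df2 = unname(fit$parameter["denom df"]),
    p_value = unname(fit$p.value),
    n_obs = length(y),
    n_groups = nlevels(g)
  )
}

#' Tukey honestly-significant-difference pairwise comparisons
#'
#' Studentized-range-adjusted pairwise mean comparisons across all group
#' pairs, as the post hoc companion to [anova_oneway()].
#'
#' @inheritParams anova_oneway
#' @param conf_level Family-wise confidence level.
#'
#' @return A tibble with one row per group pair: `group1`, `group2`,
#'   `estimate` (mean difference group2 - group1), `conf_low`, `conf_high`,
#'   `p_adj`.
#' @export
tukey_hsd <- function(data, value, group, conf_level = 0.95) {
  y <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  ok <- !is.na(y) & !is.na(g)
  y <- y[ok]
  g <- factor(g[ok])
  counts <- table(g)
  small <- names(counts)[counts < 2L]
  if (length(small) > 0L) {
    warn(sprintf("Excluding group(s) with fewer than 2 observations: %s",
                 paste(small, collapse = ", ")))
    keep <- !g %in% small
    y <- y[keep]
    g <- droplevels(g[keep])
  }
  if (nlevels(g) < 2L) {
    abort("Tukey HSD needs at least 2 groups with >= 2 observations each.")
  }
  fit <- stats::aov(y ~ g)
  tk <- stats::TukeyHSD(fit, conf.level = conf_level)$g
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  tibble(
    group1 = vapply(pairs, `[`, character(1), 2L),
    group2 = vapply(pairs, `[`, character(1), 1L),
    estimate = unname(tk[, "diff"]),
    conf_low = unname(tk[, "lwr"]),
    conf_high = unname(tk[, "upr"]),
    p_adj = unname(tk[, "p adj"])
  )
}

#' Pearson or Spearman correlation with a two-sided test
#'
#' Pearson correlation is used for continuous pairs (contralateral stenosis
#' against waveform variables); Spearman rank correlation (mid-ranks for
#' ties) for ordinal pairs (backflow grade against circle-of-Willis group).
#'
#' @inheritParams anova_oneway
#' @param x,y Columns to correlate (tidy evaluation).
#' @param method `"pearson"` or `"spearman"`.
#'
#' @return A one-row tibble: `estimate`, `p_value`, `method`, `n`.
#' @export
#' @examples
#' df <- data.frame(a = c(1, 2, 3, 4), b = c(2, 1, 4, 3))
#' correlate(df, a, b, method = "spearman")  # rho = 0.6
correlate <- function(data, x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  xv <- dplyr::pull(data, {{ x }})
  yv <- dplyr::pull(data, {{ y }})
  ok <- !is.na(xv) & !is.na(yv)
  xv <- as.numeric(xv[ok])
  yv <- as.numeric(yv[ok])
  if (length(xv) < 3L) abort("Correlation needs at least 3 complete pairs.")
  if (sd(xv) == 0 || sd(yv) == 0) {
    abort("Correlation undefined: a variable has zero variance.")
  }
  ct <- suppressWarnings(
    stats::cor.test(xv, yv, method = method, exact = FALSE)
  )
  tibble(
    estimate = unname(ct$estimate),
    p_value = unname(ct$p.value),
    method = method,
    n = length(xv)
  )
}

#' Chi-square or Fisher's exact test of a contingency table
#'
#' Follows the conventional selection rule: Pearson's chi-square (without
#' continuity correction) when every expected cell count exceeds 5; otherwise
#' Fisher's exact test for 2x2 tables, and chi-square with a warning for
#' larger sparse tables.
#'
#' @param table A matrix (or `table`) of non-negative integer counts, at least
#'   2x2.
#' @return A one-row tibble: `statistic` (chi-square statistic, `NA` for
#'   Fisher), `df`, `p_value`, `test_used`.
#' @export
#' @examples
#' categorical_test(matrix(c(10, 0, 0, 10), 2))  # Fisher, p = 2 / choose(20, 10)
categorical_test <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0) || any(tab != round(tab))) {
    abort("Contingency table must contain non-negative integer counts.")
  }
  if (nrow(tab) < 2L || ncol(tab) < 2L) {
    abort("Contingency table must be at least 2x2.")
  }
  if (sum(tab) == 0) abort("Contingency table is all zero.")
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  sparse <- any(expected <= 5)
  if (sparse && nrow(tab) == 2L && ncol(tab) == 2L) {
    ft <- stats::fisher.test(tab)
    return(tibble(statistic = NA_real_, df = NA_real_,
                  p_value = ft$p.value, test_used = "fisher"))
  }
  if (sparse) {
    warn("Expected counts below 5 in a table larger than 2x2: using chi-square.")
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble(
    statistic = unname(ct$statistic),
    df = unname(ct$parameter),
    p_value = unname(ct$p.value),
    test_used = "chi_square"
  )
}
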