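#' Run the full cohort statistical battery
#'
#' For every waveform feature column (raw ICA pressures, radial pressures,
#' ICA/radial ratios, durations, areas, decay constant, heart rate) the report
#' runs a one-way ANOVA across circle-of-Willis groups followed by Tukey HSD
#' pairwise comparisons; Pearson correlation of contralateral stenosis against
#' every feature; Spearman rank correlation of backflow grade against CoW
#' group; a chi-square/Fisher test of the backflow-by-group contingency
#' table; and a per-group mean +/- SD summary.
#'
#' @param cohort A cohort tibble (see [generate_cohort()]) with a `cow_group`
#'   column, optional `backflow_grade` and `contralateral_stenosis_pct`
#'   columns, and numeric feature columns.
#' @param features Character vector of feature columns to analyse; defaults
#'   to every numeric column prefixed `ica_`, `radial_` or `ratio_`, plus
#'   `hr` when present.
#' @param alpha Significance level recorded on the report.
#'
#' @return An object of class `cohort_report`: a list of tibbles
#'   (`anova`, `tukey`, `stenosis_pearson`, `backflow_spearman`,
#'   `categorical`, `summary`) plus `alpha` and `n_subjects`.
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_sim_params(seed = 1))
#' report <- build_cohort_report(cohort)
#' tidy(report)
build_cohort_report <- function(cohort, features = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(cohort))
  if (!"cow_group" %in% names(cohort)) {
    abort("`cohort` must have a `cow_group` column.")
  }
  groups_present <- table(cohort$cow_group)
  if (sum(groups_present >= 2L) < 2L) {
    abort("Cohort statistics need at least 2 CoW groups with >= 2 subjects.")
  }
  if (is.null(features)) {
    numeric_cols <- names(cohort)[vapply(cohort, is.numeric, logical(1))]
    features <- numeric_cols[grepl("^(ica_|radial_|ratio_)", numeric_cols)]
    if ("hr" %in% numeric_cols) features <- c(features, "hr")
  }
  missing <- setdiff(features, names(cohort))
  if (length(missing) > 0L) {
    abort(sprintf("Feature column(s) not found: %s",
                  paste(missing, collapse = ", ")))
  }

  run_feature <- function(f) {
    tryCatch(
      dplyr::mutate(
        anova_oneway(cohort, !!rlang::sym(f), .data$cow_group),
        feature = f, .before = 1L
      ),
      error = function(e) {
        warn(sprintf("ANOVA failed for `%s`: %s", f, conditionMessage(e)))
        NULL
      }
    )
  }
  anova_tbl <- purrr::map_dfr(features, run_feature)

  tukey_tbl <- purrr::map_dfr(features, function(f) {
    tryCatch(
      dplyr::mutate(
        tukey_hsd(cohort, !!rlang::sym(f), .data$cow_group),
        feature = f, .before = 1L
      ),
      error = function(e) NULL
    )
  })

  stenosis_tbl <- NULL
  if ("contralateral_stenosis_pct" %in% names(cohort)) {
    stenosis_tbl <- purrr::map_dfr(features, function(f) {
      tryCatch(
        dplyr::mutate(
          correlate(cohort, .data$contralateral_stenosis_pct,
                    !!rlang::sym(f), method = "pearson"),
          feature = f, .before = 1L
        ),
        error = function(e) NULL
      )
    })
  }

  spearman_tbl <- NULL
  categorical_tbl <- NULL
  if ("backflow_grade" %in% names(cohort)) {
    spearman_tbl <- correlate(cohort, .data$backflow_grade, .data$cow_group,
                              method = "spearman")
    tab <- table(cohort$cow_group, cohort$backflow_grade)
    if (nrow(tab) >= 2L && ncol(tab) >= 2L) {
      categorical_tbl <- dplyr::mutate(
        suppressWarnings(categorical_test(tab)),
        comparison = "backflow_grade_by_cow_group", .before = 1L
      )
    }
  }

  summary_tbl <- cohort |>
    dplyr::select(dplyr::all_of(c("cow_group", features))) |>
    tidyr::pivot_longer(-"cow_group", names_to = "feature") |>
    dplyr::group_by(.data$feature, .data$cow_group) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    )

  structure(
    list(
      anova = anova_tbl,
      tukey = tukey_tbl,
      stenosis_pearson = stenosis_tbl,
      backflow_spearman = spearman_tbl,
      categorical = categorical_tbl,
      summary = summary_tbl,
      alpha = alpha,
      n_subjects = nrow(cohort)
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat(sprintf("<cohort_report> %d subjects, alpha = %g\n", x$n_subjects, x$alpha))
  sig <- x$anova$feature[x$anova$p_value < x$alpha]
  cat(sprintf("  ANOVA across CoW groups: %d features, %d significant (%s)\n",
              nrow(x$anova), length(sig),
              if (length(sig)) paste(sig, collapse = ", ") else "none"))
  if (!is.null(x$backflow_spearman)) {
    cat(sprintf("  Spearman backflow ~ CoW group: rho = %.3f (p = %.3g)\n",
                x$backflow_spearman$estimate, x$backflow_spearman$p_value))
  }
  invisible(x)
}

#' @describeIn build_cohort_report Per-feature ANOVA table as a tibble.
#' @param x A `cohort_report`.
#' @param ... Unused.
#' @method tidy cohort_report
#' @export
tidy.cohort_report <- function(x, ...) {
  x$anova
}

#' @describeIn build_cohort_report One-row cohort-level summary.
#' @method glance cohort_report
#' @export
glance.cohort_report <- function(x, ...) {
  tibble(
    n_subjects = x$n_subjects,
    n_features = nrow(x$anova),
    n_significant = sum(x$anova$p_value < x$alpha),
    alpha = x$alpha,
    backflow_spearman_rho = if (is.null(x$backflow_spearman)) NA_real_ else x$backflow_spearman$estimate,
    backflow_spearman_p = if (is.null(x$backflow_spearman)) NA_real_ else x$backflow_spearman$p_value
  )
}
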