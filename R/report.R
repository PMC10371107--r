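#' Full learning analysis of a simulated (or loaded) cohort
#'
#' Runs the complete analysis pipeline on a long trial table: per-trial error
#' series, per-subject change in error, cross-validated exponential decay
#' fits per group, Kruskal-Wallis / Dunn-Šidák group comparisons of the
#' change in error, error-distribution shift measures per group, and percent
#' contrasts of the pooled-fit parameters between groups.
#'
#' Contrast percentages are emitted from both the all-data fits and the
#' medians of the cross-validation ensemble, since either convention is
#' defensible for summarizing a group's fit.
#'
#' @param data A trial table with `subject_id` and `group` columns (e.g. from
#'   [generate_cohort()] or [read_trials()]).
#' @param repeats,seed Passed to [cross_validated_fit()].
#' @param reference Group treated as the control in contrasts (default
#'   `"null"`).
#' @return A list of class `ef_report`: `series`, `subjects` (per-subject
#'   change in error), `cv_fits`, `group_fits` (the `"all"` fits), `tests`
#'   (an `ef_group_test` on change in error, `NULL` if fewer than 2 groups),
#'   `shift`, and `contrasts`.
#' @export
analyze_cohort <- function(data, repeats = 50, seed = 1L, reference = "null") {
  check_columns(data, c("subject_id", "group"), "data")
  series <- trial_error_series(data)
  subjects <- series |>
    dplyr::group_by(.data$group, .data$subject_id) |>
    dplyr::summarise(change_in_error = change_in_error(.data$error),
                     .groups = "drop")

  groups <- unique(series$group)
  cv_fits <- purrr::map_dfr(groups, function(g) {
    dplyr::mutate(
      cross_validated_fit(series[series$group == g, ], repeats = repeats,
                          seed = seed),
      group = g, .before = 1
    )
  })
  group_fits <- dplyr::filter(cv_fits, .data$fit == "all")

  tests <- NULL
  if (length(groups) >= 2 && all(table(subjects$group) >= 3)) {
    tests <- group_compare(subjects, value = "change_in_error")
  }

  shift <- purrr::map_dfr(groups, function(g) {
    dplyr::mutate(shift_measure(data[data$group == g, ]), group = g,
                  .before = 1)
  })

  contrasts <- NULL
  if (reference %in% groups) {
    ref_all <- group_fits[group_fits$group == reference, ]
    cv_med <- cv_fits |>
      dplyr::group_by(.data$group) |>
      dplyr::summarise(S = median(.data$S), R = median(.data$R),
                       tau = median(.data$tau), .groups = "drop")
    ref_cv <- cv_med[cv_med$group == reference, ]
    contrasts <- purrr::map_dfr(setdiff(groups, reference), function(g) {
      ga <- group_fits[group_fits$group == g, ]
      gc <- cv_med[cv_med$group == g, ]
      tibble::tibble(
        group = g, reference = reference,
        reduction_pct_more_all = 100 * (ga$R - ref_all$R) / ref_all$R,
        steady_pct_lower_all = 100 * (ref_all$S - ga$S) / ref_all$S,
        tau_pct_longer_all = 100 * (ga$tau - ref_all$tau) / ref_all$tau,
        reduction_pct_more_cv = 100 * (gc$R - ref_cv$R) / ref_cv$R,
        steady_pct_lower_cv = 100 * (ref_cv$S - gc$S) / ref_cv$S,
        tau_pct_longer_cv = 100 * (gc$tau - ref_cv$tau) / ref_cv$tau
      )
    })
  }

  structure(
    list(series = series, subjects = subjects, cv_fits = cv_fits,
         group_fits = group_fits, tests = tests, shift = shift,
         contrasts = contrasts),
    class = "ef_report"
  )
}

#' @export
print.ef_report <- function(x, ...) {
  cat("<ef_report>\n")
  cat("Pooled decay fits per group:\n")
  print(x$group_fits)
  if (!is.null(x$tests)) {
    cat("\nChange-in-error group test:\n")
    print(x$tests)
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Emits the [analyze_cohort()] result as a JSON summary plus CSV tables
#' (fits, per-subject summaries, pairwise contrasts, shift measures) in a
#' directory.
#'
#' @param report An `ef_report`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  stopifnot(inherits(report, "ef_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(report$cv_fits, file.path(dir, "cv_fits.csv"))
  readr::write_csv(report$subjects, file.path(dir, "subjects.csv"))
  readr::write_csv(report$shift, file.path(dir, "shift.csv"))
  if (!is.null(report$contrasts)) {
    readr::write_csv(report$contrasts, file.path(dir, "contrasts.csv"))
  }
  summary <- list(
    group_fits = report$group_fits,
    omnibus = if (!is.null(report$tests)) report$tests$omnibus,
    pairwise = if (!is.null(report$tests)) report$tests$pairwise,
    contrasts = report$contrasts
  )
  jsonlite::write_json(summary, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "rows")
  invisible(dir)
}
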