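trial_table_required <- c(
  "subject_id", "group", "phase", "trial_index", "direction_id",
  "transformed", "forces_on", "t", "x", "y", "extent_err", "perp_err",
  "torque_extent", "torque_perp"
)

trial_table_numeric <- c("t", "x", "y", "extent_err", "perp_err",
                         "torque_extent", "torque_perp")

validate_trial_table <- function(data, arg = "data") {
  check_columns(data, trial_table_required, arg)
  for (col in trial_table_numeric) {
    bad <- which(!is.finite(data[[col]]))
    if (length(bad) > 0) {
      abort(sprintf("Column `%s` has a non-finite value at row %d.",
                    col, bad[1]))
    }
  }
  key <- paste(data$subject_id, data$trial_index, data$t)
  if (anyDuplicated(key)) {
    abort(sprintf("Duplicate (subject_id, trial_index, t) key at row %d.",
                  anyDuplicated(key)))
  }
  invisible(data)
}

#' Read and write trial tables
#'
#' The long-format interchange table: one row per recorded sample with subject
#' and trial identity, task state, cursor position (cm), decomposed errors
#' (cm) and commanded torques (Nm). Written as comma-separated UTF-8 CSV with
#' a header row and `.` decimal; round trips are lossless to full double
#' precision. Extra columns are preserved; missing required columns or
#' non-finite values raise an error naming the column (and row).
#'
#' @param data A trial table (e.g. a [generate_cohort()] result with
#'   `subject_id` and `group` columns).
#' @param path CSV file path.
#' @return `write_trials()` returns `path` invisibly; `read_trials()` returns
#'   the validated tibble.
#' @export
write_trials <- function(data, path) {
  if ("phase" %in% names(data) && !"subject_id" %in% names(data)) {
    # single-subject protocol output: fill in identity columns
    data <- dplyr::mutate(tibble::as_tibble(data),
                          subject_id = "s01", group = "unknown", .before = 1)
  }
  validate_trial_table(data)
  readr::write_csv(tibble::as_tibble(data), path)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  data <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  validate_trial_table(data, arg = basename(path))
  data
}

#' Layout descriptor for external reaching datasets
#'
#' Describes how to map the columns of an externally deposited
#' reaching-trajectory table onto the package's trial-table schema, instead of
#' hard-coding any particular deposit structure. `columns` maps trial-table
#' column names to source column names; `units` declares the length unit of
#' the source position/error columns (`"cm"` or `"m"`; metres are converted);
#' `defaults` supplies constant values for trial-table columns absent from
#' the source.
#'
#' @param columns Named character vector, `c(trial_table_col = source_col)`.
#' @param units Length unit of source position/error columns.
#' @param defaults Named list of constants for unmapped required columns.
#' @return A list of class `ef_layout`.
#' @export
dataset_layout <- function(columns, units = c("cm", "m"), defaults = list()) {
  units <- match.arg(units)
  if (is.null(names(columns)) || any(names(columns) == "")) {
    abort("`columns` must be a fully named character vector.")
  }
  unknown <- setdiff(names(columns), trial_table_required)
  if (length(unknown) > 0) {
    abort(sprintf("Unknown trial-table column(s) in layout: %s.",
                  paste(unknown, collapse = ", ")))
  }
  structure(list(columns = columns, units = units, defaults = defaults),
            class = "ef_layout")
}

#' Load an external reaching dataset through a layout descriptor
#'
#' Reads a deposited CSV and normalizes it to the package's trial table using
#' a [dataset_layout()]. Source columns not named in the layout are dropped
#' (with a message); declared metre units are converted to cm; missing
#' required columns are filled from the layout's `defaults` or raise an error
#' listing the columns discovered in the file.
#'
#' @param path CSV file path of the downloaded deposit table.
#' @param layout A [dataset_layout()].
#' @return A validated trial-table tibble.
#' @export
load_external_dataset <- function(path, layout) {
  if (!inherits(layout, "ef_layout")) {
    abort("`layout` must be a `dataset_layout()` descriptor.")
  }
  if (!file.exists(path)) abort(sprintf("File not found: '%s'.", path))
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)

  missing_src <- setdiff(unname(layout$columns), names(raw))
  if (length(missing_src) > 0) {
    abort(sprintf(
      "Layout names source column(s) not present in '%s': %s. Columns discovered: %s.",
      basename(path), paste(missing_src, collapse = ", "),
      paste(names(raw), collapse = ", ")
    ))
  }
  dropped <- setdiff(names(raw), unname(layout$columns))
  if (length(dropped) > 0) {
    inform(sprintf("Dropping unmapped column(s): %s.",
                   paste(dropped, collapse = ", ")))
  }
  out <- tibble::as_tibble(setNames(raw[unname(layout$columns)],
                                    names(layout$columns)))
  need_default <- setdiff(trial_table_required, names(out))
  for (col in need_default) {
    if (!col %in% names(layout$defaults)) {
      abort(sprintf(
        "Required column `%s` is neither mapped nor given a default. Columns discovered: %s.",
        col, paste(names(raw), collapse = ", ")
      ))
    }
    out[[col]] <- layout$defaults[[col]]
  }
  if (layout$units == "m") {
    for (col in intersect(c("x", "y", "extent_err", "perp_err"), names(layout$columns))) {
      out[[col]] <- out[[col]] * 100
    }
  }
  out <- out[, c(trial_table_required,
                 setdiff(names(out), trial_table_required))]
  validate_trial_table(out, arg = basename(path))
  out
}
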