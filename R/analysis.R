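#' Per-trial error magnitude series
#'
#' Reduces sample-level trial records to one scalar per trial: the
#' time-averaged error-vector magnitude
#' \eqn{\overline{|\epsilon|} = \mathrm{mean}_t \sqrt{\epsilon_{ext}^2 + \epsilon_{perp}^2}}
#' over the movement. This is the primary outcome the learning-curve model is
#' fitted to. If a `phase` column is present only training-phase records are
#' used; grouping columns `group` and `subject_id` are preserved when present,
#' and `trial` numbers trials 1..n within each subject.
#'
#' @param data A trial table with columns `trial_index`, `extent_err`,
#'   `perp_err` (e.g. from [run_protocol()] or [generate_cohort()]).
#' @return A tibble with columns (`group`, `subject_id` if present), `trial`,
#'   `error` (cm).
#' @export
trial_error_series <- function(data) {
  check_columns(data, c("trial_index", "extent_err", "perp_err"), "data")
  if ("phase" %in% names(data)) {
    data <- dplyr::filter(data, .data$phase == "training")
  }
  if (nrow(data) == 0) abort("No training-phase records in `data`.")
  ids <- intersect(c("group", "subject_id"), names(data))
  data |>
    dplyr::group_by(dplyr::across(dplyr::all_of(c(ids, "trial_index")))) |>
    dplyr::summarise(
      error = mean(sqrt(.data$extent_err^2 + .data$perp_err^2)),
      .groups = "drop_last"
    ) |>
    dplyr::arrange(.data$trial_index, .by_group = TRUE) |>
    dplyr::mutate(trial = dplyr::row_number(), .before = "error") |>
    dplyr::ungroup() |>
    dplyr::select(-"trial_index")
}

# exact non-negative least squares for y ~ S + R * b, S >= 0, R >= 0:
# enumerate the KKT candidates of the 2-parameter problem
nnls_2col <- function(b, y) {
  n <- length(y)
  sb <- sum(b); sbb <- sum(b * b); sy <- sum(y); sby <- sum(b * y)
  det <- n * sbb - sb * sb
  cand <- list(c(max(mean(y), 0), 0),
               c(0, max(sby / sbb, 0)),
               c(0, 0))
  if (det > .Machine$double.eps * n * sbb) {
    S <- (sbb * sy - sb * sby) / det
    R <- (n * sby - sb * sy) / det
    if (S >= 0 && R >= 0) cand <- c(list(c(S, R)), cand)
  }
  sse <- vapply(cand, function(p) sum((y - p[1] - p[2] * b)^2), numeric(1))
  best <- cand[[which.min(sse)]]
  list(S = best[1], R = best[2], sse = min(sse))
}

decay_sse_at_tau <- function(tau, t, y) nnls_2col(exp(-t / tau), y)$sse

# core exponential-decay fit on (t, y) pairs; tau searched on a log grid with
# exact NNLS per tau, then locally refined
decay_fit_xy <- function(t, y, tau_range = c(0.5, 500), n_tau = 200,
                         refine = TRUE) {
  if (!all(is.finite(t)) || !all(is.finite(y))) {
    abort("Non-finite values in the error series.")
  }
  taus <- exp(seq(log(tau_range[1]), log(tau_range[2]), length.out = n_tau))
  sses <- vapply(taus, decay_sse_at_tau, numeric(1), t = t, y = y)
  i <- which.min(sses)
  tau <- taus[i]
  sol <- nnls_2col(exp(-t / tau), y)
  if (refine && sol$R > 0) {
    lo <- taus[max(i - 1, 1)]; hi <- taus[min(i + 1, n_tau)]
    opt <- optimize(function(lt) decay_sse_at_tau(exp(lt), t, y),
                    interval = log(c(lo, hi)), tol = 1e-10)
    tau_r <- exp(opt$minimum)
    sol_r <- nnls_2col(exp(-t / tau_r), y)
    if (sol_r$sse <= sol$sse) { tau <- tau_r; sol <- sol_r }
  }
  rng <- diff(range(y))
  nrmse <- if (rng > 0) sqrt(sol$sse / length(y)) / rng else 0
  list(S = sol$S, R = sol$R, tau = tau, nrmse = nrmse)
}

#' Fit the three-parameter exponential learning curve
#'
#' Fits \eqn{y(t) = S + R e^{-t/\tau}} to a per-trial error series by
#' non-negative least squares: \eqn{\tau} is searched over a 200-point
#' log-spaced grid on `[0.5, 500]` trials with, at each \eqn{\tau}, an exact
#' non-negative solve for \eqn{(S, R)}; the best grid point is then locally
#' refined. `S` is the steady-state error (the error after infinitely many
#' trials), `R` the error reduction amplitude, and \eqn{\tau} the learning
#' time constant in trials. Trials are numbered `t = 0, 1, ...` from the first
#' element of the series.
#'
#' For series with no decaying structure the non-negativity constraint forces
#' `R = 0`; \eqn{\tau} is then unidentifiable and is reported at the low grid
#' edge.
#'
#' @param series Numeric vector of per-trial errors (>= 10 trials), or a data
#'   frame with an `error` column (e.g. from [trial_error_series()]).
#' @param tau_range Search range for \eqn{\tau}, trials.
#' @param n_tau Number of log-spaced \eqn{\tau} grid points.
#' @param refine Locally refine \eqn{\tau} around the best grid point?
#' @return An object of class `ef_decay_fit` with elements `S`, `R`, `tau`,
#'   `nrmse` (fit RMSE divided by the series range) and the data.
#' @examples
#' y <- 1 + 4 * exp(-(0:69) / 10)
#' fit_decay(y)
#' @export
fit_decay <- function(series, tau_range = c(0.5, 500), n_tau = 200,
                      refine = TRUE) {
  if (is.data.frame(series)) {
    check_columns(series, "error", "series")
    series <- series$error
  }
  if (length(series) < 10) abort("`series` must contain at least 10 trials.")
  t <- seq_along(series) - 1
  fit <- decay_fit_xy(t, series, tau_range, n_tau, refine)
  structure(
    c(fit, list(series = as.numeric(series), t = t,
                fitted = fit$S + fit$R * exp(-t / fit$tau))),
    class = "ef_decay_fit"
  )
}

#' @export
print.ef_decay_fit <- function(x, ...) {
  cat(sprintf(
    "<ef_decay_fit> S = %.4g cm, R = %.4g cm, tau = %.4g trials (NRMSE %.3g, n = %d)\n",
    x$S, x$R, x$tau, x$nrmse, length(x$series)
  ))
  invisible(x)
}

#' @describeIn fit_decay One row per model parameter.
#' @method tidy ef_decay_fit
#' @param x An `ef_decay_fit`.
#' @param ... Unused.
#' @export
tidy.ef_decay_fit <- function(x, ...) {
  tibble::tibble(term = c("S", "R", "tau"),
                 estimate = c(x$S, x$R, x$tau),
                 unit = c("cm", "cm", "trials"))
}

#' @describeIn fit_decay One-row fit summary.
#' @method glance ef_decay_fit
#' @export
glance.ef_decay_fit <- function(x, ...) {
  tibble::tibble(S = x$S, R = x$R, tau = x$tau, nrmse = x$nrmse,
                 n_trials = length(x$series))
}

#' @describeIn fit_decay Plot the series with the fitted decay curve.
#' @method autoplot ef_decay_fit
#' @param object An `ef_decay_fit`.
#' @export
autoplot.ef_decay_fit <- function(object, ...) {
  df <- tibble::tibble(trial = object$t + 1, error = object$series,
                       fitted = object$fitted)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$trial)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$error), alpha = 0.6) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fitted), linewidth = 1) +
    ggplot2::labs(x = "training trial", y = "error (cm)",
                  title = sprintf("S = %.2f, R = %.2f, tau = %.1f trials",
                                  object$S, object$R, object$tau))
}

#' Cross-validated group learning-curve fits
#'
#' For a group of subjects: one fit pooling all subjects, plus one
#' leave-one-subject-out fit per subject. Each fit is repeated on random 80%
#' subsets of the pooled (trial, error) points, scored by normalized RMSE
#' (test RMSE divided by the training-series range) on the held-out 20%, and
#' the repeat with the lowest test NRMSE is retained. Deterministic given
#' `seed`.
#'
#' @param data A tibble with columns `subject_id`, `trial` (training trial
#'   number within subject) and `error`, e.g. [trial_error_series()] output
#'   for one group.
#' @param repeats Random train/test repeats per fit (default 50).
#' @param holdout Held-out fraction (default 0.2).
#' @param seed Integer seed for the subset draws.
#' @param ... Passed to the decay fitter ([fit_decay()] arguments).
#' @return A tibble of class `ef_cv_fits`: one row per retained fit with
#'   columns `fit` (`"all"` or the left-out subject), `S`, `R`, `tau`,
#'   `nrmse` (test NRMSE of the retained repeat). `n` subjects give `n + 1`
#'   rows.
#' @export
cross_validated_fit <- function(data, repeats = 50, holdout = 0.2, seed = 1L,
                                ...) {
  check_columns(data, c("subject_id", "trial", "error"), "data")
  subjects <- unique(data$subject_id)
  if (length(subjects) < 2) abort("Need at least 2 subjects.")
  set.seed(seed)

  one_fit <- function(df) {
    t <- df$trial - 1
    y <- df$error
    n <- length(y)
    n_test <- max(1L, round(holdout * n))
    best <- NULL
    for (r in seq_len(repeats)) {
      test <- sample.int(n, n_test)
      ft <- decay_fit_xy(t[-test], y[-test], ...)
      rng <- diff(range(y[-test]))
      resid <- y[test] - (ft$S + ft$R * exp(-t[test] / ft$tau))
      nrmse <- if (rng > 0) sqrt(mean(resid^2)) / rng else sqrt(mean(resid^2))
      if (is.null(best) || nrmse < best$nrmse) {
        best <- list(S = ft$S, R = ft$R, tau = ft$tau, nrmse = nrmse)
      }
    }
    best
  }

  labels <- c("all", as.character(subjects))
  rows <- purrr::map(labels, function(lab) {
    df <- if (lab == "all") data else data[data$subject_id != lab, ]
    c(list(fit = lab), one_fit(df))
  })
  out <- purrr::map_dfr(rows, tibble::as_tibble)
  class(out) <- c("ef_cv_fits", class(out))
  out
}

#' Change in error across training
#'
#' The non-parametric learning summary: mean of the first five per-trial
#' errors minus the mean of the last five. Positive values mean the error
#' decreased over training.
#'
#' @param series Numeric per-trial error vector (>= 10 trials) or a data
#'   frame with an `error` column.
#' @return The change in error, cm.
#' @examples
#' change_in_error(c(rep(10, 5), rep(6, 20), rep(2, 5)))  # 8
#' @export
change_in_error <- function(series) {
  if (is.data.frame(series)) {
    check_columns(series, "error", "series")
    series <- series$error
  }
  if (length(series) < 10) {
    abort("`series` must contain at least 10 trials (first and last 5 are used).")
  }
  mean(head(series, 5)) - mean(tail(series, 5))
}

#' Shift of the error-ensemble distribution from early to late training
#'
#' For each direction and error component, errors are binned on a common time
#' grid; per bin the late-training mean minus the early-training mean is
#' normalized by the early-training standard deviation, and the magnitude of
#' that normalized shift is averaged over time. A value of 1 means the error
#' distribution moved, on average, one early-training SD away from where it
#' started.
#'
#' @param early,late Error-sample tables with columns `t`, `extent_err`,
#'   `perp_err`, `direction_id`. If `late` is `NULL`, `early` must be a
#'   training-phase trial table with a `trial_index` column; the first
#'   `early_trials` and last `late_trials` trials (per subject when a
#'   `subject_id` column is present) form the two ensembles.
#' @param td Time domain upper end, seconds.
#' @param n_bins Number of uniform time bins.
#' @param sd_floor Minimum admissible early-training SD per bin, cm; bins
#'   below it raise an error (the normalization would be unstable).
#' @param early_trials,late_trials Window sizes for the single-table form.
#' @return A tibble of class `ef_shift` with columns `direction_id`,
#'   `component`, `delta`.
#' @export
shift_measure <- function(early, late = NULL, td = 1.5, n_bins = 50,
                          sd_floor = 0.05, early_trials = 10,
                          late_trials = 10) {
  if (is.null(late)) {
    check_columns(early, "trial_index", "early")
    data <- if ("phase" %in% names(early)) {
      dplyr::filter(early, .data$phase == "training")
    } else early
    ids <- intersect("subject_id", names(data))
    pick <- function(df, which) {
      trials <- sort(unique(df$trial_index))
      keep <- if (which == "early") head(trials, early_trials)
              else tail(trials, late_trials)
      df[df$trial_index %in% keep, ]
    }
    split_by <- function(which) {
      if (length(ids) > 0) {
        data |> dplyr::group_by(.data$subject_id) |>
          dplyr::group_modify(~ pick(.x, which)) |> dplyr::ungroup()
      } else pick(data, which)
    }
    early_s <- split_by("early")
    late_s <- split_by("late")
    return(shift_measure(early_s, late_s, td = td, n_bins = n_bins,
                         sd_floor = sd_floor))
  }
  req <- c("t", "extent_err", "perp_err", "direction_id")
  check_columns(early, req, "early")
  check_columns(late, req, "late")
  if (nrow(early) == 0 || nrow(late) == 0) {
    abort("Both ensembles must be non-empty.")
  }
  edges <- seq(0, td, length.out = n_bins + 1)
  bin_of <- function(t) pmin(pmax(findInterval(t, edges, all.inside = TRUE), 1),
                             n_bins)
  stats_of <- function(df) {
    df |>
      tidyr::pivot_longer(c("extent_err", "perp_err"), names_to = "component",
                          values_to = "err") |>
      dplyr::mutate(component = sub("_err$", "", .data$component),
                    bin = bin_of(.data$t)) |>
      dplyr::group_by(.data$direction_id, .data$component, .data$bin) |>
      dplyr::summarise(m = mean(.data$err), s = sd(.data$err),
                       .groups = "drop")
  }
  e <- stats_of(early)
  l <- stats_of(late)
  joined <- dplyr::inner_join(e, l, by = c("direction_id", "component", "bin"),
                              suffix = c("_early", "_late"))
  if (any(!is.finite(joined$s_early)) || any(joined$s_early < sd_floor)) {
    abort(sprintf(
      "Early-training SD below the %g cm floor in at least one time bin; shift normalization is unstable.",
      sd_floor
    ))
  }
  out <- joined |>
    dplyr::mutate(z = (.data$m_late - .data$m_early) / .data$s_early) |>
    dplyr::group_by(.data$direction_id, .data$component) |>
    dplyr::summarise(delta = mean(abs(.data$z)), .groups = "drop")
  class(out) <- c("ef_shift", class(out))
  out
}

#' Group learning curves with cross-validation envelopes
#'
#' Plots per-subject error series (thin lines) with each group's pooled decay
#' fit (thick line), faceted by group.
#'
#' @param series A [trial_error_series()] tibble with `group`, `subject_id`,
#'   `trial`, `error` columns.
#' @param fits Optional named list of `ef_cv_fits` per group; the `"all"` fit
#'   is drawn when supplied, otherwise pooled fits are computed.
#' @return A ggplot object.
#' @export
plot_learning_curves <- function(series, fits = NULL) {
  check_columns(series, c("group", "subject_id", "trial", "error"), "series")
  groups <- unique(series$group)
  fit_df <- purrr::map_dfr(groups, function(g) {
    sub <- series[series$group == g, ]
    par <- if (!is.null(fits) && g %in% names(fits)) {
      as.list(fits[[g]][fits[[g]]$fit == "all", c("S", "R", "tau")])
    } else {
      f <- decay_fit_xy(sub$trial - 1, sub$error)
      f[c("S", "R", "tau")]
    }
    tibble::tibble(group = g, trial = sort(unique(sub$trial)),
                   fitted = par$S + par$R * exp(-(sort(unique(sub$trial)) - 1) / par$tau))
  })
  ggplot2::ggplot(series, ggplot2::aes(x = .data$trial, y = .data$error)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$subject_id), alpha = 0.3) +
    ggplot2::geom_line(data = fit_df, ggplot2::aes(y = .data$fitted),
                       linewidth = 1.2, colour = "firebrick") +
    ggplot2::facet_wrap(~group) +
    ggplot2::labs(x = "training trial", y = "error (cm)")
}
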