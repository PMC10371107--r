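#' Characterize a subject's error statistics as a Gaussian likelihood field
#'
#' Builds the per-direction, per-component statistical error model from a set
#' of characterization trials (typically the transformed intermittent-exposure
#' trials). For each movement direction and each error component (extent,
#' perpendicular), samples are binned on a common time grid over `[0, td]`
#' (nearest-sample assignment per trial), the across-trial mean and standard
#' deviation are computed at each grid time, and degree-7 polynomials are
#' least-squares fitted to the mean and SD curves. Time is rescaled to
#' `[0, 1]` before fitting to keep the degree-7 basis well conditioned.
#'
#' Evaluated standard deviations are floored at `sigma_floor` so the Gaussian
#' density (see [error_density()]) can never blow up for near-deterministic
#' errors.
#'
#' @param samples A data frame of error samples with columns `t` (s),
#'   `extent_err`, `perp_err` (cm), `direction_id`, and `trial_index`
#'   (distinguishing trials within a direction).
#' @param td Reach duration defining the time domain, seconds.
#' @param sigma_floor Minimum standard deviation in cm (default 0.05).
#' @param n_bins Number of uniform time bins over `[0, td]` (default 50).
#' @param degree Polynomial degree for the mean and SD curves (default 7).
#' @return An object of class `error_field_model`.
#' @seealso [mu_sigma_at()], [error_density()], [write_error_model()]
#' @export
characterize_errors <- function(samples, td = 1.5, sigma_floor = 0.05,
                                n_bins = 50, degree = 7) {
  check_columns(samples, c("t", "extent_err", "perp_err", "direction_id",
                           "trial_index"), "samples")
  if (!all(is.finite(samples$t)) || !all(is.finite(samples$extent_err)) ||
      !all(is.finite(samples$perp_err))) {
    abort("Non-finite error samples; characterization requires finite data.")
  }
  if (sigma_floor <= 0) abort("`sigma_floor` must be positive.")
  grid_t <- seq(0, td, length.out = n_bins)

  dirs <- sort(unique(samples$direction_id))
  fits <- list()
  for (d in dirs) {
    sub <- samples[samples$direction_id == d, , drop = FALSE]
    trials <- unique(sub$trial_index)
    if (length(trials) < 2) {
      abort(sprintf(
        "Direction %s has %d characterization trial(s); at least 2 are required.",
        d, length(trials)
      ))
    }
    # trials x bins matrices of nearest-sample values, one per component
    val <- function(col) {
      vapply(trials, function(tr) {
        tt <- sub$t[sub$trial_index == tr]
        vv <- sub[[col]][sub$trial_index == tr]
        vv[vapply(grid_t, function(g) which.min(abs(tt - g)), integer(1))]
      }, numeric(n_bins))
    }
    for (comp in c("extent", "perp")) {
      m <- val(paste0(comp, "_err"))
      mu <- rowMeans(m)
      sig <- apply(m, 1, sd)
      fits[[model_key(d, comp)]] <- list(
        mu_coeffs = polyfit_unit(grid_t / td, mu, degree),
        sigma_coeffs = polyfit_unit(grid_t / td, sig, degree)
      )
    }
  }

  structure(
    list(fits = fits, directions = as.integer(dirs), td = td,
         sigma_floor = sigma_floor, degree = degree, n_bins = n_bins),
    class = "error_field_model"
  )
}

model_key <- function(direction, component) paste0("d", direction, "_", component)

# least-squares polynomial fit on u in [0,1]; coefficients in increasing power
polyfit_unit <- function(u, y, degree) {
  X <- outer(u, 0:degree, `^`)
  qr.solve(qr(X), y)
}

polyval_unit <- function(coeffs, u) {
  # Horner evaluation, vectorized over u
  out <- rep(coeffs[length(coeffs)], length(u))
  for (k in seq(length(coeffs) - 1, 1)) out <- out * u + coeffs[k]
  out
}

check_model <- function(model, direction = NULL, component = NULL) {
  if (!inherits(model, "error_field_model")) {
    abort("`model` must be an `error_field_model` (see `characterize_errors()`).")
  }
  if (!is.null(component) && !component %in% c("extent", "perp")) {
    abort(sprintf("Unknown component '%s'; use \"extent\" or \"perp\".", component))
  }
  if (!is.null(direction) && !direction %in% model$directions) {
    abort(sprintf("Unknown direction %s; model covers %s.",
                  direction, paste(model$directions, collapse = ", ")))
  }
  invisible(model)
}

#' Evaluate the modelled error mean and standard deviation
#'
#' Evaluates the fitted polynomial mean and SD curves for one direction and
#' component. Times are clamped to the model's `[0, td]` domain and the SD is
#' floored at the model's `sigma_floor`.
#'
#' @param model An `error_field_model` from [characterize_errors()].
#' @param direction Movement direction id present in the model.
#' @param component `"extent"` or `"perp"`.
#' @param t Time(s) in seconds; vectorized.
#' @return A tibble with columns `t`, `mu`, `sigma` (cm).
#' @export
mu_sigma_at <- function(model, direction, component, t) {
  check_model(model, direction, component)
  u <- pmin(pmax(t / model$td, 0), 1)
  f <- model$fits[[model_key(direction, component)]]
  tibble::tibble(
    t = t,
    mu = polyval_unit(f$mu_coeffs, u),
    sigma = pmax(polyval_unit(f$sigma_coeffs, u), model$sigma_floor)
  )
}

#' Gaussian error likelihood
#'
#' The probability density of observing error `eps` (cm) at time `t` for one
#' direction and component:
#' \eqn{p(\epsilon) = \exp(-(\epsilon-\mu)^2 / 2\sigma^2) / (\sigma\sqrt{2\pi})},
#' with \eqn{\mu(t)}, \eqn{\sigma(t)} from [mu_sigma_at()]. This scalar
#' per-component density is what weights the error-field torque.
#'
#' @inheritParams mu_sigma_at
#' @param eps Error value(s) in cm; recycled against `t`.
#' @return Numeric density values (per cm).
#' @export
error_density <- function(model, direction, component, t, eps) {
  ms <- mu_sigma_at(model, direction, component, t)
  dnorm(eps, mean = ms$mu, sd = ms$sigma)
}

#' @export
print.error_field_model <- function(x, ...) {
  cat(sprintf(
    "<error_field_model> %d direction(s) x {extent, perp}, degree-%d fits on [0, %g] s, sigma floor %g cm\n",
    length(x$directions), x$degree, x$td, x$sigma_floor
  ))
  invisible(x)
}

#' @describeIn characterize_errors Tidy the fitted coefficients into a long
#'   tibble with one row per (direction, component, curve, power).
#' @method tidy error_field_model
#' @param x An `error_field_model`.
#' @param ... Unused.
#' @export
tidy.error_field_model <- function(x, ...) {
  purrr::map_dfr(x$directions, function(d) {
    purrr::map_dfr(c("extent", "perp"), function(comp) {
      f <- x$fits[[model_key(d, comp)]]
      tibble::tibble(
        direction_id = d, component = comp,
        curve = rep(c("mu", "sigma"), each = x$degree + 1),
        power = rep(0:x$degree, 2),
        coefficient = c(f$mu_coeffs, f$sigma_coeffs)
      )
    })
  })
}

#' Serialize an error-field model to JSON (and back)
#'
#' The model is stored as a plain-text JSON document: degree, time domain,
#' sigma floor, and the mean/SD polynomial coefficients per direction and
#' component (coefficients apply to time rescaled to `[0, 1]`).
#'
#' @param model An `error_field_model`.
#' @param path File path.
#' @return `write_error_model()` returns `path` invisibly;
#'   `read_error_model()` returns the reconstructed `error_field_model`.
#' @export
write_error_model <- function(model, path) {
  check_model(model)
  doc <- list(
    type = "error_field_model", degree = model$degree, td = model$td,
    sigma_floor = model$sigma_floor, n_bins = model$n_bins,
    directions = model$directions,
    fits = purrr::map(model$fits, function(f) {
      list(mu_coeffs = unname(f$mu_coeffs), sigma_coeffs = unname(f$sigma_coeffs))
    })
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_error_model
#' @export
read_error_model <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(doc$type) || doc$type != "error_field_model") {
    abort(sprintf("'%s' is not a serialized error_field_model.", path))
  }
  structure(
    list(
      fits = purrr::map(doc$fits, function(f) {
        list(mu_coeffs = as.numeric(f$mu_coeffs),
             sigma_coeffs = as.numeric(f$sigma_coeffs))
      }),
      directions = as.integer(doc$directions), td = doc$td,
      sigma_floor = doc$sigma_floor, degree = doc$degree, n_bins = doc$n_bins
    ),
    class = "error_field_model"
  )
}

#' Plot the fitted error field
#'
#' Mean error with a one-SD ribbon over movement time, faceted by direction
#' and component.
#'
#' @param object An `error_field_model`.
#' @param n Number of evaluation points over the time domain.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.error_field_model <- function(object, n = 100, ...) {
  tt <- seq(0, object$td, length.out = n)
  df <- purrr::map_dfr(object$directions, function(d) {
    purrr::map_dfr(c("extent", "perp"), function(comp) {
      dplyr::mutate(mu_sigma_at(object, d, comp, tt),
                    direction_id = d, component = comp)
    })
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$mu)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mu - .data$sigma, ymax = .data$mu + .data$sigma),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(component ~ direction_id,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "time (s)", y = "error (cm)",
                  title = "Characterized error field (mean ± SD)")
}
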