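#' Define a planar reach
#'
#' A reach is a straight-line movement between two points in the on-screen
#' angle-angle plane, with an ideal duration that fixes the minimum-jerk
#' reference profile. The default geometry is the study task: targets 15 cm
#' apart and an ideal duration of 1.5 s.
#'
#' @param x0 Numeric length-2, start point in screen cm.
#' @param xT Numeric length-2, target point in screen cm.
#' @param td Ideal movement duration in seconds.
#' @param direction_id Integer label for the movement direction (0, 1, 2 in the
#'   default three-direction protocol).
#' @return An object of class `reach_spec`.
#' @examples
#' spec <- reach_spec(c(0, 0), c(15, 0))
#' min_jerk_position(spec, c(0, 0.75, 1.5))
#' @export
reach_spec <- function(x0, xT, td = 1.5, direction_id = 0L) {
  x0 <- as.numeric(x0)
  xT <- as.numeric(xT)
  if (length(x0) != 2 || length(xT) != 2 || !all(is.finite(c(x0, xT)))) {
    abort("`x0` and `xT` must be finite length-2 numeric points (screen cm).")
  }
  if (!is.numeric(td) || length(td) != 1 || !is.finite(td) || td <= 0) {
    abort("`td` must be a single positive duration in seconds.")
  }
  if (sqrt(sum((xT - x0)^2)) <= 0) {
    abort("Degenerate reach: start and target coincide.")
  }
  structure(
    list(x0 = x0, xT = xT, td = td, direction_id = as.integer(direction_id)),
    class = "reach_spec"
  )
}

#' @export
print.reach_spec <- function(x, ...) {
  cat(sprintf(
    "<reach_spec> direction %d: (%.2f, %.2f) -> (%.2f, %.2f) cm, td = %g s\n",
    x$direction_id, x$x0[1], x$x0[2], x$xT[1], x$xT[2], x$td
  ))
  invisible(x)
}

#' Default three-direction reach set
#'
#' Three reaches of equal length fanning out from a common origin at headings
#' 0, 120 and 240 degrees in the angle-angle plane, matching the study's
#' 15 cm / 1.5 s task geometry.
#'
#' @param distance Reach length in cm.
#' @param td Ideal duration in seconds.
#' @param headings_deg Numeric vector of reach headings in degrees; one reach
#'   spec is produced per heading, with `direction_id` 0, 1, ...
#' @param origin Common start point, screen cm.
#' @return A list of [reach_spec()] objects.
#' @export
default_reach_specs <- function(distance = 15, td = 1.5,
                                headings_deg = c(0, 120, 240),
                                origin = c(0, 0)) {
  purrr::imap(as.list(headings_deg), function(h, i) {
    a <- h * pi / 180
    reach_spec(origin, origin + distance * c(cos(a), sin(a)),
               td = td, direction_id = i - 1L)
  })
}

# unit vectors of the reach frame: u along start->target, n its +90deg rotation
reach_frame <- function(spec) {
  d <- spec$xT - spec$x0
  len <- sqrt(sum(d^2))
  u <- d / len
  list(u = u, n = c(-u[2], u[1]), length = len)
}

#' Minimum-jerk reference position
#'
#' Evaluates the smoothness-optimal straight-line reference
#' \eqn{x(t) = x_0 + (x_T - x_0)(10 s^3 - 15 s^4 + 6 s^5)} with
#' \eqn{s = t / t_d}. For `t > td` the reference is clamped at the target, so
#' the polynomial is never extrapolated.
#'
#' @param spec A [reach_spec()].
#' @param t Time(s) in seconds, each `>= 0`; vectorized.
#' @return A tibble with columns `t`, `x`, `y` (cm).
#' @export
min_jerk_position <- function(spec, t) {
  stopifnot(inherits(spec, "reach_spec"))
  if (!is.numeric(t) || !all(is.finite(t))) abort("`t` must be finite numeric.")
  if (any(t < 0)) abort("`t` must be non-negative.")
  s <- pmin(t / spec$td, 1)
  g <- 10 * s^3 - 15 * s^4 + 6 * s^5
  d <- spec$xT - spec$x0
  tibble::tibble(t = t, x = spec$x0[1] + d[1] * g, y = spec$x0[2] + d[2] * g)
}

#' Minimum-jerk reference trajectory on a regular grid
#'
#' @param spec A [reach_spec()].
#' @param dt Sample interval in seconds (default 0.01, i.e. 100 Hz).
#' @return A tibble with columns `t`, `x`, `y` covering `[0, td]`.
#' @export
min_jerk_trajectory <- function(spec, dt = 0.01) {
  stopifnot(inherits(spec, "reach_spec"))
  if (!is.numeric(dt) || length(dt) != 1 || !is.finite(dt) || dt <= 0) {
    abort("`dt` must be a single positive sample interval in seconds.")
  }
  if (dt >= spec$td) abort("`dt` must be smaller than the reach duration `td`.")
  min_jerk_position(spec, seq(0, spec$td, by = dt))
}

#' Affine calibration between joint angles and screen position
#'
#' The display plots shoulder rotation against elbow flexion; the calibration
#' is the per-axis scale (cm per radian) and offset that places that plot in
#' screen cm. It must be invertible (non-zero scales).
#'
#' @param scale Length-2 numeric, cm per radian for (shoulder, elbow).
#' @param offset Length-2 numeric, screen cm.
#' @return An object of class `screen_calibration`.
#' @export
screen_calibration <- function(scale = c(10, 10), offset = c(0, 0)) {
  scale <- as.numeric(scale); offset <- as.numeric(offset)
  if (length(scale) != 2 || !all(is.finite(scale)) || any(scale == 0)) {
    abort("Singular calibration: `scale` must be two non-zero finite values.")
  }
  if (length(offset) != 2 || !all(is.finite(offset))) {
    abort("`offset` must be two finite values.")
  }
  structure(list(scale = scale, offset = offset), class = "screen_calibration")
}

#' Map joint angles to screen position (and back)
#'
#' `angle_to_screen()` applies the affine calibration to joint angles
#' (radians); `screen_to_angle()` is its exact inverse.
#'
#' @param joints A data frame with columns `theta_shoulder`, `theta_elbow`
#'   (radians).
#' @param points A data frame with columns `x`, `y` (screen cm).
#' @param calibration A [screen_calibration()].
#' @return A tibble with columns `x`, `y` (cm), or `theta_shoulder`,
#'   `theta_elbow` (radians) for the inverse.
#' @export
angle_to_screen <- function(joints, calibration = screen_calibration()) {
  stopifnot(inherits(calibration, "screen_calibration"))
  req <- c("theta_shoulder", "theta_elbow")
  check_columns(joints, req, "joints")
  tibble::tibble(
    x = joints$theta_shoulder * calibration$scale[1] + calibration$offset[1],
    y = joints$theta_elbow * calibration$scale[2] + calibration$offset[2]
  )
}

#' @rdname angle_to_screen
#' @export
screen_to_angle <- function(points, calibration = screen_calibration()) {
  stopifnot(inherits(calibration, "screen_calibration"))
  check_columns(points, c("x", "y"), "points")
  tibble::tibble(
    theta_shoulder = (points$x - calibration$offset[1]) / calibration$scale[1],
    theta_elbow = (points$y - calibration$offset[2]) / calibration$scale[2]
  )
}

#' Resolve cursor error into extent and perpendicular components
#'
#' The error vector is the cursor position minus the minimum-jerk reference at
#' the same time. It is resolved along the start-to-target unit vector
#' (*extent*, positive toward or past the target) and its +90-degree rotation
#' (*perpendicular*, positive on the counter-clockwise side). The
#' decomposition is an isometry: `extent^2 + perpendicular^2 = |error|^2`.
#'
#' @param actual A data frame with columns `t` (s), `x`, `y` (cm): measured
#'   cursor samples.
#' @param spec The [reach_spec()] the samples belong to.
#' @return A tibble with columns `t`, `extent_err`, `perp_err` (cm), and
#'   `direction_id`.
#' @export
decompose_error <- function(actual, spec) {
  stopifnot(inherits(spec, "reach_spec"))
  check_columns(actual, c("t", "x", "y"), "actual")
  if (any(actual$t < 0)) abort("`t` must be non-negative.")
  fr <- reach_frame(spec)
  ref <- min_jerk_position(spec, actual$t)
  ex <- actual$x - ref$x
  ey <- actual$y - ref$y
  tibble::tibble(
    t = actual$t,
    extent_err = ex * fr$u[1] + ey * fr$u[2],
    perp_err = ex * fr$n[1] + ey * fr$n[2],
    direction_id = spec$direction_id
  )
}

check_columns <- function(data, required, arg) {
  if (!is.data.frame(data)) abort(sprintf("`%s` must be a data frame.", arg))
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    abort(sprintf(
      "`%s` is missing required column%s: %s.",
      arg, if (length(missing) > 1) "s" else "", paste(missing, collapse = ", ")
    ))
  }
  invisible(data)
}
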