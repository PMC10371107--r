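#' Visuomotor transformation applied to the cursor
#'
#' On transformed trials the cursor is driven by the angle-angle remapping
#' rather than veridical hand position. Relative to the reach start point the
#' remap acts as an affine distortion: `cursor_rel = M %*% aim_rel + bias`,
#' with `M` a rotation scaled by `gain`. A naive mover aiming along the
#' reference therefore produces systematic, direction-dependent errors — the
#' raw material for characterization and training.
#'
#' @param rotation_deg Rotation of the distortion, degrees (default 25).
#' @param gain Isotropic gain of the distortion (default 1).
#' @param bias Constant offset, cm.
#' @return An object of class `visuomotor_transform`.
#' @export
visuomotor_transform <- function(rotation_deg = 25, gain = 1, bias = c(0, 0)) {
  if (!is.finite(rotation_deg) || !is.finite(gain) || gain <= 0) {
    abort("`rotation_deg` must be finite and `gain` positive.")
  }
  a <- rotation_deg * pi / 180
  structure(
    list(M = gain * matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2),
         bias = as.numeric(bias), rotation_deg = rotation_deg, gain = gain),
    class = "visuomotor_transform"
  )
}

#' Synthetic adapting learner
#'
#' Linear state-space model of trial-by-trial motor adaptation: the learner
#' holds an internal compensation for the visuomotor transformation (a 2x2
#' gain matrix plus bias, its estimate of the inverse remap relative to the
#' veridical default) and updates it after each transformed trial with a
#' retention factor and an error-driven gradient step. Reaches are executed
#' with correlated motor noise, and applied robot torque displaces the cursor
#' through a scalar admittance — so haptic augmentation changes the
#' *experienced* error that drives adaptation.
#'
#' @param learning_rate Error-to-update gain, in `[0, 1)` (0 = no learning).
#' @param retention Trial-to-trial retention of the internal map, in (0, 1].
#' @param motor_noise_sd Within-trial motor noise SD per error component, cm.
#' @param admittance Cursor displacement per unit applied torque, cm/Nm.
#' @param map_gain Initial 2x2 compensation matrix (default zero = naive).
#' @param map_bias Initial compensation bias, cm.
#' @return An object of class `learner_state`.
#' @export
learner_state <- function(learning_rate = 0.15, retention = 0.99,
                          motor_noise_sd = 0.5, admittance = 0.1,
                          map_gain = matrix(0, 2, 2), map_bias = c(0, 0)) {
  if (learning_rate < 0 || learning_rate >= 1) {
    abort("`learning_rate` must lie in [0, 1).")
  }
  if (retention <= 0 || retention > 1) abort("`retention` must lie in (0, 1].")
  if (motor_noise_sd < 0) abort("`motor_noise_sd` must be non-negative (cm).")
  if (admittance < 0) abort("`admittance` must be non-negative (cm/Nm).")
  map_gain <- matrix(as.numeric(map_gain), 2, 2)
  structure(
    list(learning_rate = learning_rate, retention = retention,
         motor_noise_sd = motor_noise_sd, admittance = admittance,
         map_gain = map_gain, map_bias = as.numeric(map_bias)),
    class = "learner_state"
  )
}

#' @export
print.learner_state <- function(x, ...) {
  cat(sprintf(
    "<learner_state> lr %.3g, retention %.4g, noise %.3g cm, admittance %.3g cm/Nm\n",
    x$learning_rate, x$retention, x$motor_noise_sd, x$admittance
  ))
  invisible(x)
}

#' Simulation protocol configuration
#'
#' Trial counts and task geometry for the three-phase protocol: baseline
#' (veridical cursor, forces off), intermittent exposure (the transformation
#' on a random one-in-five of trials, forces off — used to characterize naive
#' errors), and training (transformation always on, forces per controller
#' mode, 70 trials).
#'
#' @param seed Integer seed; all randomness in [run_protocol()] flows from it.
#' @param n_baseline,n_intermittent,n_training Trial counts per phase.
#' @param intermittent_fraction Fraction of intermittent-exposure trials with
#'   the transformation on (default 1/5); the realized count is exact
#'   (`round(n * fraction)`), spread as evenly as possible across directions.
#' @param reach_specs List of [reach_spec()]s, one per movement direction.
#' @param transform The [visuomotor_transform()] to be learned.
#' @param dt Sample interval, seconds (default 0.01 = 100 Hz).
#' @param duration_tolerance Half-width of the "proper timing" feedback band
#'   around the ideal duration, seconds.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_baseline = 30, n_intermittent = 50,
                       n_training = 70, intermittent_fraction = 1 / 5,
                       reach_specs = default_reach_specs(),
                       transform = visuomotor_transform(), dt = 0.01,
                       duration_tolerance = 0.15) {
  if (n_baseline <= 0 || n_intermittent <= 0 || n_training <= 0) {
    abort("Trial counts must be positive.")
  }
  if (intermittent_fraction <= 0 || intermittent_fraction >= 1) {
    abort("`intermittent_fraction` must lie in (0, 1).")
  }
  stopifnot(length(reach_specs) >= 1,
            all(vapply(reach_specs, inherits, logical(1), "reach_spec")),
            inherits(transform, "visuomotor_transform"))
  structure(
    list(seed = as.integer(seed), n_baseline = n_baseline,
         n_intermittent = n_intermittent, n_training = n_training,
         intermittent_fraction = intermittent_fraction,
         reach_specs = reach_specs, transform = transform, dt = dt,
         duration_tolerance = duration_tolerance),
    class = "sim_config"
  )
}

# correlated (moving-average smoothed) motor noise, rescaled to target sd
smooth_noise <- function(n, sd_target, window = 15) {
  if (sd_target <= 0) return(numeric(n))
  w <- min(window, n)
  raw <- rnorm(n + w - 1)
  sm <- as.numeric(stats::filter(raw, rep(1 / w, w), sides = 1))[w:(n + w - 1)]
  s <- sd(sm)
  if (!is.finite(s) || s == 0) return(numeric(n))
  sm / s * sd_target
}

#' Execute one simulated reaching trial
#'
#' Runs the closed loop for a single trial: the learner plans a minimum-jerk
#' reach and aims through its internal compensation; on transformed trials the
#' visuomotor distortion maps the aim to the cursor; motor noise is added; and
#' when forces are on, the controller torque computed from the *current*
#' experienced error displaces the cursor through the learner's admittance
#' (torque acts with a one-sample delay, the causal discrete-time loop).
#'
#' Randomness (motor noise, movement duration) is drawn from the current R
#' RNG state, so results are reproducible by seeding before the call.
#'
#' @param learner A [learner_state()].
#' @param spec The [reach_spec()] for this trial.
#' @param transformed Is the visuomotor transformation on?
#' @param cfg A [controller_config()]; torques are computed only when
#'   `forces_on` is `TRUE` and `cfg$mode != "null"`.
#' @param model `error_field_model` (required for EF with forces on).
#' @param transform The [visuomotor_transform()].
#' @param forces_on Are treatment forces applied this trial?
#' @param dt Sample interval, seconds.
#' @return A tibble with one row per sample: `t`, `x`, `y` (cursor, cm),
#'   `ref_x`, `ref_y`, `extent_err`, `perp_err` (cm), `torque_extent`,
#'   `torque_perp` (Nm), `direction_id`, `transformed`, `forces_on`; the
#'   realized movement duration is attached as attribute `"duration"`.
#' @export
execute_trial <- function(learner, spec, transformed, cfg = controller_config("null"),
                          model = NULL, transform = visuomotor_transform(),
                          forces_on = FALSE, dt = 0.01) {
  stopifnot(inherits(learner, "learner_state"), inherits(spec, "reach_spec"),
            inherits(cfg, "controller_config"))
  apply_forces <- isTRUE(forces_on) && cfg$mode != "null"
  if (apply_forces && cfg$mode == "ef" && is.null(model)) {
    abort("EF mode with forces on requires an `error_field_model`.")
  }
  tt <- seq(0, spec$td, by = dt)
  n <- length(tt)
  ref <- min_jerk_position(spec, tt)
  fr <- reach_frame(spec)
  rel <- cbind(ref$x - spec$x0[1], ref$y - spec$x0[2])  # n x 2

  if (isTRUE(transformed)) {
    aim <- rel %*% t(diag(2) + learner$map_gain) +
      matrix(learner$map_bias, n, 2, byrow = TRUE)
    cursor_rel <- aim %*% t(transform$M) +
      matrix(transform$bias, n, 2, byrow = TRUE)
    e_raw <- cursor_rel - rel
  } else {
    e_raw <- matrix(0, n, 2)  # veridical display: the default map is correct
  }
  noise_e <- smooth_noise(n, learner$motor_noise_sd)
  noise_p <- smooth_noise(n, learner$motor_noise_sd)
  # base error in the reach frame
  e_ext <- e_raw[, 1] * fr$u[1] + e_raw[, 2] * fr$u[2] + noise_e
  e_perp <- e_raw[, 1] * fr$n[1] + e_raw[, 2] * fr$n[2] + noise_p

  tau_ext <- numeric(n)
  tau_perp <- numeric(n)
  if (apply_forces) {
    if (cfg$mode == "ef") {
      ms_e <- mu_sigma_at(model, spec$direction_id, "extent", tt)
      ms_p <- mu_sigma_at(model, spec$direction_id, "perp", tt)
    }
    adm <- learner$admittance
    lam <- cfg$lambda
    cap <- cfg$torque_cap
    gate <- tt < cfg$force_window
    pe <- prev_e <- 0
    prev_te <- prev_tp <- 0
    inv_sqrt2pi <- 1 / sqrt(2 * pi)
    for (k in seq_len(n)) {
      ee <- e_ext[k] + adm * prev_te
      ep <- e_perp[k] + adm * prev_tp
      if (abs(ee) > 1e3 || abs(ep) > 1e3) {
        abort("Closed-loop divergence (> 1000 cm): unstable admittance/lambda configuration.")
      }
      e_ext[k] <- ee
      e_perp[k] <- ep
      if (gate[k]) {
        if (cfg$mode == "ea") {
          te <- lam * ee
          tp <- lam * ep
        } else {
          ze <- (ee - ms_e$mu[k]) / ms_e$sigma[k]
          zp <- (ep - ms_p$mu[k]) / ms_p$sigma[k]
          te <- lam * exp(-0.5 * ze * ze) * inv_sqrt2pi / ms_e$sigma[k] * ee
          tp <- lam * exp(-0.5 * zp * zp) * inv_sqrt2pi / ms_p$sigma[k] * ep
        }
        mag <- sqrt(te * te + tp * tp)
        if (mag > cap) {
          te <- te * cap / mag
          tp <- tp * cap / mag
        }
      } else {
        te <- tp <- 0
      }
      tau_ext[k] <- te
      tau_perp[k] <- tp
      prev_te <- te
      prev_tp <- tp
    }
  }

  cx <- ref$x + e_ext * fr$u[1] + e_perp * fr$n[1]
  cy <- ref$y + e_ext * fr$u[2] + e_perp * fr$n[2]
  out <- tibble::tibble(
    t = tt, x = cx, y = cy, ref_x = ref$x, ref_y = ref$y,
    extent_err = e_ext, perp_err = e_perp,
    torque_extent = tau_ext, torque_perp = tau_perp,
    direction_id = spec$direction_id,
    transformed = isTRUE(transformed), forces_on = apply_forces
  )
  attr(out, "duration") <- spec$td + rnorm(1, 0, 0.08)
  out
}

#' Update the learner from one trial's experienced error
#'
#' Trial-by-trial adaptation: the internal compensation is pulled toward
#' cancelling the trial's experienced cursor error (which includes any
#' torque-induced displacement), with retention decay toward the naive
#' default. The update is purely error-driven — it uses only the recorded
#' cursor and reference, never the true transformation. Each trial informs the
#' map only along its own movement direction; cycling directions identifies
#' the full map.
#'
#' @param learner A [learner_state()].
#' @param record A trial tibble from [execute_trial()].
#' @return The updated `learner_state`.
#' @export
update_learner <- function(learner, record) {
  stopifnot(inherits(learner, "learner_state"))
  check_columns(record, c("x", "y", "ref_x", "ref_y"), "record")
  if (nrow(record) == 0) abort("`record` has no samples.")
  e <- cbind(record$x - record$ref_x, record$y - record$ref_y)
  r <- cbind(record$ref_x - record$ref_x[1], record$ref_y - record$ref_y[1])
  denom <- sum(r * r)
  grad <- if (denom > 0) crossprod(e, r) / denom else matrix(0, 2, 2)
  learner$map_gain <- learner$retention * learner$map_gain -
    learner$learning_rate * grad
  learner$map_bias <- learner$retention * learner$map_bias -
    learner$learning_rate * colMeans(e)
  learner
}

# balanced, shuffled direction sequence for a phase
direction_sequence <- function(n, n_dirs) {
  sample(rep_len(seq_len(n_dirs) - 1L, n))
}

duration_feedback <- function(duration, td, tol) {
  dplyr::case_when(
    abs(duration - td) <= tol ~ "proper",
    duration > td ~ "slow",
    TRUE ~ "fast"
  )
}

#' Run the full three-phase training protocol for one subject
#'
#' Executes baseline, intermittent exposure, and training in order. Between
#' intermittent exposure and training (for EF/EA modes) the transformed
#' intermittent trials are used to characterize the subject's error statistics
#' ([characterize_errors()]) and to calibrate the torque scale factor
#' ([calibrate_lambda()]); training then runs with the transformation always
#' on and forces per controller mode. The learner adapts on every transformed
#' trial. Fully reproducible from `sim$seed`.
#'
#' @param sim A [sim_config()].
#' @param learner A [learner_state()].
#' @param cfg A [controller_config()]; its `lambda` is replaced by the
#'   per-subject calibrated value for EF/EA modes.
#' @return A long tibble of class `ef_protocol` with one row per recorded
#'   sample and columns `phase`, `trial_index`, `direction_id`, `transformed`,
#'   `forces_on`, `duration_feedback`, `t`, `x`, `y`, `ref_x`, `ref_y`,
#'   `extent_err`, `perp_err`, `torque_extent`, `torque_perp`. The fitted
#'   `error_field_model`, the calibrated lambda, the final learner state and
#'   the configuration are attached as attributes `"model"`, `"lambda"`,
#'   `"learner"`, `"config"`.
#' @export
run_protocol <- function(sim, learner, cfg = controller_config("null")) {
  stopifnot(inherits(sim, "sim_config"), inherits(learner, "learner_state"),
            inherits(cfg, "controller_config"))
  set.seed(sim$seed)
  n_dirs <- length(sim$reach_specs)
  records <- list()
  trial_meta <- list()
  trial_no <- 0L

  run_phase <- function(phase, n, transformed_flags, forces, model = NULL,
                        update = TRUE) {
    dirs <- direction_sequence(n, n_dirs)
    for (j in seq_len(n)) {
      trial_no <<- trial_no + 1L
      spec <- sim$reach_specs[[dirs[j] + 1L]]
      rec <- execute_trial(learner, spec, transformed = transformed_flags[j],
                           cfg = cfg, model = model,
                           transform = sim$transform,
                           forces_on = forces, dt = sim$dt)
      if (update && transformed_flags[j]) {
        learner <<- update_learner(learner, rec)
      }
      records[[trial_no]] <<- rec
      trial_meta[[trial_no]] <<- list(
        phase = phase, trial_index = trial_no,
        duration = attr(rec, "duration")
      )
    }
    invisible(dirs)
  }

  # Baseline: veridical display, no forces, no adaptation needed
  run_phase("baseline", sim$n_baseline, rep(FALSE, sim$n_baseline),
            forces = FALSE)

  # Intermittent exposure: transformation on an exact 1-in-5 of trials,
  # stratified over directions so every direction yields >= 2 trials
  n_int <- sim$n_intermittent
  dirs_int <- direction_sequence(n_int, n_dirs)
  k <- round(n_int * sim$intermittent_fraction)
  per_dir <- rep(k %/% n_dirs, n_dirs)
  extra <- k %% n_dirs
  if (extra > 0) {
    bump <- sample(seq_len(n_dirs), extra)
    per_dir[bump] <- per_dir[bump] + 1L
  }
  flags <- rep(FALSE, n_int)
  for (d in seq_len(n_dirs)) {
    idx <- which(dirs_int == d - 1L)
    take <- min(per_dir[d], length(idx))
    if (take > 0) flags[sample(idx, take)] <- TRUE
  }
  start_int <- trial_no + 1L
  for (j in seq_len(n_int)) {
    trial_no <- trial_no + 1L
    spec <- sim$reach_specs[[dirs_int[j] + 1L]]
    rec <- execute_trial(learner, spec, transformed = flags[j], cfg = cfg,
                         transform = sim$transform, forces_on = FALSE,
                         dt = sim$dt)
    if (flags[j]) learner <- update_learner(learner, rec)
    records[[trial_no]] <- rec
    trial_meta[[trial_no]] <- list(phase = "intermittent",
                                   trial_index = trial_no,
                                   duration = attr(rec, "duration"))
  }

  # Characterize and calibrate from transformed intermittent trials
  model <- NULL
  lambda <- NA_real_
  if (cfg$mode != "null") {
    char_idx <- which(flags) + start_int - 1L
    char <- purrr::map_dfr(char_idx, function(i) {
      dplyr::mutate(
        records[[i]][, c("t", "extent_err", "perp_err", "direction_id")],
        trial_index = i
      )
    })
    model <- tryCatch(
      characterize_errors(char, td = sim$reach_specs[[1]]$td),
      error = function(e) {
        abort(paste0("Error characterization failed: ", conditionMessage(e)))
      }
    )
    lambda <- calibrate_lambda(char, mode = cfg$mode, model = model)
    cfg <- controller_config(cfg$mode, lambda = lambda,
                             torque_cap = cfg$torque_cap,
                             force_window = cfg$force_window)
  }

  # Training: transformation always on, forces per mode
  run_phase("training", sim$n_training, rep(TRUE, sim$n_training),
            forces = cfg$mode != "null", model = model)

  meta <- purrr::map_dfr(trial_meta, tibble::as_tibble)
  meta$duration_feedback <- duration_feedback(
    meta$duration, sim$reach_specs[[1]]$td, sim$duration_tolerance
  )
  out <- dplyr::bind_rows(records, .id = ".trial") |>
    dplyr::mutate(trial_index = as.integer(.data$.trial), .trial = NULL) |>
    dplyr::left_join(meta, by = "trial_index") |>
    dplyr::select("phase", "trial_index", "direction_id", "transformed",
                  "forces_on", "duration_feedback", "t", "x", "y",
                  "ref_x", "ref_y", "extent_err", "perp_err",
                  "torque_extent", "torque_perp")
  attr(out, "model") <- model
  attr(out, "lambda") <- lambda
  attr(out, "learner") <- learner
  attr(out, "config") <- list(sim = sim, controller = cfg)
  class(out) <- c("ef_protocol", class(out))
  out
}

#' Prior distributions for cohort learner parameters
#'
#' Uniform ranges from which per-subject learner parameters are drawn by
#' [generate_cohort()]. Defaults emulate a healthy adult cohort: moderate
#' learning rates, high retention, sub-centimetre motor noise, and a limb
#' admittance that makes a 15 Nm torque displace the cursor by one to two cm.
#'
#' @param learning_rate,retention,motor_noise_sd,admittance Length-2 numeric
#'   ranges (min, max).
#' @param map_jitter_sd SD of the random initial compensation entries
#'   (subject-specific starting map error).
#' @return A list of class `learner_prior`.
#' @export
learner_prior <- function(learning_rate = c(0.10, 0.25),
                          retention = c(0.98, 0.999),
                          motor_noise_sd = c(0.3, 0.8),
                          admittance = c(0.05, 0.15),
                          map_jitter_sd = 0.03) {
  structure(
    list(learning_rate = learning_rate, retention = retention,
         motor_noise_sd = motor_noise_sd, admittance = admittance,
         map_jitter_sd = map_jitter_sd),
    class = "learner_prior"
  )
}

draw_learner <- function(prior) {
  u <- function(rg) runif(1, rg[1], rg[2])
  learner_state(
    learning_rate = u(prior$learning_rate),
    retention = u(prior$retention),
    motor_noise_sd = u(prior$motor_noise_sd),
    admittance = u(prior$admittance),
    map_gain = matrix(rnorm(4, 0, prior$map_jitter_sd), 2, 2),
    map_bias = rnorm(2, 0, prior$map_jitter_sd * 10)
  )
}

#' Simulate a cohort of subjects across treatment groups
#'
#' Draws per-subject learner parameters from `prior`, runs the full protocol
#' for each subject in each treatment group, and binds everything into one
#' long trial table. Reproducible from `base_seed`.
#'
#' @param n_per_group Subjects per group (>= 2).
#' @param modes Character vector of controller modes, one group per entry.
#' @param base_seed Integer master seed.
#' @param prior A [learner_prior()].
#' @param sim A [sim_config()] template; each subject gets its own seed.
#' @return A tibble of class `ef_cohort`: the [run_protocol()] columns plus
#'   `subject_id` and `group`. Per-subject calibrated lambdas are attached as
#'   attribute `"lambdas"` (a tibble).
#' @export
generate_cohort <- function(n_per_group = 7, modes = c("ef", "ea", "null"),
                            base_seed = 1L, prior = learner_prior(),
                            sim = sim_config()) {
  if (n_per_group < 2) abort("`n_per_group` must be at least 2.")
  set.seed(base_seed)
  plan <- tidyr::expand_grid(group = modes, subject = seq_len(n_per_group))
  plan$seed <- sample.int(.Machine$integer.max, nrow(plan))
  # draw all learners under the master seed before any protocol reseeds
  learners <- purrr::map(seq_len(nrow(plan)), function(i) draw_learner(prior))

  runs <- purrr::map(seq_len(nrow(plan)), function(i) {
    g <- plan$group[i]
    sid <- sprintf("%s_%02d", g, plan$subject[i])
    sub_sim <- sim
    sub_sim$seed <- plan$seed[i]
    res <- run_protocol(sub_sim, learners[[i]], controller_config(g))
    list(
      trials = dplyr::mutate(tibble::as_tibble(res), subject_id = sid,
                             group = g, .before = 1),
      lambda = tibble::tibble(subject_id = sid, group = g,
                              lambda = attr(res, "lambda"))
    )
  })
  out <- purrr::map_dfr(runs, "trials")
  attr(out, "lambdas") <- purrr::map_dfr(runs, "lambda")
  class(out) <- c("ef_cohort", class(out))
  out
}
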