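spec0 <- reach_spec(c(0, 0), c(15, 0), td = 1.5, direction_id = 0L)

test_that("a learner holding the inverse transform makes no error", {
  tf <- visuomotor_transform(rotation_deg = 25, gain = 1.1, bias = c(1, -2))
  Minv <- solve(tf$M)
  perfect <- learner_state(motor_noise_sd = 0,
                           map_gain = Minv - diag(2),
                           map_bias = as.numeric(-Minv %*% tf$bias))
  rec <- execute_trial(perfect, spec0, transformed = TRUE, transform = tf)
  expect_equal(max(abs(rec$extent_err)), 0, tolerance = 1e-12)
  expect_equal(max(abs(rec$perp_err)), 0, tolerance = 1e-12)
})

test_that("a pure display bias produces a constant cursor bias", {
  tf <- visuomotor_transform(rotation_deg = 0, gain = 1, bias = c(0.8, -0.3))
  naive <- learner_state(motor_noise_sd = 0)
  rec <- execute_trial(naive, spec0, transformed = TRUE, transform = tf)
  # closed form: error = bias, constant along the whole reach
  expect_equal(unique(round(rec$extent_err, 12)), 0.8)
  expect_equal(unique(round(rec$perp_err, 12)), -0.3)
})

test_that("trial execution is bit-identical under a repeated seed", {
  l <- learner_state()
  set.seed(33)
  a <- execute_trial(l, spec0, transformed = TRUE)
  set.seed(33)
  b <- execute_trial(l, spec0, transformed = TRUE)
  expect_identical(a, b)
})

test_that("learner updates are retention-and-error driven", {
  tf <- visuomotor_transform(rotation_deg = 20)
  l <- learner_state(learning_rate = 0.2, retention = 0.95,
                     motor_noise_sd = 0, map_gain = diag(0.1, 2))
  # zero experienced error: map only shrinks by retention
  zero_rec <- tibble::tibble(x = 1:5, y = 1:5, ref_x = 1:5, ref_y = 1:5)
  l2 <- update_learner(l, zero_rec)
  expect_equal(l2$map_gain, 0.95 * l$map_gain)
  expect_equal(l2$map_bias, 0.95 * l$map_bias)
  # zero learning rate: unchanged up to retention
  l0 <- learner_state(learning_rate = 0, retention = 0.9, motor_noise_sd = 0,
                      map_gain = diag(0.2, 2), map_bias = c(1, 1))
  rec <- execute_trial(l0, spec0, transformed = TRUE, transform = tf)
  l02 <- update_learner(l0, rec)
  expect_equal(l02$map_gain, 0.9 * l0$map_gain)

  # repeated identical trials with no noise: error norm non-increasing
  lr <- learner_state(learning_rate = 0.2, retention = 1, motor_noise_sd = 0)
  errs <- numeric(50)
  for (k in 1:50) {
    rec <- execute_trial(lr, spec0, transformed = TRUE, transform = tf)
    errs[k] <- mean(sqrt(rec$extent_err^2 + rec$perp_err^2))
    lr <- update_learner(lr, rec)
  }
  expect_true(all(diff(errs) <= 1e-10))
  expect_lt(errs[50], errs[1] / 10)
})

test_that("an over-aggressive closed loop is reported, not silently run", {
  # admittance x lambda gain far above 1 diverges within the trial
  l <- learner_state(motor_noise_sd = 0, admittance = 0.9)
  cfg <- controller_config("ea", lambda = 200, torque_cap = 1e9)
  tf <- visuomotor_transform(rotation_deg = 25)
  expect_error(
    execute_trial(l, spec0, transformed = TRUE, cfg = cfg, transform = tf,
                  forces_on = TRUE),
    "divergence"
  )
})

test_that("the protocol runs its phases with exact intermittent dosing", {
  sim <- sim_config(seed = 5, n_baseline = 12, n_intermittent = 50,
                    n_training = 20)
  res <- run_protocol(sim, learner_state(), controller_config("null"))
  trials <- dplyr::distinct(res, .data$phase, .data$trial_index,
                            .data$transformed, .data$forces_on,
                            .data$duration_feedback)
  expect_equal(sum(trials$phase == "baseline"), 12)
  expect_equal(sum(trials$phase == "intermittent"), 50)
  expect_equal(sum(trials$phase == "training"), 20)
  # exactly one-in-five intermittent trials carry the transformation
  expect_equal(sum(trials$transformed[trials$phase == "intermittent"]), 10)
  expect_false(any(trials$transformed[trials$phase == "baseline"]))
  expect_true(all(trials$transformed[trials$phase == "training"]))
  # null mode: every torque is zero
  expect_true(all(res$torque_extent == 0 & res$torque_perp == 0))
  expect_true(all(trials$duration_feedback %in% c("proper", "slow", "fast")))
  # determinism
  res2 <- run_protocol(sim, learner_state(), controller_config("null"))
  expect_identical(tibble::as_tibble(res), tibble::as_tibble(res2))
})

test_that("forces-on protocols respect the torque envelope end-to-end", {
  sim <- sim_config(seed = 8, n_baseline = 6, n_intermittent = 30,
                    n_training = 25)
  for (mode in c("ef", "ea")) {
    res <- run_protocol(sim, learner_state(), controller_config(mode))
    expect_true(is.finite(attr(res, "lambda")) && attr(res, "lambda") > 0)
    expect_s3_class(attr(res, "model"), "error_field_model")
    mag <- sqrt(res$torque_extent^2 + res$torque_perp^2)
    expect_true(all(mag <= 15 + 1e-9))
    expect_true(all(mag[res$t >= 1.5] == 0))
    expect_true(any(mag[res$phase == "training"] > 0))
    expect_true(all(mag[res$phase != "training"] == 0))
  }
})

test_that("without the transformation errors sit at the motor-noise floor", {
  sim <- sim_config(seed = 13, n_baseline = 30, n_intermittent = 30,
                    n_training = 10)
  l <- learner_state(motor_noise_sd = 0.5)
  res <- run_protocol(sim, l, controller_config("null"))
  base <- dplyr::filter(res, .data$phase == "baseline")
  mean_mag <- mean(sqrt(base$extent_err^2 + base$perp_err^2))
  # mean |2-D noise| is about 1.25 * sd; must be within 2 SDs of the floor
  expect_lt(abs(mean_mag), 2 * 0.5 + 1.25 * 0.5)
  expect_gt(mean_mag, 0)
})

test_that("training error trends downward for an adapting learner", {
  rhos <- purrr::map_dbl(1:4, function(s) {
    res <- run_protocol(
      sim_config(seed = 100 + s, n_baseline = 5, n_intermittent = 15),
      learner_state(), controller_config("null")
    )
    ser <- trial_error_series(res)
    suppressWarnings(stats::cor(ser$trial, ser$error, method = "spearman"))
  })
  expect_true(all(rhos < 0))
})

test_that("cohorts are reproducible and heterogeneous", {
  a <- generate_cohort(n_per_group = 2, modes = "null", base_seed = 77,
                       sim = sim_config(n_baseline = 5, n_intermittent = 15,
                                        n_training = 15))
  b <- generate_cohort(n_per_group = 2, modes = "null", base_seed = 77,
                       sim = sim_config(n_baseline = 5, n_intermittent = 15,
                                        n_training = 15))
  expect_identical(tibble::as_tibble(a), tibble::as_tibble(b))
  expect_equal(length(unique(a$subject_id)), 2)
  # subjects differ: per-subject mean intermittent transformed error varies
  means <- a |>
    dplyr::filter(.data$phase == "intermittent", .data$transformed) |>
    dplyr::group_by(.data$subject_id) |>
    dplyr::summarise(m = mean(sqrt(.data$extent_err^2 + .data$perp_err^2)))
  expect_gt(stats::var(means$m), 0)
})
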