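fake_training <- function(fn, n_trials = 12, n_samples = 6) {
  tidyr::expand_grid(trial_index = seq_len(n_trials),
                     s = seq_len(n_samples)) |>
    dplyr::mutate(t = (s - 1) * 0.25, phase = "training",
                  extent_err = fn(trial_index, "extent"),
                  perp_err = fn(trial_index, "perp")) |>
    dplyr::select(-"s")
}

test_that("trial error series averages the error magnitude per trial", {
  zeros <- fake_training(function(i, c) 0)
  expect_equal(trial_error_series(zeros)$error, rep(0, 12))
  const <- fake_training(function(i, c) if (c == "extent") 3 else 4)
  s <- trial_error_series(const)
  expect_equal(s$error, rep(5, 12))
  expect_equal(s$trial, 1:12)
  doubled <- fake_training(function(i, c) 2 * (if (c == "extent") 3 else 4))
  expect_equal(trial_error_series(doubled)$error, 2 * s$error)
  expect_error(trial_error_series(const[0, ]), "No training")
})

test_that("noiseless decay series are recovered almost exactly", {
  y <- 1 + 4 * exp(-(0:69) / 10)
  f <- fit_decay(y)
  expect_equal(f$S, 1, tolerance = 1e-3)
  expect_equal(f$R, 4, tolerance = 1e-3)
  expect_equal(f$tau, 10, tolerance = 1e-3)
  expect_lt(f$nrmse, 1e-4)
  td <- tidy(f)
  expect_equal(td$term, c("S", "R", "tau"))
  expect_equal(glance(f)$n_trials, 70)
})

test_that("degenerate series hit the non-negativity boundary correctly", {
  cst <- fit_decay(rep(3.2, 20))
  expect_equal(cst$S, 3.2)
  expect_equal(cst$R, 0)
  expect_equal(cst$tau, 0.5)  # unidentifiable: reported at the grid edge
  inc <- fit_decay(seq(1, 5, length.out = 20))
  expect_equal(inc$R, 0)
  expect_equal(inc$S, 3, tolerance = 1e-10)  # the series mean
  expect_error(fit_decay(c(1, NA, rep(1, 10))), "finite|Non-finite")
  expect_error(fit_decay(1:5), "at least 10")
})

test_that("the fit is never worse than a brute-force (S, R, tau) grid", {
  set.seed(14)
  for (i in 1:20) {
    S <- runif(1, 0, 3); R <- runif(1, 0.5, 6); tau <- runif(1, 2, 40)
    t <- 0:49
    y <- S + R * exp(-t / tau) + rnorm(50, 0, 0.1 * R)
    y <- pmax(y, 0)
    f <- fit_decay(y)
    sse_fit <- sum((y - f$S - f$R * exp(-t / f$tau))^2)
    sse_brute <- brute_force_decay_sse(t, y)
    expect_lte(sse_fit, sse_brute * 1.01)
  }
})

test_that("parameters are recovered from noisy series within stated bounds", {
  set.seed(15)
  rel <- purrr::map_dfr(1:100, function(i) {
    S <- runif(1, 0.5, 2); R <- runif(1, 2, 6); tau <- runif(1, 5, 25)
    y <- S + R * exp(-(0:69) / tau) + rnorm(70, 0, 0.1 * R)
    f <- fit_decay(y)
    tibble::tibble(S = abs(f$S - S) / S, R = abs(f$R - R) / R,
                   tau = abs(f$tau - tau) / tau)
  })
  expect_lte(median(rel$S), 0.10)
  expect_lte(median(rel$R), 0.10)
  expect_lte(median(rel$tau), 0.25)
})

test_that("change in error uses only the first and last five trials", {
  toy <- c(rep(10, 5), rep(7, 60), rep(2, 5))
  expect_identical(change_in_error(toy), 8)
  expect_equal(change_in_error(rep(4, 15)), 0)
  expect_equal(change_in_error(rev(toy)), -8)
  shuffled <- c(toy[1:5], sample(toy[6:65]), toy[66:70])
  expect_identical(change_in_error(shuffled), 8)
  expect_error(change_in_error(1:9), "at least 10")
})

test_that("cross-validation returns n+1 deterministic fits", {
  mk <- function(noise_sd) {
    tidyr::expand_grid(subject_id = sprintf("s%02d", 1:7), trial = 1:40) |>
      dplyr::mutate(error = 1 + 4 * exp(-(trial - 1) / 8) +
                      rnorm(dplyr::n(), 0, noise_sd))
  }
  set.seed(6)
  noiseless <- mk(0)
  fits <- cross_validated_fit(noiseless, repeats = 10, seed = 2)
  expect_equal(nrow(fits), 8)
  expect_equal(fits$fit[1], "all")
  # identical noiseless subjects: all eight fits agree
  expect_lt(diff(range(fits$S)), 1e-6)
  expect_lt(diff(range(fits$tau)), 1e-3)
  expect_equal(fits$S[1], 1, tolerance = 1e-6)
  noisy <- mk(0.3)
  f1 <- cross_validated_fit(noisy, repeats = 10, seed = 9)
  f2 <- cross_validated_fit(noisy, repeats = 10, seed = 9)
  expect_identical(f1, f2)
})

test_that("shift measure reports the normalized ensemble displacement", {
  tt <- seq(0.05, 1.45, by = 0.05)
  mk <- function(offsets) {
    purrr::imap_dfr(offsets, function(off, tr) {
      tibble::tibble(t = tt, extent_err = off[1] + c(1, -1)[tr],
                     perp_err = off[1] + c(1, -1)[tr],
                     direction_id = 0L, trial_index = tr)
    })
  }
  early <- mk(list(0, 0))  # per-bin SD is sqrt(2), mean 0
  expect_equal(shift_measure(early, early)$delta, c(0, 0))
  late1 <- mk(list(sqrt(2), sqrt(2)))  # +1 SD everywhere
  expect_equal(shift_measure(early, late1)$delta, c(1, 1), tolerance = 1e-12)
  # +2 SD on exactly half of the occupied bins, 0 on the rest -> averages to 1
  tt2 <- seq(0.025, 1.475, by = 0.05)  # 30 samples, one bin each, 15 shifted
  mk2 <- function(shift) {
    purrr::map_dfr(1:2, function(tr) {
      s <- ifelse(tt2 < 0.75, shift, 0)
      tibble::tibble(t = tt2, extent_err = s + c(1, -1)[tr],
                     perp_err = s + c(1, -1)[tr],
                     direction_id = 0L, trial_index = tr)
    })
  }
  sm <- shift_measure(mk2(0), mk2(2 * sqrt(2)))
  expect_equal(sm$delta, c(1, 1), tolerance = 1e-12)
  # early SD below the floor is refused
  tight <- mk(list(0, 0))
  tight$extent_err <- tight$extent_err * 1e-4
  tight$perp_err <- tight$perp_err * 1e-4
  expect_error(shift_measure(tight, late1), "floor")
})
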