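# Shared fixtures built in code.

# Error samples for characterization: `trials` trials per direction on a time
# grid, each trial's component errors given by fn(t, trial, component).
make_samples <- function(fn, trials = 2, directions = 0L, td = 1.5, dt = 0.05) {
  tt <- seq(0, td, by = dt)
  purrr::map_dfr(directions, function(d) {
    purrr::map_dfr(seq_len(trials), function(tr) {
      tibble::tibble(
        t = tt,
        extent_err = fn(tt, tr, "extent"),
        perp_err = fn(tt, tr, "perp"),
        direction_id = d,
        trial_index = tr + 1000L * (d + 1L)
      )
    })
  })
}

# Model whose SD is exactly 1 everywhere: two trials at +/- 1/sqrt(2)
unit_sigma_model <- function(directions = 0L) {
  characterize_errors(
    make_samples(function(t, tr, comp) rep(c(1, -1)[tr] / sqrt(2), length(t)),
                 trials = 2, directions = directions)
  )
}

# Characterization-like samples with realistic smooth structure, fixed seed
noisy_samples <- function(trials = 6, directions = 0:2, seed = 11, td = 1.5) {
  set.seed(seed)
  make_samples(function(t, tr, comp) {
    amp <- runif(1, 0.5, 3)
    amp * sin(pi * t / td) + rnorm(length(t), 0, 0.3)
  }, trials = trials, directions = directions, td = td)
}

# Brute-force dense grid search over (S, R, tau): the independent oracle for
# the exponential decay fit. Returns the best SSE found on the grid.
brute_force_decay_sse <- function(t, y, n_s = 60, n_r = 60, n_tau = 60) {
  S_grid <- seq(0, max(y), length.out = n_s)
  R_grid <- seq(0, 2 * diff(range(y)) + max(y), length.out = n_r)
  tau_grid <- exp(seq(log(0.5), log(500), length.out = n_tau))
  n <- length(y)
  best <- Inf
  for (tau in tau_grid) {
    b <- exp(-t / tau)
    sy <- sum(y^2); sb <- sum(b); sbb <- sum(b^2); syb <- sum(y * b); s1y <- sum(y)
    for (S in S_grid) {
      # SSE over the R grid in closed form from the sufficient statistics
      sse <- sy - 2 * S * s1y + n * S^2 +
        R_grid^2 * sbb + 2 * R_grid * (S * sb - syb)
      best <- min(best, min(sse))
    }
  }
  best
}

# Tiny single-subject trial table in the long interchange layout
tiny_trial_table <- function(n_trials = 3, n_samples = 4) {
  tidyr::expand_grid(trial_index = seq_len(n_trials),
                     s = seq_len(n_samples)) |>
    dplyr::mutate(
      subject_id = "s01", group = "ea", phase = "training",
      direction_id = (trial_index - 1L) %% 3L,
      transformed = TRUE, forces_on = TRUE,
      t = (s - 1) * 0.01,
      x = sin(trial_index + s), y = cos(trial_index + s),
      extent_err = 0.1 * trial_index, perp_err = -0.05 * s,
      torque_extent = 0.5, torque_perp = -0.25
    ) |>
    dplyr::select(-"s") |>
    dplyr::relocate("subject_id", "group", "phase", "trial_index")
}
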