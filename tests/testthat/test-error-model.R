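test_that("constant identical trials give flat mean and floored SD", {
  m <- characterize_errors(
    make_samples(function(t, tr, comp) rep(2.5, length(t)), trials = 3),
    sigma_floor = 0.05
  )
  ms <- mu_sigma_at(m, 0, "extent", seq(0, 1.5, by = 0.1))
  expect_equal(ms$mu, rep(2.5, length(ms$mu)), tolerance = 1e-8)
  expect_equal(ms$sigma, rep(0.05, length(ms$sigma)))
  # clamping beyond the time domain
  far <- mu_sigma_at(m, 0, "perp", 99)
  expect_equal(far$mu, 2.5, tolerance = 1e-8)
})

test_that("degree-7 fit exactly reproduces a nested-degree mean curve", {
  poly3 <- function(t) 0.4 - 1.2 * t + 0.8 * t^2 - 0.1 * t^3
  # 31 bins put every bin time on a sample time (dt = 0.05), so the binned
  # means are exactly the polynomial and the nested degree-7 fit reproduces it
  m <- characterize_errors(
    make_samples(function(t, tr, comp) poly3(t) + c(1, -1)[tr] * 0.5,
                 trials = 2, dt = 0.05),
    n_bins = 31
  )
  grid <- seq(0, 1.5, length.out = 31)
  expect_equal(mu_sigma_at(m, 0, "extent", grid)$mu, poly3(grid),
               tolerance = 1e-8)
})

test_that("two opposite trials give zero mean and the n=2 sample SD", {
  a <- 1.3
  m <- characterize_errors(
    make_samples(function(t, tr, comp) rep(c(a, -a)[tr], length(t)),
                 trials = 2)
  )
  ms <- mu_sigma_at(m, 0, "extent", seq(0.1, 1.4, by = 0.1))
  expect_equal(ms$mu, rep(0, length(ms$mu)), tolerance = 1e-8)
  expect_equal(ms$sigma, rep(a * sqrt(2), length(ms$sigma)), tolerance = 1e-6)
})

test_that("fitted mean matches an independent normal-equations solve", {
  samples <- noisy_samples(trials = 4, directions = 0L)
  n_bins <- 12
  m <- characterize_errors(samples, n_bins = n_bins, degree = 7)
  # independent oracle: bin by nearest sample, then solve X'X beta = X'y
  grid_t <- seq(0, 1.5, length.out = n_bins)
  trials <- unique(samples$trial_index)
  vals <- vapply(trials, function(tr) {
    s <- samples[samples$trial_index == tr, ]
    s$extent_err[vapply(grid_t, function(g) which.min(abs(s$t - g)),
                        integer(1))]
  }, numeric(n_bins))
  mu <- rowMeans(vals)
  X <- outer(grid_t / 1.5, 0:7, `^`)
  beta <- solve(t(X) %*% X, t(X) %*% mu)
  # compare the fitted mean curves (the coefficient bases differ in
  # conditioning far below the curve-level agreement)
  expect_equal(mu_sigma_at(m, 0, "extent", grid_t)$mu, as.numeric(X %*% beta),
               tolerance = 1e-8)
})

test_that("the Gaussian likelihood has the right mode, ratio and mass", {
  m <- unit_sigma_model()
  # sigma = 1, mu = 0: mode is 1/sqrt(2*pi)
  expect_equal(error_density(m, 0, "extent", 0.7, 0), 1 / sqrt(2 * pi),
               tolerance = 1e-6)
  # one-sigma ratio
  ms <- mu_sigma_at(m, 0, "extent", 0.7)
  expect_equal(
    error_density(m, 0, "extent", 0.7, ms$mu + ms$sigma) /
      error_density(m, 0, "extent", 0.7, ms$mu),
    exp(-0.5), tolerance = 1e-10
  )
})

test_that("the density integrates to one, is symmetric, with monotone tails", {
  m <- characterize_errors(noisy_samples())
  set.seed(21)
  for (i in 1:10) {
    d <- sample(0:2, 1)
    comp <- sample(c("extent", "perp"), 1)
    tq <- runif(1, 0, 1.5)
    ms <- mu_sigma_at(m, d, comp, tq)
    mass <- stats::integrate(function(e) error_density(m, d, comp, tq, e),
                             ms$mu - 8 * ms$sigma, ms$mu + 8 * ms$sigma,
                             rel.tol = 1e-9)$value
    expect_equal(mass, 1, tolerance = 1e-6)
    # symmetry about the mean
    x <- runif(1, 0, 4 * ms$sigma)
    expect_equal(error_density(m, d, comp, tq, ms$mu + x),
                 error_density(m, d, comp, tq, ms$mu - x))
    # strictly decreasing tails
    offs <- seq(0, 5, by = 0.5) * ms$sigma
    dens <- error_density(m, d, comp, tq, ms$mu + offs)
    expect_true(all(diff(dens) < 0))
  }
})

test_that("characterization rejects deficient or non-finite input", {
  one_trial <- make_samples(function(t, tr, comp) t, trials = 1,
                            directions = 1L)
  expect_error(characterize_errors(one_trial), "Direction 1")
  bad <- make_samples(function(t, tr, comp) t, trials = 2)
  bad$extent_err[5] <- NA
  expect_error(characterize_errors(bad), "finite")
  m <- unit_sigma_model()
  expect_error(mu_sigma_at(m, 7, "extent", 0.5), "Unknown direction")
  expect_error(mu_sigma_at(m, 0, "sideways", 0.5), "Unknown component")
})

test_that("models survive a JSON round trip and tidy cleanly", {
  m <- characterize_errors(noisy_samples())
  path <- withr::local_tempfile(fileext = ".json")
  write_error_model(m, path)
  m2 <- read_error_model(path)
  tt <- seq(0, 1.5, length.out = 25)
  for (d in 0:2) {
    expect_equal(mu_sigma_at(m2, d, "perp", tt), mu_sigma_at(m, d, "perp", tt))
  }
  td <- tidy(m)
  expect_equal(nrow(td), 3 * 2 * 2 * 8)
  expect_true(all(is.finite(td$coefficient)))
})
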