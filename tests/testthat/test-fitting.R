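test_that("r_squared matches hand arithmetic and handles degeneracy", {
  obs <- c(1, 2, 3)
  expect_equal(r_squared(obs, obs), 1)
  expect_equal(r_squared(obs, rep(mean(obs), 3)), 0)
  expect_equal(r_squared(obs, c(1, 2, 4)), 0.5)
  expect_error(r_squared(c(2, 2, 2), c(1, 2, 3)),
               class = "degenerate_data_error")
})

test_that("noise-free pseudo-order data return the generating constants", {
  tt <- seq(0, 96, by = 12)
  ts1 <- time_series(tt, 10 * exp(-0.057 * tt), "crvi")
  f1 <- fit_rate_constant(ts1, "first")
  expect_equal(f1$k, 0.057, tolerance = 1e-10)
  expect_equal(f1$C0_used, 10, tolerance = 1e-9)
  expect_equal(f1$r_squared, 1, tolerance = 1e-9)

  ts2 <- time_series(tt, 25 / (1 + 0.126 * 25 * tt), "crvi")
  f2 <- fit_rate_constant(ts2, "second")
  expect_equal(f2$k, 0.126, tolerance = 1e-10)
  expect_equal(f2$C0_used, 25, tolerance = 1e-9)
})

test_that("a flat series fits k = 0 with degenerate R^2 reported as 0", {
  ts <- time_series(c(0, 10), c(10, 10), "crvi")
  f <- fit_rate_constant(ts, "first")
  expect_identical(f$k, 0)
  expect_identical(f$r_squared, 0)
})

test_that("two-point first-order fit equals the closed-form rate", {
  # oracle: k = ln(C0/C1) / t1 for exactly two points
  ts <- time_series(c(0, 18), c(40, 13.7), "crvi")
  f <- fit_rate_constant(ts, "first")
  expect_equal(f$k, log(40 / 13.7) / 18, tolerance = 1e-12)
})

test_that("points below the detection limit are excluded from transforms", {
  tt <- seq(0, 120, by = 12)
  vals <- pmax(10 * exp(-0.1 * tt) - 0.02, 0)  # tail underflows to ~0
  ts <- time_series(tt, vals, "crvi")
  f <- fit_rate_constant(ts, "first", detection_limit = 0.05)
  expect_lt(f$n_points, length(tt))
  expect_gt(f$k, 0)
  expect_error(fit_rate_constant(time_series(tt, rep(0.01, length(tt)), "crvi")),
               class = "insufficient_data_error")
})

test_that("Haldane fits recover all three reference parameter sets", {
  sets <- recovery_haldane_sets()
  for (nm in names(sets)) {
    truth <- sets[[nm]]$params
    dat <- generate_mu_dataset(truth, sets[[nm]]$grid)
    fit <- fit_haldane(dat, n_starts = 20, seed = 11)
    expect_true(fit$converged)
    expect_equal(fit$params$mu_max, truth$mu_max,
                 tolerance = 0.005, label = paste(nm, "mu_max"))
    expect_equal(fit$params$K_I, truth$K_I,
                 tolerance = 0.02, label = paste(nm, "K_I"))
    expect_gt(fit$r_squared, 0.999)
  }
})

test_that("a null growth signal is flagged degenerate at the lower bound", {
  dat <- data.frame(S = c(1, 5, 25, 125), mu = 0)
  fit <- fit_haldane(dat, seed = 2)
  expect_true(fit$degenerate)
  expect_equal(fit$params$mu_max, 1e-6, tolerance = 1e-6)
})

test_that("best-of-starts objective is non-increasing in n_starts", {
  truth <- recovery_haldane_sets()$glucose$params
  dat <- generate_mu_dataset(truth, c(0.1, 0.3, 0.7, 1.5, 4, 12),
                             noise_cv = 0.1, seed = 31)
  devs <- vapply(c(2, 5, 10, 20), function(ns) {
    fit_haldane(dat, n_starts = ns, seed = 17)$residual_norm
  }, numeric(1))
  expect_true(all(diff(devs) <= 1e-12))
})

test_that("tertiary fit recovers nine interaction constants on a 3x3x3 design", {
  truth <- recovery_tertiary_truth()
  dat <- generate_mu_dataset(truth, recovery_tertiary_design())
  base <- list(base_C = truth$base_C, base_P = truth$base_P,
               base_h = truth$base_h)
  fit <- fit_tertiary(dat, base, n_starts = 20, seed = 7)
  est <- interaction_vector(fit$params)
  expect_true(fit$converged)
  expect_equal(unname(est), unname(interaction_vector(truth)),
               tolerance = 0.05)
  expect_gt(fit$r_squared, 0.999)
  # base parameters are frozen, never re-estimated
  expect_identical(fit$params$base_C, truth$base_C)
  expect_identical(fit$params$base_P, truth$base_P)
  expect_identical(fit$params$base_h, truth$base_h)
})

test_that("zero interaction constants are recovered at the lower bound", {
  truth <- recovery_tertiary_truth()
  p0 <- tertiary_monod_params(truth$base_C, truth$base_P, truth$base_h)
  dat <- generate_mu_dataset(p0, recovery_tertiary_design())
  base <- list(base_C = truth$base_C, base_P = truth$base_P,
               base_h = truth$base_h)
  fit <- fit_tertiary(dat, base, n_starts = 10, seed = 5)
  expect_true(all(interaction_vector(fit$params) <= 1e-6 + 1e-12))
  # the generating value 0 sits on the positivity-box boundary, so the fit
  # can only approach it from inside; near-perfect rather than perfect fit
  expect_gt(fit$r_squared, 0.99)
})

test_that("a design without substrate variation triggers an identifiability warning", {
  truth <- recovery_tertiary_truth()
  design <- expand.grid(S_C = 4000, S_P = c(5, 10, 25, 50, 75, 100,
                                            150, 200, 300, 400),
                        S_h = 4000)
  dat <- generate_mu_dataset(truth, design)
  base <- list(base_C = truth$base_C, base_P = truth$base_P,
               base_h = truth$base_h)
  expect_warning(fit <- fit_tertiary(dat, base, n_starts = 5, seed = 9),
                 "not identifiable")
  expect_gt(length(fit$identifiability_warnings), 0)
})

test_that("moderate noise leaves median recovered Haldane parameters near truth", {
  truth <- recovery_haldane_sets()$glucose$params
  grid <- recovery_haldane_sets()$glucose$grid
  rec <- t(vapply(1:30, function(i) {
    dat <- generate_mu_dataset(truth, grid, noise_cv = 0.05, seed = 500 + i)
    fit <- fit_haldane(dat, n_starts = 8, seed = 900 + i)
    c(fit$params$mu_max, fit$params$K_I)
  }, numeric(2)))
  med <- apply(rec, 2, stats::median)
  expect_equal(med[1], truth$mu_max, tolerance = 0.15)
  expect_equal(med[2], truth$K_I, tolerance = 0.15)
})

test_that("a missing seed is rejected for every stochastic fitter", {
  dat <- data.frame(S = 1:5, mu = 0.01 * (1:5))
  expect_error(fit_haldane(dat), class = "domain_error")
  tdat <- cbind(recovery_tertiary_design()[1:10, ], mu = 0.05)
  base <- list(base_C = list(mu_max = 0.1, K_S = 1),
               base_P = list(mu_max = 0.1, K_S = 1),
               base_h = list(mu_max = 0.1, K_S = 1))
  expect_error(fit_tertiary(tdat, base), class = "domain_error")
})
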