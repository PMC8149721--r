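noise_free_sim <- function(preset, cr0 = 100, seed = 1) {
  ps <- simulation_preset(preset, cr0 = cr0, noise_cv = 0, seed = seed)
  simulate_batch(ps$condition, ps$config)
}

test_that("no reduction pathway leaves Cr(VI) at its initial level", {
  gp <- haldane_params(0.1129, 500, 1010)
  cfg <- simulation_config(growth_params = gp, yield_C = 5e-5, q_P = 0,
                           noise_cv = 0, seed = 1)
  sim <- simulate_batch(batch_condition(25, "binary", hcif_dose = 0), cfg)
  expect_equal(sim$truth$crvi$values, rep(25, length(cfg$t_grid)),
               tolerance = 1e-8)
})

test_that("an inert system keeps biomass and glucose constant", {
  cfg <- simulation_config(growth_params = NULL, yield_C = 1e-4, q_P = 0,
                           noise_cv = 0, seed = 1)
  sim <- simulate_batch(batch_condition(25, "binary", hcif_dose = 0), cfg)
  expect_equal(sim$truth$biomass$values, rep(cfg$X0, length(cfg$t_grid)),
               tolerance = 1e-10)
  expect_equal(sim$truth$glucose$values, rep(4000, length(cfg$t_grid)),
               tolerance = 1e-8)
})

test_that("all simulated states stay non-negative", {
  for (preset in c("set1_binary", "set2_tertiary", "first_order")) {
    ps <- simulation_preset(preset, noise_cv = 0.05, seed = 42)
    sim <- simulate_batch(ps$condition, ps$config)
    for (ts in sim$truth) expect_true(all(ts$values >= 0))
    for (rep in sim$replicates) {
      for (ts in rep) expect_true(all(ts$values >= 0))
    }
  }
})

test_that("noise-free glucose and HCIF trajectories are non-increasing", {
  for (preset in c("set1_binary", "set2_tertiary")) {
    sim <- noise_free_sim(preset)
    expect_true(all(diff(sim$truth$glucose$values) <= 1e-9))
    expect_true(all(diff(sim$truth$hcif$values) <= 1e-9))
  }
})

test_that("identical config and seed reproduce bit-identical output", {
  ps <- simulation_preset("set2_tertiary", cr0 = 40, noise_cv = 0.05, seed = 77)
  s1 <- simulate_batch(ps$condition, ps$config)
  s2 <- simulate_batch(ps$condition, ps$config)
  expect_identical(s1$truth, s2$truth)
  expect_identical(s1$replicates, s2$replicates)
})

test_that("preset calibration meets the reduction milestones", {
  # tertiary: 100 mg/L essentially fully reduced by 120 h
  s2 <- noise_free_sim("set2_tertiary", cr0 = 100)
  cr_120 <- s2$truth$crvi$values[s2$truth$crvi$times == 120]
  expect_lt(cr_120, 1)  # < 1% of cr0
  # binary: 100 mg/L far from complete at 90 h
  s1 <- noise_free_sim("set1_binary", cr0 = 100)
  cr_90 <- utils::tail(s1$truth$crvi$values[s1$truth$crvi$times <= 90], 1)
  expect_gte(cr_90, 5)  # >= 5% of cr0 remains
  # binary glucose essentially exhausted around 60 h
  glu_72 <- s1$truth$glucose$values[s1$truth$glucose$times == 72]
  expect_lt(glu_72, 40)
})

test_that("first-order-calibrated scenario closes the loop with the rate fitter", {
  ps <- simulation_preset("first_order", noise_cv = 0, seed = 3)
  sim <- simulate_batch(ps$condition, ps$config)
  fit <- fit_rate_constant(sim$truth$crvi, "first")
  expect_equal(fit$k, ps$calibrated$k1, tolerance = 0.05)
  expect_gt(fit$r_squared, 0.999)
})

test_that("mu-dataset generation is exact without noise and seeded with it", {
  truth <- recovery_haldane_sets()$crvi$params
  grid <- recovery_haldane_sets()$crvi$grid
  dat0 <- generate_mu_dataset(truth, grid)
  expect_identical(dat0$mu, haldane_mu(truth, grid))
  d1 <- generate_mu_dataset(truth, grid, noise_cv = 0.05, seed = 8)
  d2 <- generate_mu_dataset(truth, grid, noise_cv = 0.05, seed = 8)
  expect_identical(d1, d2)
  expect_false(identical(d1$mu, dat0$mu))
  # relative noise magnitude matches its nominal CV
  one <- generate_mu_dataset(truth, rep(25, 200), noise_cv = 0.05, seed = 9)
  ratio <- stats::sd(one$mu) / mean(one$mu)
  expect_gt(ratio, 0.04)
  expect_lt(ratio, 0.06)
})

test_that("simulator rejects invalid configurations", {
  expect_error(simulation_config(yield_C = 1e-4, q_P = 1),
               class = "domain_error")  # no seed
  expect_error(simulation_config(yield_C = 0, q_P = 1, seed = 1),
               class = "domain_error")
  expect_error(batch_condition(25, "binary", hcif_dose = 1),
               class = "domain_error")
  expect_error(batch_condition(-5, "tertiary"), class = "domain_error")
})
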