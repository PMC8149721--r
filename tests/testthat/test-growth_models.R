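test_that("Haldane law vanishes at S = 0 and peaks at sqrt(K_S * K_I)", {
  p <- haldane_params(mu_max = 0.1129, K_S = 0.5, K_I = 1.01)
  expect_identical(haldane_mu(p, 0), 0)

  # Closed-form peak, computed independently by direct arithmetic.
  s_star <- sqrt(0.5 * 1.01)
  expected_peak <- 0.1129 / (1 + 2 * sqrt(0.5 / 1.01))
  expect_equal(haldane_mu(p, s_star), expected_peak, tolerance = 1e-10)
  pk <- haldane_peak(p)
  expect_equal(pk$S, s_star)
  expect_equal(pk$mu, expected_peak, tolerance = 1e-12)
})

test_that("Haldane law reduces to Monod when inhibition is negligible", {
  p <- haldane_params(mu_max = 0.1129, K_S = 0.5, K_I = 1e12)
  expect_equal(haldane_mu(p, 0.5), 0.1129 / 2, tolerance = 1e-6)
})

test_that("Haldane law is unimodal: rising below the peak, falling above", {
  set.seed(101)
  for (i in 1:10) {
    p <- haldane_params(mu_max = runif(1, 0.01, 1),
                        K_S = 10^runif(1, -1, 2), K_I = 10^runif(1, -1, 3))
    s_star <- sqrt(p$K_S * p$K_I)
    below <- seq(0, s_star, length.out = 60)
    above <- seq(s_star, 20 * s_star, length.out = 60)
    expect_true(all(diff(haldane_mu(p, below)) > 0))
    expect_true(all(diff(haldane_mu(p, above)) < 0))
    # rate finite and non-negative everywhere sampled
    expect_true(all(is.finite(haldane_mu(p, c(below, above)))))
    expect_true(all(haldane_mu(p, c(below, above)) >= 0))
  }
})

test_that("growth-law domain errors are raised for invalid input", {
  p <- haldane_params(0.1, 1, 1)
  expect_error(haldane_mu(p, -1), class = "domain_error")
  expect_error(haldane_params(0, 1, 1), class = "domain_error")
  expect_error(haldane_params(0.1, -1, 1), class = "domain_error")
  expect_error(substrate_state(-1, 0, 0), class = "domain_error")
  expect_error(rate_law_predict(rate_law_params("first", 0.1, 10), -1),
               class = "domain_error")
  expect_error(tertiary_monod_params(list(mu_max = 0.1, K_S = 1),
                                     list(mu_max = 0.1, K_S = 1),
                                     list(mu_max = 0.1, K_S = 1),
                                     K2_C = -1),
               class = "domain_error")
})

test_that("tertiary law vanishes with no substrate and reduces to Monod", {
  p <- tertiary_monod_params(base_C = list(mu_max = 0.1129, K_S = 0.5),
                             base_P = list(mu_max = 0.002346, K_S = 5),
                             base_h = list(mu_max = 0.1923, K_S = 50))
  expect_identical(tertiary_mu(p, substrate_state(0, 0, 0)), 0)
  # two substrates absent, the third at half-saturation -> mu_max / 2
  expect_equal(tertiary_mu(p, substrate_state(0.5, 0, 0)), 0.1129 / 2,
               tolerance = 1e-12)
  expect_equal(tertiary_mu(p, substrate_state(0, 5, 0)), 0.002346 / 2,
               tolerance = 1e-12)
  expect_equal(tertiary_mu(p, substrate_state(0, 0, 50)), 0.1923 / 2,
               tolerance = 1e-12)
})

test_that("tertiary law matches a term-by-term arithmetic oracle", {
  # Interaction constants recovered from the reference K*S products
  # (10 mg/L column) at the stated substrate state.
  st <- substrate_state(S_C = 4000, S_P = 10, S_h = 4000)
  ks <- interaction_constants_from_products(
    interaction_products_reference()$cr10, st)
  p <- tertiary_monod_params(
    base_C = list(mu_max = 0.1129, K_S = 0.5),
    base_P = list(mu_max = 0.002346, K_S = 5),
    base_h = list(mu_max = 0.1923, K_S = 50),
    K2_C = ks[["K2_C"]], K3_C = ks[["K3_C"]], K4_C = ks[["K4_C"]],
    K2_P = ks[["K2_P"]], K3_P = ks[["K3_P"]], K4_P = ks[["K4_P"]],
    K2_h = ks[["K2_h"]], K3_h = ks[["K3_h"]], K4_h = ks[["K4_h"]])
  # Hand-summed three-term evaluation: each denominator written out with
  # the reference products directly, independent of the implementation.
  term_C <- 0.1129 * 4000 / (0.5 + 4000 + 0.287 + 0.015 + 0.0249)
  term_P <- 0.002346 * 10 / (5 + 10 + 0.586 + 0.489 + 0.04)
  term_h <- 0.1923 * 4000 / (50 + 4000 + 0.017 + 0.08 + 0.041)
  expect_equal(tertiary_mu(p, st), term_C + term_P + term_h,
               tolerance = 1e-12)
})

test_that("as-printed variant swaps the Cr(VI) saturation slot to glucose", {
  p_sym <- tertiary_monod_params(base_C = list(mu_max = 0.1, K_S = 1),
                                 base_P = list(mu_max = 0.2, K_S = 2),
                                 base_h = list(mu_max = 0.3, K_S = 3),
                                 form_variant = "symmetric")
  p_prn <- tertiary_monod_params(base_C = list(mu_max = 0.1, K_S = 1),
                                 base_P = list(mu_max = 0.2, K_S = 2),
                                 base_h = list(mu_max = 0.3, K_S = 3),
                                 form_variant = "as_printed")
  st <- substrate_state(S_C = 7, S_P = 4, S_h = 0)
  # symmetric Cr term: 0.2*4/(2+4); as-printed: 0.2*4/(2+7)
  common <- 0.1 * 7 / (1 + 7)
  expect_equal(tertiary_mu(p_sym, st), common + 0.2 * 4 / (2 + 4))
  expect_equal(tertiary_mu(p_prn, st), common + 0.2 * 4 / (2 + 7))
  # with all interactions zero and S_C = S_P the variants coincide
  st_eq <- substrate_state(4, 4, 1)
  expect_equal(tertiary_mu(p_sym, st_eq), tertiary_mu(p_prn, st_eq))
})

test_that("tertiary rate is non-increasing in every interaction constant", {
  set.seed(202)
  kn <- c("K2_C", "K3_C", "K4_C", "K2_P", "K3_P", "K4_P",
          "K2_h", "K3_h", "K4_h")
  for (i in 1:8) {
    args <- list(base_C = list(mu_max = runif(1, 0.01, 1), K_S = 10^runif(1, -1, 3)),
                 base_P = list(mu_max = runif(1, 0.01, 1), K_S = 10^runif(1, -1, 3)),
                 base_h = list(mu_max = runif(1, 0.01, 1), K_S = 10^runif(1, -1, 3)))
    ks <- stats::setNames(as.list(10^runif(9, -4, 0)), kn)
    st <- substrate_state(10^runif(1, 0, 3), 10^runif(1, 0, 2), 10^runif(1, 0, 3))
    mu0 <- tertiary_mu(do.call(tertiary_monod_params, c(args, ks)), st)
    for (nm in kn) {
      ks_up <- ks
      ks_up[[nm]] <- ks[[nm]] * 10
      mu_up <- tertiary_mu(do.call(tertiary_monod_params, c(args, ks_up)), st)
      expect_lte(mu_up, mu0 + 1e-15)
    }
  }
})

test_that("pseudo-order decay laws obey their half-life identities", {
  expect_equal(rate_law_predict(rate_law_params("first", 0, 10), 100), 10)
  # first-order half-life with the binary 10 mg/L rate constant
  p1 <- rate_law_params("first", 0.057, 10)
  expect_equal(rate_law_predict(p1, log(2) / 0.057), 5, tolerance = 1e-9)
  # second-order half-life with the tertiary 25 mg/L rate constant
  p2 <- rate_law_params("second", 0.126, 25)
  expect_equal(rate_law_predict(p2, 1 / (0.126 * 25)), 12.5, tolerance = 1e-9)
})

test_that("decay predictions are monotone in time and continuous in k", {
  tt <- seq(0, 200, length.out = 101)
  for (ord in c("first", "second")) {
    pred <- rate_law_predict(rate_law_params(ord, 0.04, 25), tt)
    expect_true(all(diff(pred) <= 0))
    expect_true(all(pred > 0 & pred <= 25))
    # continuity in k: small parameter change, small prediction change
    pred_eps <- rate_law_predict(rate_law_params(ord, 0.04 + 1e-9, 25), tt)
    expect_lt(max(abs(pred - pred_eps)), 1e-5)
  }
})
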