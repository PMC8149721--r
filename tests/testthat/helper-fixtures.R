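# Shared fixtures and independent oracles for the test suite.

# Reference single-substrate Haldane parameter sets used as generating truth
# in the recovery experiments (mu_max/K_I are the reported constants; K_S is
# the package convention since the affinity constants were never reported).
recovery_haldane_sets <- function() {
  list(
    glucose = list(params = haldane_params(0.1129, 0.5, 1.01),
                   grid = exp(seq(log(0.05), log(20), length.out = 10))),
    crvi = list(params = haldane_params(0.002346, 5, 134.12),
                grid = exp(seq(log(1), log(500), length.out = 10))),
    hcif = list(params = haldane_params(0.1923, 5, 11.99),
                grid = exp(seq(log(0.5), log(200), length.out = 10)))
  )
}

# Tertiary generating truth for the nine-constant recovery experiment:
# balanced base rates so every term contributes to mu, and interaction
# constants sized so each K*S summand moves its denominator appreciably
# over the design.
recovery_tertiary_truth <- function() {
  tertiary_monod_params(
    base_C = list(mu_max = 0.1129, K_S = 500),
    base_P = list(mu_max = 0.05, K_S = 30),
    base_h = list(mu_max = 0.1923, K_S = 2000),
    K2_C = 1.5, K3_C = 0.02, K4_C = 1e-4,
    K2_P = 0.01, K3_P = 0.005, K4_P = 5e-6,
    K2_h = 0.003, K3_h = 0.5, K4_h = 2e-5)
}

recovery_tertiary_design <- function() {
  expand.grid(S_C = c(200, 1000, 4000), S_P = c(5, 25, 100),
              S_h = c(500, 2000, 4000))
}

interaction_vector <- function(p) {
  c(K2_C = p$K2_C, K3_C = p$K3_C, K4_C = p$K4_C,
    K2_P = p$K2_P, K3_P = p$K3_P, K4_P = p$K4_P,
    K2_h = p$K2_h, K3_h = p$K3_h, K4_h = p$K4_h)
}

# Independent exhaustive-window oracle for the growth-rate estimator:
# brute force over every contiguous above-floor window via stats::lm,
# sharing no code with estimate_mu().
oracle_estimate_mu <- function(times, values, min_window = 3,
                               detection_floor = 0.01) {
  n <- length(times)
  best <- NULL
  for (i in 1:(n - min_window + 1)) {
    for (j in (i + min_window - 1):n) {
      vals <- values[i:j]
      if (any(vals <= detection_floor)) next
      fit <- stats::lm(log(vals) ~ times[i:j])
      r2 <- summary(fit)$r.squared
      if (!is.finite(r2)) r2 <- if (sum(residuals(fit)^2) < 1e-18) 1 else 0
      len <- j - i + 1
      better <- is.null(best) || r2 > best$r2 + 1e-12 ||
        (abs(r2 - best$r2) <= 1e-12 &&
           (len > best$len || (len == best$len && i < best$i)))
      if (better) {
        best <- list(mu = unname(coef(fit)[2]), i = i, j = j,
                     r2 = r2, len = len)
      }
    }
  }
  best
}
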