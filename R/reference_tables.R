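# Published kinetic constants for the Serratia sp. / glucose / HCIF
# Cr(VI)-cometabolism system. These are the reference inputs to the
# parameter-recovery experiments: the fitters must return them when data are
# generated from them.

#' Reference pseudo-order rate constants per batch condition
#'
#' Reported first- and second-order rate constants (with linearised-fit R^2)
#' for Cr(VI) decay across the ten batch conditions: five initial Cr(VI)
#' levels in the binary system (bacteria + glucose) and five in the tertiary
#' system (bacteria + glucose + HCIF).
#'
#' @return data frame with columns `system` (`"binary"`/`"tertiary"`), `cr0`
#'   (mg/L), `k1` (h^-1), `r2_1`, `k2` (mg^-1 L h^-1), `r2_2`.
#' @export
rate_constants_reference <- function() {
  data.frame(
    system = rep(c("binary", "tertiary"), each = 5L),
    cr0 = rep(c(10, 25, 40, 50, 100), 2L),
    k1 = c(0.057, 0.0388, 0.0238, 0.024, 0.0119,
           0.0139, 0.0037, 0.0016, 0.0029, 0.0004),
    r2_1 = c(0.97, 0.82, 0.91, 0.943, 0.938,
             0.9306, 0.729, 0.892, 0.868, 0.852),
    k2 = c(0.0306, 0.0071, 0.0017, 0.0015, 0.0002,
           0.046, 0.126, 0.0426, 0.0695, 0.0236),
    r2_2 = c(0.8789, 0.68, 0.78, 0.88, 0.88,
             0.954, 0.969, 0.909, 0.928, 0.9118)
  )
}

#' Reference single-substrate Haldane-Andrews fits
#'
#' Reported maximum specific growth rates and inhibition constants from the
#' single-substrate growth experiments (Cr(VI), glucose, HCIF each varied
#' alone). The substrate affinity constants `K_S` were not reported and are
#' free parameters in any refit; the `K_S` column here carries the
#' conventional values this package uses when generating recovery data.
#'
#' @return data frame with columns `substrate` (`"crvi"`, `"glucose"`,
#'   `"hcif"`), `mu_max` (h^-1), `K_I` (mg/L), `K_S` (mg/L, package
#'   convention), `r_squared`.
#' @export
single_substrate_reference <- function() {
  data.frame(
    substrate = c("crvi", "glucose", "hcif"),
    mu_max = c(0.002346, 0.1129, 0.1923),
    K_I = c(134.12, 1.01, 11.99),
    K_S = c(5, 0.5, 5),
    r_squared = c(0.977, 0.9916, 0.9876)
  )
}

#' Reference interaction products for the tertiary system
#'
#' Reported cross-inhibition products K·S (rows) at each initial Cr(VI)
#' level (columns). Rows are labelled by the product they represent, e.g.
#' `K2_C.S_P` is the inhibition of glucose consumption by Cr(VI). The
#' reported quantities are products of an interaction constant with the
#' substrate concentration(s) it multiplies, not the bare constants; use
#' [interaction_constants_from_products()] to recover constants under a
#' stated substrate state.
#'
#' @return data frame with column `product` (9 labels) and one numeric
#'   column per Cr(VI) level: `cr10`, `cr25`, `cr40`, `cr50`, `cr100`.
#' @export
interaction_products_reference <- function() {
  data.frame(
    product = c("K2_C.S_P", "K3_C.S_h", "K4_C.S_P.S_h",
                "K2_P.S_C", "K3_P.S_h", "K4_P.S_C.S_h",
                "K2_h.S_C", "K3_h.S_P", "K4_h.S_C.S_P"),
    cr10 = c(0.287, 0.015, 0.0249, 0.586, 0.489, 0.04, 0.017, 0.08, 0.041),
    cr25 = c(0.655, 0.047, 0.068, 1.221, 0.812, 0.042, 0.052, 0.094, 0.057),
    cr40 = c(0.834, 0.062, 0.083, 1.146, 0.741, 0.092, 0.035, 0.103, 0.1149),
    cr50 = c(0.761, 0.059, 0.061, 1.452, 1.332, 0.289, 0.124, 0.121, 0.201),
    cr100 = c(0.934, 0.114, 0.154, 1.625, 1.524, 0.451, 0.1, 0.267, 0.415)
  )
}

# Which substrate concentrations each interaction product multiplies, in
# the canonical row order of interaction_products_reference().
interaction_product_factors <- function(state) {
  c(K2_C = state$S_P, K3_C = state$S_h, K4_C = state$S_P * state$S_h,
    K2_P = state$S_C, K3_P = state$S_h, K4_P = state$S_C * state$S_h,
    K2_h = state$S_C, K3_h = state$S_P, K4_h = state$S_C * state$S_P)
}

#' Recover interaction constants from reported K·S products
#'
#' Divides each of the nine reported products by the substrate
#' concentration(s) it multiplies under the given state, yielding the bare
#' constants `K2`/`K3`/`K4` per substrate term.
#'
#' @param products numeric vector of the 9 products in the canonical order
#'   of [interaction_products_reference()] (a column of that table).
#' @param state a [substrate_state()] giving the concentrations the products
#'   were evaluated at.
#' @return named numeric vector `K2_C`, `K3_C`, ..., `K4_h`.
#' @examples
#' tab <- interaction_products_reference()
#' st <- substrate_state(S_C = 4000, S_P = 10, S_h = 4000)
#' interaction_constants_from_products(tab$cr10, st)
#' @export
interaction_constants_from_products <- function(products, state) {
  if (length(products) != 9L) {
    stop_kin("`products` must have exactly 9 entries", "domain_error")
  }
  fac <- interaction_product_factors(state)
  if (any(fac == 0)) {
    stop_kin("all substrate concentrations must be > 0 to invert products",
             "domain_error")
  }
  stats::setNames(as.numeric(products) / fac, names(fac))
}

#' Reconstruct K·S interaction products from fitted constants
#'
#' The inverse of [interaction_constants_from_products()]: multiplies each
#' fitted interaction constant by the substrate concentration(s) it acts
#' through, producing the 9-row product table shape used for reporting.
#'
#' @param params a [tertiary_monod_params()] object.
#' @param state a [substrate_state()].
#' @return named numeric vector of the nine products.
#' @export
interaction_products <- function(params, state) {
  if (!inherits(params, "tertiary_monod_params")) {
    stop_kin("`params` must be a tertiary_monod_params object", "domain_error")
  }
  ks <- c(params$K2_C, params$K3_C, params$K4_C,
          params$K2_P, params$K3_P, params$K4_P,
          params$K2_h, params$K3_h, params$K4_h)
  fac <- interaction_product_factors(state)
  stats::setNames(ks * fac, names(fac))
}
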