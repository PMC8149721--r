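# Forward evaluation of all growth and decay laws used in the analysis.
# Everything here is pure: parameters in, rates/concentrations out.

#' Haldane-Andrews substrate-inhibition parameters
#'
#' Parameter set for the Haldane-Andrews growth law
#' \deqn{\mu(S) = \frac{\mu_{max} S}{S + S^2/K_I + K_S}}
#' which extends the Monod law with a self-inhibition term \eqn{S^2/K_I}:
#' growth first rises with substrate, peaks at \eqn{S^* = \sqrt{K_S K_I}},
#' then declines as the substrate becomes toxic.
#'
#' @param mu_max maximum specific growth rate, h^-1 (> 0).
#' @param K_S half-saturation (substrate affinity) constant, mg/L (> 0).
#' @param K_I inhibition constant, mg/L (> 0). Large `K_I` recovers the
#'   plain Monod law.
#' @return an object of class `haldane_params`.
#' @seealso [haldane_mu()], [fit_haldane()]
#' @examples
#' p <- haldane_params(mu_max = 0.1129, K_S = 0.5, K_I = 1.01)
#' haldane_mu(p, sqrt(0.5 * 1.01)) # growth peak
#' @export
haldane_params <- function(mu_max, K_S, K_I) {
  check_number(mu_max, "mu_max", lower = 0, allow_zero = FALSE)
  check_number(K_S, "K_S", lower = 0, allow_zero = FALSE)
  check_number(K_I, "K_I", lower = 0, allow_zero = FALSE)
  structure(list(mu_max = mu_max, K_S = K_S, K_I = K_I),
            class = "haldane_params")
}

#' @export
print.haldane_params <- function(x, ...) {
  cat("Haldane-Andrews parameters\n")
  cat(sprintf("  mu_max: %g h^-1   K_S: %g mg/L   K_I: %g mg/L\n",
              x$mu_max, x$K_S, x$K_I))
  cat(sprintf("  peak: mu = %g h^-1 at S* = %g mg/L\n",
              x$mu_max / (1 + 2 * sqrt(x$K_S / x$K_I)), sqrt(x$K_S * x$K_I)))
  invisible(x)
}

#' Evaluate the Haldane-Andrews growth law
#'
#' @param params a [haldane_params()] object.
#' @param S substrate concentration(s), mg/L (>= 0); vectorised.
#' @return specific growth rate(s), h^-1.
#' @export
haldane_mu <- function(params, S) {
  if (!inherits(params, "haldane_params")) {
    stop_kin("`params` must be a haldane_params object", "domain_error")
  }
  if (!is.numeric(S) || any(!is.finite(S)) || any(S < 0)) {
    stop_kin("`S` must be finite and >= 0", "domain_error")
  }
  params$mu_max * S / (S + S^2 / params$K_I + params$K_S)
}

#' Location and height of the Haldane-Andrews growth peak
#'
#' Closed form: the rate is maximal at \eqn{S^* = \sqrt{K_S K_I}} where it
#' equals \eqn{\mu_{max} / (1 + 2\sqrt{K_S/K_I})}.
#'
#' @inheritParams haldane_mu
#' @return a list with elements `S` (mg/L) and `mu` (h^-1).
#' @export
haldane_peak <- function(params) {
  if (!inherits(params, "haldane_params")) {
    stop_kin("`params` must be a haldane_params object", "domain_error")
  }
  list(S = sqrt(params$K_S * params$K_I),
       mu = params$mu_max / (1 + 2 * sqrt(params$K_S / params$K_I)))
}

#' Substrate state of the tertiary cometabolic system
#'
#' Concentrations of the three interacting substrates: glucose (carbon
#' source), Cr(VI) (the pollutant being reduced), and high-carbon iron
#' filings (HCIF, expressed as a pseudo-concentration via [dose_mg_per_l()]).
#'
#' @param S_C glucose concentration, mg/L (>= 0).
#' @param S_P Cr(VI) concentration, mg/L (>= 0).
#' @param S_h HCIF pseudo-concentration, mg/L (>= 0).
#' @return an object of class `substrate_state`.
#' @export
substrate_state <- function(S_C, S_P, S_h) {
  check_number(S_C, "S_C", lower = 0)
  check_number(S_P, "S_P", lower = 0)
  check_number(S_h, "S_h", lower = 0)
  structure(list(S_C = S_C, S_P = S_P, S_h = S_h), class = "substrate_state")
}

#' Three-substrate Monod growth parameters with cross-inhibition
#'
#' Parameter set for the tertiary Monod growth law: the specific growth rate
#' is the sum of three Monod-type terms, one per substrate, each of whose
#' denominators is inflated by the other two substrates through interaction
#' constants,
#' \deqn{\mu = \sum_{i \in \{C,P,h\}}
#'   \frac{\mu_{max,i} S_i}{K_{S,i} + S_i + K_{2i} S_j + K_{3i} S_k +
#'         K_{4i} S_j S_k}}
#' so that `K2`/`K3` quantify inhibition of substrate i's use by one of the
#' other substrates alone and `K4` their joint inhibition. All interaction
#' constants zero decouples the system into three independent Monod terms.
#'
#' The published form of the Cr(VI) term carries `S_C` in place of `S_P` in
#' its denominator's saturation slot, which would make chromium's
#' saturation depend on glucose, at odds with the stated meaning of the
#' interaction terms. `form_variant = "symmetric"` (default) uses `S_P`
#' there, consistent with the glucose and HCIF terms; `"as_printed"`
#' reproduces the published denominator verbatim.
#'
#' @param base_C,base_P,base_h per-substrate base parameters, each a list
#'   with elements `mu_max` (h^-1, > 0) and `K_S` (mg/L, > 0), for glucose,
#'   Cr(VI) and HCIF respectively.
#' @param K2_C,K3_C,K4_C interaction constants in the glucose term:
#'   inhibition by Cr(VI), by HCIF, and by both jointly (>= 0). `K2`/`K3`
#'   are per (mg/L), `K4` per (mg/L)^2, so every denominator summand has
#'   concentration units.
#' @param K2_P,K3_P,K4_P likewise for the Cr(VI) term (inhibition by
#'   glucose, HCIF, both).
#' @param K2_h,K3_h,K4_h likewise for the HCIF term (inhibition by glucose,
#'   Cr(VI), both).
#' @param form_variant `"symmetric"` (default) or `"as_printed"`; see
#'   Details.
#' @return an object of class `tertiary_monod_params`.
#' @seealso [tertiary_mu()], [fit_tertiary()], [interaction_products()]
#' @export
tertiary_monod_params <- function(base_C, base_P, base_h,
                                  K2_C = 0, K3_C = 0, K4_C = 0,
                                  K2_P = 0, K3_P = 0, K4_P = 0,
                                  K2_h = 0, K3_h = 0, K4_h = 0,
                                  form_variant = c("symmetric", "as_printed")) {
  form_variant <- match.arg(form_variant)
  check_base <- function(b, name) {
    if (!is.list(b) || !all(c("mu_max", "K_S") %in% names(b))) {
      stop_kin(sprintf("`%s` must be a list with mu_max and K_S", name),
               "domain_error")
    }
    check_number(b$mu_max, paste0(name, "$mu_max"), lower = 0, allow_zero = FALSE)
    check_number(b$K_S, paste0(name, "$K_S"), lower = 0, allow_zero = FALSE)
    list(mu_max = b$mu_max, K_S = b$K_S)
  }
  ks <- list(K2_C = K2_C, K3_C = K3_C, K4_C = K4_C,
             K2_P = K2_P, K3_P = K3_P, K4_P = K4_P,
             K2_h = K2_h, K3_h = K3_h, K4_h = K4_h)
  for (nm in names(ks)) check_number(ks[[nm]], nm, lower = 0)
  structure(c(list(base_C = check_base(base_C, "base_C"),
                   base_P = check_base(base_P, "base_P"),
                   base_h = check_base(base_h, "base_h")),
              ks, list(form_variant = form_variant)),
            class = "tertiary_monod_params")
}

#' @export
print.tertiary_monod_params <- function(x, ...) {
  cat("Tertiary Monod growth parameters (", x$form_variant, " variant)\n",
      sep = "")
  for (nm in c("C", "P", "h")) {
    b <- x[[paste0("base_", nm)]]
    lab <- c(C = "glucose", P = "Cr(VI) ", h = "HCIF   ")[nm]
    cat(sprintf("  %s: mu_max %-10g K_S %-10g K2 %-10g K3 %-10g K4 %g\n",
                lab, b$mu_max, b$K_S,
                x[[paste0("K2_", nm)]], x[[paste0("K3_", nm)]],
                x[[paste0("K4_", nm)]]))
  }
  invisible(x)
}

# Per-substrate terms of the tertiary law, vectorised over parallel
# concentration vectors. The simulator needs the individual terms to
# apportion substrate consumption; tertiary_mu() reports their sum.
tertiary_mu_terms <- function(params, S_C, S_P, S_h) {
  term_C <- params$base_C$mu_max * S_C /
    (params$base_C$K_S + S_C + params$K2_C * S_P + params$K3_C * S_h +
       params$K4_C * S_P * S_h)
  sat_P <- if (params$form_variant == "as_printed") S_C else S_P
  term_P <- params$base_P$mu_max * S_P /
    (params$base_P$K_S + sat_P + params$K2_P * S_C + params$K3_P * S_h +
       params$K4_P * S_C * S_h)
  term_h <- params$base_h$mu_max * S_h /
    (params$base_h$K_S + S_h + params$K2_h * S_C + params$K3_h * S_P +
       params$K4_h * S_C * S_P)
  list(C = term_C, P = term_P, h = term_h)
}

tertiary_mu_vec <- function(params, S_C, S_P, S_h) {
  tm <- tertiary_mu_terms(params, S_C, S_P, S_h)
  tm$C + tm$P + tm$h
}

#' Evaluate the tertiary Monod growth law
#'
#' @param params a [tertiary_monod_params()] object.
#' @param state a [substrate_state()] object.
#' @return specific growth rate, h^-1.
#' @export
tertiary_mu <- function(params, state) {
  if (!inherits(params, "tertiary_monod_params")) {
    stop_kin("`params` must be a tertiary_monod_params object", "domain_error")
  }
  if (!inherits(state, "substrate_state")) {
    stop_kin("`state` must be a substrate_state object", "domain_error")
  }
  tertiary_mu_vec(params, state$S_C, state$S_P, state$S_h)
}

#' Pseudo-order decay-law parameters
#'
#' Empirical decay laws for pollutant disappearance: pseudo-first-order
#' \eqn{C(t) = C_0 e^{-kt}} and the integrated pseudo-second-order law
#' \eqn{C(t) = C_0 / (1 + k C_0 t)} (from \eqn{1/C - 1/C_0 = kt}).
#'
#' @param order `"first"` or `"second"`.
#' @param k rate constant (h^-1 for first order, mg^-1 L h^-1 for second;
#'   >= 0).
#' @param C0 initial concentration, mg/L (> 0).
#' @return an object of class `rate_law_params`.
#' @seealso [rate_law_predict()], [fit_rate_constant()]
#' @export
rate_law_params <- function(order = c("first", "second"), k, C0) {
  order <- match.arg(order)
  check_number(k, "k", lower = 0)
  check_number(C0, "C0", lower = 0, allow_zero = FALSE)
  structure(list(order = order, k = k, C0 = C0), class = "rate_law_params")
}

#' Predict concentration under a pseudo-order decay law
#'
#' @param params a [rate_law_params()] object.
#' @param t time(s), h (>= 0); vectorised.
#' @return concentration(s), mg/L; non-increasing in `t`, in `(0, C0]`.
#' @examples
#' p <- rate_law_params("first", k = 0.057, C0 = 10)
#' rate_law_predict(p, log(2) / 0.057) # half-life: 5 mg/L
#' @export
rate_law_predict <- function(params, t) {
  if (!inherits(params, "rate_law_params")) {
    stop_kin("`params` must be a rate_law_params object", "domain_error")
  }
  if (!is.numeric(t) || any(!is.finite(t)) || any(t < 0)) {
    stop_kin("`t` must be finite and >= 0", "domain_error")
  }
  if (params$order == "first") {
    params$C0 * exp(-params$k * t)
  } else {
    params$C0 / (1 + params$k * params$C0 * t)
  }
}
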