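# Nonlinear least-squares estimation of all model parameters, with
# goodness-of-fit reporting. Rate laws are fitted in their linearised
# spaces (closed form); the growth models by bounded multi-start
# Levenberg-Marquardt in log-parameter space.

#' Coefficient of determination
#'
#' Conventional \eqn{R^2 = 1 - \sum(obs - pred)^2 / \sum(obs - \bar{obs})^2}
#' with the total sum of squares about the observed mean. May be negative
#' for fits worse than the mean predictor.
#'
#' @param observed,predicted numeric vectors of equal length >= 2.
#' @return R^2, dimensionless.
#' @export
r_squared <- function(observed, predicted) {
  if (length(observed) != length(predicted) || length(observed) < 2L) {
    stop_kin("`observed` and `predicted` must have equal length >= 2",
             "domain_error")
  }
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) {
    stop_kin("observed values are all identical: R^2 undefined",
             "degenerate_data_error")
  }
  1 - sum((observed - predicted)^2) / ss_tot
}

#' Fit a pseudo-order rate constant to a decay time series
#'
#' Fits via linearisation, keeping the estimates closed-form: first order
#' regresses ln(C) on t (k = -slope, C0 = exp(intercept)); second order
#' regresses 1/C on t (k = slope, C0 = 1/intercept). R^2 is computed in the
#' linearised space and clipped to \[0, 1\] for reporting; a negative fitted
#' rate is clipped to k = 0. Points at or below `detection_limit` are
#' excluded, since complete reduction yields zeros the transforms cannot
#' accept.
#'
#' @param series a Cr(VI) (or other decaying quantity) [time_series()].
#' @param order `"first"` or `"second"`.
#' @param detection_limit concentration below which points are discarded,
#'   mg/L (default 0.05).
#' @return a list of class `rate_fit`: `order`, `k`, `r_squared`, `C0_used`,
#'   `n_points`.
#' @examples
#' tt <- seq(0, 96, by = 12)
#' ts <- time_series(tt, 10 * exp(-0.057 * tt), "crvi")
#' fit_rate_constant(ts, "first")$k # 0.057
#' @export
fit_rate_constant <- function(series, order = c("first", "second"),
                              detection_limit = 0.05) {
  order <- match.arg(order)
  if (!inherits(series, "time_series")) {
    stop_kin("`series` must be a time_series", "domain_error")
  }
  keep <- series$values > detection_limit
  if (sum(keep) < 2L) {
    stop_kin(sprintf("need >= 2 points above the detection limit (%g)",
                     detection_limit), "insufficient_data_error")
  }
  t <- series$times[keep]
  y <- if (order == "first") log(series$values[keep]) else 1 / series$values[keep]
  fit <- loglinear_fit(t, y)
  intercept <- mean(y) - fit$slope * mean(t)
  k <- if (order == "first") -fit$slope else fit$slope
  C0 <- if (order == "first") exp(intercept) else 1 / intercept
  r2 <- fit$r_squared
  # A flat series carries no decay information: degenerate R^2 reported as 0.
  if (stats::var(y) < 1e-18) r2 <- 0
  structure(list(order = order, k = max(k, 0), r_squared = r2,
                 C0_used = C0, n_points = sum(keep)),
            class = "rate_fit")
}

#' @export
print.rate_fit <- function(x, ...) {
  unit <- if (x$order == "first") "h^-1" else "mg^-1 L h^-1"
  cat(sprintf("pseudo-%s-order fit: k = %g %s (R^2 = %.4f, n = %d, C0 = %g)\n",
              x$order, x$k, unit, x$r_squared, x$n_points, x$C0_used))
  invisible(x)
}

# Bounded multi-start Levenberg-Marquardt. Each start runs LM in
# log-parameter space (enforcing positivity and taming parameter-scale
# spread), then is polished by a second LM pass in linear space, which
# escapes the flat log-scale valleys near weakly determined constants.
# Starts are drawn log-uniformly from [lower, upper] as one sequential
# stream under `seed`, so the start set for n_starts = k is a prefix of the
# set for k + 1 (best-of-starts objective is monotone in n_starts).
multistart_lm <- function(resid_fn, n_par, lower, upper, n_starts, seed) {
  lower <- rep_len(lower, n_par); upper <- rep_len(upper, n_par)
  llo <- log(lower); lup <- log(upper)
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(i) {
    stats::runif(n_par, llo, lup)
  }))
  best <- NULL
  n_conv <- 0L
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-15,
                                     ptol = 1e-15, gtol = 0)
  for (st in starts) {
    fit <- tryCatch({
      f1 <- minpack.lm::nls.lm(par = st, lower = llo, upper = lup,
                               fn = function(lp) resid_fn(exp(lp)),
                               control = ctrl)
      f2 <- minpack.lm::nls.lm(par = exp(f1$par), lower = lower, upper = upper,
                               fn = resid_fn, control = ctrl)
      if (f2$deviance <= f1$deviance) {
        list(par = f2$par, deviance = f2$deviance, info = f2$info)
      } else {
        list(par = exp(f1$par), deviance = f1$deviance, info = f1$info)
      }
    }, error = function(e) NULL)
    if (is.null(fit)) next
    ok <- fit$info %in% 1:4
    if (ok) n_conv <- n_conv + 1L
    if (is.null(best) || fit$deviance < best$deviance) {
      best <- list(par = fit$par, deviance = fit$deviance, converged = ok)
    }
  }
  if (is.null(best) || n_conv == 0L) {
    stop_kin("no multi-start attempt converged", "convergence_error")
  }
  c(best, list(n_starts_used = n_starts))
}

new_fit_result <- function(params, r2, deviance, converged, n_starts, seed,
                           degenerate = FALSE, warnings = character()) {
  structure(list(params = params, r_squared = r2,
                 residual_norm = sqrt(deviance), converged = converged,
                 n_starts_used = n_starts, seed = seed,
                 degenerate = degenerate,
                 identifiability_warnings = warnings),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat("Nonlinear least-squares fit (", x$n_starts_used, " starts, seed ",
      x$seed, ")\n", sep = "")
  cat(sprintf("  R^2 = %s, residual norm = %g, converged: %s\n",
              if (is.na(x$r_squared)) "NA" else sprintf("%.4f", x$r_squared),
              x$residual_norm, x$converged))
  if (x$degenerate) cat("  WARNING: degenerate data (null signal)\n")
  for (w in x$identifiability_warnings) cat("  WARNING:", w, "\n")
  print(x$params)
  invisible(x)
}

#' Fit the Haldane-Andrews model to (substrate, growth rate) observations
#'
#' Minimises the residual sum of squares of [haldane_mu()] over
#' (`mu_max`, `K_S`, `K_I`) by bounded multi-start Levenberg-Marquardt.
#' Optimisation runs in log-parameter space, which enforces positivity and
#' copes with the orders-of-magnitude spread between growth rates and
#' inhibition constants. Starts are log-uniform over `bounds`; the seed is
#' mandatory so the procedure is reproducible.
#'
#' @param mu_obs data frame with columns `S` (mg/L) and `mu` (h^-1);
#'   >= 4 distinct `S` values.
#' @param bounds length-2 numeric: common lower and upper box bound for all
#'   parameters (default `c(1e-6, 1e4)`).
#' @param n_starts number of multi-start draws (default 20).
#' @param seed integer RNG seed (required).
#' @return a `kinetic_fit` with `params` a [haldane_params()] object plus
#'   goodness-of-fit fields.
#' @export
fit_haldane <- function(mu_obs, bounds = c(1e-6, 1e4), n_starts = 20, seed) {
  if (missing(seed)) stop_kin("`seed` is required", "domain_error")
  if (!is.data.frame(mu_obs) || !all(c("S", "mu") %in% names(mu_obs))) {
    stop_kin("`mu_obs` must be a data frame with columns S and mu",
             "domain_error")
  }
  if (length(unique(mu_obs$S)) < 4L) {
    stop_kin("need >= 4 distinct substrate levels for 3 free parameters",
             "insufficient_data_error")
  }
  S <- mu_obs$S; mu <- mu_obs$mu
  resid_fn <- function(p) mu - p[1] * S / (S + S^2 / p[3] + p[2])
  best <- multistart_lm(resid_fn, 3L, bounds[1], bounds[2], n_starts, seed)
  params <- haldane_params(best$par[1], best$par[2], best$par[3])
  degenerate <- all(mu == 0) || stats::var(mu) == 0
  r2 <- if (degenerate) NA_real_ else r_squared(mu, haldane_mu(params, S))
  new_fit_result(params, r2, best$deviance, best$converged,
                 best$n_starts_used, seed, degenerate = degenerate)
}

#' Fit the tertiary Monod interaction constants
#'
#' Estimates the nine cross-inhibition constants `K2`/`K3`/`K4` of the
#' tertiary Monod law by bounded multi-start Levenberg-Marquardt, holding
#' the per-substrate base parameters (`mu_max`, `K_S`) fixed — these come
#' from the single/binary-substrate fits and are not re-estimated.
#' Optimisation runs in log-parameter space over the box `bounds`.
#'
#' @param mu_obs data frame with columns `S_C`, `S_P`, `S_h` (mg/L) and
#'   `mu` (h^-1); >= 10 observations, ideally spanning variation in all
#'   three substrates.
#' @param base_params list with elements `base_C`, `base_P`, `base_h`, each
#'   `list(mu_max =, K_S =)`, held fixed.
#' @param form_variant passed to [tertiary_monod_params()].
#' @inheritParams fit_haldane
#' @return a `kinetic_fit` with `params` a [tertiary_monod_params()] object.
#'   A design with (near-)no variation in some substrate yields an
#'   identifiability warning attached to the result.
#' @export
fit_tertiary <- function(mu_obs, base_params,
                         form_variant = c("symmetric", "as_printed"),
                         bounds = c(1e-6, 1e4), n_starts = 20, seed) {
  form_variant <- match.arg(form_variant)
  if (missing(seed)) stop_kin("`seed` is required", "domain_error")
  need <- c("S_C", "S_P", "S_h", "mu")
  if (!is.data.frame(mu_obs) || !all(need %in% names(mu_obs))) {
    stop_kin("`mu_obs` must be a data frame with columns S_C, S_P, S_h, mu",
             "domain_error")
  }
  if (nrow(mu_obs) < 10L) {
    stop_kin("need >= 10 observations for 9 free interaction constants",
             "insufficient_data_error")
  }
  warnings <- character()
  for (col in c("S_C", "S_P", "S_h")) {
    if (length(unique(mu_obs[[col]])) < 2L) {
      warnings <- c(warnings, sprintf(
        "no variation in %s: its interaction constants are not identifiable",
        col))
    }
  }
  if (length(warnings)) warning(paste(warnings, collapse = "; "))
  mk <- function(k) {
    tertiary_monod_params(base_params$base_C, base_params$base_P,
                          base_params$base_h,
                          K2_C = k[1], K3_C = k[2], K4_C = k[3],
                          K2_P = k[4], K3_P = k[5], K4_P = k[6],
                          K2_h = k[7], K3_h = k[8], K4_h = k[9],
                          form_variant = form_variant)
  }
  resid_fn <- function(k) {
    mu_obs$mu - tertiary_mu_vec(mk(k), mu_obs$S_C, mu_obs$S_P, mu_obs$S_h)
  }
  best <- multistart_lm(resid_fn, 9L, bounds[1], bounds[2], n_starts, seed)
  params <- mk(best$par)
  pred <- tertiary_mu_vec(params, mu_obs$S_C, mu_obs$S_P, mu_obs$S_h)
  degenerate <- stats::var(mu_obs$mu) == 0
  r2 <- if (degenerate) NA_real_ else r_squared(mu_obs$mu, pred)
  new_fit_result(params, r2, best$deviance, best$converged,
                 best$n_starts_used, seed, degenerate = degenerate,
                 warnings = warnings)
}
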