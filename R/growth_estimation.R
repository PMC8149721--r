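# Specific growth rate from biomass time courses: mu = d ln X / dt over the
# exponential phase, with the phase located automatically.

#' Measured time series for one quantity, condition and replicate
#'
#' @param times sampling times, h; strictly increasing, length >= 2.
#' @param values measurements (OD600 for biomass, mg/L for concentrations);
#'   all >= 0.
#' @param quantity one of `"biomass"`, `"crvi"`, `"glucose"`, or `"hcif"`
#'   (the latter only for simulator ground truth: HCIF pseudo-concentration
#'   is not a measurable quantity).
#' @param replicate_id replicate label (default `"r1"`).
#' @return an object of class `time_series`.
#' @export
time_series <- function(times, values,
                        quantity = c("biomass", "crvi", "glucose", "hcif"),
                        replicate_id = "r1") {
  quantity <- match.arg(quantity)
  if (!is.numeric(times) || length(times) < 2L || any(!is.finite(times))) {
    stop_kin("`times` must be numeric, finite, length >= 2", "domain_error")
  }
  if (any(diff(times) <= 0)) {
    stop_kin("`times` must be strictly increasing", "domain_error")
  }
  if (!is.numeric(values) || length(values) != length(times) ||
      any(!is.finite(values))) {
    stop_kin("`values` must be numeric, finite, same length as `times`",
             "domain_error")
  }
  if (any(values < 0)) stop_kin("`values` must be >= 0", "domain_error")
  structure(list(times = as.numeric(times), values = as.numeric(values),
                 quantity = quantity, replicate_id = as.character(replicate_id)),
            class = "time_series")
}

#' @export
print.time_series <- function(x, ...) {
  cat(sprintf("time_series<%s> replicate %s: %d points, t = %g..%g h\n",
              x$quantity, x$replicate_id, length(x$times),
              min(x$times), max(x$times)))
  invisible(x)
}

# Ordinary least squares of y on x returning slope and R^2, with a flat
# response treated as a perfect (R^2 = 1) zero-slope fit.
loglinear_fit <- function(x, y) {
  n <- length(x)
  mx <- mean(x); my <- mean(y)
  sxx <- sum((x - mx)^2)
  slope <- sum((x - mx) * (y - my)) / sxx
  pred <- my + slope * (x - mx)
  ss_res <- sum((y - pred)^2)
  ss_tot <- sum((y - my)^2)
  r2 <- if (ss_tot < 1e-18) {
    if (ss_res / n < 1e-18) 1 else 0
  } else {
    1 - ss_res / ss_tot
  }
  list(slope = slope, r_squared = min(max(r2, 0), 1))
}

#' Estimate the specific growth rate from a biomass time series
#'
#' Implements the log-slope definition \eqn{\mu = d\ln X/dt}, evaluated over
#' the exponential phase. The phase is located automatically: among all
#' contiguous windows of at least `min_window` points whose biomass exceeds
#' `detection_floor`, the window maximising the R^2 of the linear fit of
#' ln(X) on t is selected (ties broken in favour of the longer window, then
#' the earlier start). The slope of that fit is mu. Points at or below the
#' floor are never log-transformed; they break window contiguity. The
#' returned mu may be negative when the best log-linear window lies in the
#' decline phase — callers decide whether to keep such estimates.
#'
#' @param series a biomass [time_series()].
#' @param min_window minimum number of points per candidate window
#'   (default 3).
#' @param detection_floor biomass detection floor, OD units (default 0.01);
#'   points at or below it are excluded.
#' @return a list of class `growth_rate_estimate` with elements `mu` (h^-1),
#'   `window_start`, `window_end` (h), `r_squared`, `n_points`.
#' @examples
#' ts <- time_series(0:10, 0.05 * exp(0.1 * 0:10), "biomass")
#' estimate_mu(ts)$mu # 0.1
#' @export
estimate_mu <- function(series, min_window = 3, detection_floor = 0.01) {
  if (!inherits(series, "time_series") || series$quantity != "biomass") {
    stop_kin("`series` must be a biomass time_series", "domain_error")
  }
  if (min_window < 3) stop_kin("`min_window` must be >= 3", "domain_error")
  usable <- series$values > detection_floor
  if (sum(usable) < min_window) {
    stop_kin(sprintf(
      "need >= %d points above the detection floor (%g); have %d",
      min_window, detection_floor, sum(usable)), "insufficient_data_error")
  }
  n <- length(series$times)
  best <- NULL
  run_start <- NULL
  runs <- list()
  for (i in seq_len(n)) {
    if (usable[i] && is.null(run_start)) run_start <- i
    if ((!usable[i] || i == n) && !is.null(run_start)) {
      run_end <- if (usable[i]) i else i - 1L
      runs[[length(runs) + 1L]] <- c(run_start, run_end)
      run_start <- NULL
    }
  }
  for (run in runs) {
    if (run[2] - run[1] + 1L < min_window) next
    for (i in run[1]:(run[2] - min_window + 1L)) {
      for (j in (i + min_window - 1L):run[2]) {
        fit <- loglinear_fit(series$times[i:j], log(series$values[i:j]))
        len <- j - i + 1L
        cand <- list(mu = fit$slope, i = i, j = j,
                     r_squared = fit$r_squared, n_points = len)
        if (is.null(best) ||
            fit$r_squared > best$r_squared + 1e-12 ||
            (abs(fit$r_squared - best$r_squared) <= 1e-12 &&
             (len > best$n_points ||
              (len == best$n_points && i < best$i)))) {
          best <- cand
        }
      }
    }
  }
  if (is.null(best)) {
    stop_kin("no contiguous window of usable points is long enough",
             "insufficient_data_error")
  }
  structure(list(mu = best$mu,
                 window_start = series$times[best$i],
                 window_end = series$times[best$j],
                 r_squared = best$r_squared,
                 n_points = best$n_points),
            class = "growth_rate_estimate")
}

#' @export
print.growth_rate_estimate <- function(x, ...) {
  cat(sprintf("mu = %g h^-1 over t = %g..%g h (%d points, R^2 = %.4f)\n",
              x$mu, x$window_start, x$window_end, x$n_points, x$r_squared))
  invisible(x)
}
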