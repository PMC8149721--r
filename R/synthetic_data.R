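# Batch-reactor simulator: ground-truth time courses with the statistical
# structure the downstream analysis assumes (triplicates, multiplicative
# Gaussian measurement noise, growth by the Haldane or tertiary Monod law).
# The mass-balance ODEs are the minimal standard yield/Monod constructions —
# they exist so every fitting stage has a generator with known truth, and
# make no mechanistic claim about Fe0/Fe(II)/Cr(VI) chemistry.

#' Batch experimental condition
#'
#' Design metadata for one batch reactor: initial Cr(VI), substrate doses
#' and the substrate-system type. The binary system is bacteria + glucose;
#' the tertiary system adds high-carbon iron filings (HCIF).
#'
#' @param cr0 initial Cr(VI) concentration, mg/L (> 0); the study levels
#'   are 10, 25, 40, 50, 100.
#' @param system `"tertiary"` or `"binary"`.
#' @param glucose_dose glucose added, g per 250 mL (default 1).
#' @param hcif_dose HCIF added, g per 250 mL (default 1 for tertiary, must
#'   be 0 for binary).
#' @param temperature incubation temperature, degrees C (metadata).
#' @param rpm shaker speed (metadata).
#' @return an object of class `batch_condition`.
#' @export
batch_condition <- function(cr0, system = c("tertiary", "binary"),
                            glucose_dose = 1,
                            hcif_dose = if (match.arg(system) == "binary") 0 else 1,
                            temperature = 35, rpm = 120) {
  system <- match.arg(system)
  check_number(cr0, "cr0", lower = 0, allow_zero = FALSE)
  check_number(glucose_dose, "glucose_dose", lower = 0)
  check_number(hcif_dose, "hcif_dose", lower = 0)
  if (system == "binary" && hcif_dose != 0) {
    stop_kin("binary system must have hcif_dose = 0", "domain_error")
  }
  structure(list(cr0 = cr0, glucose_dose = glucose_dose,
                 hcif_dose = hcif_dose, system = system,
                 temperature = temperature, rpm = rpm),
            class = "batch_condition")
}

#' @export
print.batch_condition <- function(x, ...) {
  cat(sprintf(
    "%s batch: Cr(VI) %g mg/L, glucose %g g/250 mL, HCIF %g g/250 mL (%g C, %g rpm)\n",
    x$system, x$cr0, x$glucose_dose, x$hcif_dose, x$temperature, x$rpm))
  invisible(x)
}

#' Simulator configuration
#'
#' @param growth_params a [tertiary_monod_params()] or [haldane_params()]
#'   object (the latter grows on glucose only), or `NULL` for a
#'   non-growing culture.
#' @param yield_C biomass yield on glucose, OD per (mg/L) consumed (> 0).
#' @param yield_h biomass yield on HCIF pseudo-concentration (> 0; default
#'   `yield_C`).
#' @param q_P specific Cr(VI) reduction rate, mg/L per OD unit per h
#'   (>= 0).
#' @param decay_rate first-order biomass decay once growth substrates are
#'   exhausted, h^-1 (default 0.02).
#' @param K_red saturation constant of the reduction term, mg/L (default
#'   1): reduction is first-order in Cr(VI) below `K_red` and
#'   biomass-limited above it.
#' @param exhaustion_threshold total growth substrate (mg/L) below which
#'   biomass decay switches on (default 10).
#' @param X0 inoculum biomass, OD600 (default 0.05).
#' @param noise_cv relative SD of the multiplicative Gaussian measurement
#'   noise (default 0.05; 0 for noise-free replicates).
#' @param n_replicates replicate count (default 3, the triplicate design).
#' @param seed integer RNG seed; required, so simulations are reproducible.
#' @param t_grid sampling times, h (default every 12 h up to 124 h).
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(growth_params = NULL, yield_C, yield_h = yield_C,
                              q_P, decay_rate = 0.02, K_red = 1,
                              exhaustion_threshold = 10, X0 = 0.05,
                              noise_cv = 0.05, n_replicates = 3, seed,
                              t_grid = seq(0, 124, by = 12)) {
  if (missing(seed)) stop_kin("`seed` is required", "domain_error")
  if (!is.null(growth_params) &&
      !inherits(growth_params, c("haldane_params", "tertiary_monod_params"))) {
    stop_kin("`growth_params` must be haldane_params, tertiary_monod_params or NULL",
             "domain_error")
  }
  check_number(yield_C, "yield_C", lower = 0, allow_zero = FALSE)
  check_number(yield_h, "yield_h", lower = 0, allow_zero = FALSE)
  check_number(q_P, "q_P", lower = 0)
  check_number(decay_rate, "decay_rate", lower = 0)
  check_number(K_red, "K_red", lower = 0, allow_zero = FALSE)
  check_number(X0, "X0", lower = 0, allow_zero = FALSE)
  check_number(noise_cv, "noise_cv", lower = 0)
  if (length(t_grid) < 2L || any(diff(t_grid) <= 0)) {
    stop_kin("`t_grid` must be strictly increasing, length >= 2", "domain_error")
  }
  structure(list(growth_params = growth_params, yield_C = yield_C,
                 yield_h = yield_h, q_P = q_P, decay_rate = decay_rate,
                 K_red = K_red, exhaustion_threshold = exhaustion_threshold,
                 X0 = X0, noise_cv = noise_cv,
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed), t_grid = as.numeric(t_grid)),
            class = "simulation_config")
}

# Mass-balance right-hand side shared by all growth laws.
batch_derivs <- function(t, y, parms) {
  X <- max(y[1], 0); S_C <- max(y[2], 0); S_P <- max(y[3], 0)
  S_h <- max(y[4], 0)
  gp <- parms$growth_params
  if (is.null(gp)) {
    mu_C <- 0; mu_h <- 0; mu <- 0; growth_substrate <- Inf
  } else if (inherits(gp, "haldane_params")) {
    mu_C <- haldane_mu(gp, S_C); mu_h <- 0; mu <- mu_C
    growth_substrate <- S_C
  } else {
    tm <- tertiary_mu_terms(gp, S_C, S_P, S_h)
    mu_C <- tm$C; mu_h <- tm$h; mu <- tm$C + tm$P + tm$h
    growth_substrate <- S_C + S_h
  }
  exhausted <- is.null(gp) == FALSE && growth_substrate < parms$exhaustion_threshold
  dX <- (mu - parms$decay_rate * exhausted) * X
  dS_C <- -mu_C * X / parms$yield_C
  dS_h <- -mu_h * X / parms$yield_h
  dS_P <- -parms$q_P * X * S_P / (S_P + parms$K_red)
  list(c(dX, dS_C, dS_P, dS_h))
}

#' Simulate one batch reactor
#'
#' Integrates the batch mass balances
#' \deqn{dX/dt = (\mu(S) - k_d \, 1[\mathrm{exhausted}]) X}
#' \deqn{dS_C/dt = -\mu_C X / Y_C, \quad dS_h/dt = -\mu_h X / Y_h}
#' \deqn{dS_P/dt = -q_P X \, S_P / (S_P + K_{red})}
#' where \eqn{\mu_C}, \eqn{\mu_h} are the glucose/HCIF terms of the growth
#' law, and adds seeded multiplicative Gaussian measurement noise per
#' replicate. The noise-free trajectory is always returned alongside the
#' replicates.
#'
#' @param condition a [batch_condition()].
#' @param config a [simulation_config()].
#' @return an object of class `batch_simulation`: list with `condition`,
#'   `config`, `truth` (named list of noise-free biomass/crvi/glucose
#'   [time_series()]), and `replicates` (list per replicate of the same
#'   named structure).
#' @export
simulate_batch <- function(condition, config) {
  if (!inherits(condition, "batch_condition")) {
    stop_kin("`condition` must be a batch_condition", "domain_error")
  }
  if (!inherits(config, "simulation_config")) {
    stop_kin("`config` must be a simulation_config", "domain_error")
  }
  y0 <- c(X = config$X0,
          S_C = dose_mg_per_l(condition$glucose_dose),
          S_P = condition$cr0,
          S_h = dose_mg_per_l(condition$hcif_dose))
  sol <- tryCatch(
    deSolve::lsoda(y0, config$t_grid, batch_derivs,
                   parms = config, rtol = 1e-8, atol = 1e-10),
    warning = function(w) {
      stop_kin(paste0("ODE integration failed: ", conditionMessage(w),
                      "; initial state [", paste(signif(y0, 6), collapse = ", "),
                      "]"), "simulation_error")
    })
  sol <- as.data.frame(sol)
  # Integrator jitter can leave tiny negatives; states are masses.
  for (col in c("X", "S_C", "S_P", "S_h")) sol[[col]] <- pmax(sol[[col]], 0)
  mk_series <- function(values, quantity, rep_id) {
    time_series(sol$time, values, quantity, rep_id)
  }
  truth <- list(biomass = mk_series(sol$X, "biomass", "truth"),
                crvi = mk_series(sol$S_P, "crvi", "truth"),
                glucose = mk_series(sol$S_C, "glucose", "truth"),
                hcif = mk_series(sol$S_h, "hcif", "truth"))
  n_t <- nrow(sol)
  replicates <- with_seed(config$seed, {
    lapply(seq_len(config$n_replicates), function(r) {
      rep_id <- paste0("r", r)
      noisy <- function(v, quantity) {
        obs <- v * (1 + config$noise_cv * stats::rnorm(n_t))
        mk_series(pmax(obs, 0), quantity, rep_id)
      }
      list(biomass = noisy(sol$X, "biomass"),
           crvi = noisy(sol$S_P, "crvi"),
           glucose = noisy(sol$S_C, "glucose"))
    })
  })
  structure(list(condition = condition, config = config,
                 truth = truth, replicates = replicates),
            class = "batch_simulation")
}

#' @export
print.batch_simulation <- function(x, ...) {
  print(x$condition)
  cat(sprintf("  %d replicates, noise CV %g, seed %d, t = %g..%g h\n",
              length(x$replicates), x$config$noise_cv, x$config$seed,
              min(x$config$t_grid), max(x$config$t_grid)))
  cat(sprintf("  final (noise-free): X %.3g OD, Cr(VI) %.3g mg/L, glucose %.3g mg/L\n",
              utils::tail(x$truth$biomass$values, 1),
              utils::tail(x$truth$crvi$values, 1),
              utils::tail(x$truth$glucose$values, 1)))
  invisible(x)
}

#' Calibrated simulation presets
#'
#' Named scenario presets whose parameters are calibrated once to the
#' qualitative milestones of the batch study:
#' \describe{
#'   \item{`set1_binary`}{bacteria + glucose. Haldane growth on glucose
#'     (constants on the g/L scale: `K_S` 500, `K_I` 1010 mg/L), glucose
#'     exhausted by ~60 h, and incomplete Cr(VI) reduction at high initial
#'     Cr (>= 5 mg/L left of 100 mg/L at 90 h).}
#'   \item{`set2_tertiary`}{bacteria + glucose + HCIF. Tertiary Monod
#'     growth with the reference interaction constants (10 mg/L column,
#'     inverted at state 4000/10/4000), growth sustained to ~120 h, and
#'     complete reduction of 100 mg/L Cr(VI) by 120 h.}
#'   \item{`first_order`}{non-growing culture with `K_red` far above
#'     `cr0`, so Cr(VI) decays exponentially with an exactly known rate
#'     constant `k = q_P X0 / K_red`; used to close the loop between the
#'     simulator and [fit_rate_constant()]. The calibrated constant is
#'     returned in `$calibrated$k1`.}
#' }
#'
#' @param name preset name.
#' @param cr0 initial Cr(VI), mg/L (default 100; the `first_order` preset
#'   defaults to 10 to stay far below its `K_red`).
#' @param noise_cv,n_replicates,seed forwarded to [simulation_config()].
#' @return list with elements `condition`, `config`, `calibrated` (named
#'   list of scenario constants with known ground truth).
#' @export
simulation_preset <- function(name = c("set1_binary", "set2_tertiary",
                                       "first_order"),
                              cr0 = if (match.arg(name) == "first_order") 10 else 100,
                              noise_cv = 0.05, n_replicates = 3, seed) {
  name <- match.arg(name)
  if (missing(seed)) stop_kin("`seed` is required", "domain_error")
  if (name == "set1_binary") {
    gp <- haldane_params(mu_max = 0.1129, K_S = 500, K_I = 1010)
    cond <- batch_condition(cr0, system = "binary", hcif_dose = 0)
    cfg <- simulation_config(growth_params = gp, yield_C = 5e-5,
                             q_P = 3.5, decay_rate = 0.02,
                             noise_cv = noise_cv,
                             n_replicates = n_replicates, seed = seed)
    calib <- list()
  } else if (name == "set2_tertiary") {
    ref <- interaction_products_reference()
    st <- substrate_state(S_C = 4000, S_P = 10, S_h = 4000)
    ks <- interaction_constants_from_products(ref$cr10, st)
    gp <- tertiary_monod_params(
      base_C = list(mu_max = 0.02, K_S = 500),
      base_P = list(mu_max = 0.002346, K_S = 30),
      base_h = list(mu_max = 0.03, K_S = 2000),
      K2_C = ks[["K2_C"]], K3_C = ks[["K3_C"]], K4_C = ks[["K4_C"]],
      K2_P = ks[["K2_P"]], K3_P = ks[["K3_P"]], K4_P = ks[["K4_P"]],
      K2_h = ks[["K2_h"]], K3_h = ks[["K3_h"]], K4_h = ks[["K4_h"]])
    cond <- batch_condition(cr0, system = "tertiary")
    cfg <- simulation_config(growth_params = gp, yield_C = 2.3e-4,
                             yield_h = 2.6e-4, q_P = 2.4, decay_rate = 0.02,
                             noise_cv = noise_cv,
                             n_replicates = n_replicates, seed = seed)
    calib <- list(growth_params = gp)
  } else {
    X0 <- 0.05; K_red <- 1000; k1 <- 0.057
    cond <- batch_condition(cr0, system = "binary", hcif_dose = 0)
    cfg <- simulation_config(growth_params = NULL, yield_C = 1e-4,
                             q_P = k1 * K_red / X0, K_red = K_red,
                             decay_rate = 0, X0 = X0, noise_cv = noise_cv,
                             n_replicates = n_replicates, seed = seed)
    calib <- list(k1 = k1)
  }
  list(name = name, condition = cond, config = cfg, calibrated = calib)
}

#' Generate a (substrate, growth rate) dataset from a growth model
#'
#' Evaluates a growth law over a design of substrate states and perturbs
#' the rates with seeded multiplicative Gaussian noise — the ground-truth
#' generator behind the parameter-recovery experiments for [fit_haldane()]
#' and [fit_tertiary()].
#'
#' @param model a [haldane_params()] or [tertiary_monod_params()] object.
#' @param design for a Haldane model, a numeric vector of substrate
#'   concentrations (or data frame with column `S`); for a tertiary model,
#'   a data frame with columns `S_C`, `S_P`, `S_h` (mg/L).
#' @param noise_cv relative SD of the noise (default 0, i.e. exact forward
#'   evaluations).
#' @param seed integer RNG seed; required when `noise_cv > 0`.
#' @return the design as a data frame with an added `mu` column (h^-1).
#' @export
generate_mu_dataset <- function(model, design, noise_cv = 0, seed = NULL) {
  check_number(noise_cv, "noise_cv", lower = 0)
  if (noise_cv > 0 && is.null(seed)) {
    stop_kin("`seed` is required when noise_cv > 0", "domain_error")
  }
  if (inherits(model, "haldane_params")) {
    S <- if (is.data.frame(design)) design$S else design
    if (is.null(S) || length(S) == 0L) {
      stop_kin("`design` must supply substrate concentrations", "domain_error")
    }
    out <- data.frame(S = as.numeric(S))
    mu <- haldane_mu(model, out$S)
  } else if (inherits(model, "tertiary_monod_params")) {
    need <- c("S_C", "S_P", "S_h")
    if (!is.data.frame(design) || !all(need %in% names(design)) ||
        nrow(design) == 0L) {
      stop_kin("`design` must be a data frame with columns S_C, S_P, S_h",
               "domain_error")
    }
    out <- design[need]
    mu <- tertiary_mu_vec(model, out$S_C, out$S_P, out$S_h)
  } else {
    stop_kin("`model` must be haldane_params or tertiary_monod_params",
             "domain_error")
  }
  if (noise_cv > 0) {
    mu <- with_seed(seed, mu * (1 + noise_cv * stats::rnorm(length(mu))))
  }
  out$mu <- mu
  out
}
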