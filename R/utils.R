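# Internal helpers shared across modules.

# Classed errors so callers can distinguish data problems from code bugs.
stop_kin <- function(message, class, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "crkinetics_error", "error", "condition"),
    list(message = message, call = call)
  ))
}

check_number <- function(x, name, lower = -Inf, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop_kin(sprintf("`%s` must be a single finite number", name), "domain_error")
  }
  if (x < lower || (!allow_zero && x == lower)) {
    cmp <- if (allow_zero) ">=" else ">"
    stop_kin(sprintf("`%s` must be %s %g (got %g)", name, cmp, lower, x),
             "domain_error")
  }
  invisible(x)
}

# Run `code` with the RNG seeded to `seed`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stream-specific 32-bit seed from a user seed.
derive_seed <- function(seed, offset) {
  (as.numeric(seed) * 7919 + offset * 104729) %% 2147483647
}

#' Convert a solids dose to a pseudo-concentration
#'
#' Doses of insoluble media (e.g. iron filings added per reactor bottle) have
#' no aqueous concentration; the convention used throughout this package is to
#' express them per litre of reactor liquid so they can enter concentration-
#' based growth laws. The default reactor volume is 250 mL, so 1 g/bottle
#' maps to 4000 mg/L.
#'
#' @param dose_g mass added per reactor, g.
#' @param volume_ml reactor liquid volume, mL (default 250).
#' @return pseudo-concentration, mg/L.
#' @examples
#' dose_mg_per_l(1) # 4000
#' @export
dose_mg_per_l <- function(dose_g, volume_ml = 250) {
  check_number(dose_g, "dose_g", lower = 0)
  check_number(volume_ml, "volume_ml", lower = 0, allow_zero = FALSE)
  dose_g * 1000 / (volume_ml / 1000)
}
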