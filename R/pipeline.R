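# End-to-end analysis: read (or synthesize) batch time courses, estimate
# specific growth rates, fit pseudo-order rate laws per condition, fit the
# single-substrate Haldane models and the tertiary Monod interaction
# constants, and emit table-shaped reports.

csv_columns <- c("condition_id", "system", "cr0_mg_per_L", "replicate",
                 "time_h", "quantity", "value")

#' Write batch time courses to the package CSV format
#'
#' Long-format, UTF-8, comma-separated with header
#' `condition_id,system,cr0_mg_per_L,replicate,time_h,quantity,value`.
#' The noise-free trajectory is written with replicate id `"truth"`.
#'
#' @param x a `batch_simulation` (from [simulate_batch()]) or a list of
#'   them.
#' @param path output file path.
#' @param include_truth write the noise-free trajectory too (default TRUE).
#' @return `path`, invisibly.
#' @export
write_timeseries_csv <- function(x, path, include_truth = TRUE) {
  sims <- if (inherits(x, "batch_simulation")) list(x) else x
  if (!all(vapply(sims, inherits, logical(1), "batch_simulation"))) {
    stop_kin("`x` must be a batch_simulation or list of them", "domain_error")
  }
  rows <- list()
  for (sim in sims) {
    cid <- sprintf("%s_cr%g", sim$condition$system, sim$condition$cr0)
    sets <- sim$replicates
    if (include_truth) sets <- c(list(sim$truth), sets)
    for (set in sets) {
      for (ts in set) {
        if (ts$quantity == "hcif") next  # not a measured quantity
        rows[[length(rows) + 1L]] <- data.frame(
          condition_id = cid, system = sim$condition$system,
          cr0_mg_per_L = sim$condition$cr0, replicate = ts$replicate_id,
          time_h = ts$times, quantity = ts$quantity, value = ts$values)
      }
    }
  }
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read batch time courses from the package CSV format
#'
#' Strictly validated: missing columns, duplicate
#' (condition, replicate, quantity, time) keys, negative values and
#' non-monotone times are parse errors naming the offending row.
#'
#' @param path CSV file path (format as written by
#'   [write_timeseries_csv()]).
#' @return named list, one entry per condition: `condition_id`, `condition`
#'   (a [batch_condition()]; doses taken as the standard 1 g/250 mL per
#'   system), and `series`, a list per replicate of named
#'   biomass/crvi/glucose [time_series()].
#' @export
read_timeseries_csv <- function(path) {
  if (!file.exists(path)) {
    stop_kin(sprintf("file not found: %s", path), "parse_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  missing_cols <- setdiff(csv_columns, names(df))
  if (length(missing_cols)) {
    stop_kin(sprintf("missing column(s): %s", paste(missing_cols, collapse = ", ")),
             "parse_error")
  }
  # Row numbers reported to the user count the header line.
  row_no <- seq_len(nrow(df)) + 1L
  bad <- which(!is.finite(df$value) | df$value < 0)
  if (length(bad)) {
    stop_kin(sprintf("negative or non-numeric value at row %d", row_no[bad[1]]),
             "parse_error")
  }
  bad <- which(!df$quantity %in% c("biomass", "crvi", "glucose"))
  if (length(bad)) {
    stop_kin(sprintf("unknown quantity '%s' at row %d",
                     df$quantity[bad[1]], row_no[bad[1]]), "parse_error")
  }
  key <- paste(df$condition_id, df$replicate, df$quantity, df$time_h)
  if (anyDuplicated(key)) {
    stop_kin(sprintf("duplicate (condition, replicate, quantity, time) key at row %d",
                     row_no[which(duplicated(key))[1]]), "parse_error")
  }
  out <- list()
  for (cid in unique(df$condition_id)) {
    sub <- df[df$condition_id == cid, ]
    system <- unique(sub$system); cr0 <- unique(sub$cr0_mg_per_L)
    if (length(system) != 1L || length(cr0) != 1L) {
      stop_kin(sprintf("condition '%s' has inconsistent system/cr0 metadata", cid),
               "parse_error")
    }
    cond <- batch_condition(cr0, system = system,
                            hcif_dose = if (system == "binary") 0 else 1)
    series <- list()
    for (rep_id in unique(sub$replicate)) {
      rsub <- sub[sub$replicate == rep_id, ]
      qlist <- list()
      for (q in unique(rsub$quantity)) {
        qsub <- rsub[rsub$quantity == q, ]
        ord <- order(qsub$time_h)
        if (any(diff(qsub$time_h[ord]) <= 0)) {
          stop_kin(sprintf(
            "non-monotone times for condition '%s' replicate '%s' quantity '%s'",
            cid, rep_id, q), "parse_error")
        }
        qlist[[q]] <- time_series(qsub$time_h[ord], qsub$value[ord], q, rep_id)
      }
      series[[rep_id]] <- qlist
    }
    out[[cid]] <- list(condition_id = cid, condition = cond, series = series)
  }
  out
}

#' Percentage of Cr(VI) reduced at the end of a time course
#'
#' `100 * (cr0 - final) / cr0`, clipped to \[0, 100\]; a final value at or
#' below the detection limit counts as complete (100%) reduction.
#'
#' @param series a Cr(VI) [time_series()].
#' @param cr0 initial Cr(VI), mg/L (> 0).
#' @param detection_limit mg/L (default 0.05).
#' @return percentage in \[0, 100\].
#' @export
reduction_percent <- function(series, cr0, detection_limit = 0.05) {
  if (!inherits(series, "time_series") || length(series$values) == 0L) {
    stop_kin("`series` must be a non-empty time_series", "insufficient_data_error")
  }
  check_number(cr0, "cr0", lower = 0, allow_zero = FALSE)
  final <- utils::tail(series$values, 1)
  if (final <= detection_limit) return(100)
  min(max(100 * (cr0 - final) / cr0, 0), 100)
}

# Replicate-mean series for one quantity (requires a shared time grid).
replicate_mean_series <- function(series_by_rep, quantity) {
  reps <- Filter(Negate(is.null), lapply(series_by_rep, `[[`, quantity))
  reps <- Filter(function(ts) ts$replicate_id != "truth", reps)
  if (!length(reps)) return(NULL)
  times <- reps[[1]]$times
  if (!all(vapply(reps, function(ts) identical(ts$times, times), logical(1)))) {
    stop_kin(sprintf("replicates of '%s' are on different time grids", quantity),
             "domain_error")
  }
  vals <- rowMeans(do.call(cbind, lapply(reps, `[[`, "values")))
  time_series(times, vals, quantity, "mean")
}

summarize_haldane_fit <- function(fit) {
  list(status = "ok", mu_max = fit$params$mu_max, K_S = fit$params$K_S,
       K_I = fit$params$K_I, r_squared = fit$r_squared,
       residual_norm = fit$residual_norm, converged = fit$converged,
       n_starts_used = fit$n_starts_used)
}

stage_skipped <- function(reason) list(status = "skipped", reason = reason)

# Log-spaced substrate grids spanning each single-substrate growth peak.
haldane_recovery_grid <- function(substrate) {
  switch(substrate,
         crvi = exp(seq(log(1), log(500), length.out = 10)),
         glucose = exp(seq(log(0.05), log(20), length.out = 10)),
         hcif = exp(seq(log(0.5), log(200), length.out = 10)))
}

# 3x3x3 factorial design spanning all three substrates.
tertiary_recovery_design <- function() {
  expand.grid(S_C = c(200, 1000, 4000), S_P = c(5, 25, 100),
              S_h = c(500, 2000, 4000))
}

analyze_condition <- function(cid, cond, series_by_rep, detection_limit,
                              min_window = 3, detection_floor = 0.01) {
  mu_reps <- list()
  for (rep_id in names(series_by_rep)) {
    if (rep_id == "truth") next
    bio <- series_by_rep[[rep_id]]$biomass
    if (is.null(bio)) next
    est <- tryCatch(estimate_mu(bio, min_window, detection_floor),
                    crkinetics_error = function(e) NULL)
    if (!is.null(est)) {
      mu_reps[[rep_id]] <- list(replicate = rep_id, mu = est$mu,
                                window_start = est$window_start,
                                window_end = est$window_end,
                                r_squared = est$r_squared,
                                n_points = est$n_points)
    }
  }
  mus <- vapply(mu_reps, `[[`, numeric(1), "mu")
  mu_summary <- if (length(mus)) {
    list(status = "ok", mean = mean(mus),
         sd = if (length(mus) > 1) stats::sd(mus) else NA_real_,
         n = length(mus), replicates = unname(mu_reps))
  } else stage_skipped("no usable biomass replicate")
  crvi <- replicate_mean_series(series_by_rep, "crvi")
  if (is.null(crvi)) {
    rate1 <- rate2 <- stage_skipped("no Cr(VI) series")
    red <- NULL
  } else {
    fit1 <- tryCatch(fit_rate_constant(crvi, "first", detection_limit),
                     crkinetics_error = function(e) NULL)
    fit2 <- tryCatch(fit_rate_constant(crvi, "second", detection_limit),
                     crkinetics_error = function(e) NULL)
    as_stage <- function(f) {
      if (is.null(f)) return(stage_skipped("insufficient data above detection limit"))
      list(status = "ok", k = f$k, r_squared = max(f$r_squared, 0),
           C0_used = f$C0_used, n_points = f$n_points)
    }
    rate1 <- as_stage(fit1); rate2 <- as_stage(fit2)
    red <- reduction_percent(crvi, cond$cr0, detection_limit)
  }
  list(condition_id = cid, system = cond$system, cr0 = cond$cr0,
       mu = mu_summary, rate_first = rate1, rate_second = rate2,
       reduction_percent = red)
}

#' Run the full kinetic analysis
#'
#' Binds all stages end-to-end: obtain per-condition time courses (from a
#' CSV file or by simulating a preset at every study Cr(VI) level),
#' estimate the specific growth rate per replicate, fit first- and
#' second-order rate constants per condition, fit the three
#' single-substrate Haldane models, fit the tertiary Monod interaction
#' constants with frozen base parameters, and assemble a report.
#'
#' For preset input the Haldane and tertiary stages run as parameter-
#' recovery experiments: rate-vs-substrate datasets are generated from the
#' reference constants ([single_substrate_reference()], and the preset's
#' tertiary parameters) and refitted. For CSV input the Haldane Cr(VI)
#' stage uses the per-condition (cr0, mean mu) pairs when at least four
#' distinct Cr(VI) levels are present; the glucose/HCIF and tertiary stages
#' need dose-varied designs a single batch file does not contain and are
#' marked skipped.
#'
#' @param input path to a CSV in the [read_timeseries_csv()] format, or a
#'   preset name accepted by [simulation_preset()].
#' @param seed integer seed governing every stochastic stage (required).
#' @param noise_cv measurement-noise CV for synthetic stages (default 0.05).
#' @param n_starts multi-start count for the nonlinear fits (default 20).
#' @param form_variant tertiary-law variant (default `"symmetric"`).
#' @param detection_limit Cr(VI) detection limit, mg/L (default 0.05).
#' @param out_dir if non-NULL, directory (created if needed) receiving
#'   `report.json`, `rate_fits.csv` and `interaction_products.csv`.
#' @return an `analysis_report` list (schema_version, provenance,
#'   conditions, haldane, tertiary).
#' @export
run_analysis <- function(input, seed, noise_cv = 0.05, n_starts = 20,
                         form_variant = c("symmetric", "as_printed"),
                         detection_limit = 0.05, out_dir = NULL) {
  form_variant <- match.arg(form_variant)
  if (missing(seed)) stop_kin("`seed` is required", "domain_error")
  presets <- c("set1_binary", "set2_tertiary", "first_order")
  is_preset <- is.character(input) && length(input) == 1L && input %in% presets
  ref <- single_substrate_reference()
  tertiary_truth <- NULL

  if (is_preset) {
    cr_levels <- c(10, 25, 40, 50, 100)
    conditions <- list()
    sims <- list()
    for (i in seq_along(cr_levels)) {
      ps <- simulation_preset(input, cr0 = cr_levels[i], noise_cv = noise_cv,
                              seed = derive_seed(seed, i))
      sim <- simulate_batch(ps$condition, ps$config)
      cid <- sprintf("%s_cr%g", ps$condition$system, ps$condition$cr0)
      sims[[cid]] <- sim
      conditions[[cid]] <- list(condition = ps$condition,
                                series = stats::setNames(
                                  sim$replicates,
                                  paste0("r", seq_along(sim$replicates))))
    }
    input_label <- input
    input_md5 <- NA_character_
    if (input == "set2_tertiary") {
      tertiary_truth <- simulation_preset(input, seed = 1)$calibrated$growth_params
    }
  } else {
    parsed <- read_timeseries_csv(input)
    conditions <- lapply(parsed, function(e) list(condition = e$condition,
                                                  series = e$series))
    names(conditions) <- names(parsed)
    input_label <- input
    input_md5 <- unname(tools::md5sum(input))
  }

  cond_results <- lapply(names(conditions), function(cid) {
    analyze_condition(cid, conditions[[cid]]$condition,
                      conditions[[cid]]$series, detection_limit)
  })
  names(cond_results) <- names(conditions)

  # Single-substrate Haldane stages.
  haldane <- list()
  if (is_preset) {
    for (i in seq_len(nrow(ref))) {
      sub <- ref$substrate[i]
      truth <- haldane_params(ref$mu_max[i], ref$K_S[i], ref$K_I[i])
      dat <- generate_mu_dataset(truth, haldane_recovery_grid(sub),
                                 noise_cv = noise_cv,
                                 seed = derive_seed(seed, 10 + i))
      fit <- fit_haldane(dat, n_starts = n_starts,
                         seed = derive_seed(seed, 20 + i))
      haldane[[sub]] <- c(summarize_haldane_fit(fit),
                          list(generating = list(mu_max = ref$mu_max[i],
                                                 K_S = ref$K_S[i],
                                                 K_I = ref$K_I[i])))
    }
  } else {
    mus <- vapply(cond_results, function(cr) {
      if (identical(cr$mu$status, "ok")) cr$mu$mean else NA_real_
    }, numeric(1))
    cr0s <- vapply(cond_results, `[[`, numeric(1), "cr0")
    ok <- is.finite(mus)
    if (length(unique(cr0s[ok])) >= 4L) {
      fit <- fit_haldane(data.frame(S = cr0s[ok], mu = mus[ok]),
                         n_starts = n_starts, seed = derive_seed(seed, 21))
      haldane$crvi <- summarize_haldane_fit(fit)
    } else {
      haldane$crvi <- stage_skipped("fewer than 4 distinct Cr(VI) levels with usable mu")
    }
    haldane$glucose <- stage_skipped("no glucose dose variation in input")
    haldane$hcif <- stage_skipped("no HCIF dose variation in input")
  }

  # Tertiary Monod interaction-constant stage.
  if (!is.null(tertiary_truth)) {
    design <- tertiary_recovery_design()
    dat <- generate_mu_dataset(tertiary_truth, design, noise_cv = noise_cv,
                               seed = derive_seed(seed, 30))
    base <- list(base_C = tertiary_truth$base_C, base_P = tertiary_truth$base_P,
                 base_h = tertiary_truth$base_h)
    fit <- fit_tertiary(dat, base, form_variant = form_variant,
                        n_starts = n_starts, seed = derive_seed(seed, 31))
    p <- fit$params
    prod_tab <- lapply(c(10, 25, 40, 50, 100), function(cr0) {
      st <- substrate_state(S_C = 4000, S_P = cr0, S_h = 4000)
      as.list(interaction_products(p, st))
    })
    names(prod_tab) <- paste0("cr", c(10, 25, 40, 50, 100))
    tertiary <- list(
      status = "ok", form_variant = form_variant,
      constants = list(K2_C = p$K2_C, K3_C = p$K3_C, K4_C = p$K4_C,
                       K2_P = p$K2_P, K3_P = p$K3_P, K4_P = p$K4_P,
                       K2_h = p$K2_h, K3_h = p$K3_h, K4_h = p$K4_h),
      base_params = list(base_C = p$base_C, base_P = p$base_P,
                         base_h = p$base_h),
      r_squared = fit$r_squared, residual_norm = fit$residual_norm,
      converged = fit$converged, n_starts_used = fit$n_starts_used,
      identifiability_warnings = fit$identifiability_warnings,
      products = prod_tab)
  } else {
    tertiary <- stage_skipped(
      if (is_preset) "preset has no tertiary growth model"
      else "no multi-substrate mu design in input")
  }

  report <- structure(list(
    schema_version = 1L,
    provenance = list(input = input_label, input_md5 = input_md5,
                      seed = as.integer(seed), noise_cv = noise_cv,
                      n_starts = as.integer(n_starts),
                      form_variant = form_variant,
                      detection_limit = detection_limit,
                      package_version =
                        as.character(utils::packageVersion("crkinetics"))),
    conditions = unname(cond_results),
    haldane = haldane,
    tertiary = tertiary), class = "analysis_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Serialize the report: one JSON file plus flat CSVs mirroring the
# rate-constant and interaction-product table layouts.
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  rate_rows <- lapply(report$conditions, function(cr) {
    data.frame(condition_id = cr$condition_id, system = cr$system,
               cr0 = cr$cr0,
               k1 = if (identical(cr$rate_first$status, "ok")) cr$rate_first$k else NA,
               r2_1 = if (identical(cr$rate_first$status, "ok")) cr$rate_first$r_squared else NA,
               k2 = if (identical(cr$rate_second$status, "ok")) cr$rate_second$k else NA,
               r2_2 = if (identical(cr$rate_second$status, "ok")) cr$rate_second$r_squared else NA,
               reduction_percent = if (is.null(cr$reduction_percent)) NA else cr$reduction_percent)
  })
  utils::write.csv(do.call(rbind, rate_rows),
                   file.path(out_dir, "rate_fits.csv"), row.names = FALSE)
  if (identical(report$tertiary$status, "ok")) {
    tab <- data.frame(product = names(report$tertiary$products[[1]]))
    for (col in names(report$tertiary$products)) {
      tab[[col]] <- unlist(report$tertiary$products[[col]])
    }
    utils::write.csv(tab, file.path(out_dir, "interaction_products.csv"),
                     row.names = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("Cr(VI) cometabolism kinetic analysis report (schema",
      x$schema_version, ")\n")
  cat("  input:", x$provenance$input, " seed:", x$provenance$seed, "\n")
  cat("  conditions:\n")
  for (cr in x$conditions) {
    mu_txt <- if (identical(cr$mu$status, "ok")) {
      sprintf("mu %.4g", cr$mu$mean)
    } else "mu skipped"
    k1_txt <- if (identical(cr$rate_first$status, "ok")) {
      sprintf("k1 %.4g (R2 %.3f)", cr$rate_first$k, cr$rate_first$r_squared)
    } else "k1 skipped"
    cat(sprintf("    %-16s %s, %s, reduction %s%%\n", cr$condition_id,
                mu_txt, k1_txt,
                if (is.null(cr$reduction_percent)) "NA"
                else sprintf("%.1f", cr$reduction_percent)))
  }
  for (sub in names(x$haldane)) {
    h <- x$haldane[[sub]]
    if (identical(h$status, "ok")) {
      cat(sprintf("  Haldane %-8s mu_max %.4g, K_S %.4g, K_I %.4g (R2 %.4f)\n",
                  sub, h$mu_max, h$K_S, h$K_I, h$r_squared))
    } else {
      cat(sprintf("  Haldane %-8s skipped: %s\n", sub, h$reason))
    }
  }
  if (identical(x$tertiary$status, "ok")) {
    cat(sprintf("  tertiary Monod fit (%s): R2 %.4f, %d starts\n",
                x$tertiary$form_variant, x$tertiary$r_squared,
                x$tertiary$n_starts_used))
  } else {
    cat("  tertiary Monod fit skipped:", x$tertiary$reason, "\n")
  }
  invisible(x)
}
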