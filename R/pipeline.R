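#' End-to-end pipeline configuration
#'
#' Every tolerance, threshold and seed used by the analysis lives here --
#' no stage reads configuration from anywhere else, so two runs with equal
#' config and inputs are identical.
#'
#' @param experiment An [experiment_config()] (used by [run_simulate()]
#'   and for geometry/units defaults).
#' @param percentile_lo,percentile_hi Percentile-filter thresholds applied
#'   to temperature and salinity.
#' @param iqr_k IQR-fence multiplier applied to irradiance.
#' @param iqr_by_day Apply the irradiance fence within mesocosm-days
#'   (see [filter_iqr()]); pooled fences on a diel variable flag real
#'   midday values instead of sensor errors.
#' @param o2_units Declared O2 sensor units (`"umol_L"` or `"mg_L"`).
#' @param bins Temperature-bin definitions ([temperature_bins()]).
#' @param form Algebraic reading of the temperature-modified model
#'   (`"shifted"` or `"scaled"`, see [temp_pi()]).
#' @param robust_bins Use robust (bisquare IRLS) binned fits.
#' @param mc_n_iter,mc_sampling Monte-Carlo iterations and sampling law
#'   for accumulated-production CIs.
#' @param accumulate_treatments Treatments accumulated and compared
#'   against the control.
#' @param severity_threshold Exceedance threshold (degC).
#' @param severity_per_hour Severity definition switch, see
#'   [cumulative_severity()].
#' @param severity_bin_width Histogram bin width.
#' @param gap_max_h Longest driver gap (h) filled by interpolation.
#' @param seed Master seed for the analysis randomness (Monte Carlo).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(experiment = experiment_config(),
                            percentile_lo = 0.001, percentile_hi = 0.995,
                            iqr_k = 1.2,
                            iqr_by_day = TRUE,
                            o2_units = "umol_L",
                            bins = temperature_bins(),
                            form = "shifted",
                            robust_bins = TRUE,
                            mc_n_iter = 1000,
                            mc_sampling = "normal",
                            accumulate_treatments = c("1MH", "2MH"),
                            severity_threshold = 11,
                            severity_per_hour = FALSE,
                            severity_bin_width = 10,
                            gap_max_h = 2,
                            seed = experiment$seed) {
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Scalar fields override the defaults of [pipeline_config()]; nested
#' `experiment:` fields override [experiment_config()] defaults.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
pipeline_config_from_yaml <- function(path) {
  raw <- yaml::read_yaml(path)
  exp_args <- raw$experiment %||% list()
  raw$experiment <- NULL
  cfg_exp <- do.call(experiment_config, exp_args)
  do.call(pipeline_config, c(list(experiment = cfg_exp), raw))
}

#' Simulate a synthetic experiment and write it to disk
#'
#' @param config A [pipeline_config()].
#' @param dir Output directory.
#' @param quiet Suppress progress messages.
#' @return The generated `experiment`, invisibly.
#' @export
run_simulate <- function(config = pipeline_config(), dir, quiet = FALSE) {
  say <- if (quiet) function(...) invisible() else inform
  exp <- generate_experiment(config$experiment)
  say(sprintf("[simulate] %d mesocosms, %d days, %d incubation windows.",
              length(unique(exp$schedule$mesocosm_id)),
              config$experiment$days, nrow(exp$schedule)))
  write_experiment(exp, dir)
  say(sprintf("[simulate] wrote sensor files, schedule and manifest to %s.", dir))
  invisible(exp)
}

# Hourly per-treatment drivers (replicate means of QC'd hourly means).
treatment_drivers <- function(temp_sensors, par_sensors) {
  hm <- function(df, name) {
    df %>%
      group_by(.data$mesocosm_id, .data$treatment) %>%
      dplyr::group_modify(~ hourly_mean(.x)) %>%
      ungroup() %>%
      group_by(.data$treatment, .data$timestamp) %>%
      summarise(value = mean(.data$value, na.rm = TRUE), .groups = "drop") %>%
      mutate(value = ifelse(is.nan(.data$value), NA_real_, .data$value)) %>%
      rename(!!name := "value")
  }
  left_join(hm(temp_sensors, "temperature"), hm(par_sensors, "par"),
            by = c("treatment", "timestamp")) %>%
    arrange(.data$treatment, .data$timestamp)
}

#' Run the full analysis pipeline
#'
#' Sensor QC (percentile filter on temperature and salinity, IQR fence on
#' irradiance) -> hourly incubation rates -> temperature-binned P-I fits
#' -> temperature-modified model fit -> accumulated production with
#' Monte-Carlo CIs and treatment comparison -> heatwave severity. Every
#' stage logs sample counts in/out; failures abort with the stage name.
#'
#' @param config A [pipeline_config()].
#' @param experiment Optional in-memory `experiment` (from
#'   [generate_experiment()]); generated from `config$experiment` when
#'   neither this nor `dir` is given.
#' @param dir Optional directory holding an experiment written by
#'   [run_simulate()]/[write_experiment()].
#' @param out_dir Optional directory for the five report files
#'   (`rates.csv`, `pi_bins.csv`, `temp_model.csv`, `accumulation.csv`,
#'   `severity.csv`).
#' @param quiet Suppress progress messages.
#' @return A list of class `pipeline_result`: `rates`, `bin_fits`,
#'   `bin_table`, `temp_fit`, `temp_table`, `drivers`, `predictions`,
#'   `accumulation`, `severity`, `qc_log`, `config`.
#' @export
run_analyze <- function(config = pipeline_config(), experiment = NULL,
                        dir = NULL, out_dir = NULL, quiet = FALSE) {
  say <- if (quiet) function(...) invisible() else inform
  stage <- function(name, code) {
    tryCatch(code, error = function(e) {
      abort(sprintf("Stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  data <- stage("input", {
    if (!is.null(experiment)) {
      list(sensors = experiment$sensors, schedule = experiment$schedule)
    } else if (!is.null(dir)) {
      read_experiment(dir)
    } else {
      exp <- generate_experiment(config$experiment)
      list(sensors = exp$sensors, schedule = exp$schedule)
    }
  })
  sensors <- data$sensors
  schedule <- data$schedule

  qc_log <- list()
  sensors <- stage("qc", {
    masked <- function(df) sum(!df$qc)
    for (v in intersect(c("temperature", "salinity"), names(sensors))) {
      before <- masked(sensors[[v]])
      sensors[[v]] <- filter_percentile(sensors[[v]], config$percentile_lo,
                                        config$percentile_hi)
      qc_log[[v]] <- c(n = nrow(sensors[[v]]),
                        masked = masked(sensors[[v]]) - before)
      say(sprintf("[qc] %s: %d samples, %d masked by percentile filter.",
                  v, nrow(sensors[[v]]), masked(sensors[[v]]) - before))
    }
    before <- masked(sensors$PAR)
    sensors$PAR <- filter_iqr(sensors$PAR, config$iqr_k,
                              by_day = config$iqr_by_day)
    qc_log[["PAR"]] <- c(n = nrow(sensors$PAR),
                          masked = masked(sensors$PAR) - before)
    say(sprintf("[qc] PAR: %d samples, %d masked by IQR fence.",
                nrow(sensors$PAR), masked(sensors$PAR) - before))
    sensors
  })

  rates <- stage("rates", {
    r <- extract_rates(sensors, schedule, geom = config$experiment$geometry,
                       units = config$o2_units)
    say(sprintf("[rates] %d hourly rates from %d windows (%d skipped hours).",
                nrow(r), nrow(schedule),
                nrow(schedule) * config$experiment$incubation_duration_h - nrow(r)))
    r
  })
  light <- filter(rates, .data$mode == "light")

  bin_fits <- stage("fit-bins", {
    f <- fit_pi_bins(light, bins = config$bins, robust = config$robust_bins)
    say(sprintf("[fit-bins] fitted %d of %d bins (%s).",
                length(f), nrow(config$bins),
                paste(names(f), collapse = ", ")))
    f
  })
  bin_table <- bind_rows(lapply(names(bin_fits), function(nm) {
    mutate(tidy(bin_fits[[nm]]), bin = nm, n = bin_fits[[nm]]$n,
           rmse = bin_fits[[nm]]$rmse, .before = 1)
  }))

  temp_fit <- stage("fit-temp-model", {
    f <- fit_temp_pi(light, form = config$form, bins = config$bins)
    say(sprintf("[fit-temp-model] n = %d, rmse = %.2f, F = %.1f.",
                f$n, f$rmse, f$f.statistic))
    f
  })

  drivers <- stage("drivers", {
    d <- treatment_drivers(sensors$temperature, sensors$PAR)
    say(sprintf("[drivers] %d treatment-hours assembled.", nrow(d)))
    d
  })

  acc <- stage("accumulate", {
    trts <- c("control", setdiff(config$accumulate_treatments, "control"))
    res <- purrr::map(trts, function(tr) {
      dr <- filter(drivers, .data$treatment == tr)
      pred <- predict_ncp(temp_fit, dr, gap_max_h = config$gap_max_h)
      ci <- mc_accumulated_ci(pred, n_iter = config$mc_n_iter,
                              seed = derive_seed(config$seed, paste0("mc-", tr)),
                              sampling = config$mc_sampling)
      list(pred = mutate(pred, treatment = tr),
           ci = mutate(ci, treatment = tr, .before = 1))
    })
    tab <- compare_treatments(bind_rows(purrr::map(res, "ci")))
    say(paste0("[accumulate] ",
               paste(sprintf("%s = %.0f mmol O2 m-2", tab$treatment,
                             tab$accumulated), collapse = ", "), "."))
    list(table = tab, predictions = bind_rows(purrr::map(res, "pred")))
  })

  sev <- stage("severity", {
    trts <- setdiff(config$accumulate_treatments, "control")
    s <- lapply(setNames(trts, trts), function(tr) {
      dr <- filter(drivers, .data$treatment == tr)
      severity_summary(select(dr, "timestamp", "temperature"),
                       threshold = config$severity_threshold,
                       per_hour = config$severity_per_hour,
                       bin_width = config$severity_bin_width)
    })
    say(paste0("[severity] hours above ",
               config$severity_threshold, " degC: ",
               paste(sprintf("%s = %d", names(s),
                             vapply(s, `[[`, 0L, "hours_above")),
                     collapse = ", "), "."))
    s
  })

  result <- structure(list(
    rates = rates, bin_fits = bin_fits, bin_table = bin_table,
    temp_fit = temp_fit, temp_table = tidy(temp_fit),
    drivers = drivers, predictions = acc$predictions,
    accumulation = acc$table, severity = sev,
    qc_log = qc_log, config = config
  ), class = "pipeline_result")

  if (!is.null(out_dir)) {
    stage("report", write_reports(result, out_dir))
    say(sprintf("[report] wrote 5 report files to %s.", out_dir))
  }
  result
}

write_reports <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(result$rates, file.path(out_dir, "rates.csv"))
  readr::write_csv(result$bin_table, file.path(out_dir, "pi_bins.csv"))
  tm <- mutate(result$temp_table, n = result$temp_fit$n,
               rmse = result$temp_fit$rmse,
               f_statistic = result$temp_fit$f.statistic)
  readr::write_csv(tm, file.path(out_dir, "temp_model.csv"))
  readr::write_csv(result$accumulation, file.path(out_dir, "accumulation.csv"))
  sev <- bind_rows(lapply(names(result$severity), function(tr) {
    s <- result$severity[[tr]]
    mutate(s$histogram, treatment = tr, threshold = s$threshold,
           hours_above = s$hours_above, .before = 1)
  }))
  readr::write_csv(sev, file.path(out_dir, "severity.csv"))
  invisible(out_dir)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("<pipeline_result>\n")
  cat(sprintf("  rates: %d (light %d, dark %d)\n", nrow(x$rates),
              sum(x$rates$mode == "light"), sum(x$rates$mode == "dark")))
  cat(sprintf("  binned fits: %s\n", paste(names(x$bin_fits), collapse = ", ")))
  cat(sprintf("  temp model: rmse %.2f, F %.1f\n",
              x$temp_fit$rmse, x$temp_fit$f.statistic))
  print(select(x$accumulation, dplyr::any_of(c(
    "treatment", "accumulated", "ci_low", "ci_high", "pct_decrease_int"))))
  invisible(x)
}
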