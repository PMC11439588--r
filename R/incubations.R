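#' Mesocosm geometry
#'
#' @param volume Water volume in litres (default 1000 L = 1 m3).
#' @param footprint_area Footprint area in m2 (default a 1.1 m diameter
#'   circle, ~0.95 m2).
#' @return A list of class `mesocosm_geometry`.
#' @export
mesocosm_geometry <- function(volume = 1000, footprint_area = pi * (1.1 / 2)^2) {
  if (volume <= 0 || footprint_area <= 0) {
    abort("`volume` and `footprint_area` must be > 0.")
  }
  structure(list(volume = volume, footprint_area = footprint_area),
            class = "mesocosm_geometry")
}

#' Hourly oxygen-change rate by least squares
#'
#' Ordinary least-squares slope of O2 concentration against time (in
#' hours) over the retained samples of one hour-long window, with the
#' standard slope SE and r-squared. Requires at least 3 retained samples
#' spanning at least 30 minutes.
#'
#' @param o2_segment Tibble with `timestamp` (or `time_min`), `value` (or
#'   `o2`) and optional `qc`.
#' @return Tibble with `slope` (concentration h-1), `se`, `r2`, `n`.
#' @export
hourly_rate <- function(o2_segment) {
  nm <- names(o2_segment)
  val <- o2_segment[[intersect(c("value", "o2"), nm)[1]]]
  th <- if ("timestamp" %in% nm) {
    as.numeric(o2_segment$timestamp - min(o2_segment$timestamp), units = "hours")
  } else {
    o2_segment$time_min / 60
  }
  keep <- if ("qc" %in% nm) o2_segment$qc & is.finite(val) else is.finite(val)
  th <- th[keep]; val <- val[keep]
  if (length(val) < 3L || diff(range(th)) < 0.5) {
    abort(sprintf(
      "Insufficient samples for an hourly rate: %d retained spanning %.0f min (need >= 3 over >= 30 min).",
      length(val), if (length(th) > 1) diff(range(th)) * 60 else 0))
  }
  fit <- lm(val ~ th)
  sm <- suppressWarnings(summary(fit)) # noiseless traces fit perfectly
  tibble(slope = unname(coef(fit)[2]),
         se = unname(sm$coefficients[2, 2]),
         r2 = if (sd(val) > 0) sm$r.squared else NA_real_,
         n = length(val))
}

#' Convert a volumetric rate to an areal rate
#'
#' `slope_areal = slope_volumetric * volume / 1000 / footprint_area`, i.e.
#' umol L-1 h-1 in a `volume`-litre tank, normalized to the m2 footprint,
#' gives mmol O2 m-2 h-1. Rates in mg L-1 h-1 are first converted to
#' umol L-1 h-1 with the 31.998 g mol-1 molar mass of O2. Units must be
#' declared -- they are never guessed.
#'
#' @param raw_slope Volumetric rate(s).
#' @param geom A [mesocosm_geometry()].
#' @param units `"umol_L"` or `"mg_L"` (per hour).
#' @return Areal rate (mmol O2 m-2 h-1).
#' @export
#' @examples
#' to_areal(10, mesocosm_geometry(1000, 0.95), units = "umol_L") # 10.526
to_areal <- function(raw_slope, geom = mesocosm_geometry(), units) {
  if (missing(units) || is.null(units) || is.na(units)) {
    abort("O2 units must be declared ('umol_L' or 'mg_L'); refusing to guess.")
  }
  if (!units %in% c("umol_L", "mg_L")) {
    abort(sprintf("Unknown O2 unit '%s' (expected 'umol_L' or 'mg_L').", units))
  }
  if (units == "mg_L") raw_slope <- raw_slope / 31.998 * 1000
  raw_slope * geom$volume / 1000 / geom$footprint_area
}

#' Hourly rate estimates for one incubation window
#'
#' Splits a closed-incubation window into non-overlapping hour-long
#' sub-windows anchored at the incubation start (half-open `[t, t+1h)`),
#' regresses O2 on time within each, converts the slope and SE to areal
#' units, and attaches the mean retained temperature and irradiance of the
#' same hour as context. Hours with insufficient O2 samples are skipped
#' with a message.
#'
#' @param window One-row tibble (or list) with `start`, `end`, `mode`
#'   (`"light"`/`"dark"`), and optional `mesocosm_id`, `treatment`,
#'   `replicate`.
#' @param o2,temp,par Sensor tibbles (`timestamp`, `value`, `qc`) covering
#'   the window.
#' @param geom A [mesocosm_geometry()].
#' @param units O2 units, passed to [to_areal()].
#' @return Tibble of rate estimates: one row per successful hour with
#'   `hour_index` (1-based), areal `slope` and `se`, `r2`, `n`,
#'   `mean_temp`, `mean_par`, `mode` and provenance columns.
#' @export
process_window <- function(window, o2, temp = NULL, par = NULL,
                           geom = mesocosm_geometry(), units = "umol_L") {
  start <- window$start[1]
  end <- window$end[1]
  n_h <- floor(as.numeric(end - start, units = "hours") + 1e-9)
  if (n_h < 1) abort("Incubation window must span at least 1 h.")
  ctx_mean <- function(series, w0, w1) {
    if (is.null(series)) return(NA_real_)
    sel <- series$timestamp >= w0 & series$timestamp < w1 &
      series$qc & is.finite(series$value)
    if (!any(sel)) return(NA_real_)
    mean(series$value[sel])
  }
  rows <- list()
  for (h in seq_len(n_h)) {
    w0 <- start + lubridate::dhours(h - 1)
    w1 <- start + lubridate::dhours(h)
    seg <- filter(o2, .data$timestamp >= w0, .data$timestamp < w1)
    est <- tryCatch(hourly_rate(seg), error = function(e) {
      inform(sprintf("Hour %d of window starting %s skipped: %s",
                     h, format(start), conditionMessage(e)))
      NULL
    })
    if (is.null(est)) next
    getcol <- function(nm, default) {
      if (nm %in% names(window)) window[[nm]][1] else default
    }
    rows[[length(rows) + 1L]] <- tibble(
      mesocosm_id = getcol("mesocosm_id", NA_character_),
      treatment = as.character(getcol("treatment", NA_character_)),
      replicate = getcol("replicate", NA_integer_),
      mode = as.character(getcol("mode", "light")),
      window_start = start,
      hour_index = h,
      slope = to_areal(est$slope, geom, units),
      se = to_areal(est$se, geom, units),
      r2 = est$r2,
      n = est$n,
      mean_temp = ctx_mean(temp, w0, w1),
      mean_par = ctx_mean(par, w0, w1)
    )
  }
  bind_rows(rows)
}

#' Extract all incubation rates from an experiment
#'
#' Applies [process_window()] to every row of an incubation schedule,
#' pulling each mesocosm's O2, temperature and PAR series from a sensor
#' set as produced by [generate_experiment()] (or assembled from files).
#'
#' @param sensors Named list of long sensor tibbles (`O2`, `temperature`,
#'   `PAR`), each with `mesocosm_id`, `timestamp`, `value`, `qc`.
#' @param schedule Tibble with `mesocosm_id`, `treatment`, `replicate`,
#'   `start`, `end`, `mode`.
#' @param geom A [mesocosm_geometry()].
#' @param units O2 units, passed to [to_areal()].
#' @return Tibble of rate estimates (see [process_window()]).
#' @export
extract_rates <- function(sensors, schedule, geom = mesocosm_geometry(),
                          units = "umol_L") {
  pick <- function(df, id, w0, w1) {
    filter(df, .data$mesocosm_id == id,
           .data$timestamp >= w0, .data$timestamp < w1)
  }
  out <- purrr::map(seq_len(nrow(schedule)), function(i) {
    w <- schedule[i, ]
    process_window(
      w,
      o2 = pick(sensors$O2, w$mesocosm_id, w$start, w$end),
      temp = pick(sensors$temperature, w$mesocosm_id, w$start, w$end),
      par = pick(sensors$PAR, w$mesocosm_id, w$start, w$end),
      geom = geom, units = units
    )
  })
  bind_rows(out)
}

#' Community respiration by incubation hour
#'
#' Summarises dark-incubation rates per treatment and hour index as
#' mean +/- SE (SE of the mean across estimates).
#'
#' @param dark_estimates Rate tibble (rows with `mode == "dark"` are used).
#' @return Tibble with `treatment`, `hour_index`, `mean_cr`, `se_cr`, `n`.
#' @export
cr_by_hour <- function(dark_estimates) {
  dark_estimates %>%
    filter(.data$mode == "dark") %>%
    group_by(.data$treatment, .data$hour_index) %>%
    summarise(
      mean_cr = mean(.data$slope),
      se_cr = if (n() > 1) sd(.data$slope) / sqrt(n()) else 0,
      n = n(),
      .groups = "drop"
    )
}
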