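#' Treatment scenario specification
#'
#' Parametric description of one treatment's temperature-offset profile.
#' Offsets are relative to ambient (the control). The experiment has four
#' conditions: `control` (ambient), `HT` (constant +1.8 degC warming), `1MH`
#' (one moderate, long heatwave: +2.8 degC held for 13 days) and `2MH` (two
#' short, intense heatwaves: +3.9 degC held for 5 days each, separated by
#' 3 days at the warming baseline).
#'
#' The common timeline is: 48 h acclimation at ambient, a linear ramp over
#' `ramp_days` (~0.6 degC per day) to `base_offset`, then a 48 h hold before
#' any heatwave ramping begins. Heatwave ramps are linear at
#' `peak_ramp_rate`; the plateau duration is measured at the peak value.
#' The default ramp rate is 1 degC/day for `1MH` and 2.8 degC/day for `2MH`
#' so that the double-peak scenario completes within a 23-day experiment.
#'
#' @param treatment One of `"control"`, `"HT"`, `"1MH"`, `"2MH"`.
#' @param acclimation_h Hours at ambient before the baseline ramp starts.
#' @param ramp_days Duration (days) of the linear ramp to `base_offset`.
#' @param base_offset Baseline warming offset (degC) shared by HT/1MH/2MH.
#' @param peak_offset Peak heatwave offset (degC); 0 for control/HT.
#' @param peak_duration_days Plateau duration (days) at `peak_offset`.
#' @param n_peaks Number of heatwave peaks (0, 1 or 2).
#' @param inter_peak_gap_days Days at `base_offset` between two peaks.
#' @param peak_ramp_rate Ramp rate (degC/day) between base and peak.
#' @param base_hold_h Hours held at `base_offset` before heatwave ramping.
#' @return An object of class `scenario_spec`.
#' @export
#' @examples
#' scenario_spec("1MH")
scenario_spec <- function(treatment = c("control", "HT", "1MH", "2MH"),
                          acclimation_h = 48,
                          ramp_days = 3,
                          base_offset = NULL,
                          peak_offset = NULL,
                          peak_duration_days = NULL,
                          n_peaks = NULL,
                          inter_peak_gap_days = 3,
                          peak_ramp_rate = NULL,
                          base_hold_h = 48) {
  treatment <- match.arg(treatment)
  preset <- switch(treatment,
    control = list(base = 0,   peak = 0,   dur = 0,  np = 0L, rate = 1),
    HT      = list(base = 1.8, peak = 0,   dur = 0,  np = 0L, rate = 1),
    `1MH`   = list(base = 1.8, peak = 2.8, dur = 13, np = 1L, rate = 1),
    `2MH`   = list(base = 1.8, peak = 3.9, dur = 5,  np = 2L, rate = 2.8)
  )
  spec <- structure(list(
    treatment = treatment,
    acclimation_h = acclimation_h,
    ramp_days = ramp_days,
    base_offset = base_offset %||% preset$base,
    peak_offset = peak_offset %||% preset$peak,
    peak_duration_days = peak_duration_days %||% preset$dur,
    n_peaks = as.integer(n_peaks %||% preset$np),
    inter_peak_gap_days = inter_peak_gap_days,
    peak_ramp_rate = peak_ramp_rate %||% preset$rate,
    base_hold_h = base_hold_h
  ), class = "scenario_spec")
  validate_scenario_spec(spec)
}

validate_scenario_spec <- function(spec) {
  with(spec, {
    if (base_offset < 0 || peak_offset < 0) {
      abort("Offsets must be >= 0.")
    }
    if (acclimation_h < 0 || ramp_days <= 0 || peak_ramp_rate <= 0) {
      abort("Durations and ramp rates must be positive.")
    }
    if (treatment == "control" && (base_offset != 0 || peak_offset != 0)) {
      abort("The control scenario must have all offsets equal to 0.")
    }
    if (treatment == "2MH" && n_peaks != 2L) {
      abort("The 2MH scenario must have exactly 2 peaks.")
    }
    if (n_peaks > 0L) {
      if (peak_offset <= base_offset) {
        abort("`peak_offset` must exceed `base_offset` for heatwave scenarios.")
      }
      if (peak_duration_days <= 0) abort("`peak_duration_days` must be > 0.")
      if (n_peaks > 1L && inter_peak_gap_days <= 0) {
        abort("`inter_peak_gap_days` must be > 0.")
      }
    }
  })
  spec
}

#' @export
print.scenario_spec <- function(x, ...) {
  cat(sprintf("<scenario_spec: %s> base +%.1f degC", x$treatment, x$base_offset))
  if (x$n_peaks > 0) {
    cat(sprintf(", %d peak(s) of +%.1f degC for %g d (ramp %g degC/d)",
                x$n_peaks, x$peak_offset, x$peak_duration_days,
                x$peak_ramp_rate))
  }
  cat("\n")
  invisible(x)
}

# Piecewise-linear node set (hours from start, offset degC) for a scenario.
offset_nodes <- function(spec) {
  t <- c(0, spec$acclimation_h)
  v <- c(0, 0)
  t <- c(t, spec$acclimation_h + spec$ramp_days * 24)
  v <- c(v, spec$base_offset)
  if (spec$n_peaks > 0L && spec$peak_offset > spec$base_offset) {
    ramp_h <- (spec$peak_offset - spec$base_offset) / spec$peak_ramp_rate * 24
    cur <- t[length(t)] + spec$base_hold_h
    t <- c(t, cur); v <- c(v, spec$base_offset)
    for (k in seq_len(spec$n_peaks)) {
      cur <- cur + ramp_h
      t <- c(t, cur); v <- c(v, spec$peak_offset)
      cur <- cur + spec$peak_duration_days * 24
      t <- c(t, cur); v <- c(v, spec$peak_offset)
      cur <- cur + ramp_h
      t <- c(t, cur); v <- c(v, spec$base_offset)
      if (k < spec$n_peaks) {
        cur <- cur + spec$inter_peak_gap_days * 24
        t <- c(t, cur); v <- c(v, spec$base_offset)
      }
    }
  }
  list(t = t, v = v)
}

#' Temperature-offset profile for a scenario
#'
#' Evaluates the continuous piecewise-linear offset profile of a treatment
#' on an hourly timeline: zero during acclimation, a linear ramp to the
#' warming baseline, and (for heatwave scenarios) linear ramps to/from each
#' peak plateau. After the last programmed node the offset stays at
#' `base_offset`.
#'
#' @param spec A [scenario_spec()].
#' @param timeline Hourly POSIXct timeline (interval-start convention).
#' @return Tibble with columns `timestamp` and `offset` (degC).
#' @export
#' @examples
#' tl <- hourly_timeline(days = 23)
#' range(offset_profile(scenario_spec("HT"), tl)$offset)
offset_profile <- function(spec, timeline) {
  stopifnot(inherits(spec, "scenario_spec"))
  check_hourly(timeline)
  nodes <- offset_nodes(spec)
  h <- as.numeric(timeline - timeline[1], units = "hours")
  required_h <- nodes$t[length(nodes$t)]
  # the final sample's interval [t, t+1h) must reach the last node
  if (max(h) + 1 < required_h) {
    abort(sprintf(
      "Timeline too short for scenario '%s': %g h provided, %g h (%.1f days) required.",
      spec$treatment, max(h) + 1, required_h, required_h / 24))
  }
  off <- approx(nodes$t, nodes$v, xout = h, rule = 2)$y
  tibble(timestamp = timeline, offset = off)
}

#' Ambient (control) temperature model
#'
#' A transparent stand-in for the in-situ seawater temperature feeding the
#' mesocosms: linear seasonal trend + sinusoidal diel cycle (peaking at
#' 15:00 UTC, zero at 09:00 when incubations start) + AR(1) noise. Defaults
#' place the 23-day median inside the 8.5-11.4 degC band observed at the
#' source sites in early Arctic summer.
#'
#' @param mean_temp Temperature (degC) at the experiment start, 09:00 phase.
#' @param seasonal_trend Linear warming trend, degC per day.
#' @param diel_amplitude Amplitude (degC) of the diel sinusoid.
#' @param noise_sd Marginal standard deviation of the AR(1) component.
#' @param ar1_coef AR(1) autocorrelation, in `[0, 1)`.
#' @param seed Optional integer seed for reproducibility.
#' @return An object of class `ambient_model`.
#' @export
ambient_model <- function(mean_temp = 7.9, seasonal_trend = 0.065,
                          diel_amplitude = 0.25, noise_sd = 0.10,
                          ar1_coef = 0.8, seed = NULL) {
  if (ar1_coef < 0 || ar1_coef >= 1) {
    abort("`ar1_coef` must lie in [0, 1).")
  }
  if (noise_sd < 0 || diel_amplitude < 0) abort("Noise terms must be >= 0.")
  structure(list(mean_temp = mean_temp, seasonal_trend = seasonal_trend,
                 diel_amplitude = diel_amplitude, noise_sd = noise_sd,
                 ar1_coef = ar1_coef, seed = seed),
            class = "ambient_model")
}

# Stationary AR(1) with marginal sd `sd` and autocorrelation `phi`.
ar1_noise <- function(n, sd, phi) {
  if (sd == 0 || n == 0L) return(numeric(n))
  e <- rnorm(n, 0, sd * sqrt(1 - phi^2))
  init <- rnorm(1, 0, sd)
  as.numeric(stats::filter(e, phi, method = "recursive", init = init))
}

with_opt_seed <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

#' Generate an ambient temperature series
#'
#' @param model An [ambient_model()].
#' @param timeline Hourly POSIXct timeline.
#' @return Tibble with columns `timestamp` and `temperature` (degC).
#' @export
ambient_series <- function(model, timeline) {
  stopifnot(inherits(model, "ambient_model"))
  check_hourly(timeline)
  days <- as.numeric(timeline - timeline[1], units = "days")
  hod <- lubridate::hour(timeline) + lubridate::minute(timeline) / 60
  diel <- model$diel_amplitude * sin(2 * pi * (hod - 9) / 24)
  noise <- with_opt_seed(model$seed,
                         ar1_noise(length(timeline), model$noise_sd,
                                   model$ar1_coef))
  tibble(timestamp = timeline,
         temperature = model$mean_temp + model$seasonal_trend * days +
           diel + noise)
}

#' Irradiance (PAR) model
#'
#' Generates hourly photosynthetically available radiation under a
#' midnight-sun regime. Each day receives a target daily integral inside
#' `daily_integral_range`; under the default `weather = "synoptic"` the
#' targets follow a synoptic-scale pattern -- overcast conditions at the
#' range floor with one clear spell (a Gaussian hump of width
#' `spell_width_days` centred on `spell_center_day`) reaching the range
#' ceiling -- plus AR(1) day-to-day noise, clamped to the range.
#' `weather = "ar1"` instead draws smoothly-correlated targets spanning
#' the whole range. Within a day the target is distributed as a raised
#' half-sinusoid peaking at 15:00 with a small positive night floor,
#' optionally modulated hour-to-hour by lognormal AR(1) cloud flicker;
#' hourly values are rescaled so the realized daily integral
#' (`sum * 3600 / 1e6`, mol photons m-2 d-1) matches the target exactly.
#'
#' @param daily_integral_range Range (mol photons m-2 d-1) of daily
#'   integrals; the degenerate range `c(x, x)` yields exactly `x` each day.
#' @param photoperiod_h Photoperiod in hours (24 = midnight sun).
#' @param replicate_sd Between-replicate SD (mol photons m-2 d-1) of daily
#'   integrals, applied when replicate series are generated.
#' @param night_floor Night value as a fraction of the diel peak.
#' @param weather `"synoptic"` (clear spells amid overcast) or `"ar1"`.
#' @param spell_center_day Centre of the main clear spell, days from start.
#' @param spell_width_days Gaussian width (days) of the main clear spell.
#' @param spell2_center_day,spell2_width_days,spell2_amplitude A second,
#'   briefer and weaker clear interlude (amplitude as a fraction of the
#'   range span; 0 disables it), by default early in the experiment.
#' @param day_noise_sd AR(1) day-to-day noise SD (mol photons m-2 d-1) on
#'   the synoptic targets.
#' @param day_ar1 AR(1) coefficient of the day-to-day weather state.
#' @param flicker_log_sd Log-scale SD of hourly cloud modulation (0 = no
#'   flicker).
#' @param flicker_ar1 AR(1) coefficient of the hourly cloud modulation.
#' @param shading_log_sd Log-scale SD of per-mesocosm hourly shading
#'   modulation: under the midnight sun the solar azimuth sweeps the full
#'   circle daily, so neighbouring mesocosms and structures cast rotating
#'   shadows that differ between tanks (0 = none).
#' @param seed Optional integer seed.
#' @return An object of class `par_model`.
#' @export
par_model <- function(daily_integral_range = c(14, 65), photoperiod_h = 24,
                      replicate_sd = 2, night_floor = 0.05,
                      weather = c("synoptic", "ar1"),
                      spell_center_day = 16, spell_width_days = 2.75,
                      spell2_center_day = 2, spell2_width_days = 1.5,
                      spell2_amplitude = 0.55,
                      day_noise_sd = 0.8, day_ar1 = 0.6,
                      flicker_log_sd = 0.5, flicker_ar1 = 0.3,
                      shading_log_sd = 0.3,
                      seed = NULL) {
  weather <- match.arg(weather)
  r <- daily_integral_range
  if (length(r) != 2L || any(!is.finite(r)) || any(r < 0) || r[2] < r[1]) {
    abort("`daily_integral_range` must be nonnegative bounds c(lo, hi) with lo <= hi.")
  }
  if (photoperiod_h <= 0 || photoperiod_h > 24) {
    abort("`photoperiod_h` must be in (0, 24].")
  }
  if (replicate_sd < 0 || day_noise_sd < 0 || flicker_log_sd < 0) {
    abort("Noise SDs must be >= 0.")
  }
  structure(list(daily_integral_range = r, photoperiod_h = photoperiod_h,
                 replicate_sd = replicate_sd, night_floor = night_floor,
                 weather = weather, spell_center_day = spell_center_day,
                 spell_width_days = spell_width_days,
                 spell2_center_day = spell2_center_day,
                 spell2_width_days = spell2_width_days,
                 spell2_amplitude = spell2_amplitude,
                 day_noise_sd = day_noise_sd, day_ar1 = day_ar1,
                 flicker_log_sd = flicker_log_sd, flicker_ar1 = flicker_ar1,
                 shading_log_sd = shading_log_sd,
                 seed = seed),
            class = "par_model")
}

#' Daily PAR integral
#'
#' Converts hourly PAR values (mmol photons m-2 h-1, logger numerics) to a
#' daily integral in mol photons m-2 d-1 using the logger convention
#' `sum(values) * 3600 / 1e6`.
#'
#' @param values Hourly PAR values for one day.
#' @return Daily integral (mol photons m-2 d-1).
#' @export
par_daily_integral <- function(values) {
  sum(values) * 3600 / 1e6
}

# Diel weight profile for the hours-of-day of one day.
par_diel_weights <- function(hod, photoperiod_h, night_floor) {
  w <- 0.5 * (1 - cos(2 * pi * (hod - 3) / 24)) # peak at 15:00, min at 03:00
  w <- night_floor + (1 - night_floor) * w
  if (photoperiod_h < 24) {
    lit <- abs(((hod - 15 + 12) %% 24) - 12) <= photoperiod_h / 2
    w[!lit] <- 0
  }
  w
}

# Daily-integral targets inside the configured range.
par_daily_targets <- function(n_days, model) {
  r <- model$daily_integral_range
  if (r[1] == r[2]) return(rep(r[1], n_days))
  mid <- seq_len(n_days) - 0.5
  raw <- if (model$weather == "synoptic") {
    hump <- exp(-((mid - model$spell_center_day) / model$spell_width_days)^2)
    if (model$spell2_amplitude > 0) {
      hump2 <- model$spell2_amplitude *
        exp(-((mid - model$spell2_center_day) / model$spell2_width_days)^2)
      hump <- pmax(hump, hump2)
    }
    r[1] + (r[2] - r[1]) * hump +
      ar1_noise(n_days, model$day_noise_sd, model$day_ar1)
  } else {
    z <- ar1_noise(n_days, 1, model$day_ar1)
    r[1] + pnorm(z) * (r[2] - r[1])
  }
  pmin(pmax(raw, r[1]), r[2])
}

# Hourly lognormal cloud-modulation factors for a timeline.
par_flicker <- function(n, model) {
  if (model$flicker_log_sd == 0) return(rep(1, n))
  exp(ar1_noise(n, model$flicker_log_sd, model$flicker_ar1))
}

#' Generate an hourly PAR series
#'
#' @param model A [par_model()].
#' @param timeline Hourly POSIXct timeline.
#' @param daily_targets Optional explicit daily integrals (mol photons
#'   m-2 d-1), one per day; drawn from the model when `NULL`.
#' @param flicker Optional hourly cloud-modulation factors (same length
#'   as `timeline`), e.g. shared across replicate mesocosms; drawn from
#'   the model when `NULL`.
#' @return Tibble with columns `timestamp` and `par`
#'   (mmol photons m-2 h-1).
#' @export
par_series <- function(model, timeline, daily_targets = NULL,
                       flicker = NULL) {
  stopifnot(inherits(model, "par_model"))
  check_hourly(timeline)
  day <- as.integer(floor(as.numeric(timeline - lubridate::floor_date(timeline[1], "day"),
                                     units = "days")))
  day <- day - min(day)
  n_days <- max(day) + 1L
  draw <- with_opt_seed(model$seed, list(
    targets = daily_targets %||% par_daily_targets(n_days, model),
    flicker = flicker %||% par_flicker(length(timeline), model)
  ))
  targets <- draw$targets
  if (length(targets) != n_days) {
    abort(sprintf("Need %d daily targets, got %d.", n_days, length(targets)))
  }
  hod <- lubridate::hour(timeline) + lubridate::minute(timeline) / 60
  w <- par_diel_weights(hod, model$photoperiod_h, model$night_floor) *
    draw$flicker
  par <- numeric(length(timeline))
  for (d in seq_len(n_days) - 1L) {
    idx <- which(day == d)
    tot <- sum(w[idx]) * 3600 / 1e6
    par[idx] <- if (tot > 0) w[idx] * targets[d + 1L] / tot else 0
  }
  tibble(timestamp = timeline, par = par)
}

#' Ground-truth production parameters for simulation
#'
#' Parameters of the production model used to generate synthetic incubation
#' oxygen traces. Three forms are available:
#'
#' * `"empirical"` (default): per-temperature P-I coefficients with a
#'   built-in negative temperature effect -- the tanh curve [pi_tanh()] is
#'   evaluated with `Pmax` following a logistic decline across a threshold
#'   temperature (`pmax_t50`, width `pmax_tw`), `alpha` an exponential
#'   decay (`alpha_decay` per degC) and `CR` a linear deepening
#'   (`cr_slope` per degC), all anchored at their `ref_temp` values
#'   `Pmax`/`alpha`/`Rd`. This emulates a community whose binned P-I
#'   coefficients genuinely decline with warming; the aggregate
#'   temperature-modified model then plays its real-world role of an
#'   approximating fit.
#' * `"temp_modified"`: the [temp_pi()] model itself as nature.
#' * `"binned_tanh"`: a single temperature-independent [pi_tanh()] curve.
#'
#' @param Pmax Maximum production rate (mmol O2 m-2 h-1) at `ref_temp`,
#'   > 0.
#' @param alpha Initial slope (mmol O2 m-2 h-1 per mmol photons m-2 h-1)
#'   at `ref_temp`, > 0.
#' @param Rd Respiration intercept (mmol O2 m-2 h-1) at `ref_temp`
#'   (negative = consuming).
#' @param model_form `"empirical"`, `"temp_modified"` or `"binned_tanh"`.
#' @param pmax_t50 Temperature (degC) of half-decline of `Pmax`.
#' @param pmax_tw Logistic width (degC) of the `Pmax` decline.
#' @param pmax_floor Fraction of the cool-end `Pmax` retained above the
#'   decline (heat-stressed but persisting baseline production).
#' @param alpha_decay Exponential decay rate of `alpha` per degC warming.
#' @param cr_slope Linear deepening of respiration per degC warming.
#' @param ref_temp Reference temperature (degC) anchoring the coefficients.
#' @param o2_noise_sd Additive Gaussian noise SD of simulated O2 samples
#'   (umol L-1).
#' @param form Algebraic reading used when `model_form = "temp_modified"`,
#'   see [temp_pi()].
#' @return An object of class `truth_params`.
#' @export
truth_params <- function(Pmax = 22, alpha = 0.06, Rd = -5,
                         model_form = c("empirical", "temp_modified",
                                        "binned_tanh"),
                         pmax_t50 = 11, pmax_tw = 0.35, pmax_floor = 0.45,
                         alpha_decay = 0.2, cr_slope = 0.02, ref_temp = 8,
                         o2_noise_sd = 2.5, form = "shifted") {
  model_form <- match.arg(model_form)
  if (Pmax <= 0 || alpha <= 0) abort("`Pmax` and `alpha` must be > 0.")
  if (o2_noise_sd < 0) abort("`o2_noise_sd` must be >= 0.")
  structure(list(Pmax = Pmax, alpha = alpha, Rd = Rd,
                 model_form = model_form,
                 pmax_t50 = pmax_t50, pmax_tw = pmax_tw,
                 pmax_floor = pmax_floor,
                 alpha_decay = alpha_decay, cr_slope = cr_slope,
                 ref_temp = ref_temp,
                 o2_noise_sd = o2_noise_sd, form = form),
            class = "truth_params")
}

#' Per-temperature coefficients of the empirical ground truth
#'
#' @param truth A [truth_params()] with `model_form = "empirical"`.
#' @param temp Temperature(s), degC.
#' @return Tibble with `temp`, `Pmax`, `alpha`, `CR`.
#' @export
truth_coefficients <- function(truth, temp) {
  stopifnot(inherits(truth, "truth_params"))
  dT <- temp - truth$ref_temp
  decline <- function(x) {
    truth$pmax_floor + (1 - truth$pmax_floor) /
      (1 + exp((x - truth$pmax_t50) / truth$pmax_tw))
  }
  tibble(
    temp = temp,
    Pmax = truth$Pmax * decline(temp) / decline(truth$ref_temp),
    alpha = truth$alpha * exp(-truth$alpha_decay * dT),
    CR = truth$Rd - truth$cr_slope * dT
  )
}

#' Evaluate the ground-truth NCP model
#'
#' @param truth A [truth_params()].
#' @param I PAR (mmol photons m-2 h-1).
#' @param temp Temperature (degC); ignored for `model_form = "binned_tanh"`.
#' @return NCP (mmol O2 m-2 h-1).
#' @export
ncp_truth <- function(truth, I, temp) {
  stopifnot(inherits(truth, "truth_params"))
  switch(truth$model_form,
    binned_tanh = pi_tanh(I, truth$Pmax, truth$alpha, truth$Rd),
    temp_modified = temp_pi(I, temp, truth$Pmax, truth$alpha, truth$Rd,
                            form = truth$form),
    empirical = {
      n <- max(length(I), length(temp))
      cf <- truth_coefficients(truth, rep_len(temp, n))
      cf$Pmax * tanh(cf$alpha * rep_len(I, n) / cf$Pmax) + cf$CR
    }
  )
}

#' Simulate a closed-incubation oxygen trace
#'
#' Generates the O2 concentration series a sensor would record during a
#' closed incubation: the areal production rate implied by the ground
#' truth at each hour's irradiance/temperature is converted to a
#' volumetric concentration slope (`rate * area / volume * 1000`,
#' umol L-1 h-1), integrated piecewise-linearly, and additive Gaussian
#' sensor noise is applied.
#'
#' @param truth A [truth_params()].
#' @param temp Temperature (degC), scalar or one value per hour.
#' @param par PAR (mmol photons m-2 h-1), scalar or one value per hour.
#' @param duration_h Incubation duration in whole hours (>= 1).
#' @param dt_min Sampling interval in minutes; must divide 60.
#' @param volume Mesocosm volume (L), > 0.
#' @param area Mesocosm footprint area (m2), > 0.
#' @param o2_init Initial O2 concentration (umol L-1).
#' @param seed Optional integer seed.
#' @param start Optional POSIXct start time; adds a `timestamp` column.
#' @return Tibble with `time_min`, `o2` (umol L-1) and `qc`; the noiseless
#'   hourly areal rates are attached as attribute `"true_rates"`.
#' @export
simulate_incubation <- function(truth, temp, par, duration_h = 3,
                                dt_min = 1, volume = 1000,
                                area = pi * (1.1 / 2)^2,
                                o2_init = 300, seed = NULL, start = NULL) {
  stopifnot(inherits(truth, "truth_params"))
  if (duration_h < 1) abort("`duration_h` must be >= 1.")
  if (60 %% dt_min != 0) abort("`dt_min` must divide 60.")
  if (volume <= 0 || area <= 0) abort("`volume` and `area` must be > 0.")
  temp <- rep_len(temp, duration_h)
  par <- rep_len(par, duration_h)
  rates <- ncp_truth(truth, par, temp)                 # mmol O2 m-2 h-1
  slopes <- rates * area / volume * 1000               # umol L-1 h-1
  tmin <- seq(0, duration_h * 60 - dt_min, by = dt_min)
  hr <- pmin(tmin %/% 60, duration_h - 1L)
  frac <- tmin / 60 - hr
  cum <- c(0, cumsum(slopes))[hr + 1L]
  o2 <- o2_init + cum + slopes[hr + 1L] * frac
  noise <- with_opt_seed(seed, rnorm(length(o2), 0, truth$o2_noise_sd))
  out <- tibble(time_min = tmin, o2 = o2 + noise, qc = TRUE)
  if (!is.null(start)) {
    out <- mutate(out, timestamp = start + lubridate::dminutes(.data$time_min),
                  .before = 1)
  }
  attr(out, "true_rates") <- rates
  out
}
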