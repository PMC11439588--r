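#' Experiment configuration for the scenario generator
#'
#' Bundles every parameter of the synthetic 23-day mesocosm experiment:
#' four treatments (control, HT, 1MH, 2MH) in triplicate (12 mesocosms),
#' a shared ambient temperature and sky, per-treatment offset profiles,
#' and the closed-incubation schedule (weekly light incubations for
#' control/HT; 1MH/2MH incubated additionally at heatwave peaks and on
#' remission; two all-mesocosm dark incubations).
#'
#' @param start Experiment start date (UTC midnight).
#' @param days Experiment duration in days.
#' @param replicates Replicate mesocosms per treatment.
#' @param geometry A [mesocosm_geometry()].
#' @param ambient An [ambient_model()] (its `seed` is overridden by the
#'   master-seed splitting scheme).
#' @param par A [par_model()].
#' @param truth A [truth_params()] ground truth for O2 traces.
#' @param light_days Named list (per treatment) of experiment-day indices
#'   on which light incubations start.
#' @param dark_days Day indices of the all-mesocosm dark incubations.
#' @param incubation_hour Local start hour of incubations (mid-morning).
#' @param incubation_duration_h Incubation length in hours.
#' @param placement_factors Named multiplicative light-exposure factor per
#'   treatment, emulating the systematic irradiance differences caused by
#'   mesocosm placement across the outdoor array (rows shade each other
#'   unequally); applied to the daily-integral targets before clamping to
#'   the configured range.
#' @param replicate_temp_sd,replicate_temp_ar1 Marginal SD (degC) and
#'   AR(1) coefficient of per-mesocosm temperature deviations.
#' @param sensor_temp_noise_sd 1-min temperature sensor noise SD (degC).
#' @param o2_baseline Flow-through baseline O2 concentration (umol L-1).
#' @param salinity_mean,salinity_sd Salinity level and slow-variation SD.
#' @param par_cadence_min PAR logger cadence (minutes).
#' @param seed Master seed; all component streams derive from it.
#' @return A list of class `experiment_config`.
#' @export
experiment_config <- function(start = "2022-06-30",
                              days = 23,
                              replicates = 3,
                              geometry = mesocosm_geometry(),
                              ambient = ambient_model(),
                              par = par_model(),
                              truth = truth_params(),
                              light_days = list(
                                control = c(2, 9, 16, 22),
                                HT = c(2, 9, 16, 22),
                                `1MH` = c(2, 9, 16, 17, 19, 22),
                                `2MH` = c(2, 5, 9, 12, 15, 18, 21, 22)
                              ),
                              dark_days = c(1, 10),
                              incubation_hour = 9,
                              incubation_duration_h = 3,
                              placement_factors = c(control = 1, HT = 1,
                                                    `1MH` = 0.9, `2MH` = 1),
                              replicate_temp_sd = 0.08,
                              replicate_temp_ar1 = 0.8,
                              sensor_temp_noise_sd = 0.02,
                              o2_baseline = 310,
                              salinity_mean = 34,
                              salinity_sd = 0.02,
                              par_cadence_min = 10,
                              seed = 42) {
  structure(as.list(environment()), class = "experiment_config")
}

exp_treatments <- c("control", "HT", "1MH", "2MH")

#' Generate a full synthetic mesocosm experiment
#'
#' Produces per-mesocosm sensor series (O2, temperature and salinity at
#' 1-min cadence; PAR at the logger cadence), the incubation schedule, the
#' clean hourly drivers, and the ground-truth manifest, all reproducible
#' from one master seed. Temperature is shared ambient + treatment offset
#' + small per-mesocosm AR(1) deviations; irradiance is a shared sky with
#' per-mesocosm daily-integral deviations (`replicate_sd`, clamped to the
#' configured range); O2 follows the flow-through baseline except inside
#' incubation windows, where the closed-tank drift implied by the ground
#' truth is overlaid (irradiance set to zero during dark incubations).
#'
#' @param config An [experiment_config()].
#' @param seed Master seed (defaults to the config's).
#' @return A list of class `experiment` with elements `sensors` (named
#'   list of long tibbles: `O2`, `temperature`, `salinity`, `PAR`),
#'   `schedule`, `hourly` (clean hourly drivers per mesocosm), `ambient`,
#'   `truth`, `config`, `seed`.
#' @export
generate_experiment <- function(config = experiment_config(),
                                seed = config$seed) {
  cfg <- config
  tl <- hourly_timeline(cfg$start, cfg$days)
  start0 <- tl[1]
  n_h <- length(tl)
  h_num <- as.numeric(tl)

  ambient <- cfg$ambient
  ambient$seed <- NULL
  amb <- with_opt_seed(derive_seed(seed, "ambient"),
                       ambient_series(ambient, tl))

  specs <- lapply(setNames(exp_treatments, exp_treatments), scenario_spec)
  offsets <- lapply(specs, function(s) offset_profile(s, tl)$offset)

  # shared sky: one daily-integral target sequence and one hourly cloud
  # pattern for all mesocosms
  parm <- cfg$par
  parm$seed <- NULL
  targets <- with_opt_seed(derive_seed(seed, "par-targets"),
                           par_daily_targets(cfg$days, parm))
  flicker <- with_opt_seed(derive_seed(seed, "par-flicker"),
                           par_flicker(n_h, parm))

  meso <- tidyr::expand_grid(treatment = exp_treatments,
                             replicate = seq_len(cfg$replicates)) %>%
    mutate(mesocosm_id = paste(.data$treatment, .data$replicate, sep = "-"))

  # incubation schedule
  sched_l <- purrr::imap(cfg$light_days, function(days_i, tr) {
    tibble(treatment = tr, day = days_i, mode = "light")
  })
  sched <- bind_rows(
    bind_rows(sched_l),
    tibble(treatment = rep(exp_treatments, each = length(cfg$dark_days)),
           day = rep(cfg$dark_days, times = length(exp_treatments)),
           mode = "dark")
  ) %>%
    left_join(meso, by = "treatment", relationship = "many-to-many") %>%
    mutate(start = start0 + lubridate::ddays(.data$day) +
             lubridate::dhours(cfg$incubation_hour),
           end = .data$start + lubridate::dhours(cfg$incubation_duration_h)) %>%
    select("mesocosm_id", "treatment", "replicate", "start", "end", "mode") %>%
    arrange(.data$start, .data$mesocosm_id)

  # minute-level grids
  min_tl <- start0 + lubridate::dminutes(seq_len(cfg$days * 1440) - 1)
  m_num <- as.numeric(min_tl)
  par_tl <- start0 + lubridate::dminutes(
    (seq_len(cfg$days * 1440 / cfg$par_cadence_min) - 1) * cfg$par_cadence_min)
  p_num <- as.numeric(par_tl)

  truth0 <- cfg$truth
  truth0$o2_noise_sd <- 0

  sens_o2 <- list(); sens_t <- list(); sens_s <- list(); sens_p <- list()
  hourly <- list()

  for (i in seq_len(nrow(meso))) {
    id <- meso$mesocosm_id[i]
    tr <- meso$treatment[i]
    rep_i <- meso$replicate[i]
    wins <- filter(sched, .data$mesocosm_id == id)

    # hourly drivers
    dev <- with_opt_seed(derive_seed(seed, paste0("temp-", id)),
                         ar1_noise(n_h, cfg$replicate_temp_sd,
                                   cfg$replicate_temp_ar1))
    temp_h <- amb$temperature + offsets[[tr]] + dev
    placement <- cfg$placement_factors[[tr]] %||% 1
    tgt_i <- with_opt_seed(
      derive_seed(seed, paste0("par-", id)),
      pmin(pmax(targets * placement + rnorm(cfg$days, 0, parm$replicate_sd),
                parm$daily_integral_range[1]), parm$daily_integral_range[2]))
    # local rotating-shadow modulation on top of the shared sky
    shade <- if (parm$shading_log_sd > 0) {
      with_opt_seed(derive_seed(seed, paste0("shade-", id)),
                    exp(ar1_noise(n_h, parm$shading_log_sd, parm$flicker_ar1)))
    } else rep(1, n_h)
    par_h <- par_series(parm, tl, daily_targets = tgt_i,
                        flicker = flicker * shade)$par
    # lights out during dark incubations (black plastic cover)
    for (j in which(wins$mode == "dark")) {
      par_h[tl >= wins$start[j] & tl < wins$end[j]] <- 0
    }

    hourly[[i]] <- tibble(mesocosm_id = id, treatment = tr,
                          replicate = rep_i, timestamp = tl,
                          temperature = temp_h, par = par_h)

    # 1-min temperature: interpolated drivers + sensor noise
    t_min <- approx(h_num, temp_h, xout = m_num, rule = 2)$y +
      with_opt_seed(derive_seed(seed, paste0("tnoise-", id)),
                    rnorm(length(m_num), 0, cfg$sensor_temp_noise_sd))
    # salinity: slow wander + sensor noise
    s_min <- cfg$salinity_mean +
      with_opt_seed(derive_seed(seed, paste0("sal-", id)),
                    ar1_noise(length(m_num), cfg$salinity_sd, 0.99) +
                      rnorm(length(m_num), 0, cfg$salinity_sd / 2))
    # O2: slow baseline wander; closed-tank drift inside incubations
    o2_clean <- cfg$o2_baseline +
      with_opt_seed(derive_seed(seed, paste0("o2base-", id)),
                    ar1_noise(length(m_num), 2, 0.999))
    for (j in seq_len(nrow(wins))) {
      idx <- which(min_tl >= wins$start[j] & min_tl < wins$end[j])
      hsel <- which(tl >= wins$start[j] & tl < wins$end[j])
      trace <- simulate_incubation(
        truth0,
        temp = temp_h[hsel],
        par = if (wins$mode[j] == "dark") 0 else par_h[hsel],
        duration_h = length(hsel), dt_min = 1,
        volume = cfg$geometry$volume, area = cfg$geometry$footprint_area,
        o2_init = o2_clean[idx[1]]
      )
      o2_clean[idx] <- trace$o2
    }
    o2_min <- o2_clean +
      with_opt_seed(derive_seed(seed, paste0("o2noise-", id)),
                    rnorm(length(m_num), 0, cfg$truth$o2_noise_sd))
    # PAR logger samples
    p_vals <- approx(h_num, par_h, xout = p_num, rule = 2)$y
    p_vals <- pmax(p_vals + with_opt_seed(derive_seed(seed, paste0("pnoise-", id)),
                                          rnorm(length(p_num), 0, 0.5)), 0)

    meta <- function(ts, v) tibble(mesocosm_id = id, treatment = tr,
                                   replicate = rep_i, timestamp = ts,
                                   value = v, qc = TRUE)
    sens_o2[[i]] <- meta(min_tl, o2_min)
    sens_t[[i]] <- meta(min_tl, t_min)
    sens_s[[i]] <- meta(min_tl, s_min)
    sens_p[[i]] <- meta(par_tl, p_vals)
  }

  structure(list(
    sensors = list(O2 = bind_rows(sens_o2), temperature = bind_rows(sens_t),
                   salinity = bind_rows(sens_s), PAR = bind_rows(sens_p)),
    schedule = sched,
    hourly = bind_rows(hourly),
    ambient = amb,
    truth = cfg$truth,
    config = cfg,
    seed = seed
  ), class = "experiment")
}

#' @export
print.experiment <- function(x, ...) {
  cat(sprintf("<experiment> %d mesocosms, %d days, %d incubation windows, seed %s\n",
              length(unique(x$schedule$mesocosm_id)), x$config$days,
              nrow(x$schedule), format(x$seed)))
  invisible(x)
}

#' Write a synthetic experiment to disk
#'
#' One delimited file per mesocosm-variable pair under `dir/sensors/`,
#' plus `schedule.csv` and a `manifest.yaml` holding the ground truth and
#' every derived seed. Output is byte-identical across runs with the same
#' config and seed.
#'
#' @param exp An `experiment` from [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @param dialect A [sensor_dialect()].
#' @return `dir`, invisibly.
#' @export
write_experiment <- function(exp, dir, dialect = sensor_dialect()) {
  sens_dir <- file.path(dir, "sensors")
  dir.create(sens_dir, recursive = TRUE, showWarnings = FALSE)
  for (var in names(exp$sensors)) {
    df <- exp$sensors[[var]]
    for (id in unique(df$mesocosm_id)) {
      sub <- filter(df, .data$mesocosm_id == id)
      write_sensor_series(sub, file.path(sens_dir, paste0(id, "_", var, ".csv")),
                          dialect)
    }
  }
  sched <- mutate(exp$schedule,
                  start = format(.data$start, dialect$time_format, tz = dialect$tz),
                  end = format(.data$end, dialect$time_format, tz = dialect$tz))
  readr::write_csv(sched, file.path(dir, "schedule.csv"))
  truth <- exp$truth
  manifest <- list(
    seed = exp$seed,
    truth = list(Pmax = truth$Pmax, alpha = truth$alpha, Rd = truth$Rd,
                 model_form = truth$model_form, o2_noise_sd = truth$o2_noise_sd,
                 form = truth$form),
    geometry = list(volume = exp$config$geometry$volume,
                    footprint_area = exp$config$geometry$footprint_area),
    start = format(exp$sensors$O2$timestamp[1], dialect$time_format, tz = dialect$tz),
    days = exp$config$days,
    component_seeds = derived_seed_table(exp)
  )
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(dir)
}

derived_seed_table <- function(exp) {
  ids <- unique(exp$schedule$mesocosm_id)
  seeds <- c(
    ambient = derive_seed(exp$seed, "ambient"),
    `par-targets` = derive_seed(exp$seed, "par-targets"),
    setNames(lapply(ids, function(id) derive_seed(exp$seed, paste0("temp-", id))),
             paste0("temp-", ids))
  )
  lapply(as.list(seeds), as.integer)
}

#' Read a synthetic experiment back from disk
#'
#' Counterpart of [write_experiment()]: reassembles the sensor set and
#' schedule from the per-mesocosm files.
#'
#' @param dir Directory written by [write_experiment()].
#' @param dialect A [sensor_dialect()].
#' @return List with `sensors`, `schedule` and `manifest`.
#' @export
read_experiment <- function(dir, dialect = sensor_dialect()) {
  sens_dir <- file.path(dir, "sensors")
  files <- list.files(sens_dir, pattern = "\\.csv$", full.names = TRUE)
  if (length(files) == 0L) abort(sprintf("No sensor files under %s.", sens_dir))
  parse_id <- function(f) {
    base <- sub("\\.csv$", "", basename(f))
    parts <- strsplit(base, "_", fixed = TRUE)[[1]]
    list(id = parts[1], variable = parts[2])
  }
  sensors <- list()
  for (f in files) {
    p <- parse_id(f)
    s <- read_sensor_series(f, dialect, variable = p$variable)
    trt <- strsplit(p$id, "-", fixed = TRUE)[[1]]
    s <- mutate(s, mesocosm_id = p$id, treatment = trt[1],
                replicate = as.integer(trt[2]), .before = 1)
    sensors[[p$variable]] <- bind_rows(sensors[[p$variable]], s)
  }
  sched <- readr::read_csv(file.path(dir, "schedule.csv"),
                           show_col_types = FALSE) %>%
    mutate(start = as.POSIXct(.data$start, format = dialect$time_format,
                              tz = dialect$tz),
           end = as.POSIXct(.data$end, format = dialect$time_format,
                            tz = dialect$tz))
  manifest_path <- file.path(dir, "manifest.yaml")
  manifest <- if (file.exists(manifest_path)) yaml::read_yaml(manifest_path) else NULL
  list(sensors = sensors, schedule = sched, manifest = manifest)
}
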