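tl23 <- hourly_timeline(days = 23)

test_that("offset profiles reproduce the programmed treatment structure", {
  ctrl <- offset_profile(scenario_spec("control"), tl23)$offset
  expect_true(all(ctrl == 0))

  ht <- offset_profile(scenario_spec("HT"), tl23)$offset
  expect_identical(max(ht), 1.8)
  expect_identical(ht[length(ht)], 1.8)

  one <- offset_profile(scenario_spec("1MH"), tl23)$offset
  expect_identical(max(one), 2.8)
  r1 <- rle(one)
  peak1 <- r1$lengths[r1$values == 2.8]
  # 13-day plateau, hourly sampling includes both endpoints
  expect_length(peak1, 1L)
  expect_true(peak1 %in% c(13 * 24, 13 * 24 + 1))

  two <- offset_profile(scenario_spec("2MH"), tl23)$offset
  r2 <- rle(two)
  peaks <- r2$lengths[r2$values == 3.9]
  expect_length(peaks, 2L)
  expect_true(all(peaks %in% c(5 * 24, 5 * 24 + 1)))
  # the run at base offset between the two peaks is the 3-day gap
  base_runs <- which(r2$values == 1.8)
  p_idx <- which(r2$values == 3.9)
  between <- base_runs[base_runs > p_idx[1] & base_runs < p_idx[2]]
  expect_length(between, 1L)
  expect_true(r2$lengths[between] %in% c(3 * 24 - 1, 3 * 24, 3 * 24 + 1))
})

test_that("offset profiles are continuous piecewise-linear with bounded slope", {
  for (tr in c("control", "HT", "1MH", "2MH")) {
    spec <- scenario_spec(tr)
    off <- offset_profile(spec, tl23)$offset
    max_rate_h <- max(spec$base_offset / (spec$ramp_days * 24),
                      spec$peak_ramp_rate / 24)
    expect_true(all(abs(diff(off)) <= max_rate_h + 1e-9))
    expect_identical(max(off),
                     if (spec$n_peaks > 0) spec$peak_offset else spec$base_offset)
    expect_true(all(off >= 0))
  }
})

test_that("warming time above an intermediate threshold favours the long heatwave", {
  # threshold between base (1.8) and either peak: mirrors the exceedance
  # ordering of the two heatwave designs
  one <- offset_profile(scenario_spec("1MH"), tl23)$offset
  two <- offset_profile(scenario_spec("2MH"), tl23)$offset
  expect_gt(sum(one > 2.3), sum(two > 2.3))
})

test_that("a too-short timeline is rejected with the required length", {
  expect_error(offset_profile(scenario_spec("2MH"), hourly_timeline(days = 10)),
               "required")
  expect_error(offset_profile(scenario_spec("2MH"), hourly_timeline(days = 10)),
               "552")
})

test_that("scenario specs are validated", {
  expect_error(scenario_spec("1MH", base_offset = -1), "Offsets")
  expect_error(scenario_spec("2MH", n_peaks = 1), "exactly 2")
  expect_error(scenario_spec("control", base_offset = 0.5), "control")
  expect_error(scenario_spec("1MH", peak_offset = 1), "exceed")
})

test_that("ambient series honours degenerate and seeded configurations", {
  m0 <- ambient_model(mean_temp = 9, seasonal_trend = 0, diel_amplitude = 0,
                      noise_sd = 0)
  a0 <- ambient_series(m0, tl23)
  expect_true(all(a0$temperature == 9))

  m1 <- ambient_model(seed = 11)
  expect_identical(ambient_series(m1, tl23), ambient_series(m1, tl23))

  expect_error(ambient_model(ar1_coef = 1), "\\[0, 1\\)")
  expect_error(ambient_model(ar1_coef = -0.1), "\\[0, 1\\)")
})

test_that("default ambient medians fall in the observed summer band", {
  for (s in c(42, 1, 7)) {
    a <- ambient_series(ambient_model(seed = s), tl23)
    expect_gt(median(a$temperature), 8.5)
    expect_lt(median(a$temperature), 11.4)
  }
})

test_that("PAR series matches daily-integral targets exactly", {
  m <- par_model(daily_integral_range = c(20, 20), replicate_sd = 0, seed = 3)
  p <- par_series(m, tl23)
  ints <- tapply(p$par, as.Date(p$timestamp, tz = "UTC"),
                 function(v) sum(v) * 3600 / 1e6)
  expect_equal(as.numeric(ints), rep(20, 23), tolerance = 1e-12)
  expect_true(all(p$par >= 0))
})

test_that("default PAR daily integrals stay inside the configured range", {
  for (s in c(42, 5)) {
    p <- par_series(par_model(seed = s), tl23)
    ints <- tapply(p$par, as.Date(p$timestamp, tz = "UTC"),
                   function(v) sum(v) * 3600 / 1e6)
    expect_gte(min(ints), 14 - 1e-9)
    expect_lte(max(ints), 65 + 1e-9)
  }
})

test_that("PAR re-integration recovers the explicit targets", {
  tgts <- seq(15, 59, length.out = 23)
  p <- par_series(par_model(seed = 1), tl23, daily_targets = tgts)
  ints <- vapply(split(p$par, as.Date(p$timestamp, tz = "UTC")),
                 par_daily_integral, numeric(1))
  expect_equal(unname(ints), tgts, tolerance = 1e-12)
})

test_that("PAR model rejects invalid ranges", {
  expect_error(par_model(daily_integral_range = c(-5, 10)), "nonnegative")
  expect_error(par_model(daily_integral_range = c(30, 10)), "lo <= hi")
})

test_that("noiseless incubations invert to the generating rate exactly", {
  truth <- truth_params(model_form = "binned_tanh", Pmax = 20, alpha = 0.05,
                        Rd = -4, o2_noise_sd = 0)
  geom <- mesocosm_geometry()
  trace <- simulate_incubation(truth, temp = 9, par = 300, duration_h = 3,
                               volume = geom$volume,
                               area = geom$footprint_area)
  want <- pi_tanh(300, 20, 0.05, -4)
  for (h in 1:3) {
    seg <- trace[trace$time_min >= (h - 1) * 60 & trace$time_min < h * 60, ]
    est <- hourly_rate(dplyr::rename(seg, value = "o2"))
    got <- to_areal(est$slope, geom, units = "umol_L")
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("dark incubations with negative respiration are strictly decreasing", {
  truth <- truth_params(model_form = "binned_tanh", Pmax = 20, alpha = 0.05,
                        Rd = -5, o2_noise_sd = 0)
  trace <- simulate_incubation(truth, temp = 9, par = 0, duration_h = 3)
  expect_true(all(diff(trace$o2) < 0))
})

test_that("noisy incubation slopes are unbiased over repeated simulation", {
  truth <- truth_params(model_form = "binned_tanh", Pmax = 20, alpha = 0.05,
                        Rd = -4, o2_noise_sd = 3)
  geom <- mesocosm_geometry()
  want <- pi_tanh(250, 20, 0.05, -4)
  got <- vapply(1:200, function(s) {
    tr <- simulate_incubation(truth, temp = 9, par = 250, duration_h = 1,
                              seed = s, volume = geom$volume,
                              area = geom$footprint_area)
    to_areal(hourly_rate(dplyr::rename(tr, value = "o2"))$slope, geom,
             units = "umol_L")
  }, numeric(1))
  se_mean <- sd(got) / sqrt(length(got))
  expect_lt(abs(mean(got) - want), 2 * se_mean)
})

test_that("incubation simulation is reproducible and validates inputs", {
  truth <- truth_params()
  a <- simulate_incubation(truth, 9, 300, seed = 5)
  b <- simulate_incubation(truth, 9, 300, seed = 5)
  expect_identical(a, b)
  expect_error(simulate_incubation(truth, 9, 300, volume = 0), "> 0")
  expect_error(simulate_incubation(truth, 9, 300, dt_min = 7), "divide")
  expect_error(simulate_incubation(truth, 9, 300, duration_h = 0), ">= 1")
})

test_that("the default experiment has the design's shape", {
  exp <- default_experiment()
  ids <- unique(exp$sensors$temperature$mesocosm_id)
  expect_length(ids, 12L)
  n_min <- 23 * 24 * 60
  counts <- table(exp$sensors$temperature$mesocosm_id)
  expect_true(all(counts == n_min))
  # incubation cadence: 4/4/6/8 light events, 2 dark events, x3 replicates
  sched <- dplyr::count(exp$schedule, .data$treatment, .data$mode)
  get_n <- function(tr, md) sched$n[sched$treatment == tr & sched$mode == md]
  expect_identical(get_n("control", "light"), 12L)
  expect_identical(get_n("HT", "light"), 12L)
  expect_identical(get_n("1MH", "light"), 18L)
  expect_identical(get_n("2MH", "light"), 24L)
  expect_true(all(sched$n[sched$mode == "dark"] == 6L))
})

test_that("replicate PAR series differ while daily integrals stay tight", {
  exp <- default_experiment()
  h <- exp$hourly
  p1 <- h$par[h$mesocosm_id == "control-1"]
  p2 <- h$par[h$mesocosm_id == "control-2"]
  expect_gt(sum(p1 != p2), 0)
  ints <- h %>%
    dplyr::mutate(day = floor(as.numeric(.data$timestamp - min(.data$timestamp),
                                         units = "days"))) %>%
    dplyr::group_by(.data$treatment, .data$replicate, .data$day) %>%
    dplyr::summarise(int = sum(.data$par) * 3600 / 1e6, .groups = "drop") %>%
    dplyr::group_by(.data$treatment, .data$day) %>%
    dplyr::summarise(sd = sd(.data$int), .groups = "drop")
  expect_lte(mean(ints$sd), 2.99)
})

test_that("experiment generation is deterministic under a fixed master seed", {
  a <- generate_experiment(experiment_config(seed = 7))
  b <- generate_experiment(experiment_config(seed = 7))
  expect_identical(a$sensors, b$sensors)
  expect_identical(a$schedule, b$schedule)
  c_ <- generate_experiment(experiment_config(seed = 8))
  expect_false(identical(a$sensors$O2$value, c_$sensors$O2$value))
})

test_that("empirical ground-truth coefficients decline with warming", {
  truth <- truth_params()
  cf <- truth_coefficients(truth, c(8.3, 10.6, 12, 13.25))
  expect_true(all(diff(cf$Pmax) < 0))
  expect_true(all(diff(cf$alpha) < 0))
  expect_true(all(diff(cf$CR) < 0))
  expect_true(all(cf$Pmax > 0))
})
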