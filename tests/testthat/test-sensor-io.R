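test_that("sensor files round-trip through write and read", {
  s <- make_series(c(300.25, 301.5, 299.875))
  path <- withr::local_tempfile(fileext = ".csv")
  write_sensor_series(s, path)
  back <- read_sensor_series(path)
  expect_equal(back$value, s$value, tolerance = 1e-9)
  expect_identical(back$timestamp, s$timestamp)
  expect_true(all(back$qc))
})

test_that("blank lines are skipped with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,value",
               "2022-06-30T00:00:00Z,300",
               "",
               "2022-06-30T00:01:00Z,301"), path)
  expect_warning(s <- read_sensor_series(path), "blank")
  expect_identical(nrow(s), 2L)
})

test_that("malformed rows and non-monotonic timestamps are located", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,value",
               "2022-06-30T00:00:00Z,300",
               "not-a-time,301"), path)
  expect_error(read_sensor_series(path), "line")

  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,value",
               "2022-06-30T00:01:00Z,300",
               "2022-06-30T00:00:00Z,301"), path2)
  expect_error(read_sensor_series(path2), "increasing")

  path3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,value", "2022-06-30T00:00:00Z"), path3)
  expect_error(read_sensor_series(path3), "2 fields")
})

test_that("percentile filter matches the sort-based oracle", {
  s <- make_series(as.numeric(1:1000))
  f <- filter_percentile(s, 0.001, 0.995)
  qlo <- quantile7(s$value, 0.001)
  qhi <- quantile7(s$value, 0.995)
  oracle_masked <- sum(s$value < qlo | s$value > qhi)
  expect_identical(sum(!f$qc), oracle_masked)
  expect_identical(f$value, s$value) # values never altered

  # identity and degenerate cases
  expect_identical(filter_percentile(s, 0, 1)$qc, s$qc)
  const <- make_series(rep(5, 50))
  expect_true(all(filter_percentile(const, 0.001, 0.995)$qc))
  dead <- make_series(1:10, qc = FALSE)
  expect_error(filter_percentile(dead, 0.001, 0.995), "degenerate")
  expect_error(filter_percentile(s, 0.5, 0.4), "lo < hi")
})

test_that("IQR filter fences match a hand-computed oracle", {
  s <- make_series(c(1, 2, 3, 4, 100))
  f <- filter_iqr(s, k = 1.2)
  # type-7 quartiles of 1,2,3,4,100: Q1 = 2, Q3 = 4, fence [-0.4, 6.4]
  expect_identical(which(!f$qc), 5L)

  sym <- make_series(c(10, 11, 12, 13, 14))
  expect_true(all(filter_iqr(sym, 1.2)$qc))
  expect_error(filter_iqr(make_series(c(1, 2, 3)), 1.2), "at least 4")
  expect_error(filter_iqr(s, k = 0), "> 0")
})

test_that("both filters agree with brute-force fences on random series", {
  for (i in 1:30) {
    set.seed(400 + i)
    v <- rnorm(200, sd = exp(rnorm(1)))
    if (i %% 3 == 0) v <- c(v, rnorm(5, mean = 50)) # occasional gross values
    s <- make_series(v)

    f1 <- filter_percentile(s, 0.001, 0.995)
    qs <- c(quantile7(v, 0.001), quantile7(v, 0.995))
    expect_identical(sum(!f1$qc), sum(v < qs[1] | v > qs[2]))

    f2 <- filter_iqr(s, 1.2)
    q14 <- c(quantile7(v, 0.25), quantile7(v, 0.75))
    iqr <- q14[2] - q14[1]
    expect_identical(sum(!f2$qc),
                     sum(v < q14[1] - 1.2 * iqr | v > q14[2] + 1.2 * iqr))
  }
})

test_that("filters are idempotent and preserve series length", {
  for (i in 1:10) {
    set.seed(900 + i)
    s <- make_series(rt(300, df = 3))
    once <- filter_percentile(s, 0.001, 0.995)
    expect_identical(filter_percentile(once, 0.001, 0.995), once)
    once2 <- filter_iqr(s, 1.2)
    expect_identical(filter_iqr(once2, 1.2), once2)
    expect_identical(nrow(once), nrow(s))
  }
})

test_that("per-day IQR fencing passes clean diel data and catches spikes", {
  tl <- hourly_timeline(days = 3)
  p <- par_series(par_model(daily_integral_range = c(30, 30),
                            flicker_log_sd = 0, seed = 1), tl)
  s <- tibble::tibble(timestamp = p$timestamp, value = p$par, qc = TRUE)
  clean <- filter_iqr(s, 1.2, by_day = TRUE)
  expect_true(all(clean$qc))
  s$value[30] <- s$value[30] * 20 # logger glitch
  spiked <- filter_iqr(s, 1.2, by_day = TRUE)
  expect_false(spiked$qc[30])
})

test_that("offset calibration shifts values and records itself", {
  s <- make_series(c(1, 2, 3))
  up <- apply_offset(s, 0.5)
  expect_equal(up$value, s$value + 0.5)
  expect_equal(apply_offset(up, -0.5)$value, s$value)
  expect_equal(mean(up$value), mean(s$value) + 0.5)
  expect_identical(apply_offset(s, 0)$value, s$value)
  expect_equal(attr(up, "calibration"), 0.5)
})

test_that("replicate fill takes the per-timestamp donor mean with provenance", {
  broken <- make_series(rep(0, 6))
  d1 <- make_series(c(10, 10, 10, 10, 10, 10))
  d2 <- make_series(c(20, 20, 20, 20, 20, 20))
  from <- broken$timestamp[4]
  filled <- fill_replicate(broken, d1, d2, from)
  expect_equal(filled$value, c(0, 0, 0, 15, 15, 15))
  expect_identical(filled$filled, c(rep(FALSE, 3), rep(TRUE, 3)))

  same <- fill_replicate(broken, d1, d1, from)
  expect_equal(same$value[4:6], d1$value[4:6])

  short <- d1[1:4, ]
  expect_error(fill_replicate(broken, short, d2, from), "missing")
})

test_that("close donors imply a fill close to either donor", {
  set.seed(12)
  base <- 100 + cumsum(rnorm(48, 0, 0.2))
  d1 <- make_series(base)
  d2 <- make_series(base + runif(48, -1.9, 1.9)) # |difference| < 2
  broken <- make_series(rep(NA_real_, 48))
  filled <- fill_replicate(broken, d1, d2, d1$timestamp[1])
  expect_true(all(abs(filled$value - d1$value) < 1))
  expect_true(all(abs(filled$value - d2$value) < 1))
})

test_that("hourly means average retained samples per hour window", {
  s <- make_series(as.numeric(1:60))
  hm <- hourly_mean(s)
  expect_identical(nrow(hm), 1L)
  expect_equal(hm$value, 30.5)

  const <- make_series(rep(7, 180))
  expect_true(all(hourly_mean(const)$value == 7))

  s2 <- make_series(as.numeric(1:60))
  s2$qc[1:10] <- FALSE
  expect_equal(hourly_mean(s2)$value, mean(11:60))
  expect_identical(hourly_mean(s2)$n, 50L)

  s3 <- make_series(as.numeric(1:120))
  s3$qc[61:120] <- FALSE
  hm3 <- hourly_mean(s3)
  expect_true(is.na(hm3$value[2]))
})
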