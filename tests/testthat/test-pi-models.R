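test_that("the tanh P-I curve has its analytic limits and worked values", {
  expect_identical(pi_tanh(0, 26.58, 0.551, -5.049), -5.049)
  expect_equal(pi_tanh(1e6, 26.58, 0.551, -5.049), 26.58 - 5.049,
               tolerance = 1e-9)
  # direct evaluation at the low-temperature coefficients, I = 100
  expect_equal(pi_tanh(100, 26.58, 0.551, -5.049), 20.7026936721,
               tolerance = 1e-8)
  # strictly increasing in I, bounded above by Pmax + CR
  I <- seq(0, 500, by = 5)
  v <- pi_tanh(I, 26.58, 0.551, -5.049)
  expect_true(all(diff(v) > 0))
  expect_true(all(v <= 26.58 - 5.049))
})

test_that("the temperature-modified model matches its worked values and limits", {
  expect_equal(temp_pi(1e7, 0, 22, 0.42, 1.418), 22 + 1.418, tolerance = 1e-6)
  # reference aggregate-model coefficients at I = 100, T = 8
  expect_equal(temp_pi(100, 8, 22, 0.42, 1.418), 14.2004533908,
               tolerance = 1e-8)
  # monotone nonincreasing in temperature at fixed irradiance (both readings)
  for (form in c("shifted", "scaled")) {
    for (I in c(20, 60, 120)) {
      v <- temp_pi(I, seq(0, 14, by = 0.25), 22, 0.42, 1.418, form = form)
      expect_true(all(diff(v) <= 1e-12))
    }
  }
  # warming raises the saturating irradiance under the shifted reading:
  # the irradiance reaching 90% of the asymptotic span grows with T
  i90 <- vapply(c(4, 8, 12), function(Tv) {
    f <- function(I) {
      span <- (22 - Tv) * (1 - tanh(-Tv / 22))
      temp_pi(I, Tv, 22, 0.42, 1.418) -
        (temp_pi(0, Tv, 22, 0.42, 1.418) + 0.9 * span)
    }
    uniroot(f, c(0, 1e4))$root
  }, numeric(1))
  expect_true(all(diff(i90) > 0))
})

test_that("binned fits recover generating coefficients exactly without noise", {
  y <- pi_tanh(design_I34, 26.58, 0.551, -5.049)
  for (robust in c(FALSE, TRUE)) {
    f <- fit_pi_bin(tibble::tibble(mean_par = design_I34, slope = y),
                    robust = robust)
    expect_equal(unname(coef(f)), c(26.58, 0.551, -5.049), tolerance = 1e-6)
    expect_lt(f$rmse, 1e-6)
  }
  # the 2-coefficient variant used for the extreme bin
  y2 <- pi_tanh(design_I34, 9.07, 0.091, 0)
  f2 <- fit_pi_bin(tibble::tibble(mean_par = design_I34, slope = y2),
                   include_cr = FALSE)
  expect_equal(unname(coef(f2)), c(9.07, 0.091), tolerance = 1e-6)
  expect_identical(names(coef(f2)), c("Pmax", "alpha"))
})

test_that("binned fits enforce their minimum sample sizes", {
  d <- tibble::tibble(mean_par = c(10, 50, 100, 150), slope = c(1, 5, 8, 9))
  expect_error(fit_pi_bin(d), "at least 5")
  expect_error(fit_pi_bin(d[1:2, ], include_cr = FALSE), "at least 3")
})

test_that("robust fits resist a gross outlier better than plain fits", {
  truth <- pi_tanh(design_I34, 26.58, 0.551, -5.049)
  wins <- 0L
  n_seeds <- 100L
  for (s in seq_len(n_seeds)) {
    set.seed(s)
    y <- truth + rnorm(34, 0, 1)
    y_out <- y
    y_out[7] <- y_out[7] + 25
    shift <- function(robust) {
      f1 <- coef(fit_pi_bin(tibble::tibble(mean_par = design_I34, slope = y),
                            robust = robust))
      f2 <- coef(fit_pi_bin(tibble::tibble(mean_par = design_I34, slope = y_out),
                            robust = robust))
      sum(abs(f2 - f1))
    }
    if (shift(TRUE) < shift(FALSE)) wins <- wins + 1L
  }
  expect_gte(wins, 0.95 * n_seeds)
})

test_that("compensation irradiance matches numeric root-finding", {
  y <- pi_tanh(design_I34, 26.58, 0.551, -5.049)
  f <- fit_pi_bin(tibble::tibble(mean_par = design_I34, slope = y),
                  robust = FALSE)
  ic <- compensation_irradiance(f)
  expect_equal(ic$ic, 9.276001863, tolerance = 1e-6)
  cf <- coef(f)
  root <- uniroot(function(I) pi_tanh(I, cf[["Pmax"]], cf[["alpha"]], cf[["CR"]]),
                  c(0, 200), tol = 1e-12)$root
  expect_lt(abs(ic$ic - root), 1e-9)
  # the definition: the curve is zero at Ic
  expect_lt(abs(pi_tanh(ic$ic, cf[["Pmax"]], cf[["alpha"]], cf[["CR"]])), 1e-9)
  expect_gte(ic$se, 0)
})

test_that("compensation irradiance handles degenerate respiration", {
  y0 <- pi_tanh(design_I34, 20, 0.3, 0)
  f0 <- fit_pi_bin(tibble::tibble(mean_par = design_I34, slope = y0),
                   robust = FALSE)
  ic0 <- compensation_irradiance(f0)
  expect_equal(ic0$ic, 0, tolerance = 1e-6)

  f2 <- fit_pi_bin(tibble::tibble(mean_par = design_I34,
                                  slope = pi_tanh(design_I34, 9.07, 0.091, 0)),
                   include_cr = FALSE)
  expect_message(icna <- compensation_irradiance(f2), "undefined")
  expect_true(is.na(icna$ic))
})

test_that("the aggregate temperature model recovers exact parameters", {
  set.seed(31)
  I <- runif(171, 5, 120)
  Tv <- runif(171, 7.5, 13.5)
  for (form in c("shifted", "scaled")) {
    y <- temp_pi(I, Tv, 22, 0.42, 1.418, form = form)
    f <- suppressWarnings(
      fit_temp_pi(tibble::tibble(mean_par = I, mean_temp = Tv, slope = y),
                  form = form))
    expect_equal(unname(coef(f)), c(22, 0.42, 1.418), tolerance = 1e-6)
    expect_lt(f$rmse, 1e-6)
  }
})

test_that("the aggregate fit validates inputs and flags weak respiration", {
  small <- tibble::tibble(mean_par = 1:5, mean_temp = 8:12, slope = 1:5)
  expect_error(fit_temp_pi(small), "at least 10")
  narrow <- tibble::tibble(mean_par = runif(20, 5, 120),
                           mean_temp = rep(8, 20), slope = rnorm(20, 5))
  expect_error(fit_temp_pi(narrow), "two temperature bins")

  set.seed(8)
  I <- runif(120, 5, 120)
  Tv <- runif(120, 7.5, 13.5)
  y <- temp_pi(I, Tv, 22, 0.42, 0) + rnorm(120, 0, 4)
  expect_warning(
    fit_temp_pi(tibble::tibble(mean_par = I, mean_temp = Tv, slope = y)),
    "not significant")
})

test_that("delta-method predictions behave like confidence intervals", {
  set.seed(5)
  I <- runif(80, 5, 120)
  Tv <- runif(80, 7.5, 13.5)
  y <- temp_pi(I, Tv, 22, 0.42, 1.418) + rnorm(80, 0, 2)
  f <- suppressWarnings(
    fit_temp_pi(tibble::tibble(mean_par = I, mean_temp = Tv, slope = y)))
  pr <- predict_with_ci(f, tibble::tibble(I = c(10, 50, 100), temp = c(8, 10, 12)))
  expect_true(all(pr$upr >= pr$fit & pr$fit >= pr$lwr))
  expect_true(all(pr$se >= 0))
  # zero covariance collapses the interval onto the point prediction
  f0 <- f
  f0$vcov <- f$vcov * 0
  pr0 <- predict_with_ci(f0, tibble::tibble(I = 50, temp = 10))
  expect_identical(pr0$lwr, pr0$fit)
  expect_identical(pr0$upr, pr0$fit)
  # interval half-width scales with the coefficient covariance
  f4 <- f
  f4$vcov <- f$vcov * 4
  pr4 <- predict_with_ci(f4, tibble::tibble(I = 50, temp = 10))
  pr1 <- predict_with_ci(f, tibble::tibble(I = 50, temp = 10))
  expect_equal(pr4$upr - pr4$lwr, 2 * (pr1$upr - pr1$lwr), tolerance = 1e-9)
})

test_that("prediction intervals cover the noiseless truth at design points", {
  set.seed(77)
  I <- runif(150, 5, 120)
  Tv <- runif(150, 7.5, 13.5)
  truth <- temp_pi(I, Tv, 22, 0.42, 1.418)
  y <- truth + rnorm(150, 0, 3)
  f <- suppressWarnings(
    fit_temp_pi(tibble::tibble(mean_par = I, mean_temp = Tv, slope = y)))
  pr <- predict_with_ci(f, tibble::tibble(I = I, temp = Tv))
  covered <- mean(truth >= pr$lwr & truth <= pr$upr)
  expect_gte(covered, 0.90)
})

test_that("tidy and glance summaries follow broom conventions", {
  y <- pi_tanh(design_I34, 26.58, 0.551, -5.049)
  set.seed(2)
  f <- fit_pi_bin(tibble::tibble(mean_par = design_I34,
                                 slope = y + rnorm(34, 0, 1)))
  td <- tidy(f)
  expect_identical(names(td),
                   c("term", "estimate", "std.error", "statistic", "p.value"))
  expect_identical(td$term, c("Pmax", "alpha", "CR"))
  gl <- glance(f)
  expect_identical(gl$nobs, 34L)

  res <- default_analysis()
  tt <- tidy(res$temp_fit)
  expect_identical(tt$term, c("Pmax", "alpha", "Rd"))
  gt <- glance(res$temp_fit)
  expect_true(all(c("nobs", "rmse", "statistic", "p.value") %in% names(gt)))
})

test_that("bin assignment respects half-open non-contiguous intervals", {
  rates <- tibble::tibble(mean_temp = c(7.5, 8.5, 10.1, 11.09, 11.5, 12.6,
                                        13.0, 13.49, 9.0),
                          mean_par = 1, slope = 1)
  b <- assign_bins(rates)
  expect_identical(as.character(b$bin),
                   c("low", NA, "medium", "medium", "high", NA,
                     "extreme", "extreme", NA))
})
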