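#' Hyperbolic-tangent photosynthesis-irradiance curve
#'
#' The classic saturating P-I form
#' `NCP = Pmax * tanh(alpha * I / Pmax) + CR`: at `I = 0` the curve equals
#' the community respiration intercept `CR` (negative by sign convention),
#' rises with initial slope `alpha`, and saturates at `Pmax + CR`.
#'
#' @param I PAR (mmol photons m-2 h-1).
#' @param Pmax Maximum production rate (mmol O2 m-2 h-1), > 0.
#' @param alpha Initial slope (mmol O2 m-2 h-1 per mmol photons m-2 h-1).
#' @param CR Community respiration intercept (mmol O2 m-2 h-1).
#' @return NCP (mmol O2 m-2 h-1).
#' @export
#' @examples
#' pi_tanh(100, Pmax = 26.58, alpha = 0.551, CR = -5.049) # ~20.70
pi_tanh <- function(I, Pmax, alpha, CR = 0) {
  stopifnot(Pmax > 0)
  Pmax * tanh(alpha * I / Pmax) + CR
}

# Gradient of pi_tanh wrt (Pmax, alpha, CR) at given I.
pi_tanh_grad <- function(I, Pmax, alpha, CR = 0) {
  v <- alpha * I / Pmax
  s2 <- 1 / cosh(v)^2
  cbind(Pmax = tanh(v) - v * s2, alpha = I * s2, CR = rep(1, length(I)))
}

#' Temperature-modified hyperbolic-tangent production model
#'
#' Incorporates a negative temperature effect into the tanh P-I curve.
#' Two algebraic readings are supported:
#'
#' * `form = "shifted"` (default):
#'   `NCP = (Pmax - T) * tanh((alpha * I - T) / Pmax) + Rd`.
#'   Temperature lowers both the asymptote and the tanh argument, moving
#'   light saturation to higher irradiance as temperature rises.
#' * `form = "scaled"`:
#'   `NCP = (Pmax - T) * tanh(alpha * I / (Pmax - T)) + Rd`,
#'   a temperature-scaled classic curve with unchanged initial slope.
#'
#' The shifted reading mixes units inside the tanh argument; it is kept
#' because it uniquely reproduces the observed behaviour that warming
#' raises the saturating irradiance.
#'
#' @param I PAR (mmol photons m-2 h-1).
#' @param temp Temperature (degC); `Pmax` should exceed the observed
#'   temperatures, else the `Pmax - T` factor degenerates (warned).
#' @param Pmax,alpha As in [pi_tanh()].
#' @param Rd Dark respiration term (mmol O2 m-2 h-1).
#' @param form `"shifted"` or `"scaled"`.
#' @return NCP (mmol O2 m-2 h-1).
#' @export
#' @examples
#' temp_pi(100, 8, Pmax = 22, alpha = 0.42, Rd = 1.418) # ~14.20
temp_pi <- function(I, temp, Pmax, alpha, Rd = 0,
                    form = c("shifted", "scaled")) {
  form <- match.arg(form)
  stopifnot(Pmax > 0)
  if (form == "shifted") {
    (Pmax - temp) * tanh((alpha * I - temp) / Pmax) + Rd
  } else {
    (Pmax - temp) * tanh(alpha * I / (Pmax - temp)) + Rd
  }
}

# Gradient of temp_pi wrt (Pmax, alpha, Rd).
temp_pi_grad <- function(I, temp, Pmax, alpha, Rd = 0,
                         form = c("shifted", "scaled")) {
  form <- match.arg(form)
  n <- max(length(I), length(temp))
  I <- rep_len(I, n); temp <- rep_len(temp, n)
  if (form == "shifted") {
    u <- (alpha * I - temp) / Pmax
    s2 <- 1 / cosh(u)^2
    cbind(Pmax = tanh(u) - (Pmax - temp) * s2 * u / Pmax,
          alpha = (Pmax - temp) * s2 * I / Pmax,
          Rd = rep(1, n))
  } else {
    A <- Pmax - temp
    v <- alpha * I / A
    s2 <- 1 / cosh(v)^2
    cbind(Pmax = tanh(v) - v * s2,
          alpha = I * s2,
          Rd = rep(1, n))
  }
}

#' Default temperature bins
#'
#' The four non-contiguous ~1 degC bins (0.5 degC for the extreme step)
#' used to pool incubation rates into temperature scenarios. Intervals are
#' closed on the left, open on the right; rates outside every bin are
#' excluded from binned fits.
#'
#' @return Tibble with columns `label`, `t_min`, `t_max` and `fit_cr`
#'   (whether the bin's P-I fit includes a respiration intercept; the
#'   extreme bin does not, its data being too light-saturated to constrain
#'   one).
#' @export
temperature_bins <- function() {
  tibble(
    label = factor(c("low", "medium", "high", "extreme"),
                   levels = c("low", "medium", "high", "extreme")),
    t_min = c(7.5, 10.1, 11.5, 13.0),
    t_max = c(8.5, 11.1, 12.6, 13.5),
    fit_cr = c(TRUE, TRUE, TRUE, FALSE)
  )
}

#' Assign rate estimates to temperature bins
#'
#' @param rates Tibble of rate estimates with a `mean_temp` column.
#' @param bins Bin definition as from [temperature_bins()].
#' @return `rates` with an added `bin` column (`NA` outside all bins).
#' @export
assign_bins <- function(rates, bins = temperature_bins()) {
  if (any(diff(order(bins$t_min)) < 0) ||
      any(utils::head(bins$t_max, -1) > utils::tail(bins$t_min, -1) + 1e-12)) {
    abort("Bins must be non-overlapping and ordered.")
  }
  lab <- rep(NA_character_, nrow(rates))
  for (i in seq_len(nrow(bins))) {
    inb <- rates$mean_temp >= bins$t_min[i] & rates$mean_temp < bins$t_max[i]
    lab[which(inb)] <- as.character(bins$label[i])
  }
  mutate(rates, bin = factor(lab, levels = levels(bins$label)))
}

# Deterministic, data-driven starting values for tanh P-I fits: the
# primary candidate takes Pmax from the highest observed rate, alpha from
# an OLS line through the 5 lowest-irradiance points and CR from the
# lowest rate; fallback alpha candidates place the saturation onset at the
# irradiance quartiles (the OLS start is singular when the lowest-I points
# are themselves light-saturated).
pi_start_candidates <- function(I, y, include_cr = TRUE) {
  Pmax0 <- max(y)
  if (Pmax0 <= 0) Pmax0 <- max(abs(y)) + 1
  low <- order(I)[seq_len(min(5L, length(I)))]
  alpha_ols <- if (length(low) >= 2 && sd(I[low]) > 0) {
    unname(coef(lm(y[low] ~ I[low]))[2])
  } else NA_real_
  ok <- is.finite(alpha_ols) && alpha_ols > 0 &&
    alpha_ols * max(I) / Pmax0 < 10
  qI <- quantile(I[I > 0], c(0.25, 0.5, 0.75), names = FALSE)
  alphas <- unique(c(if (ok) alpha_ols, Pmax0 / qI,
                     c(0.25, 0.5) * Pmax0 / qI[2], 3 * Pmax0 / max(I)))
  crs <- if (include_cr) unique(c(min(min(y), -1e-3), -1)) else NA
  out <- list()
  for (a in alphas) {
    for (cr in crs) {
      st <- list(Pmax = Pmax0, alpha = a)
      if (include_cr) st$CR <- cr
      out[[length(out) + 1L]] <- st
    }
  }
  out
}

# Try every start candidate with plain least squares and keep the
# lowest-SSE fit; a robust fit then runs the bisquare IRLS from that
# solution. Starting the IRLS anywhere else risks a degenerate basin in
# sparse designs, where the reweighting discounts an entire limb of the
# curve as "outliers".
fit_with_candidates <- function(formula, data, starts, robust, label,
                                lower = NULL, upper = NULL) {
  lhs <- all.vars(formula[[2]])
  errs <- character()
  best <- NULL
  best_score <- Inf
  for (st in starts) {
    res <- tryCatch(irls_nls(formula, data, st, robust = FALSE,
                             lower = lower, upper = upper),
                    error = function(e) conditionMessage(e))
    if (is.character(res)) {
      errs <- c(errs, res)
      next
    }
    r <- data[[lhs]] - predict(res$fit, newdata = data)
    score <- sum(r^2)
    if (score < best_score) {
      best <- res
      best_score <- score
    }
  }
  if (is.null(best)) {
    abort(sprintf("%s did not converge from any start candidate:\n%s", label,
                  paste(sprintf("  start %d: %s", seq_along(errs), errs),
                        collapse = "\n")))
  }
  if (!robust) return(best)
  irls_nls(formula, data, as.list(coef(best$fit)), robust = TRUE,
           lower = lower, upper = upper)
}

# Tukey bisquare weights for residuals r at tuning constant c.
bisquare_weights <- function(r, c = 4.685) {
  s <- median(abs(r)) / 0.6745
  if (s <= .Machine$double.eps) return(rep(1, length(r)))
  u <- r / (c * s)
  w <- (1 - u^2)^2
  w[abs(u) >= 1] <- 0
  w
}

# Iteratively-reweighted nonlinear least squares around nlsLM.
# Box constraints keep unidentified directions (e.g. a light-saturated
# bin's Pmax/CR ridge) from diverging. Returns the final nls object and
# the final weights.
irls_nls <- function(formula, data, start, robust = TRUE, c = 4.685,
                     tol = 1e-8, max_iter = 100L,
                     lower = NULL, upper = NULL) {
  nm <- names(start)
  lo <- if (is.null(lower)) rep(-Inf, length(nm)) else unname(lower[nm])
  up <- if (is.null(upper)) rep(Inf, length(nm)) else unname(upper[nm])
  fit_once <- function(w, start) {
    d <- data
    d$.w <- w
    st <- pmin(pmax(unlist(start), lo), up)
    minpack.lm::nlsLM(formula, data = d, start = as.list(st), weights = .w,
                      lower = lo, upper = up,
                      control = minpack.lm::nls.lm.control(maxiter = 200))
  }
  lhs <- all.vars(formula[[2]])
  w <- rep(1, nrow(data))
  fit <- fit_once(w, start)
  if (!robust) return(list(fit = fit, weights = w, iterations = 0L))
  old <- coef(fit)
  for (it in seq_len(max_iter)) {
    r <- data[[lhs]] - predict(fit, newdata = data) # unweighted residuals
    w <- bisquare_weights(r, c)
    if (all(w == 0)) abort("Robust fit degenerated: all weights are zero.")
    fit <- fit_once(w, as.list(coef(fit)))
    new <- coef(fit)
    rel <- max(abs(new - old) / pmax(abs(old), 1e-10))
    old <- new
    if (rel < tol) return(list(fit = fit, weights = w, iterations = it))
  }
  warn("Robust IRLS did not converge within `max_iter` iterations.")
  list(fit = fit, weights = w, iterations = max_iter)
}

#' Fit a P-I curve to rates within one temperature bin
#'
#' Fits `NCP = Pmax * tanh(alpha * I / Pmax) + CR` (or the 2-parameter
#' variant without `CR`) by nonlinear least squares, optionally
#' iteratively reweighted with Tukey bisquare weights (tuning constant
#' 4.685, convergence when the maximum relative coefficient change drops
#' below 1e-8). Coefficient standard errors come from the final weighted
#' fit; `rmse` is `sqrt(SSE / (n - p))` on unweighted residuals.
#'
#' @param rates Tibble with columns `mean_par` (irradiance context) and
#'   `slope` (areal rate, mmol O2 m-2 h-1).
#' @param bin Optional single-row bin definition (label and range kept as
#'   metadata; also sets the default for `include_cr`).
#' @param robust Use bisquare IRLS (default) or plain least squares.
#' @param include_cr Fit the respiration intercept `CR`? Defaults to the
#'   bin's `fit_cr` flag, or `TRUE` without a bin.
#' @return Object of class `pi_fit`.
#' @export
fit_pi_bin <- function(rates, bin = NULL, robust = TRUE, include_cr = NULL) {
  include_cr <- include_cr %||% (if (!is.null(bin)) isTRUE(bin$fit_cr) else TRUE)
  need <- if (include_cr) 5L else 3L
  df <- tibble(I = rates$mean_par, y = rates$slope)
  df <- filter(df, is.finite(.data$I), is.finite(.data$y))
  if (nrow(df) < need) {
    abort(sprintf("Need at least %d rates for a %d-coefficient fit, got %d.",
                  need, if (include_cr) 3L else 2L, nrow(df)))
  }
  fml <- if (include_cr) {
    y ~ Pmax * tanh(alpha * I / Pmax) + CR
  } else {
    y ~ Pmax * tanh(alpha * I / Pmax)
  }
  starts <- pi_start_candidates(df$I, df$y, include_cr)
  # Box constraints: Pmax > 0, alpha > 0, CR <= 0. The Pmax ceiling is
  # physical, not cosmetic: since max(y) <= Pmax + CR and min(y) >= CR,
  # Pmax cannot exceed ~the observed rate range. Without it, sparse or
  # offset data admit a degenerate line basin (Pmax -> Inf, alpha -> 0)
  # with competitive SSE; the intercept-free variant is especially prone
  # because a respiration offset makes its observable curve convex.
  sc <- max(abs(df$y))
  p_up <- if (include_cr) {
    1.5 * max(max(df$y) - min(df$y), 1e-2)
  } else {
    2 * max(max(df$y), 1e-2)
  }
  res <- fit_with_candidates(fml, df, starts, robust, "P-I bin fit",
                             lower = c(Pmax = 1e-2, alpha = 1e-5,
                                       CR = -10 * sc),
                             upper = c(Pmax = p_up, alpha = 1e3, CR = 0))
  fit <- res$fit
  cf <- coef(fit)
  p <- length(cf)
  r <- df$y - predict(fit, newdata = df)
  new_pi_fit(
    coefficients = cf, vcov = vcov(fit),
    n = nrow(df), rmse = sqrt(sum(r^2) / (nrow(df) - p)),
    bin = bin, robust = robust, include_cr = include_cr,
    weights = res$weights, iterations = res$iterations,
    data = df, nls = fit
  )
}

new_pi_fit <- function(...) {
  structure(list(...), class = "pi_fit")
}

#' Fit P-I curves for every populated temperature bin
#'
#' @param rates Light rate estimates with `mean_temp`, `mean_par`, `slope`.
#' @param bins Bin definitions ([temperature_bins()]).
#' @param robust Passed to [fit_pi_bin()].
#' @param min_n Minimum rates per bin; emptier bins are skipped with a
#'   message.
#' @return Named list of `pi_fit` objects (one per populated bin).
#' @export
fit_pi_bins <- function(rates, bins = temperature_bins(), robust = TRUE,
                        min_n = NULL) {
  binned <- assign_bins(rates, bins)
  out <- list()
  for (i in seq_len(nrow(bins))) {
    lab <- as.character(bins$label[i])
    sub <- filter(binned, !is.na(.data$bin), .data$bin == lab)
    need <- min_n %||% (if (bins$fit_cr[i]) 5L else 3L)
    if (nrow(sub) < need) {
      inform(sprintf("Bin '%s': only %d rates (< %d), skipped.",
                     lab, nrow(sub), need))
      next
    }
    out[[lab]] <- fit_pi_bin(sub, bin = bins[i, ], robust = robust)
  }
  out
}

#' @export
print.pi_fit <- function(x, ...) {
  lab <- if (!is.null(x$bin)) sprintf(" [%s, %.1f-%.1f degC]",
                                      x$bin$label, x$bin$t_min, x$bin$t_max) else ""
  cat(sprintf("<pi_fit>%s n = %d, rmse = %.3f%s\n", lab, x$n, x$rmse,
              if (x$robust) ", robust" else ""))
  print(round(coef(x), 4))
  invisible(x)
}

#' @export
coef.pi_fit <- function(object, ...) object$coefficients

#' @export
vcov.pi_fit <- function(object, ...) object$vcov

#' @export
predict.pi_fit <- function(object, newdata = NULL, ...) {
  I <- if (is.null(newdata)) object$data$I else newdata$I
  cf <- coef(object)
  pi_tanh(I, cf[["Pmax"]], cf[["alpha"]],
          if (object$include_cr) cf[["CR"]] else 0)
}

#' Compensation irradiance of a fitted P-I curve
#'
#' The irradiance at which the P-I curve crosses zero (photosynthesis
#' balances respiration): `Ic = (Pmax / alpha) * atanh(-CR / Pmax)`.
#' Standard error by the delta method from the coefficient covariance.
#' Undefined (returned as `NA` with a message) when `CR >= 0`, since the
#' curve then never crosses zero from below.
#'
#' @param fit A `pi_fit` with a respiration intercept.
#' @return Tibble with columns `ic` and `se`
#'   (mmol photons m-2 h-1).
#' @export
compensation_irradiance <- function(fit) {
  stopifnot(inherits(fit, "pi_fit"))
  if (!fit$include_cr) {
    inform("Fit has no respiration intercept; compensation irradiance undefined.")
    return(tibble(ic = NA_real_, se = NA_real_))
  }
  cf <- coef(fit)
  Pmax <- cf[["Pmax"]]; alpha <- cf[["alpha"]]; CR <- cf[["CR"]]
  if (CR == 0) {
    # boundary case: the curve crosses zero exactly at the origin
    V <- vcov(fit)
    return(tibble(ic = 0, se = sqrt(V["CR", "CR"]) / alpha))
  }
  if (CR > 0) {
    inform("CR > 0: curve never crosses zero from below; Ic undefined.")
    return(tibble(ic = NA_real_, se = NA_real_))
  }
  if (abs(CR) >= Pmax) {
    inform("|CR| >= Pmax: curve never reaches zero; Ic undefined.")
    return(tibble(ic = NA_real_, se = NA_real_))
  }
  q <- -CR / Pmax
  ic <- (Pmax / alpha) * atanh(q)
  g <- c(Pmax = atanh(q) / alpha + CR / (alpha * Pmax) / (1 - q^2),
         alpha = -ic / alpha,
         CR = -1 / (alpha * (1 - q^2)))
  V <- vcov(fit)[c("Pmax", "alpha", "CR"), c("Pmax", "alpha", "CR")]
  tibble(ic = ic, se = sqrt(drop(t(g) %*% V %*% g)))
}

#' Fit the temperature-modified P-I model
#'
#' Nonlinear least squares over `(I, T)` pairs for [temp_pi()]. Reports
#' coefficient table, covariance, `rmse`, and an F-type statistic against
#' the constant-mean null model,
#' `F = ((TSS - RSS) / (p - 1)) / (RSS / (n - p))`.
#' Warns when the fitted respiration term `Rd` is not significant and when
#' fitted `Pmax` does not exceed the observed temperature range (in which
#' case the `Pmax - T` factor degenerates within the data).
#'
#' @param rates Light rate estimates with `mean_par`, `mean_temp`, `slope`;
#'   needs `n >= 10` spanning at least two temperature bins.
#' @param form Model reading, see [temp_pi()].
#' @param robust Optional bisquare IRLS (plain least squares by default,
#'   matching the aggregate-model fitting).
#' @param bins Bin definitions used only for the span check.
#' @return Object of class `temp_pi_fit`.
#' @export
fit_temp_pi <- function(rates, form = c("shifted", "scaled"), robust = FALSE,
                        bins = temperature_bins()) {
  form <- match.arg(form)
  df <- tibble(I = rates$mean_par, temp = rates$mean_temp, y = rates$slope)
  df <- filter(df, is.finite(.data$I), is.finite(.data$temp), is.finite(.data$y))
  if (nrow(df) < 10L) {
    abort(sprintf("Need at least 10 rates, got %d.", nrow(df)))
  }
  span <- assign_bins(rename(df, mean_temp = "temp"), bins)
  if (length(unique(stats::na.omit(span$bin))) < 2L &&
      diff(range(df$temp)) < 1) {
    abort("Rates must span at least two temperature bins.")
  }
  starts <- lapply(pi_start_candidates(df$I, df$y, include_cr = TRUE),
                   function(st) list(Pmax = st$Pmax + median(df$temp),
                                     alpha = st$alpha, Rd = st$CR))
  fml <- if (form == "shifted") {
    y ~ (Pmax - temp) * tanh((alpha * I - temp) / Pmax) + Rd
  } else {
    y ~ (Pmax - temp) * tanh(alpha * I / (Pmax - temp)) + Rd
  }
  sc <- max(abs(df$y)) + max(abs(df$temp))
  res <- fit_with_candidates(fml, df, starts, robust,
                             "Temperature-modified fit",
                             lower = c(Pmax = 1e-2, alpha = 1e-5,
                                       Rd = -20 * sc),
                             upper = c(Pmax = 50 * sc, alpha = 1e3,
                                       Rd = 20 * sc))
  fit <- res$fit
  cf <- coef(fit)
  p <- length(cf)
  n <- nrow(df)
  r <- df$y - predict(fit, newdata = df)
  rss <- sum(r^2)
  tss <- sum((df$y - mean(df$y))^2)
  fstat <- ((tss - rss) / (p - 1)) / (rss / (n - p))
  se <- sqrt(diag(vcov(fit)))
  tval <- cf / se
  pval <- 2 * stats::pt(-abs(tval), df = n - p)
  if (pval[["Rd"]] > 0.05) {
    warn(sprintf("Respiration term Rd is not significant (p = %.3f).",
                 pval[["Rd"]]))
  }
  if (cf[["Pmax"]] <= max(df$temp)) {
    warn("Fitted Pmax does not exceed the observed temperature range; the (Pmax - T) factor degenerates within the data.")
  }
  structure(list(
    coefficients = cf, vcov = vcov(fit), se = se, t = tval, p.value = pval,
    n = n, rmse = sqrt(rss / (n - p)), f.statistic = fstat,
    f.p.value = stats::pf(fstat, p - 1, n - p, lower.tail = FALSE),
    form = form, robust = robust, weights = res$weights,
    data = df, nls = fit
  ), class = "temp_pi_fit")
}

#' @export
print.temp_pi_fit <- function(x, ...) {
  cat(sprintf("<temp_pi_fit: %s form> n = %d, rmse = %.3f, F = %.1f\n",
              x$form, x$n, x$rmse, x$f.statistic))
  print(round(cbind(estimate = x$coefficients, se = x$se, t = x$t,
                    p = x$p.value), 4))
  invisible(x)
}

#' @export
coef.temp_pi_fit <- function(object, ...) object$coefficients

#' @export
vcov.temp_pi_fit <- function(object, ...) object$vcov

#' Predict NCP with a delta-method confidence interval
#'
#' Evaluates a fitted temperature-modified model at new `(I, T)` points and
#' attaches a normal-approximation confidence interval propagated from the
#' coefficient covariance.
#'
#' @param object A `temp_pi_fit`.
#' @param newdata Tibble/data frame with columns `I` (or `mean_par`/`par`)
#'   and `temp` (or `mean_temp`/`temperature`).
#' @param level Confidence level (default 0.95).
#' @return Tibble with `fit`, `se`, `lwr`, `upr`.
#' @export
predict_with_ci <- function(object, newdata, level = 0.95) {
  stopifnot(inherits(object, "temp_pi_fit"))
  nm <- names(newdata)
  I <- newdata[[intersect(c("I", "mean_par", "par"), nm)[1]]]
  temp <- newdata[[intersect(c("temp", "mean_temp", "temperature"), nm)[1]]]
  if (is.null(I) || is.null(temp)) {
    abort("`newdata` must provide irradiance (I/par) and temperature columns.")
  }
  cf <- coef(object)
  fitv <- temp_pi(I, temp, cf[["Pmax"]], cf[["alpha"]], cf[["Rd"]],
                  form = object$form)
  G <- temp_pi_grad(I, temp, cf[["Pmax"]], cf[["alpha"]], cf[["Rd"]],
                    form = object$form)
  V <- vcov(object)[colnames(G), colnames(G)]
  se <- sqrt(pmax(rowSums((G %*% V) * G), 0))
  z <- qnorm(1 - (1 - level) / 2)
  tibble(fit = fitv, se = se, lwr = fitv - z * se, upr = fitv + z * se)
}

#' @rdname predict_with_ci
#' @param ... Unused.
#' @export
predict.temp_pi_fit <- function(object, newdata = NULL, level = 0.95, ...) {
  if (is.null(newdata)) {
    newdata <- tibble(I = object$data$I, temp = object$data$temp)
  }
  predict_with_ci(object, newdata, level = level)
}

#' @export
tidy.pi_fit <- function(x, ...) {
  cf <- coef(x)
  se <- sqrt(diag(vcov(x)))
  tval <- cf / se
  tibble(term = names(cf), estimate = unname(cf), std.error = unname(se),
         statistic = unname(tval),
         p.value = unname(2 * stats::pt(-abs(tval), df = x$n - length(cf))))
}

#' @export
glance.pi_fit <- function(x, ...) {
  tibble(nobs = x$n, rmse = x$rmse, robust = x$robust,
         bin = if (!is.null(x$bin)) as.character(x$bin$label) else NA_character_)
}

#' @export
tidy.temp_pi_fit <- function(x, ...) {
  tibble(term = names(x$coefficients), estimate = unname(x$coefficients),
         std.error = unname(x$se), statistic = unname(x$t),
         p.value = unname(x$p.value))
}

#' @export
glance.temp_pi_fit <- function(x, ...) {
  tibble(nobs = x$n, rmse = x$rmse, statistic = x$f.statistic,
         p.value = x$f.p.value, form = x$form)
}
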