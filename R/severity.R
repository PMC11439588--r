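#' Hours above a temperature threshold
#'
#' Counts hourly samples strictly above `threshold`; with hourly cadence
#' each sample is one hour of exceedance. Non-hourly series are an error
#' (resample upstream).
#'
#' @param temp_series Tibble with `timestamp` and a temperature column
#'   (`temperature`/`temp`/`value`), or a plain numeric vector (assumed
#'   hourly).
#' @param threshold Exceedance threshold (degC), default 11.
#' @return Number of hours (integer).
#' @export
hours_above <- function(temp_series, threshold = 11) {
  x <- severity_values(temp_series)
  sum(x > threshold, na.rm = TRUE)
}

severity_values <- function(temp_series) {
  if (is.numeric(temp_series)) return(temp_series)
  check_hourly(temp_series$timestamp)
  nm <- names(temp_series)
  temp_series[[intersect(c("temperature", "temp", "value"), nm)[1]]]
}

#' Cumulative heatwave severity
#'
#' For each hour with temperature strictly above the threshold, the
#' exceedance is `T - threshold`. Exceedance episodes are maximal runs of
#' consecutive exceedance hours; within each episode the running sum of
#' exceedances is accumulated (degC h). With `per_hour = TRUE` the running
#' sum is divided by the elapsed episode duration in hours (a mean
#' exceedance reading of the severity index); both definitions are
#' otherwise identical and the default reports the raw running sum.
#'
#' @inheritParams hours_above
#' @param per_hour Divide the running sum by elapsed episode hours.
#' @return Tibble with one row per exceedance hour: `episode` (id),
#'   `hour_in_episode`, `exceedance` (degC) and `cumulative` (the running
#'   severity). Empty (zero rows) when nothing exceeds the threshold.
#' @export
cumulative_severity <- function(temp_series, threshold = 11,
                                per_hour = FALSE) {
  x <- severity_values(temp_series)
  over <- !is.na(x) & x > threshold
  if (!any(over)) {
    return(tibble(episode = integer(), hour_in_episode = integer(),
                  exceedance = numeric(), cumulative = numeric()))
  }
  r <- rle(over)
  ep_id <- rep(cumsum(r$values), r$lengths) # episode counter on TRUE runs
  idx <- which(over)
  out <- tibble(episode = ep_id[idx], exceedance = x[idx] - threshold) %>%
    group_by(.data$episode) %>%
    mutate(hour_in_episode = dplyr::row_number(),
           cumulative = cumsum(.data$exceedance)) %>%
    ungroup()
  if (per_hour) {
    out <- mutate(out, cumulative = .data$cumulative / .data$hour_in_episode)
  }
  select(out, "episode", "hour_in_episode", "exceedance", "cumulative")
}

#' Relative-frequency histogram of severity values
#'
#' Bins the running severity values and reports the percentage of values
#' per bin; percentages sum to 100.
#'
#' @param values Numeric severity values (e.g. the `cumulative` column of
#'   [cumulative_severity()]).
#' @param bin_width Bin width (same units as `values`).
#' @param origin Left edge of the first bin.
#' @return Tibble with `bin_lo`, `bin_hi`, `bin_mid`, `count`,
#'   `rel_freq` (percent).
#' @export
severity_histogram <- function(values, bin_width = 10, origin = 0) {
  if (bin_width <= 0) abort("`bin_width` must be > 0.")
  values <- values[is.finite(values)]
  if (length(values) == 0L) {
    return(tibble(bin_lo = numeric(), bin_hi = numeric(),
                  bin_mid = numeric(), count = integer(),
                  rel_freq = numeric()))
  }
  b <- floor((values - origin) / bin_width)
  tab <- table(b)
  lo <- origin + as.numeric(names(tab)) * bin_width
  tibble(bin_lo = lo, bin_hi = lo + bin_width, bin_mid = lo + bin_width / 2,
         count = as.integer(tab),
         rel_freq = as.numeric(tab) / length(values) * 100) %>%
    arrange(.data$bin_lo)
}

#' Severity summary for one temperature series
#'
#' @inheritParams cumulative_severity
#' @param bin_width Histogram bin width (severity units).
#' @return List of class `severity_summary`: `threshold`, `hours_above`,
#'   `cumulative` (per-hour tibble), `histogram`.
#' @export
severity_summary <- function(temp_series, threshold = 11, per_hour = FALSE,
                             bin_width = 10) {
  cum <- cumulative_severity(temp_series, threshold, per_hour = per_hour)
  structure(list(
    threshold = threshold,
    hours_above = hours_above(temp_series, threshold),
    cumulative = cum,
    histogram = severity_histogram(cum$cumulative, bin_width)
  ), class = "severity_summary")
}

#' @export
print.severity_summary <- function(x, ...) {
  cat(sprintf("<severity_summary> threshold %.1f degC: %d h above, %d episode(s)\n",
              x$threshold, x$hours_above,
              length(unique(x$cumulative$episode))))
  invisible(x)
}
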