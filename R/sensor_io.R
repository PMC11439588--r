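#' Sensor file dialect
#'
#' Declares how delimited sensor files are laid out: delimiter, timestamp
#' format/zone, and the measurement units per variable. Units are always
#' declared, never inferred.
#'
#' @param delim Field delimiter.
#' @param time_format Timestamp format string (strptime codes; `%OS`
#'   accepts fractional seconds).
#' @param tz Time zone of the timestamps.
#' @param units Named character vector of units per variable.
#' @return A list of class `sensor_dialect`.
#' @export
sensor_dialect <- function(delim = ",",
                           time_format = "%Y-%m-%dT%H:%M:%OSZ",
                           tz = "UTC",
                           units = c(O2 = "umol_L", temperature = "C",
                                     salinity = "psu", PAR = "mmol_m2_h")) {
  structure(list(delim = delim, time_format = time_format, tz = tz,
                 units = units), class = "sensor_dialect")
}

#' Read a sensor series from a delimited text file
#'
#' Expects two columns, `timestamp` and `value`, in the declared dialect.
#' Blank lines are skipped with a warning; rows whose timestamp or value
#' fail to parse raise an error naming the offending line numbers, as do
#' non-monotonic timestamps. The returned series carries an all-true
#' `qc` mask.
#'
#' @param path File path.
#' @param dialect A [sensor_dialect()].
#' @param variable Optional variable name used to attach the declared unit.
#' @return Tibble with columns `timestamp`, `value`, `qc`; the unit (if
#'   known) is attached as attribute `"units"`.
#' @export
read_sensor_series <- function(path, dialect = sensor_dialect(),
                               variable = NULL) {
  if (!file.exists(path)) abort(sprintf("File not found: %s", path))
  lines <- readr::read_lines(path)
  if (length(lines) == 0L) abort(sprintf("Empty file: %s", path))
  blank <- which(!nzchar(trimws(lines)))
  if (length(blank) > 0L) {
    warn(sprintf("%s: skipped %d blank line(s) at line(s) %s.",
                 basename(path), length(blank),
                 paste(utils::head(blank, 5L), collapse = ", ")))
  }
  keep <- setdiff(seq_along(lines), blank)
  body <- lines[keep]
  lineno <- keep
  # header row
  header <- strsplit(body[1], dialect$delim, fixed = TRUE)[[1]]
  has_header <- !grepl("^[0-9]", trimws(header[1]))
  if (has_header) {
    body <- body[-1]
    lineno <- lineno[-1]
  }
  parts <- strsplit(body, dialect$delim, fixed = TRUE)
  nfield <- lengths(parts)
  bad <- which(nfield < 2L)
  if (length(bad) > 0L) {
    abort(sprintf("%s: malformed row(s) at line(s) %s (need 2 fields).",
                  basename(path),
                  paste(utils::head(lineno[bad], 10L), collapse = ", ")))
  }
  ts_raw <- vapply(parts, `[[`, character(1), 1L)
  val_raw <- vapply(parts, `[[`, character(1), 2L)
  ts <- as.POSIXct(ts_raw, format = dialect$time_format, tz = dialect$tz)
  bad_ts <- which(is.na(ts))
  if (length(bad_ts) > 0L) {
    abort(sprintf("%s: unparseable timestamp(s) at line(s) %s.",
                  basename(path),
                  paste(utils::head(lineno[bad_ts], 10L), collapse = ", ")))
  }
  val <- suppressWarnings(as.numeric(val_raw))
  bad_v <- which(is.na(val) & !(trimws(val_raw) %in% c("NA", "NaN")))
  if (length(bad_v) > 0L) {
    abort(sprintf("%s: unparseable value(s) at line(s) %s.",
                  basename(path),
                  paste(utils::head(lineno[bad_v], 10L), collapse = ", ")))
  }
  if (any(diff(as.numeric(ts)) <= 0)) {
    first <- which(diff(as.numeric(ts)) <= 0)[1]
    abort(sprintf("%s: timestamps not strictly increasing (line %d).",
                  basename(path), lineno[first + 1L]))
  }
  out <- tibble(timestamp = ts, value = val, qc = TRUE)
  if (!is.null(variable) && variable %in% names(dialect$units)) {
    attr(out, "units") <- unname(dialect$units[[variable]])
  }
  out
}

#' Write a sensor series to a delimited text file
#'
#' @param series Tibble with `timestamp` and `value`.
#' @param path Output path.
#' @param dialect A [sensor_dialect()].
#' @return `path`, invisibly.
#' @export
write_sensor_series <- function(series, path, dialect = sensor_dialect()) {
  ts <- format(lubridate::with_tz(series$timestamp, dialect$tz),
               format = dialect$time_format)
  lines <- c(paste("timestamp", "value", sep = dialect$delim),
             paste(ts, formatC(series$value, format = "g", digits = 10),
                   sep = dialect$delim))
  readr::write_lines(lines, path)
  invisible(path)
}

# Grouping helper: apply a per-series function within mesocosm/variable
# groups when those identifier columns are present.
by_series <- function(series, fn) {
  keys <- intersect(c("mesocosm_id", "variable"), names(series))
  if (length(keys) == 0L) return(fn(series))
  series %>%
    group_by(across(all_of(keys))) %>%
    dplyr::group_modify(~ fn(.x)) %>%
    ungroup()
}

#' Percentile outlier filter
#'
#' Masks samples whose values fall strictly outside the empirical
#' `[lo, hi]` quantiles (type-7, linear interpolation). Quantiles are
#' computed from all finite values of the series -- not just currently
#' retained ones -- so the filter is idempotent. Values are never altered,
#' only the `qc` mask. Applied per mesocosm/variable group when those
#' columns are present.
#'
#' @param series Sensor tibble with `value` and `qc` columns.
#' @param lo,hi Quantile thresholds, `0 <= lo < hi <= 1`.
#' @return The series with an updated `qc` mask.
#' @export
filter_percentile <- function(series, lo = 0.001, hi = 0.995) {
  if (!(lo >= 0 && lo < hi && hi <= 1)) {
    abort("Need 0 <= lo < hi <= 1.")
  }
  by_series(series, function(df) {
    v <- df$value
    qs <- quantile(v[is.finite(v)], c(lo, hi), names = FALSE, type = 7)
    keep <- is.finite(v) & v >= qs[1] & v <= qs[2]
    new_qc <- df$qc & keep
    if (!any(new_qc)) abort("Percentile filter masked every sample (degenerate series).")
    mutate(df, qc = new_qc)
  })
}

#' Interquartile-range outlier filter
#'
#' Masks samples strictly outside the Tukey-style fence
#' `[Q1 - k * IQR, Q3 + k * IQR]` with quartiles by linear interpolation
#' (type 7), computed from all finite values so the filter is idempotent.
#'
#' @param series Sensor tibble with `value` and `qc` columns.
#' @param k Fence multiplier, > 0 (1.2 for the irradiance screening).
#' @param by_day Compute fences within each calendar day instead of over
#'   the whole series. Recommended for strongly diel variables such as
#'   irradiance, where pooled fences flag real midday values on bright
#'   days rather than sensor errors.
#' @return The series with an updated `qc` mask.
#' @export
filter_iqr <- function(series, k = 1.2, by_day = FALSE) {
  if (k <= 0) abort("`k` must be > 0.")
  if (by_day) {
    day <- as.Date(series$timestamp, tz = "UTC")
    out <- series %>%
      mutate(.day = day) %>%
      group_by(.data$.day) %>%
      dplyr::group_modify(~ filter_iqr(.x, k = k, by_day = FALSE)) %>%
      ungroup() %>%
      select(-".day")
    return(out[names(series)])
  }
  by_series(series, function(df) {
    if (sum(df$qc & is.finite(df$value)) < 4L) {
      abort("IQR filter needs at least 4 retained samples.")
    }
    v <- df$value
    qs <- quantile(v[is.finite(v)], c(0.25, 0.75), names = FALSE, type = 7)
    iqr <- qs[2] - qs[1]
    keep <- is.finite(v) & v >= qs[1] - k * iqr & v <= qs[2] + k * iqr
    mutate(df, qc = df$qc & keep)
  })
}

#' Apply a single-point offset calibration
#'
#' Shifts every value by `offset` (series units) and records the applied
#' calibration in the `"calibration"` attribute.
#'
#' @param series Sensor tibble with a `value` column.
#' @param offset Calibration offset, in the series' units.
#' @return The calibrated series.
#' @export
apply_offset <- function(series, offset) {
  out <- mutate(series, value = .data$value + offset)
  attr(out, "calibration") <- c(attr(series, "calibration"), offset)
  out
}

#' Replace a broken series by the mean of two replicate donors
#'
#' From `from_time` onwards, values of the broken series are replaced by
#' the per-timestamp mean of the two donor replicate series; a `filled`
#' column flags the provenance of every sample. The donors must provide
#' every needed timestamp.
#'
#' @param series_broken The series to repair.
#' @param donor1,donor2 Aligned replicate series (tibbles with
#'   `timestamp`, `value`).
#' @param from_time Replace samples at or after this time.
#' @return The repaired series with a logical `filled` column.
#' @export
fill_replicate <- function(series_broken, donor1, donor2, from_time) {
  idx <- series_broken$timestamp >= from_time
  need <- series_broken$timestamp[idx]
  m1 <- match(as.numeric(need), as.numeric(donor1$timestamp))
  m2 <- match(as.numeric(need), as.numeric(donor2$timestamp))
  if (anyNA(m1) || anyNA(m2)) {
    missing_at <- need[is.na(m1) | is.na(m2)]
    abort(sprintf("Donor series missing %d needed timestamp(s), first: %s.",
                  length(missing_at), format(missing_at[1])))
  }
  out <- mutate(series_broken, filled = idx)
  out$value[idx] <- (donor1$value[m1] + donor2$value[m2]) / 2
  out$qc[idx] <- TRUE
  out
}

#' Hourly means of retained samples
#'
#' Averages retained (`qc`) samples within each half-open hourly window
#' `[t, t + 1h)`. Windows with no retained samples yield `NA`.
#'
#' @param series Sensor tibble with `timestamp`, `value`, `qc`.
#' @return Tibble with `timestamp` (hour start), `value` (mean of retained
#'   samples) and `n` (retained sample count).
#' @export
hourly_mean <- function(series) {
  series %>%
    mutate(hour = lubridate::floor_date(.data$timestamp, "hour")) %>%
    group_by(.data$hour) %>%
    summarise(
      value = if (any(.data$qc & is.finite(.data$value))) {
        mean(.data$value[.data$qc & is.finite(.data$value)])
      } else NA_real_,
      n = sum(.data$qc & is.finite(.data$value)),
      .groups = "drop"
    ) %>%
    rename(timestamp = "hour")
}
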