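# Shared fixtures, generated once per test run.
.fixtures <- new.env(parent = emptyenv())

default_experiment <- function() {
  if (is.null(.fixtures$exp)) {
    .fixtures$exp <- generate_experiment(experiment_config())
  }
  .fixtures$exp
}

default_analysis <- function() {
  if (is.null(.fixtures$res)) {
    .fixtures$res <- suppressMessages(suppressWarnings(
      run_analyze(pipeline_config(), experiment = default_experiment(),
                  quiet = TRUE)))
  }
  .fixtures$res
}

# A minute-cadence sensor series starting at UTC midnight.
make_series <- function(values, start = as.POSIXct("2022-06-30", tz = "UTC"),
                        by_s = 60, qc = TRUE) {
  tibble::tibble(
    timestamp = start + (seq_along(values) - 1) * by_s,
    value = values,
    qc = rep_len(qc, length(values))
  )
}

# Independent type-7 quantile (linear interpolation between order stats).
quantile7 <- function(x, p) {
  x <- sort(x)
  h <- (length(x) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Low-irradiance design (logger scale of the original incubations) used
# in the recovery studies.
design_I34 <- rep(c(5, 10, 15, 25, 40, 60, 80, 100, 110, 120),
                  length.out = 34)
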