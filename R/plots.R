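#' @export
autoplot.pi_fit <- function(object, ...) {
  cf <- coef(object)
  grid <- tibble(I = seq(0, max(object$data$I) * 1.05, length.out = 200))
  grid$fit <- predict(object, newdata = grid)
  lab <- if (!is.null(object$bin)) {
    sprintf("%s (%.1f-%.1f degC)", object$bin$label, object$bin$t_min,
            object$bin$t_max)
  } else "P-I fit"
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$I, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::labs(
      x = "PAR (mmol photons m⁻² h⁻¹)",
      y = "NCP (mmol O₂ m⁻² h⁻¹)",
      title = lab,
      subtitle = sprintf("Pmax = %.2f, alpha = %.3f%s", cf[["Pmax"]],
                         cf[["alpha"]],
                         if (object$include_cr)
                           sprintf(", CR = %.2f", cf[["CR"]]) else "")
    )
}

#' @export
autoplot.temp_pi_fit <- function(object, temps = NULL, ...) {
  temps <- temps %||% quantile(object$data$temp, c(0.1, 0.5, 0.9), names = FALSE)
  grid <- tidyr::expand_grid(I = seq(0, max(object$data$I) * 1.05,
                                     length.out = 150),
                             temp = round(temps, 1))
  pred <- predict_with_ci(object, grid)
  grid <- dplyr::bind_cols(grid, pred)
  ggplot2::ggplot(grid, ggplot2::aes(x = .data$I, colour = factor(.data$temp),
                                     fill = factor(.data$temp))) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lwr, ymax = .data$upr),
                         alpha = 0.15, colour = NA) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_point(data = object$data,
                        ggplot2::aes(x = .data$I, y = .data$y),
                        inherit.aes = FALSE, alpha = 0.4) +
    ggplot2::labs(
      x = "PAR (mmol photons m⁻² h⁻¹)",
      y = "NCP (mmol O₂ m⁻² h⁻¹)",
      colour = "Temp (degC)", fill = "Temp (degC)",
      title = "Temperature-modified P-I model"
    )
}

#' Accumulated-production comparison plot
#'
#' @param accumulation Accumulation table from [run_analyze()] (columns
#'   `treatment`, `accumulated`, `ci_low`, `ci_high`).
#' @return A ggplot object.
#' @export
plot_accumulation <- function(accumulation) {
  ggplot2::ggplot(accumulation,
                  ggplot2::aes(x = .data$treatment, y = .data$accumulated)) +
    ggplot2::geom_col(fill = "steelblue", width = 0.6) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high), width = 0.2) +
    ggplot2::labs(x = NULL,
                  y = "Accumulated NCP (mmol O₂ m⁻²)",
                  title = "Accumulated net community production (95% MC CI)")
}

#' Severity relative-frequency plot
#'
#' @param severity Named list of `severity_summary` objects (per
#'   treatment), as returned by [run_analyze()].
#' @return A ggplot object.
#' @export
plot_severity <- function(severity) {
  df <- bind_rows(lapply(names(severity), function(tr) {
    mutate(severity[[tr]]$histogram, treatment = tr)
  }))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_mid, y = .data$rel_freq)) +
    ggplot2::geom_col(fill = "firebrick", width = df$bin_hi[1] - df$bin_lo[1]) +
    ggplot2::facet_wrap(~treatment) +
    ggplot2::labs(x = "Cumulative severity (degC h)",
                  y = "Relative frequency (%)",
                  title = "Cumulative heatwave severity")
}
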