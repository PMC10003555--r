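#' Plot a design sheet as a segment map
#'
#' Draws the per-step segments along the transcript, coloured by step, with
#' the terminator U-tract boundary (terminated product size) marked.
#'
#' @param object A [design_sheet()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plor_design
#' @export
autoplot.plor_design <- function(object, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df) +
    ggplot2::geom_segment(
      ggplot2::aes(x = .data$start, xend = .data$end,
                   y = factor(.data$step), yend = factor(.data$step),
                   colour = .data$included),
      linewidth = 4
    ) +
    ggplot2::labs(x = "transcript position (nt)", y = "PLOR step",
                  colour = "NTPs supplied") +
    ggplot2::theme_minimal()
  tl <- attr(object, "terminated_length")
  if (!is.na(tl)) {
    p <- p + ggplot2::geom_vline(xintercept = tl + 0.5, linetype = "dashed")
  }
  p
}

#' Plot per-condition termination statistics
#'
#' Mean termination efficiency per condition with +/- one standard deviation
#' error bars.
#'
#' @param object A [summarize_bands()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plor_quant
#' @export
autoplot.plor_quant <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$mean_efficiency)) +
    ggplot2::geom_col(fill = "grey70", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_efficiency - .data$sd_efficiency,
                   ymax = .data$mean_efficiency + .data$sd_efficiency),
      width = 0.15, na.rm = TRUE
    ) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "termination efficiency T / (T + FL)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted step-yield model
#'
#' Observed overall yields against the post-initiation step count `n`, with
#' the fitted curve `E = Ei * Ee^n`.
#'
#' @param object A [fit_yield_params()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot plor_yield_fit
#' @export
autoplot.plor_yield_fit <- function(object, ...) {
  grid <- tibble(
    n = seq(min(object$data$n), max(object$data$n), length.out = 100),
    E = object$Ei * object$Ee^seq(min(object$data$n), max(object$data$n),
                                  length.out = 100)
  )
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$n, y = .data$E)) +
    ggplot2::geom_line(data = grid, colour = "steelblue") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "post-initiation steps n", y = "overall yield E",
                  subtitle = sprintf("Ei = %.3f, Ee = %.3f", object$Ei, object$Ee)) +
    ggplot2::theme_minimal()
}
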