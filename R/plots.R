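#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Kaplan-Meier step plot
#'
#' @param object a `km_curve` from [km_estimate()].
#' @param conf show the pointwise confidence band.
#' @param ... unused.
#' @return a ggplot.
#' @method autoplot km_curve
#' @export
autoplot.km_curve <- function(object, conf = TRUE, ...) {
  td <- tidy(object)
  td0 <- dplyr::bind_rows(
    dplyr::distinct(td, .data$group) |>
      dplyr::mutate(time = 0, estimate = 1, conf.low = 1, conf.high = 1),
    td)
  p <- ggplot2::ggplot(td0, ggplot2::aes(x = .data$time, y = .data$estimate,
                                         colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "Months", y = "Overall survival", colour = NULL) +
    ggplot2::theme_minimal()
  if (conf) {
    p <- p + ggplot2::geom_step(ggplot2::aes(y = .data$conf.low),
                                linetype = 3, na.rm = TRUE) +
      ggplot2::geom_step(ggplot2::aes(y = .data$conf.high),
                         linetype = 3, na.rm = TRUE)
  }
  p
}

#' Covariate-balance (love) plot
#'
#' @param balance a [match_diagnostics()] table.
#' @param threshold reference line for the usual |SMD| = 0.1 convention.
#' @return a ggplot.
#' @export
plot_balance <- function(balance, threshold = 0.1) {
  long <- tidyr::pivot_longer(balance, c("smd_before", "smd_after"),
                              names_to = "stage", values_to = "smd") |>
    dplyr::mutate(stage = ifelse(.data$stage == "smd_before",
                                 "before matching", "after matching"))
  ggplot2::ggplot(long, ggplot2::aes(x = abs(.data$smd), y = .data$covariate,
                                     shape = .data$stage)) +
    ggplot2::geom_vline(xintercept = threshold, linetype = 2, colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "|standardized mean difference|", y = NULL, shape = NULL) +
    ggplot2::theme_minimal()
}
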