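# ggplot2 views of the profiling surfaces.

#' Bar chart of annual report counts
#'
#' @param annual tibble from [annual_distribution()].
#' @return a ggplot object.
#' @export
plot_annual_distribution <- function(annual) {
  dat <- dplyr::filter(annual, !is.na(.data$year))
  ggplot2::ggplot(dat, ggplot2::aes(
    x = factor(.data$year), y = .data$n, fill = .data$source
  )) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "receipt year", y = "reports", fill = "source") +
    ggplot2::theme_minimal()
}

#' Bar chart of system-organ-class report counts
#'
#' @param soc tibble from [soc_distribution()].
#' @return a ggplot object.
#' @export
plot_soc_distribution <- function(soc) {
  ggplot2::ggplot(soc, ggplot2::aes(
    x = .data$n, y = stats::reorder(.data$soc, .data$n)
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "reports", y = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of time-to-onset bins
#'
#' @param object a `pv_onset` from [time_to_onset()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pv_onset <- function(object, ...) {
  ggplot2::ggplot(object$bins, ggplot2::aes(x = .data$bin, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "days from therapy start to onset", y = "reports") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
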