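#' @importFrom ggplot2 autoplot ggplot aes geom_line geom_point labs
#'   theme_minimal geom_col facet_wrap geom_vline scale_x_continuous
#' @export
ggplot2::autoplot

#' Plot a temporal DNI curve
#'
#' Line plot of the dynamic network index per stage with the peak (putative
#' pre-disease tipping point) highlighted.
#'
#' @param object a `dnb_dni`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dnb_dni <- function(object, ...) {
  df <- as_tibble(object)
  ggplot(df, aes(x = .data$stage, y = .data$dni)) +
    geom_line(color = "grey40") +
    geom_point(size = 2) +
    geom_point(data = df[df$stage == peak_stage(object), ],
               color = "red", size = 3) +
    scale_x_continuous(breaks = df$stage) +
    labs(x = "temporal stage", y = "DNI = exp(-CE)",
         title = sprintf("DNI curve (peak at stage %d)", peak_stage(object))) +
    theme_minimal()
}

#' Plot per-stage outlier-score distributions
#'
#' @param object a `dnb_anomalies`.
#' @param ... unused.
#' @return A ggplot object (scores per scored stage; selected anomaly genes
#'   in red).
#' @export
autoplot.dnb_anomalies <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = factor(.data$stage), y = .data$score)) +
    ggplot2::geom_jitter(aes(color = .data$hit), width = 0.2, size = 0.8,
                         alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(`FALSE` = "grey60", `TRUE` = "red"),
                                name = "anomaly") +
    labs(x = "scored stage", y = "outlier score") +
    theme_minimal()
}

#' Plot temporal classification metrics per split
#'
#' @param object a `dnb_classification`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.dnb_classification <- function(object, ...) {
  df <- object$per_split |>
    tidyr::pivot_longer(-"split", names_to = "metric")
  ggplot(df, aes(x = factor(.data$split), y = .data$value)) +
    geom_col(fill = "steelblue") +
    facet_wrap(~metric) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    labs(x = "temporal split point s (stages <= s vs > s)", y = NULL) +
    theme_minimal()
}
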