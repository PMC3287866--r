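#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot association results
#'
#' -log10 p-value per tested unit, faceted by scope when per-family results
#' are present; untestable units are omitted from the panel.
#'
#' @param object A `famqls_assoc` tibble.
#' @param threshold Reference significance line (default 0.05).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot famqls_assoc
#' @export
autoplot.famqls_assoc <- function(object, threshold = 0.05, ...) {
  df <- object[object$status == "ok", , drop = FALSE]
  df$marker_id <- factor(df$marker_id, levels = unique(object$marker_id))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$marker_id,
                                        y = -log10(.data$p_value))) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$test)) +
    ggplot2::geom_hline(yintercept = -log10(threshold), linetype = "dashed") +
    ggplot2::labs(x = NULL, y = expression(-log[10](italic(p)))) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
  if (length(unique(object$scope)) > 1L) {
    p <- p + ggplot2::facet_wrap(ggplot2::vars(.data$scope))
  }
  p
}

#' Plot a power table
#'
#' @param object A `famqls_power` tibble.
#' @param ... Unused.
#' @return A ggplot bar chart of power per unit.
#' @method autoplot famqls_power
#' @export
autoplot.famqls_power <- function(object, ...) {
  df <- object
  df$marker_id <- factor(df$marker_id, levels = unique(df$marker_id))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$marker_id, y = .data$power,
                                   fill = .data$test)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = "power (proportion of replicates)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot the carrier-family distribution
#'
#' Histogram of how many families carry each variant, in the 0 / 1 / 2 / 3+
#' bins.
#'
#' @param object A `famqls_famdist` tibble from [family_distribution()].
#' @param ... Unused.
#' @return A ggplot bar chart.
#' @method autoplot famqls_famdist
#' @export
autoplot.famqls_famdist <- function(object, ...) {
  bins <- carrier_family_bins(object)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$bin, y = .data$n_markers)) +
    ggplot2::geom_col() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_markers), vjust = -0.4) +
    ggplot2::labs(x = "families carrying the variant", y = "number of variants") +
    ggplot2::theme_minimal()
}
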