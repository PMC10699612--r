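#' Plot a raster layer
#'
#' @param object An [raster_layer()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rc_raster
#' @export
autoplot.rc_raster <- function(object, ...) {
  df <- as_tibble.rc_raster(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey85") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = object$name, x = "x (m)", y = "y (m)",
                  fill = object$name) +
    ggplot2::theme_minimal()
}

#' Plot a variable ranking
#'
#' Bar chart of the weighted scores of the top-ranked variables, annotated
#' with correlation group ids when present.
#'
#' @param object A `rsfsa_ranking` tibble.
#' @param n_top Number of variables shown.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot rsfsa_ranking
#' @export
autoplot.rsfsa_ranking <- function(object, n_top = 20, ...) {
  df <- utils::head(dplyr::arrange(object, .data$rank), n_top)
  df$label <- if ("correlation_group" %in% names(df))
    paste0(df$variable, " [", df$correlation_group, "]") else df$variable
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score,
                                   y = stats::reorder(.data$label, -.data$rank))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "weighted score (0.6 importance + 0.4 frequency)",
                  y = NULL, title = "Variable ranking") +
    ggplot2::theme_minimal()
}

#' Plot consensus ensemble maps
#'
#' Frequency-of-consensus surface with optional core/semi-core contours.
#'
#' @param object An `ensemble_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ensemble_result
#' @export
autoplot.ensemble_result <- function(object, ...) {
  df <- as_tibble.rc_raster(object$consensus)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradientn(
      colours = c("grey90", "khaki", "orange", "red"),
      limits = c(0, object$n_members)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = sprintf("Consensus of %d calibrated models",
                                  object$n_members),
                  fill = "models\nagreeing", x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Plot a marginal response curve
#'
#' @param model A `maxent_fit`.
#' @param variable Variable name.
#' @param n Curve resolution.
#' @return A ggplot.
#' @export
plot_marginal_response <- function(model, variable, n = 100) {
  df <- marginal_response(model, variable, n = n)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$response)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::labs(x = variable, y = "cloglog suitability",
                  title = paste("Marginal response:", variable)) +
    ggplot2::theme_minimal()
}
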