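# ggplot2 methods for the fitted objects.

.contribution_palette <- c(
  red = "#d73027", red_orange = "#f46d43", orange = "#fdae61",
  gray_white = "#bdbdbd", yellow = "#ffd92f", green_blue = "#66c2a5",
  green = "#1a9850"
)

#' @rdname autoplot-hqsar
#' @param type `"fit"` for observed vs fitted training activities,
#'   `"lengths"` for the per-length q2 profile.
#' @export
autoplot.hqsar_model <- function(object, type = c("fit", "lengths"), ...) {
  type <- match.arg(type)
  if (type == "lengths") {
    return(
      ggplot2::ggplot(object$per_length,
                      ggplot2::aes(x = factor(.data$length), y = .data$q2)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::labs(x = "hologram length", y = expression(q^2),
                      title = "LOO predictivity across the length catalogue") +
        ggplot2::theme_minimal()
    )
  }
  df <- object$train
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pic50, y = .data$fitted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(colour = "steelblue") +
    ggplot2::labs(x = "observed pIC50", y = "fitted pIC50",
                  title = sprintf("Training fit (L = %d, %d components)",
                                  object$length, object$pls$ncomp)) +
    ggplot2::theme_minimal()
}

#' Plots for hologram QSAR objects
#'
#' `autoplot()` methods: training fit or length profile for a model,
#' observed-versus-predicted for an external validation, and a per-atom
#' contribution chart coloured with the conventional red-to-green bands.
#'
#' @param object A fitted `hqsar_model`, `hqsar_validation` or
#'   `hqsar_contribution` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @name autoplot-hqsar
NULL

#' @rdname autoplot-hqsar
#' @export
autoplot.hqsar_validation <- function(object, ...) {
  df <- object$residuals
  ggplot2::ggplot(df, ggplot2::aes(x = .data$actual, y = .data$predicted)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         colour = "grey50") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(
      x = "observed pIC50", y = "predicted pIC50",
      title = sprintf("External validation (r2_pred = %.3f)",
                      object$r2_pred$r2_pred)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot-hqsar
#' @export
autoplot.hqsar_contribution <- function(object, ...) {
  df <- as_tibble(object)
  df$atom_label <- paste0(df$element, df$atom)
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$atom_label, .data$atom),
    y = .data$value, fill = .data$color
  )) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = .contribution_palette,
                               drop = FALSE, name = "band") +
    ggplot2::labs(x = "atom", y = "contribution to pIC50",
                  title = "Atomic contribution map") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
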